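test_that("latin hypercube sampling stratifies every dimension", {
  s <- lhs_sample(sampling_config(4, seed = 7))
  expect_equal(dim(s), c(4L, 12L))
  breaks <- seq(0.5, 2.0, length.out = 5)
  for (d in 1:12) {
    counts <- table(cut(s[, d], breaks, include.lowest = TRUE))
    expect_true(all(counts == 1))
  }
  one <- lhs_sample(sampling_config(1, seed = 3))
  expect_true(all(one >= 0.5 & one <= 2.0))
  expect_identical(lhs_sample(sampling_config(10, seed = 5)),
                   lhs_sample(sampling_config(10, seed = 5)))
})

test_that("an all-ones sample reproduces the baseline control biomarkers", {
  m <- purkinje_model()
  base <- setNames(rep(1, 12), current_ids())
  cand <- build_candidates(m, rbind(base), prepace_beats = 40)
  expect_length(cand$members, 1)
  st <- prepace_to_steady_state(m, n_beats = 40, frequency = 1)
  ref <- compute_biomarkers(pace(m, st, pacing_protocol(1, 1))$trace)
  expect_equal(cand$members[[1]]$biomarkers$APD90, ref$APD90, tolerance = 1e-6)
  expect_equal(cand$members[[1]]$biomarkers$dVdtMax, ref$dVdtMax, tolerance = 1e-6)
})

test_that("candidates over a small sample all carry finite biomarkers", {
  m <- purkinje_model()
  cand <- build_candidates(m, lhs_sample(sampling_config(6, seed = 9)),
                           prepace_beats = 15)
  expect_length(cand$members, 6)
  for (mm in cand$members) {
    expect_true(mm$ok)
    if (mm$abnormal == "none") {
      expect_true(all(is.finite(unlist(mm$biomarkers[c("APD90", "APA", "TOP")]))))
    }
  }
})

test_that("calibration filters by range with explicit reasons", {
  pop <- test_population()
  expect_gt(length(pop$members), 0)
  expect_gt(nrow(pop$exclusions), 0)
  # retained members form a subset in original order
  idx <- vapply(pop$members, function(m) m$index, numeric(1))
  expect_false(is.unsorted(idx, strictly = TRUE))
  # every retained member is inside every range at 1 Hz
  rng <- pop$ranges
  for (m in pop$members) {
    for (b in names(rng)) {
      expect_gte(m$control_biomarkers[["1"]][[b]], rng[[b]][1])
      expect_lte(m$control_biomarkers[["1"]][[b]], rng[[b]][2])
    }
  }
  # reasons name the offending biomarker
  expect_true(all(grepl("out of range|abnormality|solver", pop$exclusions$reason)))
})

test_that("an impossible APD90 window excludes with the right reason", {
  m <- purkinje_model()
  base <- setNames(rep(1, 12), current_ids())
  cand <- build_candidates(m, rbind(base), prepace_beats = 30)
  rng <- default_calibration_ranges()
  rng$APD90 <- c(10, 20)
  pop <- calibrate(m, cand, ranges = rng, extra_frequencies = numeric(0))
  expect_length(pop$members, 0)
  expect_match(pop$exclusions$reason[1], "APD90 out of range")
})

test_that("LHS marginals are uniform by the Kolmogorov-Smirnov criterion", {
  s <- lhs_sample(sampling_config(200, seed = 11))
  crit <- 1.63 / sqrt(200)       # 1% asymptotic critical value
  for (d in 1:12) {
    ks <- suppressWarnings(
      stats::ks.test(s[, d], "punif", min = 0.5, max = 2.0))
    expect_lt(unname(ks$statistic), crit)
  }
})

test_that("populations serialize to CSV plus manifest", {
  pop <- test_population()
  dir <- tempfile()
  write_population(pop, dir)
  df <- read.csv(file.path(dir, "population.csv"))
  expect_equal(nrow(df), length(pop$members))
  expect_named(df, c("index", current_ids()))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_identical(man$hash, pop$hash)
})
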