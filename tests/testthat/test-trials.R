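test_that("zero-dose cells reproduce control and summarize to 0% change", {
  pop <- test_population()
  herg <- drug_spec("probe-herg", c(IKr = 1), concentrations = 1,
                    frequencies = 1, tdp_class = "1")
  tr <- run_drug_trial(pop, herg, n_beats = 5, concentrations = 1,
                       frequencies = 1)
  d <- tr$detail
  ctrl <- d[d$concentration == 0, ]
  expect_equal(nrow(ctrl), length(pop$members))
  for (i in seq_len(nrow(ctrl))) {
    m <- pop$members[[which(vapply(pop$members, function(x) x$index, 1) ==
                            ctrl$member[i])]]
    expect_equal(ctrl$APD90[i], m$control_biomarkers[["1"]]$APD90)
  }
})

test_that("summaries aggregate percent changes over normal members only", {
  # construct a trial result by hand: 4 members, half abnormal at dose
  mk <- function(member, conc, ab, apd90) {
    data.frame(member = member, concentration = conc, frequency = 1,
               abnormal = ab, evaluable = TRUE, repol_failure = FALSE,
               APD10 = 1, APD25 = 2, APD50 = 100, APD75 = 150, APD90 = apd90,
               dVdtMax = 400, APA = 110, TOP = -86, EOP = -86)
  }
  detail <- rbind(
    do.call(rbind, lapply(1:4, function(i) mk(i, 0, "none", 200))),
    mk(1, 1, "none", 220), mk(2, 1, "none", 220),
    { r <- mk(3, 1, "EAD", NA); r }, { r <- mk(4, 1, "EAD", NA); r }
  )
  res <- structure(list(detail = detail, drug = "synthetic",
                        population_hash = "h", manifest = list()),
                   class = "trial_result")
  s <- summarize_trial(res)
  expect_equal(s$table$incidence_pct, 50)
  expect_equal(s$table$pct_APD90, 10)
  expect_equal(s$table$n_evaluable, 4)
})

test_that("identical trial configurations give identical summaries", {
  pop <- test_population()
  herg <- drug_spec("probe-herg", c(IKr = 1), concentrations = 2,
                    frequencies = 1, tdp_class = "1")
  s1 <- summarize_trial(run_drug_trial(pop, herg, n_beats = 5, frequencies = 1))
  s2 <- summarize_trial(run_drug_trial(pop, herg, n_beats = 5, frequencies = 1))
  expect_identical(s1$table, s2$table)
})

test_that("a pure hERG blocker prolongs APD90 dose-dependently", {
  pop <- test_population()
  herg <- drug_spec("probe-herg", c(IKr = 1),
                    concentrations = c(0.5, 1.5, 3), frequencies = 1,
                    tdp_class = "1")
  s <- summarize_trial(run_drug_trial(pop, herg, n_beats = 12, frequencies = 1))
  tab <- s$table[order(s$table$concentration), ]
  ok <- is.finite(tab$pct_APD90)
  expect_true(all(diff(tab$pct_APD90[ok]) > 0))
  expect_true(all(tab$pct_APD90[ok] > 0))
})

test_that("abnormal members contribute no biomarker values", {
  pop <- test_population()
  # near-complete hERG block at slow pacing triggers abnormalities
  herg <- drug_spec("probe-herg", c(IKr = 0.05), concentrations = 3,
                    frequencies = 0.25, tdp_class = "1")
  tr <- run_drug_trial(pop, herg, n_beats = 12, frequencies = 0.25)
  d <- tr$detail
  ab <- d[d$concentration > 0 & d$abnormal != "none", ]
  if (nrow(ab)) expect_true(all(is.na(ab$APD90)))
  expect_gt(nrow(ab), 0)
  s <- summarize_trial(tr)
  expect_gt(s$table$incidence_pct[1], 0)
})

test_that("aggregation refuses summaries from different populations", {
  t1 <- structure(list(table = data.frame(concentration = 1, frequency = 1),
                       drug = "a", population_hash = "h1"), class = "trial_summary")
  t2 <- structure(list(table = data.frame(concentration = 1, frequency = 1),
                       drug = "b", population_hash = "h2"), class = "trial_summary")
  expect_error(bind_summaries(list(t1, t2)), "different populations")
  ok <- bind_summaries(list(t1, structure(modifyList(unclass(t2),
        list(population_hash = "h1")), class = "trial_summary")))
  expect_equal(nrow(ok), 2)
})
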