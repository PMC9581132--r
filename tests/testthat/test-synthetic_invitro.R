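test_that("control cohorts reproduce the configured rabbit statistics", {
  cfg <- fiber_cohort_config(n_fibers = 1000, seed = 4)
  cohort <- generate_fiber_cohort(cfg, frequencies = 1)
  # sample mean within 3 standard errors of the rabbit control mean
  expect_lt(abs(mean(cohort$APD90) - 310), 3 * 52 / sqrt(1000))
  expect_lt(abs(mean(cohort$dVdtMax) - 616), 3 * 72 / sqrt(1000))
  # seeded determinism
  expect_identical(cohort, generate_fiber_cohort(cfg, frequencies = 1))
  # zero SDs collapse every fiber onto the means
  ref <- cfg$reference
  ref$sd <- 0
  cfg0 <- fiber_cohort_config(n_fibers = 5, seed = 1, reference = ref)
  c0 <- generate_fiber_cohort(cfg0, frequencies = 1)
  expect_true(all(c0$APD90 == 310))
  expect_true(all(c0$TOP == -91))
})

test_that("generated cohorts respect physiological truncation bounds", {
  cfg <- fiber_cohort_config(n_fibers = 500, seed = 8)
  cohort <- generate_fiber_cohort(cfg)
  expect_true(all(cohort$APD90 > 0))
  expect_true(all(cohort$APA > 0))
  expect_true(all(cohort$TOP >= -100 & cohort$TOP <= -60))
})

test_that("zero-effect dosing is the identity with no EADs", {
  cfg <- fiber_cohort_config(n_fibers = 8, seed = 2)
  cohort <- generate_fiber_cohort(cfg)
  eff <- synthetic_dose_effect()
  dosed <- apply_dose_effects(cohort, c(1, 10), eff, seed = 3)
  expect_true(all(!dosed$ead_flag))
  base <- dosed[dosed$concentration_um == 1, "APD90"]
  expect_equal(base, cohort$APD90)
})

test_that("an Emax effect reproduces the target mean percent change", {
  cfg <- fiber_cohort_config(n_fibers = 200, seed = 5)
  cohort <- generate_fiber_cohort(cfg, frequencies = 1)
  # rabbit dofetilide-scale prolongation: +113% at a saturating dose
  eff <- synthetic_dose_effect(effects = list(
    APD90 = list(max_pct = 113, ec50 = 0.0005)))
  dosed <- apply_dose_effects(cohort, 0.01, eff, seed = 6, noise_sd = 0.05)
  obs <- percent_change(mean(dosed$APD90), mean(cohort$APD90))
  expect_lt(abs(obs - 113 * 0.01 / 0.0105), 2)
})

test_that("EAD probabilities drive the flags at the slow rate only", {
  cfg <- fiber_cohort_config(n_fibers = 10, seed = 2)
  cohort <- generate_fiber_cohort(cfg, frequencies = c(0.25, 1))
  eff <- synthetic_dose_effect(ead_prob = c("3" = 1.0, "1" = 0))
  dosed <- apply_dose_effects(cohort, c(1, 3), eff, seed = 9)
  top <- dosed[dosed$concentration_um == 3, ]
  expect_true(all(top$ead_flag[top$frequency_hz == 0.25]))
  expect_true(all(!top$ead_flag[top$frequency_hz == 1]))
  expect_true(all(!dosed$ead_flag[dosed$concentration_um == 1]))
})

test_that("synthesized traces round-trip their biomarker targets", {
  tg <- list(TOP = -89, APA = 128, dVdtMax = 616,
             APD10 = 48, APD25 = 120, APD50 = 239, APD75 = 275, APD90 = 310)
  tr <- synthesize_trace(tg, cycle_length = 1000)
  b <- compute_biomarkers(tr)
  expect_equal(b$APD90, 310, tolerance = 3 / 310)
  expect_equal(b$APD50, 239, tolerance = 3 / 239)
  expect_equal(b$APA, 128, tolerance = 0.01)
  expect_equal(b$TOP, -89)
  expect_equal(b$dVdtMax, 616, tolerance = 0.05)
  # a deflection during repolarization is an EAD, one in diastole a DAD
  tr2 <- synthesize_trace(tg, cycle_length = 1000,
                          ead_spec = list(time = 250, amplitude = 15))
  expect_identical(detect_abnormality(tr2), "EAD")
  tr3 <- synthesize_trace(tg, cycle_length = 1000,
                          ead_spec = list(time = 700, amplitude = 12))
  expect_identical(detect_abnormality(tr3), "DAD")
  # unsatisfiable targets
  bad <- tg; bad$APD50 <- 400
  expect_error(synthesize_trace(bad, 1000), "non-decreasing")
  expect_error(synthesize_trace(tg, cycle_length = 320), "cycle")
})

test_that("the bundled study fixtures carry the expected categorical flags", {
  fx <- load_paper_fixtures()
  expect_length(fx$drugs, 14)
  flags <- fx$risk_flags
  expect_equal(nrow(flags), 14)
  truth <- tdp_truth(flags$tdp_class)
  expect_equal(sum(truth == "risky"), 11)
  # rabbit EADs: absent for bepridil, ranolazine, terfenadine; present for
  # the other risky compounds; absent for the three safe ones
  no_ead <- flags$drug[!flags$ead_invitro & truth == "risky"]
  expect_setequal(no_ead, c("bepridil", "ranolazine", "terfenadine"))
  expect_equal(sum(flags$ead_invitro & truth == "risky"), 8)
  expect_true(all(!flags$ead_invitro[truth == "safe"]))
  # in-silico APD90 flags: all risky plus diltiazem and verapamil
  expect_true(all(flags$apd90_insilico[truth == "risky"]))
  expect_setequal(flags$drug[flags$apd90_insilico & truth == "safe"],
                  c("diltiazem", "verapamil"))
})
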