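# Shared fixtures and brute-force oracles for the test suite.

# The analytic piecewise-linear AP fixture: rest -85 mV; linear rise to
# +25 mV over 2 ms; flat plateau to 200 ms; linear fall back to -85 mV at
# 300 ms; diastole to the end of a 1000 ms cycle.
linear_ap_fixture <- function(dt = 0.5, cycle = 1000) {
  t <- seq(0, cycle, by = dt)
  v <- ifelse(t <= 2, -85 + (25 - -85) * t / 2,
       ifelse(t <= 200, 25,
       ifelse(t <= 300, 25 + (-85 - 25) * (t - 200) / 100, -85)))
  ap_trace(t, v, cycle, stimulus_duration = 0, stimulus_amplitude = 0)
}

# random piecewise-linear AP with ordered APD targets, via the package's
# own generator config but with randomized targets
random_ap_targets <- function() {
  apd90 <- runif(1, 150, 450)
  fr <- sort(runif(4, 0.05, 0.95))
  list(TOP = runif(1, -92, -80), APA = runif(1, 90, 130),
       dVdtMax = runif(1, 200, 700),
       APD10 = fr[1] * apd90, APD25 = fr[2] * apd90,
       APD50 = fr[3] * apd90, APD75 = fr[4] * apd90, APD90 = apd90)
}

# Exhaustive sample-scan oracle for APDx: first sample strictly below the
# threshold after the upstroke, no interpolation.  Returns time relative to
# the earliest sample attaining the maximal slope.
oracle_apd <- function(trace, x) {
  t <- trace$time; v <- trace$vm
  dv <- diff(v) / diff(t)
  ipk <- which.max(v)
  up <- seq_len(max(ipk - 1L, 1L))
  iup <- up[which.max(dv[up])]
  peak <- v[ipk]
  thr <- peak - x / 100 * (peak - v[1L])
  above <- which(v >= thr & seq_along(v) >= iup)
  i0 <- above[1L]
  below <- which(v < thr & seq_along(v) > i0)
  if (!length(below)) return(NA_real_)
  t[below[1L]] - t[iup]
}

# reduced-scale population used by several tests (cached per session)
test_population <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) {
      m <- purkinje_model()
      cand <- build_candidates(m, lhs_sample(sampling_config(24, seed = 42)),
                               prepace_beats = 40)
      pop <<- calibrate(m, cand, extra_frequencies = c(0.25, 3), n_beats = 25)
    }
    pop
  }
})
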