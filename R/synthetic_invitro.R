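#' Configuration for a synthetic rabbit Purkinje fiber cohort
#'
#' Emulates the statistical structure of the in-vitro rabbit assay: each
#' fiber's control biomarkers are drawn from truncated normals around the
#' published rabbit control means and SDs per pacing rate.  Only five
#' biomarkers have published rabbit statistics (APD50, APD90, dV/dtMax,
#' APA, TOP); the remaining four (APD10, APD25, APD75, EOP) default to
#' values derived from them and are labelled synthetic.
#'
#' @param n_fibers Fibers in the cohort (wet assay used 4--7 per drug).
#' @param seed Integer seed.
#' @param reference Data frame of control statistics with columns
#'   `biomarker`, `frequency_hz`, `mean`, `sd`; defaults to the bundled
#'   rabbit control table.
#' @return Object of class `fiber_cohort_config`.
#' @export
fiber_cohort_config <- function(n_fibers = 6, seed = 1L, reference = NULL) {
  stopifnot(n_fibers >= 1)
  if (is.null(reference)) {
    ref <- load_control_reference()
    ref <- ref[ref$arm == "rabbit_invitro", c("biomarker", "frequency_hz", "mean", "sd")]
    # synthetic defaults for biomarkers without published rabbit statistics
    extra <- do.call(rbind, lapply(unique(ref$frequency_hz), function(f) {
      a50 <- ref[ref$biomarker == "APD50" & ref$frequency_hz == f, ]
      a90 <- ref[ref$biomarker == "APD90" & ref$frequency_hz == f, ]
      top <- ref[ref$biomarker == "TOP" & ref$frequency_hz == f, ]
      data.frame(
        biomarker = c("APD10", "APD25", "APD75", "EOP"),
        frequency_hz = f,
        mean = c(0.2 * a50$mean, 0.5 * a50$mean,
                 (a50$mean + a90$mean) / 2, top$mean),
        sd = c(0.2 * a50$sd, 0.5 * a50$sd, (a50$sd + a90$sd) / 2, top$sd)
      )
    }))
    reference <- rbind(ref, extra)
  }
  if (any(reference$sd < 0)) stop("SDs must be >= 0")
  structure(list(n_fibers = as.integer(n_fibers), seed = as.integer(seed),
                 reference = reference),
            class = "fiber_cohort_config")
}

#' Bundled control biomarker reference table (both species, three rates)
#'
#' @return Data frame with columns `biomarker`, `arm`, `pacing`,
#'   `frequency_hz`, `mean`, `sd`.
#' @export
load_control_reference <- function() {
  read.csv(system.file("extdata", "control_biomarkers.csv",
                       package = "purkinjetrials", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

# truncated-normal draw by rejection
.pk_rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

.pk_trunc_bounds <- function(biomarker) {
  switch(biomarker,
    TOP = c(-100, -60), EOP = c(-100, -60),
    APA = c(1e-6, Inf), dVdtMax = c(1e-6, Inf),
    c(1e-6, Inf))  # APDs positive
}

#' Generate control biomarkers for a synthetic fiber cohort
#'
#' @param config A [fiber_cohort_config()].
#' @param frequencies Pacing rates (Hz) to generate; default all rates in
#'   the reference table.
#' @return Data frame: `fiber_id`, `frequency_hz`, nine biomarker columns.
#' @export
generate_fiber_cohort <- function(config, frequencies = NULL) {
  stopifnot(inherits(config, "fiber_cohort_config"))
  ref <- config$reference
  if (is.null(frequencies)) frequencies <- sort(unique(ref$frequency_hz))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  rows <- list()
  for (f in frequencies) {
    vals <- sapply(.pk_bio_cols, function(b) {
      r <- ref[ref$biomarker == b & ref$frequency_hz == f, ]
      if (!nrow(r)) stop("no reference statistics for ", b, " at ", f, " Hz")
      tb <- .pk_trunc_bounds(b)
      .pk_rtnorm(config$n_fibers, r$mean[1], r$sd[1], tb[1], tb[2])
    })
    vals <- matrix(vals, nrow = config$n_fibers,
                   dimnames = list(NULL, .pk_bio_cols))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(fiber_id = seq_len(config$n_fibers), frequency_hz = f),
      as.data.frame(vals))
  }
  do.call(rbind, rows)
}

#' Synthetic dose-effect specification
#'
#' Emax-style percent effects per biomarker plus an EAD probability per
#' concentration at the slow rate.  This emulates (not estimates) the
#' in-vitro dose-response so the downstream pipeline can be exercised.
#'
#' @param effects Named list; per biomarker a list with `max_pct`
#'   (asymptotic percent change, signed), `ec50` (uM, > 0) and optional
#'   `hill` (default 1).  Biomarkers not listed are unaffected.
#' @param ead_prob Named numeric vector: EAD probability per concentration
#'   (names = concentration in uM), all in `[0, 1]`.  Applied at the slow
#'   rate only.
#' @return Object of class `synthetic_dose_effect`.
#' @export
synthetic_dose_effect <- function(effects = list(), ead_prob = numeric()) {
  for (b in names(effects)) {
    e <- effects[[b]]
    if (is.null(e$ec50) || e$ec50 <= 0) stop("effect for ", b, " needs ec50 > 0")
    if (is.null(e$hill)) effects[[b]]$hill <- 1
  }
  if (length(ead_prob) && (any(ead_prob < 0) || any(ead_prob > 1))) {
    stop("EAD probabilities must be in [0, 1]")
  }
  structure(list(effects = effects, ead_prob = ead_prob),
            class = "synthetic_dose_effect")
}

#' Apply synthetic dose effects to a control cohort
#'
#' Scales each fiber's control biomarkers by the Emax effect at each
#' concentration (with multiplicative fiber-level noise on the effect) and
#' draws EAD flags at the slow rate from the configured probabilities.
#' Each concentration is treated independently (no carry-over; the wet
#' protocol's 30-min equilibration is assumed complete).
#'
#' @param cohort Control table from [generate_fiber_cohort()].
#' @param concentrations Doses in uM, strictly ascending.
#' @param effect A [synthetic_dose_effect()].
#' @param seed Integer seed.
#' @param noise_sd SD of the multiplicative noise on the percent effect
#'   (e.g. 0.05 for 5%).
#' @return Data frame: `fiber_id`, `concentration_um`, `frequency_hz`,
#'   nine biomarkers, `ead_flag`.
#' @export
apply_dose_effects <- function(cohort, concentrations, effect, seed = 1L,
                               noise_sd = 0.05) {
  stopifnot(inherits(effect, "synthetic_dose_effect"))
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be strictly ascending")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  slow <- min(cohort$frequency_hz)
  rows <- list()
  for (conc in concentrations) {
    dosed <- cohort
    dosed$concentration_um <- conc
    for (b in names(effect$effects)) {
      e <- effect$effects[[b]]
      pct <- e$max_pct * conc^e$hill / (conc^e$hill + e$ec50^e$hill)
      noise <- rnorm(nrow(dosed), 0, noise_sd)
      dosed[[b]] <- dosed[[b]] * (1 + pct / 100 * (1 + noise))
    }
    p <- if (length(effect$ead_prob)) {
      pv <- effect$ead_prob[as.character(conc)]
      if (is.na(pv)) 0 else pv
    } else 0
    dosed$ead_flag <- dosed$frequency_hz == slow &
      runif(nrow(dosed)) < p
    rows[[length(rows) + 1L]] <- dosed
  }
  out <- do.call(rbind, rows)
  out[, c("fiber_id", "concentration_um", "frequency_hz", .pk_bio_cols, "ead_flag")]
}

#' Synthesize an AP trace hitting biomarker targets
#'
#' Builds a piecewise-linear action potential whose computed biomarkers
#' reproduce the requested targets within 1%: a linear upstroke with slope
#' `dVdtMax` from `TOP` to `TOP + APA`, a repolarization profile anchored
#' at the five APDx points, and a tail settling at `EOP`.  Optionally
#' inserts a positive-slope deflection (an EAD/DAD-like event) at a
#' requested time and amplitude.
#'
#' @param targets Named list/vector with `TOP` (mV), `APA` (mV), `dVdtMax`
#'   (V/s) and `APD10` to `APD90` (ms, non-decreasing).  An `EOP` entry is
#'   optional (defaults to `TOP`).
#' @param cycle_length Beat length, ms; must exceed APD90 plus the tail.
#' @param ead_spec Optional list with `time` (ms), `amplitude` (mV) and
#'   optional `width` (ms, default 30) describing the deflection.
#' @param sample_interval Sampling step, ms.
#' @return An [ap_trace()].
#' @export
synthesize_trace <- function(targets, cycle_length = 1000, ead_spec = NULL,
                             sample_interval = 0.1) {
  tg <- as.list(targets)
  apds <- unlist(tg[c("APD10", "APD25", "APD50", "APD75", "APD90")])
  if (anyNA(apds)) stop("targets must include APD10, APD25, APD50, APD75, APD90")
  if (is.unsorted(apds)) stop("APD targets must be non-decreasing")
  if (is.null(tg$EOP)) tg$EOP <- tg$TOP
  tail_ms <- 40
  if (tg$APD90 + tail_ms >= cycle_length) {
    stop("APD90 plus repolarization tail must fit inside the cycle length")
  }
  peak <- tg$TOP + tg$APA
  rise <- tg$APA / tg$dVdtMax          # V/s == mV/ms
  # anchor points: (time, vm); APDx measured from the upstroke foot (the
  # instant of maximal slope on a linear upstroke)
  pts_t <- c(0, rise,
             rise / 2 + apds,          # thresholds crossed mid-slope offset
             rise / 2 + tg$APD90 + tail_ms, cycle_length)
  pts_v <- c(tg$TOP, peak,
             peak - c(10, 25, 50, 75, 90) / 100 * tg$APA,
             tg$EOP, tg$EOP)
  o <- order(pts_t)
  pts_t <- pts_t[o]; pts_v <- pts_v[o]
  keep <- !duplicated(pts_t)
  time <- seq(0, cycle_length, by = sample_interval)
  vm <- approx(pts_t[keep], pts_v[keep], xout = time, rule = 2)$y
  if (!is.null(ead_spec)) {
    w <- if (is.null(ead_spec$width)) 30 else ead_spec$width
    bump <- ead_spec$amplitude *
      0.5 * (1 + cos(pi * (time - ead_spec$time) / (w / 2)))
    bump[abs(time - ead_spec$time) > w / 2] <- 0
    vm <- vm + bump
  }
  ap_trace(time, vm, cycle_length, stimulus_duration = 0, stimulus_amplitude = 0)
}

#' Bundled categorical study outcomes and reference tables
#'
#' Returns the fixture set used by the risk-metric tests: the 14-compound
#' drug library, the control biomarker statistics for both species, and the
#' per-drug categorical outcome flags (whether each arm showed EADs, and
#' whether each arm showed >10% APD90 prolongation) with per-row notes.
#'
#' @return List with `drugs` (list of [drug_spec()]), `control_biomarkers`
#'   (data frame) and `risk_flags` (data frame).
#' @export
load_paper_fixtures <- function() {
  flags <- read.csv(system.file("extdata", "risk_flags.csv",
                                package = "purkinjetrials", mustWork = TRUE),
                    stringsAsFactors = FALSE)
  list(drugs = load_drug_library(),
       control_biomarkers = load_control_reference(),
       risk_flags = flags)
}
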