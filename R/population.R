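#' Latin hypercube sampling configuration
#'
#' @param n_initial Number of candidate models (study protocol: 1000).
#' @param low,high Bounds of the sampled conductance-multiplier range
#'   (study protocol: 0.5 to 2, i.e. 50--200% of baseline).
#' @param seed Integer seed; sampling is reproducible.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(n_initial = 1000, low = 0.5, high = 2.0, seed = 1L) {
  stopifnot(n_initial >= 1, low > 0, low < high)
  structure(list(n_initial = as.integer(n_initial), low = low, high = high,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Latin hypercube sample of conductance scaling factors
#'
#' Draws `n_initial` scaling vectors over the 12 sampled currents.  Each of
#' the 12 dimensions is partitioned into `n_initial` equal bins on
#' `[low, high]`; exactly one sample falls in each bin per dimension,
#' uniformly within the bin.
#'
#' @param config A [sampling_config()].
#' @return Numeric matrix `n_initial x 12` with columns named by
#'   [current_ids()].
#' @export
lhs_sample <- function(config) {
  stopifnot(inherits(config, "sampling_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  u <- lhs::randomLHS(config$n_initial, 12L)
  m <- config$low + (config$high - config$low) * u
  colnames(m) <- current_ids()
  m
}

#' Default calibration ranges for the nine AP biomarkers
#'
#' Acceptance windows applied to control biomarkers at 1 Hz when
#' calibrating a population.  For the five biomarkers with published
#' human references (APD50, APD90, dV/dtMax, APA, TOP) the windows are
#' mean +/- 2 SD of the human in-silico control statistics; windows for
#' APD10, APD25, APD75 and EOP derive from the bundled model's baseline
#' value +/- 50%.  Ranges live in a YAML config file, never in code.
#'
#' @param path YAML file path (defaults to the bundled ranges).
#' @return Named list; each element is `c(min, max)` for one biomarker.
#' @export
default_calibration_ranges <- function(path = system.file(
  "extdata", "calibration_ranges.yaml", package = "purkinjetrials",
  mustWork = TRUE)) {
  x <- yaml::read_yaml(path)
  ranges <- lapply(x, function(r) c(r$min, r$max))
  need <- c("APD10", "APD25", "APD50", "APD75", "APD90",
            "dVdtMax", "APA", "TOP", "EOP")
  miss <- setdiff(need, names(ranges))
  if (length(miss)) stop("calibration ranges missing: ", paste(miss, collapse = ", "))
  bad <- names(ranges)[vapply(ranges, function(r) r[1] >= r[2], logical(1))]
  if (length(bad)) stop("invalid range (min >= max) for: ", paste(bad, collapse = ", "))
  ranges[need]
}

#' Build candidate population members with control biomarkers at 1 Hz
#'
#' Paces each sampled scaling vector to steady state at 1 Hz, computes the
#' nine AP biomarkers on the last beat and screens it for repolarization
#' abnormalities.  Members whose integration fails are recorded as rejected
#' with a reason, not raised as errors.
#'
#' @param model A [purkinje_model()].
#' @param samples Matrix of scaling factors from [lhs_sample()] (or a
#'   single-row matrix / named vector for one candidate).
#' @param prepace_beats Beats of 1 Hz pre-pacing (study protocol: 1000;
#'   reduced-scale runs use fewer).
#' @return Object of class `candidate_set`: list with `members` (per
#'   candidate: `index`, `scalings`, `state_1hz`, `biomarkers`, `abnormal`,
#'   `ok`, `reason`) and `prepace_beats`.
#' @export
build_candidates <- function(model, samples, prepace_beats = 1000) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1,
                                               dimnames = list(NULL, names(samples)))
  stopifnot(ncol(samples) == 12L)
  members <- lapply(seq_len(nrow(samples)), function(i) {
    sc <- scaling_vector(setNames(as.numeric(samples[i, ]), colnames(samples)))
    res <- tryCatch({
      st <- prepace_to_steady_state(model, sc, n_beats = prepace_beats,
                                    frequency = 1)
      beat <- pace(model, st, pacing_protocol(1, 1), scalings = sc)
      ab <- detect_abnormality(beat$trace)
      bm <- if (ab == "none") compute_biomarkers(beat$trace) else NULL
      list(index = i, scalings = sc, state_1hz = beat$state,
           biomarkers = bm, abnormal = ab, ok = TRUE, reason = NA_character_)
    }, purkinje_solver_error = function(e) {
      list(index = i, scalings = sc, state_1hz = NULL, biomarkers = NULL,
           abnormal = NA_character_, ok = FALSE,
           reason = paste0("solver failure: ", conditionMessage(e)))
    })
    res
  })
  structure(list(members = members, prepace_beats = prepace_beats),
            class = "candidate_set")
}

#' Calibrate a candidate population against experimental biomarker ranges
#'
#' Retains candidates whose nine control biomarkers at 1 Hz all fall inside
#' the calibration ranges and that show no repolarization abnormality in
#' control at 1 Hz, at the slow rate, or at 3 Hz.  Calibration is a pure
#' filter: retained members are a subset of the candidates in their
#' original order, and re-calibrating the retained set is the identity.
#'
#' @param model A [purkinje_model()].
#' @param candidates A `candidate_set` from [build_candidates()].
#' @param ranges Calibration ranges ([default_calibration_ranges()]).
#' @param extra_frequencies Control frequencies (Hz) checked for
#'   abnormalities in addition to 1 Hz (study protocol: the slow rate and
#'   3 Hz).
#' @param n_beats Beats paced at each extra frequency (study protocol: 150).
#' @return Object of class `purkinje_population`: `members` (retained, each
#'   with cached control steady states and biomarkers per frequency),
#'   `exclusions` (data frame of index + reason), `ranges`, `frequencies`,
#'   `n_beats`, and a content `hash` that freezes the population.
#' @export
calibrate <- function(model, candidates, ranges = default_calibration_ranges(),
                      extra_frequencies = c(0.25, 3), n_beats = 150) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (!length(candidates$members)) stop("empty candidate list")
  if (!length(ranges)) stop("empty calibration ranges")
  keep <- list()
  excl <- list()
  for (m in candidates$members) {
    if (!isTRUE(m$ok)) {
      excl[[length(excl) + 1L]] <- data.frame(index = m$index, reason = m$reason)
      next
    }
    if (m$abnormal != "none") {
      excl[[length(excl) + 1L]] <- data.frame(
        index = m$index, reason = paste0("control abnormality (", m$abnormal, ") at 1 Hz"))
      next
    }
    out_of_range <- NULL
    for (bm in names(ranges)) {
      val <- m$biomarkers[[bm]]
      if (!is.finite(val) || val < ranges[[bm]][1] || val > ranges[[bm]][2]) {
        out_of_range <- bm
        break
      }
    }
    if (!is.null(out_of_range)) {
      excl[[length(excl) + 1L]] <- data.frame(
        index = m$index, reason = paste0(out_of_range, " out of range"))
      next
    }
    # extra-rate control screening, caching state + biomarkers per frequency
    states <- list("1" = m$state_1hz)
    bios <- list("1" = m$biomarkers)
    bad <- NULL
    for (f in extra_frequencies) {
      res <- tryCatch({
        prot <- pacing_protocol(f, n_beats)
        p <- pace(model, m$state_1hz, prot, scalings = m$scalings)
        ab <- detect_abnormality(p$trace)
        if (ab != "none") {
          list(fail = paste0("control abnormality (", ab, ") at ",
                             f, " Hz pacing"))
        } else {
          list(state = p$state, bio = compute_biomarkers(p$trace))
        }
      }, purkinje_solver_error = function(e) {
        list(fail = paste0("solver failure at ", f, " Hz"))
      })
      if (!is.null(res$fail)) { bad <- res$fail; break }
      states[[as.character(f)]] <- res$state
      bios[[as.character(f)]] <- res$bio
    }
    if (!is.null(bad)) {
      excl[[length(excl) + 1L]] <- data.frame(index = m$index, reason = bad)
      next
    }
    keep[[length(keep) + 1L]] <- list(
      index = m$index, scalings = m$scalings,
      control_states = states, control_biomarkers = bios
    )
  }
  scal_mat <- do.call(rbind, lapply(keep, function(k) as.numeric(k$scalings)))
  structure(
    list(members = keep,
         exclusions = if (length(excl)) do.call(rbind, excl)
                      else data.frame(index = integer(), reason = character()),
         ranges = ranges,
         frequencies = c(1, extra_frequencies),
         n_beats = n_beats,
         model_name = model$name,
         hash = rlang::hash(list(model$conductances, scal_mat))),
    class = "purkinje_population"
  )
}

#' @export
print.purkinje_population <- function(x, ...) {
  cat("<purkinje_population>", length(x$members), "members retained,",
      nrow(x$exclusions), "excluded\n")
  cat("  control frequencies (Hz):", paste(x$frequencies, collapse = ", "), "\n")
  cat("  hash:", x$hash, "\n")
  invisible(x)
}

#' Serialize a population to CSV + JSON manifest
#'
#' Writes one CSV row per member (index + 12 scaling factors) and a JSON
#' manifest (model name, hash, calibration ranges, frequencies).
#'
#' @param population A `purkinje_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- do.call(rbind, lapply(population$members, function(m) {
    data.frame(index = m$index, t(as.numeric(m$scalings)))
  }))
  if (!is.null(df)) colnames(df) <- c("index", current_ids())
  write.csv(df, file.path(dir, "population.csv"), row.names = FALSE)
  manifest <- list(model = population$model_name, hash = population$hash,
                   frequencies = population$frequencies,
                   n_beats = population$n_beats,
                   ranges = population$ranges)
  writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
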