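#' Run an in-silico drug trial on a calibrated population
#'
#' For every member x concentration x frequency cell of the design, applies
#' the drug's pore-block residuals, paces `n_beats` beats from the member's
#' cached control steady state at that frequency, screens the last beat for
#' repolarization abnormalities, and computes the nine AP biomarkers only
#' for normal beats.  Concentration 0 rows reproduce the cached control
#' biomarkers.  Members that fail to repolarize by the end of the last beat
#' are counted as abnormal of kind EAD (logged distinctly in `detail`).
#'
#' @param population A calibrated `purkinje_population` from [calibrate()].
#' @param drug A [drug_spec()].
#' @param model The [purkinje_model()] the population was built from.
#' @param n_beats Drugged beats per cell (study protocol: 150).
#' @param concentrations Tested doses, uM; defaults to the drug's list.
#'   0 is always prepended.
#' @param frequencies Pacing rates, Hz; defaults to the drug's rates
#'   (restricted to the population's control frequencies).
#' @param last_k Abnormality is assessed on the last beat (`last_k = 1`,
#'   default).  Setting `last_k > 1` flags a cell if any of the last k
#'   beats is abnormal, guarding against alternans artifacts.
#' @return Object of class `trial_result`: data frame `detail` with one row
#'   per (member, concentration, frequency), plus `drug`, `population_hash`,
#'   and a `manifest` of thresholds and solver settings.
#' @export
run_drug_trial <- function(population, drug, model = purkinje_model(),
                           n_beats = 150,
                           concentrations = drug$concentrations,
                           frequencies = NULL,
                           last_k = 1L) {
  stopifnot(inherits(population, "purkinje_population"),
            inherits(drug, "drug_spec"))
  if (!length(population$members)) stop("population has no members")
  freqs <- if (is.null(frequencies)) drug$frequencies else frequencies
  known <- as.numeric(names(population$members[[1]]$control_states))
  # a drug's slow rate of 0.2 Hz is matched to the population's slow control
  freqs_used <- vapply(freqs, function(f) {
    if (f %in% known) return(f)
    if (f < 1 && any(known < 1)) return(min(known))
    stop("population carries no control state at ", f, " Hz")
  }, numeric(1))
  concs <- sort(unique(c(0, concentrations)))
  rows <- list()
  for (m in population$members) {
    for (fi in seq_along(freqs_used)) {
      f <- freqs_used[fi]
      fkey <- as.character(f)
      ctrl_bio <- m$control_biomarkers[[fkey]]
      for (conc in concs) {
        if (conc == 0) {
          rows[[length(rows) + 1L]] <- .pk_trial_row(
            m$index, conc, f, "none", ctrl_bio, evaluable = TRUE,
            repol_failure = FALSE)
          next
        }
        blk <- block_set(drug, conc)
        cell <- tryCatch({
          prot <- pacing_protocol(f, max(n_beats - last_k + 1L, 1L))
          p <- pace(model, m$control_states[[fkey]], prot,
                    scalings = m$scalings, block = blk)
          ab <- detect_abnormality(p$trace)
          trace <- p$trace
          if (last_k > 1L) {
            for (k in seq_len(last_k - 1L)) {
              if (ab != "none") break
              p <- pace(model, p$state, pacing_protocol(f, 1),
                        scalings = m$scalings, block = blk)
              trace <- p$trace
              ab <- detect_abnormality(trace)
            }
          }
          repol_fail <- FALSE
          if (ab == "none" && trace$vm[length(trace$vm)] > -70) {
            ab <- "EAD"            # repolarization failure counts as EAD
            repol_fail <- TRUE
          }
          bio <- if (ab == "none") compute_biomarkers(trace) else NULL
          .pk_trial_row(m$index, conc, f, ab, bio, evaluable = TRUE,
                        repol_failure = repol_fail)
        }, purkinje_solver_error = function(e) {
          .pk_trial_row(m$index, conc, f, NA_character_, NULL,
                        evaluable = FALSE, repol_failure = FALSE)
        })
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  structure(
    list(detail = do.call(rbind, rows),
         drug = drug$name,
         population_hash = population$hash,
         manifest = list(n_beats = n_beats, last_k = last_k,
                         abnormality = list(window_start_ms = 150,
                                            slope_threshold_Vps = 0.01,
                                            repolarized_level_mV = -70),
                         solver = list(rtol = 1e-6, atol = 1e-8,
                                       sample_interval_ms = 0.05),
                         eop_definition = "vm at end of beat window")),
    class = "trial_result"
  )
}

.pk_bio_cols <- c("APD10", "APD25", "APD50", "APD75", "APD90",
                  "dVdtMax", "APA", "TOP", "EOP")

.pk_trial_row <- function(index, conc, freq, abnormal, bio, evaluable,
                          repol_failure) {
  vals <- setNames(rep(NA_real_, 9L), .pk_bio_cols)
  if (!is.null(bio)) vals[] <- unlist(bio[.pk_bio_cols])
  cbind(
    data.frame(member = index, concentration = conc, frequency = freq,
               abnormal = abnormal, evaluable = evaluable,
               repol_failure = repol_failure, stringsAsFactors = FALSE),
    as.data.frame(as.list(vals))
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>", x$drug, ":", nrow(x$detail), "cells on population",
      substr(x$population_hash, 1, 8), "\n")
  invisible(x)
}

#' Summarize a drug trial
#'
#' Per (concentration, frequency) cell: the mean percent change of each
#' biomarker relative to the same member's control (computed over members
#' with no abnormality at that cell), the abnormality incidence as a
#' percentage of the population, and the number of evaluable members.
#'
#' @param result A `trial_result` from [run_drug_trial()].
#' @return Object of class `trial_summary`: data frame with columns
#'   `concentration`, `frequency`, `n_evaluable`, `n_abnormal`,
#'   `incidence_pct` and `pct_<biomarker>` mean-change columns.
#' @export
summarize_trial <- function(result) {
  stopifnot(inherits(result, "trial_result"))
  d <- result$detail
  cells <- unique(d[d$concentration > 0, c("concentration", "frequency")])
  if (!nrow(cells)) stop("trial contains no drugged cells")
  out <- lapply(seq_len(nrow(cells)), function(i) {
    conc <- cells$concentration[i]; f <- cells$frequency[i]
    cell <- d[d$concentration == conc & d$frequency == f, ]
    ctrl <- d[d$concentration == 0 & d$frequency == f, ]
    ev <- cell[cell$evaluable, ]
    n_ab <- sum(ev$abnormal != "none")
    normal <- ev[ev$abnormal == "none", ]
    pct <- setNames(rep(NA_real_, 9L), paste0("pct_", .pk_bio_cols))
    if (nrow(normal)) {
      ctrl_match <- ctrl[match(normal$member, ctrl$member), ]
      for (b in .pk_bio_cols) {
        pct[paste0("pct_", b)] <- mean(percent_change(normal[[b]], ctrl_match[[b]]))
      }
    }
    cbind(data.frame(concentration = conc, frequency = f,
                     n_evaluable = nrow(ev), n_abnormal = n_ab,
                     incidence_pct = 100 * n_ab / max(nrow(ev), 1L)),
          as.data.frame(as.list(pct)))
  })
  structure(
    list(table = do.call(rbind, out), drug = result$drug,
         population_hash = result$population_hash,
         manifest = result$manifest),
    class = "trial_summary"
  )
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("<trial_summary>", x$drug, "\n")
  print(x$table[, c("concentration", "frequency", "incidence_pct",
                    "pct_APD90", "pct_APD50", "pct_dVdtMax")], digits = 3)
  invisible(x)
}

#' Bind summaries of several drugs, refusing mixed populations
#'
#' All drug trials must run on exactly one frozen population; this helper
#' verifies the population hashes match before aggregating.
#'
#' @param summaries List of `trial_summary` objects.
#' @return Data frame with a `drug` column prepended.
#' @export
bind_summaries <- function(summaries) {
  hashes <- unique(vapply(summaries, function(s) s$population_hash, character(1)))
  if (length(hashes) > 1L) {
    stop("summaries come from different populations; refusing to aggregate")
  }
  do.call(rbind, lapply(summaries, function(s) {
    cbind(data.frame(drug = s$drug, stringsAsFactors = FALSE), s$table)
  }))
}
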