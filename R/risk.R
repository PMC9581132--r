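#' Risk-classification configuration
#'
#' @param apd90_threshold Mean APD90 prolongation (percent) above which a
#'   drug is flagged risky (preclinical convention: 10).
#' @param apd90_frequency Pacing rate (Hz) at which the APD90 rule is
#'   evaluated (default 1 Hz).
#' @param consistency_tolerance Percent difference separating strong from
#'   qualitative agreement between arms (default 15).
#' @return Object of class `risk_config`.
#' @export
risk_config <- function(apd90_threshold = 10, apd90_frequency = 1,
                        consistency_tolerance = 15) {
  stopifnot(apd90_threshold > 0, consistency_tolerance > 0)
  structure(list(apd90_threshold = apd90_threshold,
                 apd90_frequency = apd90_frequency,
                 consistency_tolerance = consistency_tolerance),
            class = "risk_config")
}

#' Map a CredibleMeds torsade class to the binary truth
#'
#' Classes 1 (known risk) and 2 (conditional risk) are risky; NC (not
#' classified) is safe.
#'
#' @param tdp_class `"1"`, `"2"` or `"NC"` (vectorized).
#' @return `"risky"` or `"safe"`.
#' @export
tdp_truth <- function(tdp_class) {
  ifelse(tdp_class %in% c("1", "2"), "risky", "safe")
}

#' Classify a drug by drug-induced repolarization abnormalities
#'
#' A drug is risky if it induces a repolarization abnormality in at least
#' one model at any tested concentration at the drug's slow pacing rate,
#' and safe if every model fully repolarized at every dose.
#'
#' @param summary A `trial_summary` from [summarize_trial()], or any data
#'   frame with columns `concentration`, `frequency`, `incidence_pct`.
#' @param slow_rate Slow pacing rate (Hz) used for the drug; defaults to
#'   the smallest sub-1-Hz frequency present.
#' @param truth Optional `"risky"`/`"safe"` truth (from [tdp_truth()]).
#' @return Object of class `risk_call`: list with `drug`, `metric = "EAD"`,
#'   `prediction` and `truth`.
#' @export
classify_by_abnormality <- function(summary, slow_rate = NULL, truth = NA_character_) {
  tab <- if (inherits(summary, "trial_summary")) summary$table else summary
  drug <- if (inherits(summary, "trial_summary")) summary$drug else NA_character_
  if (is.null(slow_rate)) {
    slow <- tab$frequency[tab$frequency < 1]
    if (!length(slow)) stop("no slow-rate (< 1 Hz) cells in summary")
    slow_rate <- min(slow)
  }
  cells <- tab[tab$frequency == slow_rate, ]
  if (!nrow(cells)) stop("no cells at the slow rate ", slow_rate, " Hz")
  pred <- if (any(cells$incidence_pct > 0)) "risky" else "safe"
  structure(list(drug = drug, metric = "EAD", prediction = pred, truth = truth),
            class = "risk_call")
}

#' Classify a drug by mean APD90 prolongation
#'
#' A drug is risky if its mean APD90 percent change exceeds the threshold
#' (strictly) at any tested concentration at the configured rate.
#'
#' @param summary A `trial_summary` (or data frame with `concentration`,
#'   `frequency` and `pct_APD90`).
#' @param config A [risk_config()].
#' @param truth Optional truth label.
#' @return A `risk_call` with `metric = "APD90"`.
#' @export
classify_by_apd90 <- function(summary, config = risk_config(), truth = NA_character_) {
  tab <- if (inherits(summary, "trial_summary")) summary$table else summary
  drug <- if (inherits(summary, "trial_summary")) summary$drug else NA_character_
  cells <- tab[tab$frequency == config$apd90_frequency, ]
  if (!nrow(cells)) stop("no cells at ", config$apd90_frequency, " Hz")
  vals <- cells$pct_APD90[is.finite(cells$pct_APD90)]
  pred <- if (length(vals) && max(vals) > config$apd90_threshold) "risky" else "safe"
  structure(list(drug = drug, metric = "APD90", prediction = pred, truth = truth),
            class = "risk_call")
}

#' Confusion matrix and accuracy of a set of risk calls
#'
#' @param calls List of `risk_call` objects (or a data frame with columns
#'   `prediction` and `truth`).
#' @return List with `TP`, `FP`, `TN`, `FN`, `n` and `accuracy_pct`
#'   (accuracy rounded half-up to an integer percent).
#' @export
confusion_and_accuracy <- function(calls) {
  if (is.data.frame(calls)) {
    pred <- calls$prediction; truth <- calls$truth
  } else {
    if (!length(calls)) stop("empty call list")
    pred <- vapply(calls, function(c) c$prediction, character(1))
    truth <- vapply(calls, function(c) c$truth, character(1))
  }
  if (!length(pred)) stop("empty call list")
  if (any(is.na(pred)) || any(is.na(truth))) stop("calls must carry prediction and truth")
  tp <- sum(pred == "risky" & truth == "risky")
  fp <- sum(pred == "risky" & truth == "safe")
  tn <- sum(pred == "safe" & truth == "safe")
  fn <- sum(pred == "safe" & truth == "risky")
  n <- length(pred)
  list(TP = tp, FP = fp, TN = tn, FN = fn, n = n,
       accuracy_pct = floor(100 * (tp + tn) / n + 0.5))
}

#' Three-level consistency between in-silico and in-vitro percent changes
#'
#' Strong agreement if both means share the trend (sign) and differ by at
#' most `tolerance` percentage points; qualitative agreement if the trend
#' matches but the difference exceeds the tolerance; disagreement if the
#' trends differ.  An exact 0 agrees in trend with either sign.
#'
#' @param insilico_pct,invitro_pct Mean percent changes (finite scalars).
#' @param tolerance Percentage-point tolerance (default 15; the boundary
#'   value counts as strong agreement).
#' @return One of `"strong"`, `"qualitative"`, `"disagreement"`.
#' @export
consistency_category <- function(insilico_pct, invitro_pct, tolerance = 15) {
  stopifnot(is.finite(insilico_pct), is.finite(invitro_pct))
  same_trend <- insilico_pct == 0 || invitro_pct == 0 ||
    sign(insilico_pct) == sign(invitro_pct)
  if (!same_trend) return("disagreement")
  if (abs(insilico_pct - invitro_pct) <= tolerance) "strong" else "qualitative"
}
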