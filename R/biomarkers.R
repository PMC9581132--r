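#' Single-beat action potential trace
#'
#' @param time Sample times in ms, strictly increasing, starting at 0
#'   (stimulus onset).
#' @param vm Membrane voltage per sample, mV.
#' @param cycle_length Beat cycle length, ms.
#' @param stimulus_duration Stimulus pulse duration, ms.
#' @param stimulus_amplitude Stimulus amplitude in pA/pF (= mV/ms on a
#'   unit-capacitance membrane).  When non-zero, the known stimulus
#'   contribution is subtracted from voltage slopes inside the pulse window
#'   so dV/dtMax reflects ionic current only.
#' @return An object of class `ap_trace`.
#' @export
ap_trace <- function(time, vm, cycle_length,
                     stimulus_duration = 1.0, stimulus_amplitude = 0) {
  stopifnot(length(time) == length(vm), length(time) >= 50)
  if (time[1] != 0) stop("trace must start at stimulus onset (time[1] == 0)")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(
    list(time = as.numeric(time), vm = as.numeric(vm),
         cycle_length = cycle_length,
         stimulus_duration = stimulus_duration,
         stimulus_amplitude = stimulus_amplitude),
    class = "ap_trace"
  )
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("<ap_trace>", length(x$time), "samples over", round(max(x$time), 1),
      "ms; Vm in [", round(min(x$vm), 1), ",", round(max(x$vm), 1), "] mV\n")
  invisible(x)
}

# forward-difference slopes in mV/ms (== V/s), with the stimulus-current
# contribution removed inside the pulse window
.pk_slopes <- function(trace) {
  t <- trace$time; v <- trace$vm
  dv <- diff(v) / diff(t)
  if (trace$stimulus_amplitude != 0) {
    # fraction of each forward interval overlapping the pulse
    t0 <- t[-length(t)]; t1 <- t[-1L]
    ov <- pmax(0, pmin(t1, trace$stimulus_duration) - pmin(t0, trace$stimulus_duration))
    dv <- dv - trace$stimulus_amplitude * ov / (t1 - t0)
  }
  dv
}

#' Compute the nine AP biomarkers from a single-beat trace
#'
#' TOP is the voltage at stimulus onset; dV/dtMax the maximal
#' forward-difference slope during the upstroke (V/s; earliest sample
#' attaining the maximum breaks ties); APA the peak voltage minus TOP;
#' APDx the time from the instant of dV/dtMax to the first later downward
#' crossing of `peak - x%% * APA` (linear interpolation between samples);
#' EOP the voltage at the last sample of the beat window.
#'
#' Biomarkers are meaningful only for traces without repolarization
#' abnormalities; run [detect_abnormality()] first and skip abnormal beats.
#'
#' @param trace An [ap_trace()].
#' @return Object of class `biomarker_set`: a named list with `APD10`,
#'   `APD25`, `APD50`, `APD75`, `APD90` (ms), `dVdtMax` (V/s), `APA` (mV),
#'   `TOP` (mV), `EOP` (mV), and `status` (`"ok"` or `"no_ap"`).
#' @export
compute_biomarkers <- function(trace) {
  stopifnot(inherits(trace, "ap_trace"))
  t <- trace$time; v <- trace$vm
  top <- v[1L]
  ipk <- which.max(v)
  peak <- v[ipk]
  if (peak - top < 10) {
    return(structure(list(APD10 = NA_real_, APD25 = NA_real_, APD50 = NA_real_,
                          APD75 = NA_real_, APD90 = NA_real_,
                          dVdtMax = NA_real_, APA = NA_real_, TOP = top,
                          EOP = v[length(v)], status = "no_ap"),
                     class = "biomarker_set"))
  }
  apa <- peak - top
  dv <- .pk_slopes(trace)
  up <- seq_len(max(ipk - 1L, 1L))
  iup <- up[which.max(dv[up])]          # earliest sample attaining the max
  dvdtmax <- dv[iup]
  t0 <- t[iup]
  apd <- function(x) {
    thr <- peak - x / 100 * apa
    above <- which(v >= thr & seq_along(v) >= iup)
    if (!length(above)) return(NA_real_)
    i0 <- above[1L]
    below <- which(v < thr & seq_along(v) > i0)
    if (!length(below)) return(NA_real_)
    i <- below[1L]
    tc <- t[i - 1L] + (thr - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
    tc - t0
  }
  structure(list(APD10 = apd(10), APD25 = apd(25), APD50 = apd(50),
                 APD75 = apd(75), APD90 = apd(90),
                 dVdtMax = dvdtmax, APA = apa, TOP = top,
                 EOP = v[length(v)], status = "ok"),
            class = "biomarker_set")
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<biomarker_set>", if (x$status != "ok") paste0("[", x$status, "]"), "\n")
  vals <- unlist(x[c("APD10", "APD25", "APD50", "APD75", "APD90",
                     "dVdtMax", "APA", "TOP", "EOP")])
  print(round(vals, 2))
  invisible(x)
}

#' @export
as.data.frame.biomarker_set <- function(x, ...) {
  data.frame(APD10 = x$APD10, APD25 = x$APD25, APD50 = x$APD50,
             APD75 = x$APD75, APD90 = x$APD90, dVdtMax = x$dVdtMax,
             APA = x$APA, TOP = x$TOP, EOP = x$EOP,
             status = x$status, stringsAsFactors = FALSE)
}

#' Detect repolarization abnormalities (EADs and DADs)
#'
#' Flags a beat as abnormal when the membrane voltage shows a positive
#' time-derivative after `window_start`: an EAD if the deflection occurs
#' while the membrane is still repolarizing (above `repolarized_level`),
#' a DAD if it occurs after the voltage has fallen below that level.
#' Diastolic (funny-current) depolarization drifts are far slower than
#' `slope_threshold` and are not flagged.
#'
#' @param trace An [ap_trace()].
#' @param window_start Start of the detection window, ms after stimulus
#'   onset (default 150 ms; excludes the upstroke and early plateau rise).
#' @param slope_threshold Positive-slope threshold, V/s.
#' @param repolarized_level Voltage (mV) separating "still repolarizing"
#'   from "repolarized".
#' @return One of `"none"`, `"EAD"`, `"DAD"`.
#' @export
detect_abnormality <- function(trace, window_start = 150,
                               slope_threshold = 0.01,
                               repolarized_level = -70) {
  stopifnot(inherits(trace, "ap_trace"))
  if (window_start >= trace$cycle_length) {
    stop("window_start must be smaller than the cycle length")
  }
  t <- trace$time; v <- trace$vm
  dv <- .pk_slopes(trace)
  cand <- which(t[-1L] > window_start & dv > slope_threshold)
  if (!length(cand)) return("none")
  i <- cand[1L]
  if (v[i] > repolarized_level) "EAD" else "DAD"
}

#' Percent change of a drugged mean against its control
#'
#' @param drug_mean Biomarker mean under drug.
#' @param control_mean Control biomarker mean (same units, non-zero).
#' @return `100 * (drug_mean - control_mean) / abs(control_mean)`.
#' @export
percent_change <- function(drug_mean, control_mean) {
  if (any(control_mean == 0)) stop("control mean must be non-zero")
  100 * (drug_mean - control_mean) / abs(control_mean)
}
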