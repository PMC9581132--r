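#' The twelve sampled ionic currents
#'
#' Identifiers of the twelve ionic currents whose maximal conductances are
#' sampled when building a population of models and scaled when applying a
#' drug block: fast and late Na+ currents (INa, INaL), L- and T-type Ca2+
#' currents (ICaL, ICaT), transient outward and sustained K+ currents
#' (Ito, Isus), rapid and slow delayed rectifiers (IKr, IKs), funny current
#' (If), inward rectifier (IK1), Na+/Ca2+ exchanger (INCX) and Na+/K+ pump
#' (INaK).  The ordering is stable and used for serialization.
#'
#' @return Character vector of length 12.
#' @export
current_ids <- function() {
  c("INa", "INaL", "ICaL", "ICaT", "Ito", "Isus",
    "IKr", "IKs", "If", "IK1", "INCX", "INaK")
}

# baseline maximal conductances (pA/pF scale, Cm normalised to 1),
# tuned so control biomarkers sit inside the human Purkinje calibration
# windows at 0.25, 1 and 3 Hz
.pk_base_conductances <- c(
  INa = 140, INaL = 0.04, ICaL = 0.12, ICaT = 0.05, Ito = 0.30, Isus = 0.10,
  IKr = 0.15, IKs = 0.10, If = 0.10, IK1 = 0.45, INCX = 0.30, INaK = 0.50
)

# resting steady state of the baseline model (unstimulated equilibrium)
.pk_initial_state <- c(
  V = -84.831093, m = 0.001029, h = 0.819428, j = 0.819428,
  mL = 0.001029, hL = 0.451995, d = 0.000047, f = 0.999702,
  dT = 0.000942, fT = 0.928656, r = 0.000997, s = 0.999872,
  xr = 0.000302, xs = 0.005474, y = 0.410600
)

#' Reduced human Purkinje cell model
#'
#' Constructs the bundled reduced Purkinje action-potential model: a
#' Hodgkin-Huxley-style formulation of the twelve main ionic currents with
#' fixed intracellular concentrations.  The model is non-pacemaking but
#' shows funny-current-driven diastolic depolarization, giving the
#' rate-dependent take-off potential seen in Purkinje fibers, and supports
#' early afterdepolarizations under strong IKr block.
#'
#' @param name Model identifier. Only `"reduced-purkinje"` is bundled.
#' @return An object of class `purkinje_model` with elements `name`,
#'   `conductances` (the 12 baseline maximal conductances, in the order of
#'   [current_ids()]), `initial_state` (resting state vector) and
#'   `stimulus_duration` (ms).
#' @export
purkinje_model <- function(name = "reduced-purkinje") {
  if (!identical(name, "reduced-purkinje")) {
    stop("unknown model id: ", name, call. = FALSE)
  }
  structure(
    list(
      name = name,
      conductances = .pk_base_conductances,
      initial_state = .pk_initial_state,
      stimulus_duration = 1.0
    ),
    class = "purkinje_model"
  )
}

#' @export
print.purkinje_model <- function(x, ...) {
  cat("<purkinje_model>", x$name, "\n")
  cat("  12 currents:", paste(current_ids(), collapse = " "), "\n")
  cat("  resting Vm:", round(x$initial_state[["V"]], 1), "mV\n")
  invisible(x)
}

#' Conductance scaling vector
#'
#' A multiplicative factor per ionic current, defining one member of a
#' population of models.  All factors must be strictly positive; the
#' baseline model corresponds to all factors equal to 1.
#'
#' @param ... Named factors (e.g. `ICaL = 2, IK1 = 0.5`); unnamed currents
#'   default to 1.  Alternatively a single named numeric vector.
#' @return Named numeric vector of length 12 with class `scaling_vector`.
#' @export
scaling_vector <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) && length(args[[1]]) > 1L) {
    args <- as.list(args[[1]])
  }
  out <- setNames(rep(1, 12L), current_ids())
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == "")) stop("scaling factors must be named")
    bad <- setdiff(nm, current_ids())
    if (length(bad)) stop("unknown current id(s): ", paste(bad, collapse = ", "))
    out[nm] <- unlist(args)
  }
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("all scaling factors must be finite and > 0")
  }
  structure(out, class = c("scaling_vector", "numeric"))
}

#' Per-current residual fractions after drug block
#'
#' A multiplicative residual-current fraction per ionic current, in `[0, 1]`.
#' Channels not targeted by a drug keep residual 1. Composes with a
#' [scaling_vector()] by plain per-channel multiplication.
#'
#' @param ... Named residuals; unnamed currents default to 1.  Alternatively
#'   a single named numeric vector.
#' @return Named numeric vector of length 12 with class `block_set`.
#' @export
block_set_values <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) && length(args[[1]]) > 1L) {
    args <- as.list(args[[1]])
  }
  out <- setNames(rep(1, 12L), current_ids())
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == "")) stop("block residuals must be named")
    bad <- setdiff(nm, current_ids())
    if (length(bad)) stop("unknown current id(s): ", paste(bad, collapse = ", "))
    out[nm] <- unlist(args)
  }
  if (any(!is.finite(out)) || any(out < 0) || any(out > 1)) {
    stop("all block residuals must be in [0, 1]")
  }
  structure(out, class = c("block_set", "numeric"))
}

#' Pacing protocol
#'
#' @param frequency Pacing frequency in Hz (> 0).  The study rates are
#'   0.2/0.25 Hz (slow), 1 Hz (normal) and 3 Hz (fast); any positive value
#'   is accepted.
#' @param n_beats Number of beats (>= 1).
#' @param stimulus_amplitude Rectangular-pulse amplitude in pA/pF.  `NULL`
#'   (default) means twice the model's diastolic threshold, found once per
#'   model by bisection.
#' @param stimulus_duration Pulse duration in ms; must be shorter than the
#'   cycle length.
#' @param sample_interval Sampling step (ms) for the returned last-beat
#'   trace.  0.05 ms resolves the upstroke so dV/dtMax is stable.
#' @return An object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(frequency, n_beats,
                            stimulus_amplitude = NULL,
                            stimulus_duration = 1.0,
                            sample_interval = 0.05) {
  stopifnot(is.numeric(frequency), length(frequency) == 1L, frequency > 0)
  stopifnot(is.numeric(n_beats), length(n_beats) == 1L, n_beats >= 1)
  cl <- 1000 / frequency
  if (stimulus_duration >= cl) stop("stimulus_duration must be < cycle length")
  structure(
    list(frequency = frequency, n_beats = as.integer(n_beats),
         cycle_length = cl,
         stimulus_amplitude = stimulus_amplitude,
         stimulus_duration = stimulus_duration,
         sample_interval = sample_interval),
    class = "pacing_protocol"
  )
}

# ---- internal integration helpers -----------------------------------------

.pk_state_names <- names(.pk_initial_state)

.pk_integrate <- function(state, times, g_eff, istim) {
  out <- deSolve::lsoda(
    y = unname(state), times = times,
    func = "purkinje_derivs", parms = c(unname(g_eff), istim),
    dllname = "purkinjetrials", initfunc = "purkinje_init",
    rtol = 1e-6, atol = 1e-8, maxsteps = 200000
  )
  if (any(!is.finite(out))) {
    stop(structure(
      class = c("purkinje_solver_error", "error", "condition"),
      list(message = "solver failure: non-finite state", call = NULL)
    ))
  }
  out
}

.pk_effective_g <- function(model, scalings, block) {
  g <- model$conductances * as.numeric(scalings) * as.numeric(block)
  names(g) <- current_ids()
  g
}

# one beat; returns final state, optionally the sampled trace
.pk_beat <- function(state, g_eff, cycle_length, stim_amp, stim_dur,
                     sample = FALSE, dt = 0.05) {
  t1 <- if (sample) seq(0, stim_dur, by = min(dt, stim_dur / 4)) else c(0, stim_dur)
  o1 <- .pk_integrate(state, t1, g_eff, stim_amp)
  s1 <- o1[nrow(o1), -1L]
  t2 <- if (sample) seq(stim_dur, cycle_length, by = dt) else c(stim_dur, cycle_length)
  o2 <- .pk_integrate(s1, t2, g_eff, 0)
  s2 <- setNames(o2[nrow(o2), -1L], .pk_state_names)
  trace <- NULL
  if (sample) {
    trace <- list(time = c(o1[, 1L], o2[-1L, 1L]), vm = c(o1[, 2L], o2[-1L, 2L]))
  }
  list(state = s2, trace = trace)
}

# ---- exported operations ---------------------------------------------------

#' Initial state of a model for a given scaling vector
#'
#' Returns the bundled resting initial condition with the scaling vector
#' attached to the evaluation context.  Scaling affects the dynamics, not
#' the stored initial condition, so the state itself is identical for all
#' valid scalings.
#'
#' @param model A [purkinje_model()].
#' @param scalings A [scaling_vector()] (defaults to all ones).
#' @return Named numeric state vector (Vm in mV plus 14 gating variables)
#'   with the scalings stored in attribute `"scalings"` and `time = 0`.
#' @export
initialize_state <- function(model, scalings = scaling_vector()) {
  stopifnot(inherits(model, "purkinje_model"))
  scalings <- scaling_vector(scalings)
  st <- model$initial_state
  attr(st, "scalings") <- scalings
  attr(st, "time") <- 0
  st
}

#' Diastolic stimulus threshold of a model
#'
#' Finds, by bisection, the minimal rectangular-pulse amplitude that
#' elicits an action potential (peak above -10 mV) from the relaxed
#' baseline resting state at 1 Hz.  The result is cached per model.
#'
#' @param model A [purkinje_model()].
#' @param stimulus_duration Pulse duration in ms.
#' @return Threshold amplitude (pA/pF).
#' @export
stimulus_threshold <- function(model, stimulus_duration = 1.0) {
  key <- paste0("thr:", model$name, ":", stimulus_duration)
  if (!is.null(.pk_cache[[key]])) return(.pk_cache[[key]])
  g <- .pk_effective_g(model, scaling_vector(), block_set_values())
  st <- model$initial_state
  # settle unstimulated for a few cycles
  for (i in 1:5) st <- .pk_beat(st, g, 1000, 0, stimulus_duration)$state
  fires <- function(amp) {
    b <- .pk_beat(st, g, 1000, amp, stimulus_duration, sample = TRUE, dt = 0.5)
    max(b$trace$vm) > -10
  }
  lo <- 0; hi <- 10
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 1000) stop("no stimulus threshold found below 1000 pA/pF")
  }
  for (i in 1:14) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .pk_cache[[key]] <- hi
  hi
}

#' Pace a model and return the final state and last-beat trace
#'
#' Integrates the model ODEs beat by beat, with every maximal conductance
#' multiplied by its scaling factor and drug-block residual.  A beat spans
#' `[stimulus onset, next stimulus onset)` in local time.  Integration uses
#' an adaptive stiff solver (rtol 1e-6, atol 1e-8); a non-finite state
#' raises an error of class `purkinje_solver_error`, never silent NaNs.
#'
#' @param model A [purkinje_model()].
#' @param state State vector from [initialize_state()] or a previous pace.
#' @param protocol A [pacing_protocol()].
#' @param scalings A [scaling_vector()].
#' @param block A [block_set_values()] of drug residuals.
#' @return List with `state` (final state) and `trace` (an [ap_trace()] of
#'   the last beat).
#' @export
pace <- function(model, state, protocol,
                 scalings = scaling_vector(),
                 block = block_set_values()) {
  stopifnot(inherits(model, "purkinje_model"), inherits(protocol, "pacing_protocol"))
  scalings <- scaling_vector(scalings)
  block <- block_set_values(block)
  g <- .pk_effective_g(model, scalings, block)
  amp <- protocol$stimulus_amplitude
  if (is.null(amp)) amp <- 2 * stimulus_threshold(model, protocol$stimulus_duration)
  st <- state
  n <- protocol$n_beats
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      st <- .pk_beat(st, g, protocol$cycle_length, amp,
                     protocol$stimulus_duration)$state
    }
  }
  last <- .pk_beat(st, g, protocol$cycle_length, amp,
                   protocol$stimulus_duration,
                   sample = TRUE, dt = protocol$sample_interval)
  trace <- ap_trace(
    time = last$trace$time, vm = last$trace$vm,
    cycle_length = protocol$cycle_length,
    stimulus_duration = protocol$stimulus_duration,
    stimulus_amplitude = amp
  )
  list(state = last$state, trace = trace)
}

#' Pre-pace a model to steady state
#'
#' Paces from the bundled initial condition for `n_beats` beats at the
#' given frequency, returning the post-pacing state.  Results are cached
#' per (model, scalings, frequency, n_beats) so drug trials can reuse
#' control steady states.  Integration is deterministic: two identical
#' calls return bitwise-identical states.
#'
#' @param model A [purkinje_model()].
#' @param scalings A [scaling_vector()].
#' @param n_beats Number of pre-pacing beats (study protocol: 1000).
#' @param frequency Pacing frequency in Hz.
#' @param use_cache Reuse cached states for identical requests.
#' @return Named state vector.
#' @export
prepace_to_steady_state <- function(model, scalings = scaling_vector(),
                                    n_beats = 1000, frequency = 1,
                                    use_cache = TRUE) {
  stopifnot(n_beats >= 1)
  scalings <- scaling_vector(scalings)
  key <- paste0("ss:", rlang::hash(list(model$conductances, as.numeric(scalings),
                                        frequency, n_beats)))
  if (use_cache && !is.null(.pk_cache[[key]])) return(.pk_cache[[key]])
  g <- .pk_effective_g(model, scalings, block_set_values())
  amp <- 2 * stimulus_threshold(model, model$stimulus_duration)
  cl <- 1000 / frequency
  st <- model$initial_state
  for (i in seq_len(n_beats)) {
    st <- .pk_beat(st, g, cl, amp, model$stimulus_duration)$state
  }
  if (use_cache) .pk_cache[[key]] <- st
  st
}

#' Clear the per-session cache of steady states and thresholds
#' @return Invisibly, the number of entries removed.
#' @export
clear_model_cache <- function() {
  n <- length(ls(.pk_cache))
  rm(list = ls(.pk_cache), envir = .pk_cache)
  invisible(n)
}

# ---- serialization ---------------------------------------------------------

#' Write / read a model definition as YAML
#'
#' @param model A [purkinje_model()].
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   a `purkinje_model`.
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(
    list(name = model$name,
         conductances = as.list(model$conductances),
         initial_state = as.list(model$initial_state),
         stimulus_duration = model$stimulus_duration),
    path
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- yaml::read_yaml(path)
  m <- purkinje_model()
  if (!identical(sort(names(x$conductances)), sort(current_ids()))) {
    stop("model file must define exactly the 12 known conductances")
  }
  m$name <- x$name
  m$conductances <- unlist(x$conductances)[current_ids()]
  m$initial_state <- unlist(x$initial_state)[.pk_state_names]
  m$stimulus_duration <- x$stimulus_duration
  m
}

#' Export an AP trace as CSV (time_ms, vm_mV)
#'
#' @param trace An [ap_trace()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_ms = trace$time, vm_mV = trace$vm),
            path, row.names = FALSE)
  invisible(path)
}
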