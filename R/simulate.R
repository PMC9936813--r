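new_trace <- function(t, V, dt, currents, stimulus, gating, seed,
                      model_name, model_hash) {
  structure(list(t = t, V = V, dt = dt, currents = currents,
                 stimulus = stimulus, gating = gating, seed = seed,
                 model_name = model_name, model_hash = model_hash),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %.0f ms @ dt = %g ms (%d samples), model '%s'\n",
              length(x$V) * x$dt, x$dt, length(x$V), x$model_name))
  cat(sprintf("  V in [%.1f, %.1f] mV; currents: %s\n", min(x$V), max(x$V),
              if (is.null(x$currents)) "not recorded"
              else paste(colnames(x$currents), collapse = ", ")))
  invisible(x)
}

#' Simulate the single-compartment model
#'
#' Fixed-step integration (exponential Euler for gates, forward Euler for the
#' voltage) of the conductance-based model under an arbitrary stimulus.
#' Sample `k` of every output series covers `[k*dt, (k+1)*dt)`.
#'
#' The stimulus is either a numeric vector of injected current (pA,
#' depolarizing positive), a single number (constant current; `duration`
#' required), or a list with any of the elements
#' `current` (pA vector or scalar), `ge`, `gi`, `gp` (conductance series, uS)
#' and reversals `ee`, `ei`, `ep` (mV; defaults 0, -87, and the polarity's
#' reversal).  Conductance inputs model synaptic drive
#' \eqn{I_{syn} = g_e(V - E_e) + g_i(V - E_i)}; negative conductance samples
#' are clipped to zero at use time.
#'
#' @param model a [membrane_model()].
#' @param stimulus stimulus specification (see Details).
#' @param duration simulation length (ms); taken from the stimulus when a
#'   series is given.
#' @param dt time step (ms).
#' @param v0 initial voltage (mV); gates start at their steady state for `v0`.
#' @param record one of `"V"`, `"currents"`, `"full"` (currents + gating).
#' @param seed optional integer recorded in the trace (the simulation itself
#'   is deterministic; stochastic stimuli are realized by their builders).
#' @return a `sim_trace`: time grid `t`, voltage `V`, per-current matrix
#'   `currents` (pA, outward positive, inward negative), `stimulus` (pA),
#'   optional `gating`, and provenance fields.
#' @export
simulate_cell <- function(model, stimulus, duration = NULL, dt = 0.025,
                          v0 = model$v_init, record = "currents",
                          seed = NULL) {
  stopifnot(inherits(model, "membrane_model"), dt > 0)
  spec <- if (is.list(stimulus)) stimulus else list(current = stimulus)
  n <- NULL
  for (s in spec[intersect(names(spec), c("current", "ge", "gi", "gp"))])
    if (length(s) > 1) n <- length(s)
  if (is.null(n)) {
    if (is.null(duration) || duration <= 0)
      stop("duration must be given (and > 0) for constant stimuli")
    n <- round(duration / dt)
  }
  if (n < 1) stop("empty stimulus")
  cur <- spec$current %||% 0
  if (length(cur) == 1) cur <- rep(cur, n)
  if (length(cur) != n) stop("stimulus series lengths differ")
  if (anyNA(cur)) stop("NaN/NA in stimulus")
  ge <- spec$ge %||% numeric(0)
  gi <- spec$gi %||% numeric(0)
  gp <- spec$gp %||% numeric(0)
  if (anyNA(ge) || anyNA(gi) || anyNA(gp)) stop("NaN/NA in conductance input")
  rec <- match.arg(record, c("V", "currents", "full"))
  out <- simulate_cpp(as_cpp_model(model), cur, dt, v0, numeric(0),
                      ge, gi, gp,
                      spec$ee %||% 0, spec$ei %||% -87, spec$ep %||% 0,
                      match(rec, c("V", "currents", "full")) - 1L)
  currents <- NULL
  if (rec != "V") {
    currents <- out$currents
    nm <- c(channel_names(model), "leak",
            if (length(ge)) "syn_e", if (length(gi)) "syn_i",
            if (length(gp)) "syn_p")
    colnames(currents) <- nm
  }
  gating <- NULL
  if (rec == "full") {
    gating <- out$gating
    colnames(gating) <- gate_names(model)
  }
  new_trace(t = (seq_len(n) - 1) * dt, V = out$V, dt = dt,
            currents = currents, stimulus = cur, gating = gating, seed = seed,
            model_name = model$name, model_hash = model_hash(model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect spikes by upward threshold crossing
#'
#' A spike onset is the first sample at which V crosses `threshold` from
#' below; the peak is the voltage maximum within `peak_window` ms after the
#' onset.  Crossings within 1 ms of the previous onset are ignored
#' (absolute refractory floor).
#'
#' @param trace a `sim_trace` (or any list with `V`, `dt`).
#' @param threshold detection threshold (mV).
#' @param peak_window window after onset searched for the peak (ms).
#' @return a `spike_record` with `onset_times`, `peak_times` (ms) and
#'   `detection_threshold`; empty record if there are no crossings.
#' @export
detect_spikes <- function(trace, threshold = -10, peak_window = 3) {
  V <- trace$V
  dt <- trace$dt
  if (length(V) < 2)
    return(structure(list(onset_times = numeric(0), peak_times = numeric(0),
                          detection_threshold = threshold),
                     class = "spike_record"))
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1L
  if (length(up) > 1) {                       # refractory floor: 1 ms
    keep <- c(TRUE, diff(up) * dt >= 1)
    while (!all(keep)) {
      up <- up[keep]
      keep <- c(TRUE, diff(up) * dt >= 1)
    }
  }
  pw <- max(1L, round(peak_window / dt))
  peaks <- vapply(up, function(i) {
    j <- i:min(length(V), i + pw)
    j[which.max(V[j])]
  }, 1L)
  structure(list(onset_times = (up - 1L) * dt, peak_times = (peaks - 1L) * dt,
                 detection_threshold = threshold),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d spikes (threshold %.1f mV)\n",
              length(x$onset_times), x$detection_threshold))
  invisible(x)
}

#' Firing rate versus injected current (f-I curve)
#'
#' Rates are spike counts over the simulated interval divided by its length,
#' as in current-clamp practice (default 10 s per level).
#'
#' @param model a [membrane_model()].
#' @param currents injected current levels (pA).
#' @param duration per-level duration (ms); at least 10 s for stable rates.
#' @param dt time step (ms).
#' @param threshold spike-detection threshold (mV).
#' @return data.frame with columns `I_pA` and `rate_Hz`.
#' @export
fi_curve <- function(model, currents, duration = 10000, dt = 0.025,
                     threshold = -10) {
  rate <- vapply(currents, function(I) {
    tr <- simulate_cell(model, I, duration = duration, dt = dt, record = "V")
    length(detect_spikes(tr, threshold)$onset_times) / duration * 1000
  }, 1.0)
  data.frame(I_pA = currents, rate_Hz = rate)
}

#' Injected current for a target firing rate (bisection)
#'
#' Finds the smallest constant current at which the model fires at
#' `target_rate` (rate = spike count / duration), e.g. the 1 Hz operating
#' point used to anchor the f-I relation.
#'
#' @param model a [membrane_model()].
#' @param target_rate target rate (Hz), > 0.
#' @param tol current tolerance (pA) at which bisection stops.
#' @param bracket initial current interval (pA) that must straddle the target.
#' @param duration per-evaluation duration (ms).
#' @param dt time step (ms).
#' @return the current (pA) at convergence (upper end of the final interval,
#'   whose rate is within one count of the target).
#' @export
rheobase_for_rate <- function(model, target_rate = 1, tol = 0.05,
                              bracket = c(0, 200), duration = 10000,
                              dt = 0.025) {
  if (target_rate <= 0) stop("target rate must be > 0 (not bracketable)")
  rate_at <- function(I) fi_curve(model, I, duration, dt)$rate_Hz
  lo <- bracket[1]; hi <- bracket[2]
  rlo <- rate_at(lo); rhi <- rate_at(hi)
  if (rlo >= target_rate || rhi < target_rate)
    stop(sprintf(paste0("target rate %.2f Hz not bracketed by [%g, %g] pA ",
                        "(rates %.2f, %.2f); widen the interval"),
                 target_rate, lo, hi, rlo, rhi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) >= target_rate) hi <- mid else lo <- mid
  }
  hi
}

#' Signed fractional contribution of each current over time
#'
#' At every timepoint, each recorded current's share is its value divided by
#' the sum of absolute values of all currents at that timepoint (so the
#' absolute shares sum to 1), signed negative for inward and positive for
#' outward current -- the quantity plotted in currentscape-style charts.
#' Timepoints with zero total current get all-zero shares.
#'
#' @param trace a `sim_trace` recorded with currents.
#' @return matrix of shares (rows = timepoints, columns = currents).
#' @export
current_shares <- function(trace) {
  if (is.null(trace$currents)) stop("trace has no recorded currents")
  tot <- rowSums(abs(trace$currents))
  sh <- trace$currents / ifelse(tot > 0, tot, Inf)
  sh[tot == 0, ] <- 0
  sh
}
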