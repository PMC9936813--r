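#' Perturbation-frequency set for resonance scans
#'
#' The 27-frequency set {0.5} U {1..25} U {30} Hz.
#' @export
frequency_set <- function() c(0.5, 1:25, 30)

#' Spike-train PSD ratio at the perturbation frequency
#'
#' The baseline ratio
#' \eqn{\delta PSD = PSD^{perturbed}_{f_i} / PSD^{baseline}_{f_i}}
#' quantifies how effectively a periodic perturbation at `f_i` entrains
#' spiking: 1 means no effect, larger values stronger entrainment.  Both
#' spectra are evaluated at the grid frequency nearest `f_i`.
#'
#' @param perturbed,baseline `sim_trace` objects (same background and seed,
#'   differing only by the perturbation), or lists from [spike_psd()].
#' @param f_i perturbation frequency (Hz).
#' @param threshold spike-detection threshold (mV) when traces are given.
#' @param bin_ms spike-train bin (ms).
#' @param nperseg Welch segment length.
#' @return `delta_psd` value; `NA` if the baseline density at `f_i` is zero.
#' @export
delta_psd <- function(perturbed, baseline, f_i, threshold = -10, bin_ms = 1,
                      nperseg = NULL) {
  as_psd <- function(x) {
    if (inherits(x, "sim_trace")) {
      tr <- spike_train_signal(detect_spikes(x, threshold),
                               length(x$V) * x$dt, bin_ms)
      spike_psd(tr, nperseg = nperseg)
    } else x
  }
  pp <- as_psd(perturbed)
  pb <- as_psd(baseline)
  i <- which.min(abs(pp$freq - f_i))
  j <- which.min(abs(pb$freq - f_i))
  if (pb$psd[j] <= 0) return(NA_real_)
  pp$psd[i] / pb$psd[j]
}

# single double-exponential perturbation event at time `at`
single_perturbation <- function(kin, at, duration, dt, scale = 30) {
  n <- round(duration / dt)
  gp <- numeric(n)
  ev_len <- min(n, ceiling((kin$decay * 12) / dt))
  shape <- dexp_event(scale * kin$weight, kin$rise, kin$decay, ev_len, dt)
  i0 <- round(at / dt) + 1
  j <- i0:min(n, i0 + ev_len - 1)
  gp[j] <- gp[j] + shape[seq_along(j)]
  list(gp = gp, ep = kin$erev, events = at)
}

#' Resonant frequency from a perturbation-frequency scan
#'
#' Runs one baseline simulation and one perturbed simulation per frequency
#' in `freqs` (perturbation events at 30x synaptic weight), computes
#' [delta_psd()] for each, and returns the argmax frequency `f_r` (ties
#' resolved to the lowest frequency).  In `"invitro"` mode the drive is a
#' constant holding current; in `"ivl"` mode an OU background, with the
#' baseline and every perturbed run sharing the same OU seed so the ratio
#' isolates the perturbation.
#'
#' @param model a [membrane_model()].
#' @param drive holding current (pA, `"invitro"` mode) or an
#'   [ou_background()] (`"ivl"` mode).
#' @param freqs perturbation frequencies (Hz), e.g. [frequency_set()].
#' @param polarity `"inhibitory"` or `"excitatory"`.
#' @param mode `"ivl"` or `"invitro"` (inferred from `drive` by default).
#' @param seed OU seed (`"ivl"` mode).
#' @param duration run length (ms).
#' @param dt time step (ms).
#' @param threshold spike-detection threshold (mV).
#' @return a `resonance_result`: `freqs`, `delta_psd`, `f_r`, baseline rate
#'   `f_B` (Hz) and spike counts.
#' @export
resonant_frequency <- function(model, drive, freqs = frequency_set(),
                               polarity = "inhibitory", mode = NULL,
                               seed = 1, duration = 10000, dt = 0.025,
                               threshold = -10) {
  stopifnot(length(freqs) >= 1)
  polarity <- match.arg(polarity, c("inhibitory", "excitatory"))
  if (is.null(mode))
    mode <- if (inherits(drive, "ou_background")) "ivl" else "invitro"
  kin <- perturbation_synapse(polarity)
  run <- function(pert) {
    if (mode == "ivl") simulate_ivl(model, drive, duration, dt, seed,
                                    perturbation = pert, record = "V")
    else {
      stim <- list(current = drive)
      if (!is.null(pert)) { stim$gp <- pert$gp; stim$ep <- pert$ep }
      simulate_cell(model, stim, duration = duration, dt = dt, record = "V")
    }
  }
  base_tr <- run(NULL)
  base_sp <- detect_spikes(base_tr, threshold)
  base_psd <- spike_psd(spike_train_signal(base_sp, duration))
  dps <- vapply(freqs, function(f) {
    pert <- perturbation_conductance(f, kin, duration, dt)
    ptr <- run(pert)
    psp <- detect_spikes(ptr, threshold)
    if (length(psp$onset_times) == 0) return(NA_real_)
    delta_psd(spike_psd(spike_train_signal(psp, duration)), base_psd, f)
  }, 1.0)
  if (all(is.na(dps))) stop("no spikes in any perturbed run")
  f_r <- freqs[which.max(replace(dps, is.na(dps), -Inf))]  # ties -> lowest
  structure(list(freqs = freqs, delta_psd = dps, f_r = f_r,
                 f_B = length(base_sp$onset_times) / duration * 1000,
                 baseline_spikes = length(base_sp$onset_times)),
            class = "resonance_result")
}

#' @export
print.resonance_result <- function(x, ...) {
  cat(sprintf("<resonance_result> f_r = %.1f Hz (f_B = %.2f Hz), %d frequencies\n",
              x$f_r, x$f_B, length(x$freqs)))
  invisible(x)
}

#' Per-current amplitude change around a perturbation
#'
#' For each recorded current, compares the maximum absolute amplitude in the
#' pre-perturbation window (from the 2nd-last spike preceding the
#' perturbation to the perturbation) with the post window (perturbation to
#' the 2nd following spike):
#' \eqn{\Delta I = (I_1 - I_0)/I_0 \times 100} (positive = amplitude
#' increase).
#'
#' @param trace a `sim_trace` recorded with currents.
#' @param spikes a `spike_record` for the trace.
#' @param t_pert perturbation time (ms).
#' @return named vector of percent changes (`NA` where the pre-window
#'   amplitude is zero), with windows attached as attributes.
#' @export
delta_I <- function(trace, spikes, t_pert) {
  on <- spikes$onset_times
  pre <- on[on < t_pert]
  post <- on[on > t_pert]
  if (length(pre) < 2 || length(post) < 2)
    stop("need two spikes on each side of the perturbation")
  w0 <- c(pre[length(pre) - 1], t_pert)
  w1 <- c(t_pert, post[2])
  idx <- function(w) {
    i <- max(1, floor(w[1] / trace$dt) + 1):min(length(trace$V),
                                                floor(w[2] / trace$dt) + 1)
    i
  }
  I0 <- apply(abs(trace$currents[idx(w0), , drop = FALSE]), 2, max)
  I1 <- apply(abs(trace$currents[idx(w1), , drop = FALSE]), 2, max)
  out <- ifelse(I0 > 0, (I1 - I0) / I0 * 100, NA_real_)
  attr(out, "window_pre") <- w0
  attr(out, "window_post") <- w1
  out
}

#' Phase response curve with per-current amplitude changes
#'
#' Drives the model to stable periodic firing with a constant holding
#' current, then applies a single synaptic perturbation at `n_phases`
#' uniformly spaced phases of one reference inter-spike interval.  The phase
#' shift is reported as \eqn{\Delta\phi = (T_0 - T_1)/T_0 \times 100} where
#' \eqn{T_0} is the unperturbed ISI and \eqn{T_1} the perturbed one, so a
#' positive value is a phase advance (ISI shortening) and a negative value a
#' delay.  Per-current amplitude changes are measured with [delta_I()].
#'
#' @param model a [membrane_model()].
#' @param holding holding current (pA) producing stable firing.
#' @param n_phases number of uniformly spaced phases.
#' @param polarity perturbation polarity (default inhibitory).
#' @param stable_cycles cycles required before the reference ISI.
#' @param stability_tol maximum sd/mean of the preceding ISIs.
#' @param dt time step (ms).
#' @param threshold spike-detection threshold (mV).
#' @param scale perturbation amplitude in synaptic weights (default 30).
#' @return a `prc_result`: `phases` (fraction of cycle), `dphi` (%), matrix
#'   `delta_I` (phase x current, %), `T0` (ms), `T1` (ms per phase).
#' @export
prc <- function(model, holding, n_phases = 20, polarity = "inhibitory",
                stable_cycles = 10, stability_tol = 0.01, dt = 0.025,
                threshold = -10, scale = 30) {
  kin <- perturbation_synapse(polarity)
  # locate a stable reference cycle from a long unperturbed run
  probe <- simulate_cell(model, holding, duration = 20000, dt = dt, record = "V")
  sp <- detect_spikes(probe, threshold)
  if (length(sp$onset_times) < stable_cycles + 3)
    stop("holding current does not produce enough spikes for a stable baseline")
  isis <- diff(sp$onset_times)
  # skip the adaptation transient: first reference cycle whose preceding
  # `stable_cycles` ISIs are stationary, leaving room for the post window
  k <- NA
  cv_best <- Inf
  for (kk in (stable_cycles + 1):(length(isis) - 1)) {
    win <- isis[(kk - stable_cycles):(kk - 1)]
    cv <- sd(win) / mean(win)
    cv_best <- min(cv_best, cv)
    if (cv <= stability_tol &&
        sp$onset_times[kk] + 5 * isis[kk] < 20000) { k <- kk; break }
  }
  if (is.na(k))
    stop(sprintf("unstable baseline firing: best ISI CV %.3f over %d cycles",
                 cv_best, stable_cycles))
  T0 <- isis[k]
  ref_spike <- sp$onset_times[k]
  duration <- min(20000, ref_spike + 4 * T0 + 500)
  phases <- (seq_len(n_phases) - 1) / n_phases
  res <- lapply(phases, function(ph) {
    t_pert <- ref_spike + ph * T0
    pert <- single_perturbation(kin, t_pert, duration, dt, scale)
    tr <- simulate_cell(model, list(current = holding, gp = pert$gp,
                                    ep = pert$ep),
                        duration = duration, dt = dt, record = "currents")
    psp <- detect_spikes(tr, threshold)
    pon <- psp$onset_times
    i <- findInterval(t_pert, pon)        # spike preceding the perturbation
    T1 <- if (i >= 1 && i < length(pon)) pon[i + 1] - pon[i] else NA_real_
    di <- tryCatch(delta_I(tr, psp, t_pert), error = function(e) NULL)
    list(T1 = T1, di = di)
  })
  T1s <- vapply(res, `[[`, 1.0, "T1")
  cur_names <- c(channel_names(model), "leak", "syn_p")
  dI <- do.call(rbind, lapply(res, function(r)
    if (is.null(r$di)) stats::setNames(rep(NA_real_, length(cur_names)),
                                       cur_names)
    else r$di))
  structure(list(phases = phases, dphi = (T0 - T1s) / T0 * 100,
                 delta_I = dI, T0 = T0, T1 = T1s, holding = holding,
                 polarity = polarity),
            class = "prc_result")
}

#' @export
print.prc_result <- function(x, ...) {
  cat(sprintf("<prc_result> %d phases at %.1f pA (T0 = %.1f ms); dphi in [%.2f, %.2f]%%\n",
              length(x$phases), x$holding, x$T0,
              min(x$dphi, na.rm = TRUE), max(x$dphi, na.rm = TRUE)))
  invisible(x)
}
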