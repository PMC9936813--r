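#' Ornstein-Uhlenbeck background conductance parameters
#'
#' One candidate in-vivo-like background: mean-reverting stochastic
#' excitatory and inhibitory conductances
#' \deqn{dg/dt = -(g - g_0)/\tau + D N(t)}
#' with white noise N(t), giving stationary mean \eqn{g_0} and stationary
#' variance \eqn{D^2 \tau / 2}.
#'
#' @param ge0,gi0 mean excitatory/inhibitory conductances (uS).
#' @param De,Di noise standard-deviation parameters (uS / sqrt(ms)).
#' @param tau_e,tau_i decay time constants (ms).
#' @param ee,ei reversal potentials (mV).
#' @return an `ou_background` object.
#' @export
ou_background <- function(ge0, gi0, De, Di, tau_e = 3, tau_i = 10,
                          ee = 0, ei = -87) {
  stopifnot(tau_e > 0, tau_i > 0, ge0 >= 0, gi0 >= 0, De >= 0, Di >= 0)
  structure(list(ge0 = ge0, gi0 = gi0, De = De, Di = Di,
                 tau_e = tau_e, tau_i = tau_i, ee = ee, ei = ei),
            class = "ou_background")
}

# exact OU transition: g' = g0 + (g-g0) e^{-dt/tau} + D sqrt(tau/2 (1-e^{-2dt/tau})) z
ou_path <- function(g0, D, tau, n, dt) {
  rho <- exp(-dt / tau)
  s <- D * sqrt(tau / 2 * (1 - rho^2))
  if (s == 0) return(rep(g0, n))
  z <- rnorm(n - 1)
  dev <- stats::filter(s * z, rho, method = "recursive", init = 0)
  g0 + c(0, as.numeric(dev))
}

#' Generate OU background conductance series
#'
#' Uses the exact discretization of the OU process (no time-step bias), so
#' halving `dt` leaves the stationary moments unchanged.  Negative
#' excursions are retained here; they are clipped to zero where the
#' conductances are applied to the membrane.
#'
#' @param bg an [ou_background()].
#' @param duration length (ms).
#' @param dt time step (ms).
#' @param seed integer seed (the pair of series is deterministic given it).
#' @return list with series `ge`, `gi` (uS) and the reversals `ee`, `ei`.
#' @export
ou_conductances <- function(bg, duration, dt, seed = NULL) {
  stopifnot(inherits(bg, "ou_background"), duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  list(ge = ou_path(bg$ge0, bg$De, bg$tau_e, n, dt),
       gi = ou_path(bg$gi0, bg$Di, bg$tau_i, n, dt),
       ee = bg$ee, ei = bg$ei)
}

#' Synaptic current from conductance and voltage series
#'
#' \eqn{I_{syn} = g_e (V - E_e) + g_i (V - E_i)} in pA (outward positive),
#' the point-conductance formulation of fluctuating synaptic drive.
#'
#' @param ge,gi conductance series (uS); either may be `NULL`.
#' @param V voltage series (mV), aligned with the conductances.
#' @param ee,ei reversal potentials (mV).
#' @export
synaptic_current <- function(ge, gi, V, ee = 0, ei = -87) {
  out <- 0
  if (!is.null(ge)) { stopifnot(length(ge) == length(V)); out <- out + 1000 * ge * (V - ee) }
  if (!is.null(gi)) { stopifnot(length(gi) == length(V)); out <- out + 1000 * gi * (V - ei) }
  out
}

#' Synaptic event kinetics
#'
#' Double-exponential conductance event, peak-normalized so a unit-weight
#' event reaches exactly `weight` uS at its peak.
#'
#' @param weight peak conductance (uS).
#' @param rise,decay rise and decay time constants (ms), `decay > rise > 0`.
#' @param erev reversal potential (mV).
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @export
synaptic_kinetics <- function(weight, rise, decay, erev, polarity) {
  stopifnot(weight >= 0, rise > 0, decay > rise)
  polarity <- match.arg(polarity, c("excitatory", "inhibitory"))
  structure(list(weight = weight, rise = rise, decay = decay,
                 erev = erev, polarity = polarity),
            class = "synaptic_kinetics")
}

#' Default perturbation synapse for a polarity
#'
#' The perturbation weights are 0.006 uS (excitatory) and 0.0054 uS
#' (inhibitory); a perturbation event is scaled 30-fold (thirty synapses
#' collapsed onto the single compartment).  Event kinetics default to
#' rise 0.5 / decay 3 ms (excitatory) and rise 1 / decay 8 ms (inhibitory).
#'
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @export
perturbation_synapse <- function(polarity) {
  polarity <- match.arg(polarity, c("excitatory", "inhibitory"))
  if (polarity == "excitatory")
    synaptic_kinetics(0.006, 0.5, 3, 0, "excitatory")
  else
    synaptic_kinetics(0.0054, 1, 8, -87, "inhibitory")
}

# peak-normalized double exponential on a grid starting at 0
dexp_event <- function(amp, rise, decay, n, dt) {
  t <- (seq_len(n) - 1) * dt
  tp <- rise * decay / (decay - rise) * log(decay / rise)  # time of peak
  norm <- exp(-tp / decay) - exp(-tp / rise)
  amp / norm * (exp(-t / decay) - exp(-t / rise))
}

#' Periodic synaptic perturbation conductance
#'
#' A train of double-exponential conductance events at frequency `freq`,
#' each with peak amplitude `scale * kin$weight` (default scale 30), starting
#' at `onset` and superposing additively.
#'
#' @param freq perturbation frequency (Hz), > 0.
#' @param kin a [synaptic_kinetics()] (see [perturbation_synapse()]).
#' @param duration length (ms).
#' @param dt time step (ms).
#' @param onset time of the first event (ms).
#' @param scale multiple of the single-synapse weight (default 30).
#' @return list with the conductance series `gp` (uS), reversal `ep`, and the
#'   event times.
#' @export
perturbation_conductance <- function(freq, kin, duration, dt, onset = 0,
                                     scale = 30) {
  stopifnot(freq > 0, inherits(kin, "synaptic_kinetics"))
  n <- round(duration / dt)
  period <- 1000 / freq
  events <- seq(onset, duration - dt, by = period)
  if (length(events) <= 1 && freq * duration / 1000 < 1)
    warning("fewer than one perturbation period fits in the trace")
  gp <- numeric(n)
  ev_len <- min(n, ceiling((kin$decay * 12) / dt))
  shape <- dexp_event(scale * kin$weight, kin$rise, kin$decay, ev_len, dt)
  for (te in events) {
    i0 <- round(te / dt) + 1
    j <- i0:min(n, i0 + ev_len - 1)
    gp[j] <- gp[j] + shape[seq_along(j)]
  }
  list(gp = gp, ep = kin$erev, events = events)
}

#' Noisy step-train stimulus for conductance estimation
#'
#' The estimation protocol: `lead_in` ms at the base level, then steps
#' through `step_levels` pA (default 30, 60, 90, 0, -30, -60, -90), each
#' lasting `step_ms`, the whole cycle repeated `repeats` times, with Gaussian
#' white noise (mean `noise_mean`, sd `noise_sd` pA) mixed over the entire
#' train.  The noise mean matches the characterized bias current of the cell.
#'
#' @param dt time step (ms).
#' @param step_levels step currents (pA).
#' @param step_ms per-step duration (ms).
#' @param lead_in initial zero-level segment (ms).
#' @param repeats number of cycle repeats.
#' @param noise_mean,noise_sd noise parameters (pA).
#' @param seed integer seed.
#' @return list with the current series `current` (pA), the noise-free
#'   staircase `levels`, and `dt`.
#' @export
raukf_train <- function(dt = 0.025, step_levels = c(30, 60, 90, 0, -30, -60, -90),
                        step_ms = 196, lead_in = 500, repeats = 4,
                        noise_mean = 4, noise_sd = 5, seed = 1) {
  set.seed(seed)
  base <- c(rep(0, round(lead_in / dt)),
            rep(rep(step_levels, times = repeats), each = round(step_ms / dt)))
  list(current = base + rnorm(length(base), noise_mean, noise_sd),
       levels = base, dt = dt)
}

#' Table of representative OU background parameter sets
#'
#' The ten representative in-vivo-like parameter sets (set 0-9) with their
#' minimum/maximum firing rates over fifty 10-s realizations, shipped as a
#' packaged fixture.
#'
#' @return data.frame with columns `set`, `min_f`, `max_f`, `ge0`, `gi0`,
#'   `De`, `Di`.
#' @export
representative_sets <- function() {
  p <- system.file("extdata", "representative_sets.json",
                   package = "olmcell", mustWork = TRUE)
  as.data.frame(jsonlite::read_json(p, simplifyVector = TRUE))
}

#' @rdname representative_sets
#' @param set set number (0-9).
#' @export
representative_background <- function(set) {
  tb <- representative_sets()
  r <- tb[tb$set == set, ]
  if (nrow(r) != 1) stop("no representative set #", set)
  ou_background(r$ge0, r$gi0, r$De, r$Di)
}
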