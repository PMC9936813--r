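#' @useDynLib olmcell, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd coef lm pf quantile median approx var
#' @importFrom utils write.csv read.csv modifyList
NULL

#' Gating variable specification
#'
#' A Hodgkin-Huxley-style gate with a Boltzmann steady state
#' \eqn{x_\infty(V) = 1/(1+\exp((v_h - V)/k))} (activation for `k > 0`,
#' inactivation for `k < 0`) and a voltage-dependent time constant, either
#' constant or the bell-shaped sigmoid sum
#' \eqn{\tau(V) = \tau_b + \tau_a / (e^{(V-v_1)/k_1} + e^{-(V-v_2)/k_2})} (ms).
#'
#' @param name gate name (e.g. `"m"`).
#' @param power non-negative integer exponent in the channel open fraction.
#' @param vh,k Boltzmann half-activation voltage (mV) and slope (mV).
#' @param tau either a single positive number (constant time constant, ms) or
#'   a list `list(base=, amp=, v1=, k1=, v2=, k2=)` for the bell form.
#' @return an object of class `gating_spec`.
#' @export
gating_spec <- function(name, power, vh, k, tau) {
  stopifnot(is.character(name), length(name) == 1L,
            power >= 0, power == round(power), k != 0)
  if (is.numeric(tau) && length(tau) == 1L) {
    stopifnot(tau > 0)
    tau <- list(form = "constant", base = tau)
  } else {
    stopifnot(is.list(tau), all(c("base", "amp", "v1", "k1", "v2", "k2") %in% names(tau)))
    tau <- c(list(form = "bell"), tau[c("base", "amp", "v1", "k1", "v2", "k2")])
    stopifnot(tau$base > 0, tau$amp >= 0, tau$k1 > 0, tau$k2 > 0)
  }
  structure(list(name = name, power = as.integer(power),
                 vh = vh, k = k, tau = tau),
            class = "gating_spec")
}

#' Ion channel specification
#'
#' @param name channel name; the reference model uses
#'   `"Na"`, `"Kdrf"`, `"Ka"`, `"M"`, `"h"`.
#' @param gbar maximal conductance density (S/cm2, NEURON convention).  The
#'   total compartment conductance is `gbar * area_cm2 * 1e6` microsiemens.
#' @param erev reversal potential (mV).
#' @param gates list of [gating_spec()] objects (may be empty).
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name, gbar, erev, gates = list()) {
  stopifnot(is.character(name), gbar >= 0, is.finite(erev))
  stopifnot(all(vapply(gates, inherits, TRUE, "gating_spec")))
  structure(list(name = name, gbar = gbar, erev = erev, gates = gates),
            class = "channel_spec")
}

#' Single-compartment membrane model
#'
#' Assembles a conductance-based single-compartment model
#' \deqn{C \frac{dV}{dt} = I_{stim} - \sum_x \bar g_x \prod_j s_j^{p_j} (V - E_x) - g_L (V - E_L)}
#' with exponential-Euler gating updates.  Units package-wide: mV, ms, pA,
#' microsiemens (total conductances), pF; channel densities in S/cm2.
#'
#' @param channels list of [channel_spec()] objects (active channels only).
#' @param area_cm2 compartment surface area (cm2).
#' @param cm specific capacitance (uF/cm2).
#' @param leak_gbar leak conductance density (S/cm2).
#' @param leak_erev leak reversal potential (mV).
#' @param bias_pA characterized holding/bias current of the cell (pA).  It is
#'   metadata used by stimulus builders (e.g. the noisy estimation train whose
#'   noise mean matches it); [simulate()] injects only the stimulus it is given.
#' @param v_init default initial membrane potential (mV).
#' @param name model label.
#' @return an object of class `membrane_model`.
#' @export
membrane_model <- function(channels, area_cm2, cm = 1.0,
                           leak_gbar = 1e-5, leak_erev = -70,
                           bias_pA = 4, v_init = -74, name = "model") {
  stopifnot(area_cm2 > 0, cm > 0, leak_gbar >= 0)
  stopifnot(length(channels) >= 1, all(vapply(channels, inherits, TRUE, "channel_spec")))
  cn <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(cn)) stop("duplicate channel names: ", cn[duplicated(cn)][1])
  structure(list(name = name, channels = channels, area_cm2 = area_cm2,
                 cm = cm, leak_gbar = leak_gbar, leak_erev = leak_erev,
                 bias_pA = bias_pA, v_init = v_init),
            class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("<membrane_model '%s'>  C = %.1f pF, area = %.3g cm2\n",
              x$name, capacitance_pF(x), x$area_cm2))
  cat(sprintf("  leak: gbar %.3g S/cm2 (%.3g uS), Erev %.1f mV; bias %.1f pA\n",
              x$leak_gbar, x$leak_gbar * x$area_cm2 * 1e6, x$leak_erev, x$bias_pA))
  for (ch in x$channels) {
    g <- paste(vapply(ch$gates, function(g) sprintf("%s^%d", g$name, g$power), ""),
               collapse = " ")
    cat(sprintf("  %-5s gbar %.3g S/cm2 (%.4g uS), Erev %6.1f mV  [%s]\n",
                ch$name, ch$gbar, ch$gbar * x$area_cm2 * 1e6, ch$erev, g))
  }
  invisible(x)
}

#' Total capacitance of a model (pF)
#' @param model a [membrane_model()].
#' @export
capacitance_pF <- function(model) model$cm * model$area_cm2 * 1e6

#' Total conductance of a channel (microsiemens)
#' @param model a [membrane_model()].
#' @param channel channel name, or `"leak"`.
#' @export
total_gbar_uS <- function(model, channel) {
  if (channel == "leak") return(model$leak_gbar * model$area_cm2 * 1e6)
  i <- match(channel, vapply(model$channels, `[[`, "", "name"))
  if (is.na(i)) stop("no channel named '", channel, "'")
  model$channels[[i]]$gbar * model$area_cm2 * 1e6
}

#' Replace channel conductance densities
#'
#' @param model a [membrane_model()].
#' @param gbar named numeric vector of densities (S/cm2), names matching
#'   channel names (use `"leak"` for the leak density).
#' @return the modified model.
#' @export
set_gbar <- function(model, gbar) {
  stopifnot(is.numeric(gbar), !is.null(names(gbar)))
  cn <- vapply(model$channels, `[[`, "", "name")
  for (nm in names(gbar)) {
    if (nm == "leak") { model$leak_gbar <- unname(gbar[nm]); next }
    i <- match(nm, cn)
    if (is.na(i)) stop("no channel named '", nm, "'")
    model$channels[[i]]$gbar <- unname(gbar[nm])
  }
  model
}

# flat gate names in C++ state order ("Na.m", "Na.h", ...)
gate_names <- function(model) {
  unlist(lapply(model$channels, function(ch)
    vapply(ch$gates, function(g) paste(ch$name, g$name, sep = "."), "")))
}

channel_names <- function(model) vapply(model$channels, `[[`, "", "name")

# encode for the C++ core (total uS, flat tau parameter vector)
as_cpp_model <- function(model) {
  f <- model$area_cm2 * 1e6
  list(
    c_pF = capacitance_pF(model),
    gl_uS = model$leak_gbar * f,
    el_mV = model$leak_erev,
    channels = lapply(model$channels, function(ch) {
      list(gbar_uS = ch$gbar * f, erev = ch$erev,
           gates = lapply(ch$gates, function(g) {
             tp <- if (g$tau$form == "constant") c(0, g$tau$base)
                   else c(1, g$tau$base, g$tau$amp, g$tau$v1, g$tau$k1,
                          g$tau$v2, g$tau$k2)
             list(power = g$power, vh = g$vh, k = g$k, tau = tp)
           }))
    }))
}

#' Steady-state activation and time constant curves of all gates
#'
#' @param model a [membrane_model()].
#' @param V voltage grid (mV).
#' @return a list with matrices `inf` and `tau` (rows = voltages, columns =
#'   gates named `"<channel>.<gate>"`).
#' @export
gate_curves <- function(model, V = seq(-120, 60, by = 0.5)) {
  out <- gate_curves_cpp(as_cpp_model(model), V)
  colnames(out$inf) <- colnames(out$tau) <- gate_names(model)
  out$V <- V
  out
}

#' The packaged reference OLM cell model
#'
#' Loads the reduced single-compartment OLM interneuron model shipped with
#' the package: transient Na (m3h), fast delayed-rectifier K (n4), A-type K
#' (a b), non-inactivating M-type K, h-current, and leak.  The four
#' conductance densities gM = 1.91e-5, gKdrf = 4.33e-3, gKa = 7.31e-3 and
#' gNa = 4.85e-3 S/cm2 are the reference ("actual") values that the filtering
#' module estimates; channel kinetics and passive properties are provisional
#' defaults in the style of the antecedent OLM model family (see the methods
#' vignette) and can be swapped by editing the JSON definition.
#'
#' @return a [membrane_model()].
#' @export
olm_model <- function() {
  load_model(system.file("extdata", "reference_model.json",
                         package = "olmcell", mustWork = TRUE))
}
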