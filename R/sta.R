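#' Extract spike-triggered windows of current proportions
#'
#' From a trace with recorded currents, takes every spike preceded by an
#' inter-spike interval of at least `min_isi` ms and extracts the
#' per-current proportion-of-total series (see [current_shares()]) on
#' `[-pre[1], -pre[2]]` ms relative to spike onset (defaults 195 to 10 ms
#' before the spike, keeping clear of both the previous and the triggering
#' spike).
#'
#' @param trace a `sim_trace` recorded with currents.
#' @param spikes optional `spike_record`.
#' @param min_isi minimum preceding ISI (ms).
#' @param pre window start/end before the spike (ms).
#' @param threshold spike-detection threshold (mV).
#' @param currents columns of the trace's current matrix to use; the default
#'   keeps the intrinsic (biophysical) currents and leak, dropping synaptic
#'   inputs, so the proportions describe the cell's own current balance.
#' @return list of windows; each a matrix (timepoints x currents) with
#'   attribute `spike_time`.  The common relative time grid is attached as
#'   attribute `time` of the list.
#' @export
extract_sta_windows <- function(trace, spikes = NULL, min_isi = 200,
                                pre = c(195, 10), threshold = -10,
                                currents = NULL) {
  if (is.null(trace$currents)) stop("trace has no recorded currents")
  if (is.null(spikes)) spikes <- detect_spikes(trace, threshold)
  on <- spikes$onset_times
  if (is.null(currents))
    currents <- grep("^syn_", colnames(trace$currents), invert = TRUE,
                     value = TRUE)
  sub <- trace[c("currents")]
  sub$currents <- trace$currents[, currents, drop = FALSE]
  sh <- current_shares(sub)
  dt <- trace$dt
  nwin <- round((pre[1] - pre[2]) / dt) + 1
  out <- list()
  if (length(on) >= 2) {
    isis <- diff(on)
    for (k in which(isis >= min_isi) + 1L) {
      i1 <- round((on[k] - pre[1]) / dt) + 1
      if (i1 < 1) next
      w <- sh[i1:(i1 + nwin - 1), , drop = FALSE]
      attr(w, "spike_time") <- on[k]
      out[[length(out) + 1L]] <- w
    }
  }
  attr(out, "time") <- seq(-pre[1], -pre[2], by = dt)
  out
}

#' Harvest spike-triggered windows at a target resonant frequency
#'
#' Repeatedly draws in-vivo-like realizations of one representative
#' background, measures each realization's resonant frequency over `freqs`,
#' and -- only when the measured resonant frequency equals `f_r_target` --
#' collects spike-triggered windows from the run perturbed at that
#' frequency, until `n_windows` windows with 200+ ms preceding ISIs are
#' found or the seed budget is exhausted.
#'
#' @param model a [membrane_model()].
#' @param bg an [ou_background()].
#' @param f_r_target target resonant frequency (Hz), must be in `freqs`.
#' @param freqs perturbation-frequency set used to measure the resonant
#'   frequency.
#' @param polarity perturbation polarity.
#' @param n_windows number of windows requested.
#' @param seeds seed stream to draw from (the budget).
#' @param duration,dt,threshold simulation/detection settings.
#' @return list with `windows` (as in [extract_sta_windows()]), `time`,
#'   `seeds_used`, and `n` (a warning is raised when the budget runs out
#'   before `n_windows`).
#' @export
harvest_windows <- function(model, bg, f_r_target, freqs = frequency_set(),
                            polarity = "inhibitory", n_windows = 50,
                            seeds = 1:1000, duration = 10000, dt = 0.025,
                            threshold = -10) {
  stopifnot(f_r_target %in% freqs)
  kin <- perturbation_synapse(polarity)
  windows <- list()
  used <- integer(0)
  tgrid <- NULL
  for (s in seeds) {
    rr <- tryCatch(
      resonant_frequency(model, bg, freqs, polarity, seed = s,
                         duration = duration, dt = dt, threshold = threshold),
      error = function(e) NULL)
    if (is.null(rr) || rr$f_r != f_r_target) next
    pert <- perturbation_conductance(f_r_target, kin, duration, dt)
    tr <- simulate_ivl(model, bg, duration, dt, s, perturbation = pert,
                       record = "currents")
    ws <- extract_sta_windows(tr, min_isi = 200, threshold = threshold)
    tgrid <- attr(ws, "time")
    for (w in ws) {
      attr(w, "seed") <- s
      windows[[length(windows) + 1L]] <- w
      if (length(windows) >= n_windows) break
    }
    used <- c(used, s)
    if (length(windows) >= n_windows) break
  }
  if (length(windows) < n_windows)
    warning(sprintf("seed budget exhausted: %d of %d windows collected",
                    length(windows), n_windows))
  list(windows = windows, time = tgrid, seeds_used = used,
       n = length(windows))
}

#' Average spike-triggered window
#'
#' @param windows list of window matrices (from [extract_sta_windows()] or
#'   `harvest_windows()$windows`).
#' @return matrix (timepoints x currents): the mean proportion series.
#' @export
sta_mean <- function(windows) {
  if (length(windows) == 0) stop("no windows to average")
  Reduce(`+`, windows) / length(windows)
}

#' Assemble a spike-triggered-average ensemble
#'
#' @param means nested list: `means[[fr]][[set]]` = mean window matrix
#'   (timepoints x currents) for resonant frequency `fr` and representative
#'   set `set`.
#' @param time relative time grid (ms, negative before the spike).
#' @return an `sta_ensemble`: 4-d array `[time, current, set, fr]` plus the
#'   grids.
#' @export
sta_ensemble <- function(means, time) {
  frs <- names(means)
  sets <- names(means[[1]])
  cur <- colnames(means[[1]][[1]])
  if (is.null(cur)) cur <- paste0("I", seq_len(ncol(means[[1]][[1]])))
  arr <- array(NA_real_, c(length(time), length(cur), length(sets), length(frs)),
               dimnames = list(NULL, cur, sets, frs))
  for (f in seq_along(frs)) for (s in seq_along(sets))
    arr[, , s, f] <- as.matrix(means[[f]][[s]])
  structure(list(mean = arr, time = time, currents = cur,
                 sets = sets, frs = as.numeric(frs)),
            class = "sta_ensemble")
}

#' Normalize an STA ensemble across representative sets
#'
#' For each current and resonant frequency, takes absolute values of the
#' mean windows and rescales them by the minimum and maximum over all
#' representative sets and timepoints, mapping the ensemble into [0, 1]:
#' \deqn{\tilde I_x = (|\bar I_x| - \min|\bar I_x|) / (\max|\bar I_x| - \min|\bar I_x|)}
#' Degenerate slices (min = max) become all zeros with a warning.
#'
#' @param ens an [sta_ensemble()].
#' @return the ensemble with `mean` replaced by the normalized array
#'   (`normalized = TRUE`).
#' @export
normalize_sta <- function(ens) {
  stopifnot(inherits(ens, "sta_ensemble"))
  if (length(ens$sets) < 2) stop("normalization requires at least 2 sets")
  a <- abs(ens$mean)
  degenerate <- FALSE
  for (f in seq_along(ens$frs)) for (c in seq_along(ens$currents)) {
    sl <- a[, c, , f]
    lo <- min(sl); hi <- max(sl)
    if (hi > lo) a[, c, , f] <- (sl - lo) / (hi - lo)
    else { a[, c, , f] <- 0; degenerate <- TRUE }
  }
  if (degenerate) warning("degenerate normalization slice (min = max): set to 0")
  ens$mean <- a
  ens$normalized <- TRUE
  ens
}

# sum selected currents per set; returns matrix [time, set]
sta_combined <- function(ens, currents, fr) {
  f <- match(as.character(fr), dimnames(ens$mean)[[4]])
  if (is.na(f)) stop("no frequency ", fr, " in ensemble")
  ci <- match(currents, ens$currents)
  if (anyNA(ci)) stop("unknown current(s): ",
                      paste(currents[is.na(ci)], collapse = ", "))
  apply(ens$mean[, ci, , f, drop = FALSE], c(1, 3), sum)
}

#' Slope of the across-set mean STA
#'
#' Ordinary-least-squares slope of the across-set mean normalized proportion
#' versus time on the analysis range (default 195 to 25 ms before the
#' spike).  For several currents (e.g. the M- and h-current combination) the
#' currents are summed per set before averaging.
#'
#' @param ens a normalized [sta_ensemble()].
#' @param currents one current name, or several to combine.
#' @param fr resonant frequency (must be in the ensemble).
#' @param range analysis time range (ms relative to the spike).
#' @return slope (per ms).
#' @export
slope_of_mean <- function(ens, currents, fr, range = c(-195, -25)) {
  comb <- sta_combined(ens, currents, fr)
  sel <- ens$time >= range[1] & ens$time <= range[2]
  m <- rowMeans(comb[sel, , drop = FALSE])
  tt <- ens$time[sel]
  unname(coef(lm(m ~ tt))[2])
}

#' Spread of an STA ensemble at one resonant frequency
#'
#' Twice the across-set standard deviation of the normalized proportions,
#' summed over all timepoints of the analysis range.  For several currents
#' the per-set sum is taken first.
#'
#' @param ens a normalized [sta_ensemble()].
#' @param currents one current name, or several to combine.
#' @param fr resonant frequency.
#' @param range analysis time range (ms).
#' @param denom `"population"` (divide by n, default) or `"sample"` (n-1)
#'   for the per-timepoint standard deviation across sets.
#' @return the spread (dimensionless); 0 with a warning for a single set.
#' @export
sta_spread <- function(ens, currents, fr, range = c(-195, -25),
                       denom = c("population", "sample")) {
  denom <- match.arg(denom)
  comb <- sta_combined(ens, currents, fr)
  if (ncol(comb) < 2) {
    warning("spread of a single set is 0")
    return(0)
  }
  sel <- ens$time >= range[1] & ens$time <= range[2]
  x <- comb[sel, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (denom == "population") sds <- sds * sqrt((ncol(x) - 1) / ncol(x))
  sum(2 * sds)
}

#' Linear or parabolic trend of an STA statistic over resonant frequency
#'
#' Least-squares fit of slope or spread values against resonant frequency,
#' with fit quality (R^2, overall F-test p-value), the zero crossing of a
#' linear fit (when it falls inside the frequency range), and the vertex of
#' a parabolic fit.
#'
#' @param fr resonant frequencies (Hz).
#' @param value statistic per frequency.
#' @param family `"linear"` or `"parabolic"`.
#' @return a `trend_fit`: `coef`, `r_squared`, `p_value`, and
#'   `zero_crossing` (linear) or `vertex` (parabolic).
#' @export
trend_fits <- function(fr, value, family = c("linear", "parabolic")) {
  family <- match.arg(family)
  keep <- is.finite(fr) & is.finite(value)
  fr <- fr[keep]; value <- value[keep]
  need <- if (family == "linear") 3 else 4
  if (length(fr) < need)
    stop("need at least ", need, " points for a ", family, " fit")
  fit <- if (family == "linear") lm(value ~ fr) else lm(value ~ fr + I(fr^2))
  if (any(is.na(coef(fit)))) stop("rank-deficient trend design")
  sm <- summary(fit)
  p <- tryCatch(unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                          lower.tail = FALSE)),
                error = function(e) NA_real_)
  out <- list(family = family, coef = coef(fit), r_squared = sm$r.squared,
              p_value = p, fitted = data.frame(fr = fr, value = value,
                                               fit = fitted(fit)))
  if (family == "linear") {
    b <- coef(fit)
    xc <- if (abs(b[2]) > 0) unname(-b[1] / b[2]) else NA_real_
    out$zero_crossing <- if (!is.na(xc) && xc >= min(fr) && xc <= max(fr)) xc
                         else NA_real_
  } else {
    b <- coef(fit)
    out$vertex <- if (b[3] != 0) unname(-b[2] / (2 * b[3])) else NA_real_
  }
  structure(out, class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  extra <- if (x$family == "linear")
    sprintf("zero crossing %.2f Hz", x$zero_crossing)
  else sprintf("vertex %.2f Hz", x$vertex)
  cat(sprintf("<trend_fit %s> R^2 = %.3f, p = %.3g, %s\n",
              x$family, x$r_squared, x$p_value, extra))
  invisible(x)
}
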