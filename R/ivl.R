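#' Simulate the model under an OU background (one in-vivo-like realization)
#'
#' @param model a [membrane_model()].
#' @param bg an [ou_background()].
#' @param duration length (ms), default 10 s.
#' @param dt time step (ms).
#' @param seed integer seed for the OU realization.
#' @param perturbation optional list from [perturbation_conductance()] whose
#'   `gp`/`ep` are added to the synaptic drive.
#' @param record passed to [simulate_cell()].
#' @return a `sim_trace`.
#' @export
simulate_ivl <- function(model, bg, duration = 10000, dt = 0.025, seed = 1,
                         perturbation = NULL, record = "V") {
  ou <- ou_conductances(bg, duration, dt, seed)
  stim <- list(current = 0, ge = ou$ge, gi = ou$gi, ee = ou$ee, ei = ou$ei)
  if (!is.null(perturbation)) {
    stim$gp <- perturbation$gp
    stim$ep <- perturbation$ep
  }
  simulate_cell(model, stim, duration = duration, dt = dt, record = record,
                seed = seed)
}

#' Subthreshold voltage statistics after spike removal
#'
#' Removes all samples within `window` ms on either side of each spike peak
#' (overlapping windows merge) and returns the mean and standard deviation of
#' the remaining subthreshold voltage.
#'
#' @param trace a `sim_trace`.
#' @param spikes a `spike_record` from [detect_spikes()]; computed if `NULL`.
#' @param window half-width of the exclusion window around spike peaks (ms).
#' @return list with `mean_V`, `sd_V`, `var_V` and `n_retained`.
#' @export
subthreshold_stats <- function(trace, spikes = NULL, window = 7) {
  if (is.null(spikes)) spikes <- detect_spikes(trace)
  keep <- rep(TRUE, length(trace$V))
  for (tp in spikes$peak_times) {
    i <- max(1, floor((tp - window) / trace$dt) + 1)
    j <- min(length(keep), ceiling((tp + window) / trace$dt) + 1)
    keep[i:j] <- FALSE
  }
  if (!any(keep)) stop("no subthreshold samples remain after spike removal")
  v <- trace$V[keep]
  list(mean_V = mean(v), sd_V = sd(v), var_V = var(v), n_retained = length(v))
}

#' Coefficient of variation of inter-spike intervals
#'
#' @param spikes a `spike_record` (or numeric vector of spike times, ms).
#' @return sd(ISI)/mean(ISI); `NA` with fewer than 3 spikes (the
#'   irregularity criterion then fails).
#' @export
isi_cv <- function(spikes) {
  times <- if (is.numeric(spikes)) spikes else spikes$onset_times
  if (length(times) < 3) return(NA_real_)
  isi <- diff(times)
  sd(isi) / mean(isi)
}

#' In-vivo-like (IVL) state metric
#'
#' Scores a 10-s trace on the four literature-derived criteria for an OLM
#' cell in vivo, each a strict inequality:
#' mean subthreshold voltage > -70.588 mV; subthreshold voltage sd > 2.2 mV;
#' ISI coefficient of variation > 0.8; firing rate strictly between 3 and
#' 25 Hz (rate = spike count / duration).  The state is IVL-valid when all
#' four hold.
#'
#' @param trace a `sim_trace` of at least 10 s.
#' @param threshold spike-detection threshold (mV).
#' @return an `ivl_result`: `stats`, `isi_cv`, `rate`, logical vector
#'   `criteria`, integer `score` (0-4) and `valid`.
#' @export
ivl_metric <- function(trace, threshold = -10) {
  dur_s <- length(trace$V) * trace$dt / 1000
  spikes <- detect_spikes(trace, threshold)
  st <- subthreshold_stats(trace, spikes)
  cv <- isi_cv(spikes)
  f <- length(spikes$onset_times) / dur_s
  crit <- c(mean_V = st$mean_V > -70.588,
            sd_V = st$sd_V > 2.2,
            isi_cv = !is.na(cv) && cv > 0.8,
            rate = f > 3 && f < 25)
  structure(list(stats = st, isi_cv = cv, rate = f, criteria = crit,
                 score = sum(crit), valid = all(crit)),
            class = "ivl_result")
}

#' @export
print.ivl_result <- function(x, ...) {
  cat(sprintf(paste0("<ivl_result> score %d/4 (%s)  Vm = %.2f mV, sd = %.2f mV,",
                     " ISICV = %.2f, f = %.1f Hz\n"),
              x$score, if (x$valid) "IVL" else "not IVL",
              x$stats$mean_V, x$stats$sd_V, x$isi_cv, x$rate))
  invisible(x)
}

#' Grid search for OU parameter sets that yield IVL states
#'
#' Evaluates every combination on the `ge0 x gi0 x De x Di` grid with a
#' single 10-s realization and keeps the sets whose trace (i) is IVL-valid
#' and (ii) satisfies the additional comparability bounds on the subthreshold
#' mean and variance.  The additional bounds are applied to the same single
#' evaluation trace.
#'
#' The full published grid spans ge0 in [0.003, 0.006] step 0.0002, gi0 in
#' [0.008, 0.012] step 0.00027, De in [0, 0.0016] step 0.000107 and Di in
#' [0, 0.01] step 0.00067 uS (build grids by point count, not accumulation).
#'
#' @param model a [membrane_model()].
#' @param ge0,gi0,De,Di numeric vectors defining the grid.
#' @param mean_bounds additional bounds (mV) on the subthreshold mean.
#' @param var_bounds additional bounds (mV^2) on the subthreshold variance.
#' @param duration evaluation duration (ms).
#' @param dt time step (ms).
#' @param seed seed of the single evaluation realization.
#' @return data.frame, one row per grid point: parameters, statistics, IVL
#'   score and logical `pass`.
#' @export
constrained_search <- function(model, ge0, gi0, De, Di,
                               mean_bounds = c(-70, -67.5),
                               var_bounds = c(8, 10),
                               duration = 10000, dt = 0.025, seed = 1) {
  grid <- expand.grid(ge0 = ge0, gi0 = gi0, De = De, Di = Di,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    bg <- ou_background(grid$ge0[i], grid$gi0[i], grid$De[i], grid$Di[i])
    tr <- simulate_ivl(model, bg, duration, dt, seed)
    m <- ivl_metric(tr)
    data.frame(mean_V = m$stats$mean_V, var_V = m$stats$var_V,
               sd_V = m$stats$sd_V, isi_cv = m$isi_cv, rate = m$rate,
               score = m$score,
               pass = m$valid &&
                 m$stats$mean_V > mean_bounds[1] & m$stats$mean_V < mean_bounds[2] &
                 m$stats$var_V > var_bounds[1] & m$stats$var_V < var_bounds[2])
  })
  cbind(grid, do.call(rbind, res))
}

#' Firing-rate range of a parameter set over many seeds
#'
#' @param model a [membrane_model()].
#' @param bg an [ou_background()].
#' @param seeds integer vector of seeds (the same seeds should be reused
#'   across sets).
#' @param duration,dt,threshold simulation/detection settings.
#' @return list with `min_f`, `max_f` (Hz) and the per-seed `rates`.
#' @export
rate_range <- function(model, bg, seeds = 1:50, duration = 10000, dt = 0.025,
                       threshold = -10) {
  rates <- vapply(seeds, function(s) {
    tr <- simulate_ivl(model, bg, duration, dt, s)
    length(detect_spikes(tr, threshold)$onset_times) / duration * 1000
  }, 1.0)
  list(min_f = min(rates), max_f = max(rates), rates = rates)
}

#' Select representative parameter sets spanning the firing-rate plane
#'
#' For each candidate set the (min, max) firing rate over `seeds` is
#' computed; `n_out` sets spanning the (min_f, max_f) plane are then chosen
#' by greedy farthest-point sampling, seeded with the lowest-rate set (the
#' point closest to the centroid when `n_out = 1`).
#'
#' @param model a [membrane_model()].
#' @param candidates data.frame with columns `ge0`, `gi0`, `De`, `Di`
#'   (e.g. passing rows of [constrained_search()]).
#' @param seeds seeds reused for every set.
#' @param n_out number of representatives.
#' @param duration,dt simulation settings.
#' @return data.frame of the selected sets with `set` (0-based, ordered by
#'   min_f), `min_f`, `max_f` and the OU parameters.
#' @export
select_representatives <- function(model, candidates, seeds = 1:50,
                                   n_out = 10, duration = 10000, dt = 0.025) {
  if (nrow(candidates) < n_out) {
    warning("fewer valid sets (", nrow(candidates), ") than requested (",
            n_out, "); returning all")
    n_out <- nrow(candidates)
  }
  rr <- lapply(seq_len(nrow(candidates)), function(i) {
    bg <- ou_background(candidates$ge0[i], candidates$gi0[i],
                        candidates$De[i], candidates$Di[i])
    rate_range(model, bg, seeds, duration, dt)[c("min_f", "max_f")]
  })
  pts <- cbind(min_f = vapply(rr, `[[`, 1.0, "min_f"),
               max_f = vapply(rr, `[[`, 1.0, "max_f"))
  ctr <- colMeans(pts)
  d2ctr <- rowSums(sweep(pts, 2, ctr)^2)
  if (n_out == 1) {
    sel <- which.min(d2ctr)
  } else {
    sel <- which.min(pts[, "min_f"] + pts[, "max_f"])   # lowest-rate anchor
    while (length(sel) < n_out) {
      d2 <- apply(pts, 1, function(p)
        min(colSums((t(pts[sel, , drop = FALSE]) - p)^2)))
      d2[sel] <- -Inf
      sel <- c(sel, which.max(d2))
    }
  }
  ord <- sel[order(pts[sel, "min_f"])]
  data.frame(set = seq_along(ord) - 1L,
             min_f = pts[ord, "min_f"], max_f = pts[ord, "max_f"],
             candidates[ord, c("ge0", "gi0", "De", "Di")],
             row.names = NULL)
}
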