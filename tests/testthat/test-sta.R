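# build a synthetic ensemble: means[[fr]][[set]] = time x current matrix
synth_ensemble <- function(frs, nset, time, fun) {
  means <- lapply(seq_along(frs), function(f)
    lapply(seq_len(nset), function(s) {
      mm <- fun(frs[f], s, time)
      colnames(mm) <- c("M", "h")
      mm
    }))
  names(means) <- as.character(frs)
  for (f in seq_along(frs)) names(means[[f]]) <- as.character(seq_len(nset) - 1)
  sta_ensemble(means, time)
}

test_that("windows are extracted only after long ISIs at the right offsets", {
  # crafted trace: spikes at 300, 550, 800, 1050 ms -> three 250 ms ISIs
  n <- 1200
  V <- rep(-65, n)
  V[c(300, 550, 800, 1050) + 1] <- 10
  cur <- cbind(a = rep(-1, n), b = rep(3, n))
  tr <- fake_trace(V, dt = 1, currents = cur)
  ws <- extract_sta_windows(tr, min_isi = 200, pre = c(195, 10))
  expect_equal(length(ws), 3)
  expect_equal(vapply(ws, attr, 1.0, "spike_time"), c(550, 800, 1050))
  expect_equal(attr(ws, "time"), seq(-195, -10, by = 1))
  # shares of (-1, 3): 0.25 each in magnitude
  expect_equal(unique(as.vector(ws[[1]][, "a"])), -0.25)
  expect_equal(unique(as.vector(ws[[1]][, "b"])), 0.75)

  # all samples lie >= 10 ms after the previous spike (window accounting)
  for (w in ws) {
    st <- attr(w, "spike_time")
    expect_true(st - 195 >= 0)
    expect_gte(st - 195 - (st - 250), 10)
  }

  # fast firing (all ISIs < 200 ms) yields no windows
  Vf <- rep(-65, 1000)
  Vf[seq(50, 950, by = 100) + 1] <- 10
  expect_equal(length(extract_sta_windows(
    fake_trace(Vf, dt = 1, currents = cur[1:1000, ]))), 0)
})

test_that("accepted windows all satisfy the minimum-ISI rule by recomputation", {
  m <- ref_model_cached()
  bg <- representative_background(0)
  tr <- simulate_ivl(m, bg, 8000, seed = 3, record = "currents")
  sp <- detect_spikes(tr)
  ws <- extract_sta_windows(tr, sp)
  isis <- diff(sp$onset_times)
  for (w in ws) {
    k <- match(attr(w, "spike_time"), sp$onset_times)
    expect_gte(isis[k - 1], 200)
  }
  # pre-normalization proportions sum to one in absolute value
  expect_equal(rowSums(abs(ws[[1]])), rep(1, nrow(ws[[1]])), tolerance = 1e-9)
})

test_that("normalization maps each current/frequency slice onto [0, 1]", {
  time <- seq(-195, -10, by = 5)
  # hand-built: set s has constant level s+1 for M (after |.|: 2, 4, 6)
  ens <- synth_ensemble(8, 3, time, function(fr, s, tt)
    cbind(M = rep(2 * s, length(tt)), h = seq_along(tt) * s))
  nz <- normalize_sta(ens)
  expect_equal(unique(as.vector(nz$mean[, "M", 1, 1])), 0)
  expect_equal(unique(as.vector(nz$mean[, "M", 2, 1])), 0.5)
  expect_equal(unique(as.vector(nz$mean[, "M", 3, 1])), 1)
  expect_true(all(nz$mean >= 0 & nz$mean <= 1))

  # random ensembles stay bounded
  set.seed(3)
  re <- synth_ensemble(c(4, 8), 4, time, function(fr, s, tt)
    cbind(M = rnorm(length(tt)), h = rnorm(length(tt))))
  rn <- normalize_sta(re)
  expect_true(all(rn$mean >= 0 & rn$mean <= 1))

  # identical sets degenerate to zeros with a warning
  ident <- synth_ensemble(8, 2, time, function(fr, s, tt)
    cbind(M = rep(1, length(tt)), h = rep(2, length(tt))))
  expect_warning(nid <- normalize_sta(ident), "degenerate")
  expect_true(all(nid$mean == 0))
})

test_that("slopes of constructed ensembles are recovered exactly", {
  time <- seq(-195, -10, by = 1)
  ens <- synth_ensemble(8, 3, time, function(fr, s, tt)
    cbind(M = 0.002 * tt + 0.5, h = rep(0.3, length(tt))))
  ens$normalized <- TRUE
  expect_equal(slope_of_mean(ens, "M", 8), 0.002, tolerance = 1e-12)
  expect_equal(slope_of_mean(ens, "h", 8), 0, tolerance = 1e-12)
  # combined slope of two linear currents is the sum of slopes here
  expect_equal(slope_of_mean(ens, c("M", "h"), 8), 0.002, tolerance = 1e-12)
})

test_that("combining before normalization differs from summing normalized slopes", {
  time <- seq(-195, -10, by = 5)
  # nonlinear in set index so normalization does not commute with summation
  raw <- synth_ensemble(8, 3, time, function(fr, s, tt)
    cbind(M = s^2 * (0.001 * tt + 1), h = (4 - s) * (-0.002 * tt + 1)))
  nz <- normalize_sta(raw)
  combined <- slope_of_mean(nz, c("M", "h"), 8)
  separate <- slope_of_mean(nz, "M", 8) + slope_of_mean(nz, "h", 8)
  expect_equal(combined, separate, tolerance = 1e-12)  # same on normalized sum
  # but normalizing the pre-summed current gives a different slope
  pre <- synth_ensemble(8, 3, time, function(fr, s, tt)
    cbind(M = s^2 * (0.001 * tt + 1) + (4 - s) * (-0.002 * tt + 1),
          h = rep(0, length(tt))))
  nzp <- suppressWarnings(normalize_sta(pre))  # all-zero h slice is degenerate
  expect_false(isTRUE(all.equal(slope_of_mean(nzp, "M", 8), combined)))
})

test_that("spread follows the summed two-standard-deviation definition", {
  time <- seq(-195, -25, by = 1)
  # two sets differing by a constant c at every timepoint
  cc <- 0.2
  ens <- synth_ensemble(8, 2, time, function(fr, s, tt)
    cbind(M = rep(0.3 + (s - 1) * cc, length(tt)), h = rep(0, length(tt))))
  ens$normalized <- TRUE
  # population sd of {x, x + c} is c/2 at each of the timepoints
  expect_equal(sta_spread(ens, "M", 8, range = c(-195, -25)),
               length(time) * 2 * cc / 2, tolerance = 1e-12)
  # sample-denominator variant: sd = c/sqrt(2)
  expect_equal(sta_spread(ens, "M", 8, denom = "sample"),
               length(time) * 2 * cc / sqrt(2), tolerance = 1e-12)
  # permutation symmetry
  ens2 <- synth_ensemble(8, 2, time, function(fr, s, tt)
    cbind(M = rep(0.3 + (2 - s) * cc, length(tt)), h = rep(0, length(tt))))
  ens2$normalized <- TRUE
  expect_equal(sta_spread(ens2, "M", 8), sta_spread(ens, "M", 8))
  # identical sets spread to zero
  id <- synth_ensemble(8, 2, time, function(fr, s, tt)
    cbind(M = rep(0.4, length(tt)), h = rep(0, length(tt))))
  id$normalized <- TRUE
  expect_equal(sta_spread(id, "M", 8), 0)
})

test_that("trend fits recover exact lines and parabolas", {
  fr <- 1:20
  lin <- suppressWarnings(trend_fits(fr, 2 * fr - 10, "linear"))
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$zero_crossing, 5, tolerance = 1e-10)
  par <- suppressWarnings(trend_fits(1:15, 3 * (1:15 - 8)^2 + 2, "parabolic"))
  expect_equal(par$vertex, 8, tolerance = 1e-10)
  expect_equal(par$r_squared, 1)
  # constant values: zero slope, crossing undefined
  cst <- suppressWarnings(trend_fits(fr, rep(1, 20), "linear"))
  expect_equal(unname(cst$coef[2]), 0, tolerance = 1e-12)
  expect_true(is.na(cst$zero_crossing))
  expect_error(trend_fits(c(1, 2), c(1, 2), "linear"), "at least")
})
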