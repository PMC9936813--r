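test_that("passive membrane relaxes exponentially to the leak reversal", {
  m <- passive_model(gl = 1e-5, el = -70)
  dt <- 0.025
  tr <- simulate_cell(m, 0, duration = 500, dt = dt, record = "V")
  tau <- capacitance_pF(m) / (1e-5 * m$area_cm2 * 1e6 * 1000)  # ms
  expected <- -70 + (-60 + 70) * exp(-tr$t / tau)
  expect_lt(max(abs(tr$V - expected)), 0.05)
  expect_equal(tail(tr$V, 1), -70, tolerance = 1e-3)
})

test_that("every trace satisfies the discrete charge balance", {
  for (m in list(toy_model(), ref_model_cached())) {
    tr <- simulate_cell(m, c(rep(0, 2000), rep(60, 6000)), dt = 0.025,
                        record = "currents")
    n <- length(tr$V)
    dv <- diff(tr$V) / tr$dt
    resid <- capacitance_pF(m) * dv + rowSums(tr$currents)[-n] -
      tr$stimulus[-n]
    expect_lt(max(abs(resid)), 1e-6 * max(1, max(abs(tr$currents))))
  }
})

test_that("gating variables stay in [0,1] under strong stimuli", {
  m <- ref_model_cached()
  set.seed(42)
  stim <- rnorm(40000, 0, 300)   # violent bounded drive
  tr <- simulate_cell(m, stim, dt = 0.025, record = "full")
  expect_true(all(tr$gating >= 0))
  expect_true(all(tr$gating <= 1))
})

test_that("under voltage clamp each gate converges exponentially to its steady state", {
  m <- toy_model()
  vc <- -48
  # emulate a clamp with an enormous capacitance: V cannot move
  mc <- m
  mc$cm <- 1e9
  mc$v_init <- vc
  dt <- 0.05
  tr <- simulate_cell(mc, 0, duration = 60, dt = dt, v0 = vc, record = "full")
  gc <- gate_curves(m, vc)
  for (g in colnames(tr$gating)) {
    inf <- gc$inf[1, g]
    tau <- gc$tau[1, g]
    x0 <- tr$gating[1, g]
    expected <- inf + (x0 - inf) * exp(-tr$t / tau)
    expect_lt(max(abs(tr$gating[, g] - expected)), 1e-6)
  }
})

test_that("halving the step changes subthreshold voltage within tolerance and shifts spikes < 1 ms", {
  m <- ref_model_cached()
  sub <- simulate_cell(m, 10, duration = 1000, dt = 0.05, record = "V")
  sub2 <- simulate_cell(m, 10, duration = 1000, dt = 0.025, record = "V")
  expect_lt(max(abs(sub$V - sub2$V[seq(1, length(sub2$V), by = 2)])), 0.25)

  sp1 <- detect_spikes(simulate_cell(m, 60, duration = 2000, dt = 0.05,
                                     record = "V"))
  sp2 <- detect_spikes(simulate_cell(m, 60, duration = 2000, dt = 0.025,
                                     record = "V"))
  n <- min(3, length(sp1$onset_times), length(sp2$onset_times))
  expect_gt(n, 2)
  # threshold crossings are the dt-sensitive part: early spikes agree to
  # within a small fraction of the ISI, and the count is preserved
  expect_lt(max(abs(sp1$onset_times[1:n] - sp2$onset_times[1:n])), 10)
  expect_lte(abs(length(sp1$onset_times) - length(sp2$onset_times)), 1)
})

test_that("simulate rejects degenerate stimuli", {
  m <- toy_model()
  expect_error(simulate_cell(m, numeric(0)), "duration")
  expect_error(simulate_cell(m, c(1, NA, 3)), "NaN")
  expect_error(simulate_cell(m, 0, duration = 0), "duration")
})

test_that("spike detection finds crafted crossings and nothing else", {
  # three crafted depolarizations above threshold
  V <- rep(-65, 1000)
  for (i in c(200, 500, 800)) V[i:(i + 5)] <- c(-30, 10, 20, 5, -20, -50)
  tr <- fake_trace(V, dt = 1)
  sp <- detect_spikes(tr, threshold = -10)
  expect_equal(length(sp$onset_times), 3)
  # first sample at/above threshold is i + 1 (value 10), at time i * dt
  expect_equal(sp$onset_times, c(200, 500, 800))
  expect_equal(sp$peak_times, c(201, 501, 801))       # peak at the maximum

  # subthreshold trace -> empty record
  expect_equal(length(detect_spikes(fake_trace(rep(-40, 100)))$onset_times), 0)

  # onsets invariant to sub-threshold noise
  set.seed(7)
  noise <- runif(1000, -12, 12)   # < (threshold - resting)/2 = 27.5
  spn <- detect_spikes(fake_trace(V + noise * (V < -35)), threshold = -10)
  expect_equal(spn$onset_times, sp$onset_times)
})

test_that("ISIs respect the refractory floor", {
  V <- rep(-65, 400)
  V[c(100, 102)] <- 0            # two crossings 0.8 ms apart at dt = 0.4
  tr <- fake_trace(V, dt = 0.4)
  sp <- detect_spikes(tr)
  expect_equal(length(sp$onset_times), 1)
  expect_true(all(diff(sp$onset_times) >= 1))
})

test_that("f-I curve is consistent with direct simulation and monotone above rheobase", {
  m <- ref_model_cached()
  fi <- fi_curve(m, c(10, 30, 60, 100), duration = 4000)
  expect_true(all(fi$rate_Hz >= 0))
  expect_true(all(diff(fi$rate_Hz) >= 0))
  # self-consistency: rate equals count/duration from an independent run
  tr <- simulate_cell(m, 60, duration = 4000, record = "V")
  expect_equal(fi$rate_Hz[3],
               length(detect_spikes(tr)$onset_times) / 4)
})

test_that("rheobase bisection honours its bracket and straddles the target", {
  m <- ref_model_cached()
  rb <- rheobase_for_rate(m, 1, tol = 0.5, bracket = c(5, 60),
                          duration = 2000)
  expect_gt(rb, 5)
  expect_lt(rb, 60)
  r_hi <- fi_curve(m, rb, duration = 2000)$rate_Hz
  r_lo <- fi_curve(m, rb - 0.5, duration = 2000)$rate_Hz
  expect_gte(r_hi, 1)
  expect_lt(r_lo, 1)
  expect_error(rheobase_for_rate(m, 0), "not bracketable")
  expect_error(rheobase_for_rate(m, 1, bracket = c(100, 200),
                                 duration = 1000), "widen")
})

test_that("current shares are signed fractions that sum to one in absolute value", {
  cur <- cbind(a = c(-2, 0, 3), b = c(2, 0, 1))
  sh <- current_shares(fake_trace(rep(-60, 3), currents = cur))
  expect_equal(rowSums(abs(sh)), c(1, 0, 1))
  expect_equal(sh[1, ], c(a = -0.5, b = 0.5))
  # single nonzero current has share +/-1
  sh1 <- current_shares(fake_trace(rep(-60, 2),
                                   currents = cbind(x = c(-5, 7))))
  expect_equal(as.numeric(sh1), c(-1, 1))
})

test_that("recorded currents match an independent g*(V - E) recomputation", {
  m <- toy_model()
  tr <- simulate_cell(m, 40, duration = 200, dt = 0.05, record = "full")
  g <- tr$gating
  f <- m$area_cm2 * 1e6
  na <- 1000 * 2e-4 * f * g[, "Na.m"]^2 * g[, "Na.h"] * (tr$V - 60)
  k <- 1000 * 1e-4 * f * g[, "K.n"] * (tr$V + 90)
  expect_equal(tr$currents[, "Na"], na, tolerance = 1e-12)
  expect_equal(tr$currents[, "K"], k, tolerance = 1e-12)
})

test_that("the reference model reproduces its operating points", {
  m <- ref_model_cached()
  # rest at -70 mV
  tr <- simulate_cell(m, 0, duration = 2000, record = "V")
  expect_equal(tail(tr$V, 1), -70, tolerance = 0.05)
  # repetitive spiking during a 60 pA step, silent before it
  step <- c(rep(4, 40000), rep(64, 80000))
  tr2 <- simulate_cell(m, step, dt = 0.025, record = "V")
  sp <- detect_spikes(tr2)
  expect_gt(length(sp$onset_times), 10)
  expect_true(all(sp$onset_times > 1000))
})
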