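test_that("sigma points reproduce the mean and covariance they were drawn from", {
  set.seed(5)
  n <- 5
  A <- matrix(rnorm(n * n), n)
  P <- crossprod(A) + diag(n) * 0.1
  mu <- rnorm(n)
  sp <- sigma_points(mu, P, raukf_config(alpha = 0.8))
  m_rec <- as.numeric(sp$points %*% sp$wm)
  D <- sp$points - m_rec
  P_rec <- D %*% (sp$wc * t(D))
  expect_equal(m_rec, mu, tolerance = 1e-10)
  expect_equal(P_rec, P, tolerance = 1e-8)

  # symmetry for n = 1: points {mu, mu + c, mu - c}
  s1 <- sigma_points(0, matrix(1), raukf_config(alpha = 1))
  expect_equal(s1$points[1, 1], 0)
  expect_equal(s1$points[1, 2], -s1$points[1, 3])

  # scaling change preserves the reconstructed mean
  s2 <- sigma_points(mu, P, raukf_config(alpha = 0.1))
  expect_equal(as.numeric(s2$points %*% s2$wm), mu, tolerance = 1e-9)
})

test_that("the UKF equals the closed-form Kalman filter on a linear-Gaussian system", {
  set.seed(8)
  A <- matrix(c(0.95, 0.1, -0.05, 0.9), 2)
  Q <- diag(c(0.01, 0.02))
  H <- matrix(c(1, 0), 1)
  R <- 0.5
  x <- c(1, -1)
  ys <- numeric(60)
  ys[1] <- x[1]
  for (k in 2:60) {
    x <- drop(A %*% x) + drop(mvt <- t(chol(Q)) %*% rnorm(2))
    ys[k] <- x[1] + rnorm(1, 0, sqrt(R))
  }
  x0 <- c(0, 0)
  P0 <- diag(2)
  kf <- kf_linear(A, Q, H, R, x0, P0, ys)
  uk <- ukf_filter(function(z, k) drop(A %*% z), x0, P0, Q, R, ys,
                   cfg = raukf_config(alpha = 0.9))
  expect_equal(uk$means, kf$means, tolerance = 1e-8)
  expect_equal(uk$P, kf$P, tolerance = 1e-8)
})

test_that("prediction respects the random-walk identity and inflates covariance", {
  # identity dynamics: posterior covariance grows by Q between observations
  Q <- diag(c(0.1, 0.2))
  uk <- ukf_filter(function(z, k) z, c(0, 0), diag(2), Q, R = 1e6,
                   ys = rep(0, 4), cfg = raukf_config(alpha = 1))
  # with a nearly uninformative observation, P ~ P0 + 3 Q
  expect_equal(diag(uk$P), diag(diag(2) + 3 * Q), tolerance = 1e-2)
})

test_that("noise adaptation is inactive without faults and corrects a miscalibrated R", {
  set.seed(12)
  A <- matrix(0.9)
  Q <- matrix(1e-4)
  R_true <- 1
  x <- 0
  ys <- numeric(400)
  for (k in 2:400) {
    x <- 0.9 * x + rnorm(1, 0, 1e-2)
    ys[k] <- x + rnorm(1, 0, sqrt(R_true))
  }
  # calibrated filter with a huge fault threshold: Q and R never change
  cfg_quiet <- raukf_config(alpha = 1, fault_p = 1e-12)
  uk0 <- ukf_filter(function(z, k) 0.9 * z, 0, matrix(1), Q, R_true, ys,
                    cfg = cfg_quiet, adapt = TRUE)
  expect_equal(uk0$R, R_true)
  expect_equal(uk0$Q, Q)
  # R initialized 25x too small: fault-triggered updates recover its order of
  # magnitude (the tail-sample estimator equilibrates somewhat above truth)
  cfg <- raukf_config(alpha = 1)
  uk <- ukf_filter(function(z, k) 0.9 * z, 0, matrix(1), Q, R = 0.04, ys,
                   cfg = cfg, adapt = TRUE)
  expect_gt(uk$R, 0.3)
  expect_lt(uk$R, 8)
})

test_that("the compiled filter matches the reference R filter on a short recording", {
  m <- ref_model_cached()
  dt <- 0.05
  train <- raukf_train(dt = dt, seed = 9)
  nseg <- 4000                                   # 200 ms segment
  u <- train$current[1:nseg] + 15                # depolarized, subthreshold
  tr <- simulate_cell(m, u, dt = dt, record = "V")
  set.seed(31)
  y <- tr$V + rnorm(nseg, 0, 0.25)

  cn <- channel_names(m)
  idx <- match(c("M", "Kdrf", "Ka", "Na"), cn)
  truth <- theta_true(m)
  th0 <- truth * c(1.3, 0.8, 1.2, 0.9)
  G <- length(gate_names(m))
  tc <- olmcell:::theta_init_cov(th0)
  P0 <- diag(c(rep(1e-4, 1 + G), tc$P))
  Q0 <- diag(c(rep(1e-8, 1 + G), tc$Q))
  cfg <- raukf_config(fault_p = 1e-15, q_relax_ms = 0, r_relax_ms = 0)

  # R reference engine: one compiled model step per sigma point
  cppm <- olmcell:::as_cpp_model(m)
  gsc <- m$area_cm2 * 1e6
  fstep <- function(z, k) {
    mm <- cppm
    for (i in seq_along(idx))
      mm$channels[[idx[i]]]$gbar_uS <- max(0, z[1 + G + i]) * gsc
    out <- simulate_cpp(mm, u[k - 1], dt, z[1],
                        pmin(1, pmax(0, z[2:(1 + G)])),
                        numeric(0), numeric(0), numeric(0), 0, -87, 0, 0L)
    c(out$v_end, out$gate_end, z[(2 + G):length(z)])
  }
  gc0 <- gate_curves(m, y[1])
  x0 <- c(y[1], gc0$inf[1, ], th0)
  ref <- ukf_filter(fstep, x0, P0, Q0, 0.0625, y, cfg = cfg)

  cpp <- olmcell:::raukf_cpp(cppm, idx - 1L, gsc, y, u, dt, th0,
                             diag(P0), diag(Q0), 0.0625,
                             cfg$alpha, cfg$beta, cfg$kappa, cfg$lambda0,
                             cfg$delta0, cfg$a, cfg$b, cfg$chi2_thresh,
                             0, 0, nseg + 1L)
  ref_theta <- ref$means[nseg, (2 + G):(5 + G)]
  expect_equal(unname(cpp$theta), unname(ref_theta), tolerance = 1e-6)
})

test_that("conductances are recovered from a self-generated recording", {
  m <- ref_model_cached()
  # short train (one repeat) for speed; looser expectations than the full run
  train <- raukf_train(dt = 0.025, repeats = 2, seed = 21)
  tr <- simulate_cell(m, train$current, dt = 0.025, record = "V")
  set.seed(22)
  y <- tr$V + rnorm(length(tr$V), 0, 0.25)
  est <- run_raukf(m, y, train$current, dt = 0.025, theta0 = "poor",
                   R0 = 0.0625)
  expect_true(all(est$pct_diff < 8))
  expect_equal(unname(est$theta_se), unname(sqrt(diag(est$P_final)[9:12])))
  # optimal start stays near the truth throughout
  est2 <- run_raukf(m, y, train$current, dt = 0.025, theta0 = "optimal",
                    R0 = 0.0625)
  expect_true(all(est2$pct_diff < 5))
})

test_that("theta initialization helpers follow their definitions", {
  th <- c(1.91e-5, 4.33e-3, 7.31e-3, 4.85e-3)
  expect_equal(theta_poor(th), c(1e-5, 1e-3, 1e-3, 1e-3))
  tc <- olmcell:::theta_init_cov(c(1e-5, 1e-3))
  expect_equal(tc$P, c(1e-10, 1e-6))
  m <- ref_model_cached()
  expect_equal(unname(theta_true(m)), th)
})

test_that("percent difference behaves as a relative error", {
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(1.89e-5, 1.91e-5), 1.0471, tolerance = 1e-4)
  expect_equal(percent_difference(2, 1), percent_difference(4, 2))
  expect_true(is.na(percent_difference(1, 0)))
})
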