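#' RAUKF tuning configuration
#'
#' Sigma-point scaling and the fault-triggered noise-adaptation weights.
#' `lambda0`/`delta0` are the minimum convex-combination weights applied to
#' the process (Q) and observation (R) noise estimates when a fault is
#' detected, and `a`/`b` scale how strongly the weights grow with the fault
#' magnitude (`a >> b`: Q reacts only to large faults).  A fault is declared
#' when the normalized innovation squared exceeds the chi-square(1) quantile
#' at `1 - fault_p`.
#'
#' @param alpha,beta,kappa unscented-transform scaling parameters.
#' @param lambda0,delta0 minimum adaptation weights (both 0.2).
#' @param a,b fault-proportional weights (10 and 1).
#' @param fault_p tail probability of the fault detector.
#' @param q_relax_ms relaxation time constant (ms) with which a
#'   fault-inflated Q decays back to its baseline (0 disables); keeps the
#'   robustness transient so isolated spike-timing faults do not permanently
#'   loosen the parameter random walk.
#' @param r_relax_ms like `q_relax_ms`, for the observation-noise variance R.
#' @export
raukf_config <- function(alpha = 0.5, beta = 2, kappa = 0,
                         lambda0 = 0.2, delta0 = 0.2, a = 10, b = 1,
                         fault_p = 0.05, q_relax_ms = 50, r_relax_ms = 50) {
  stopifnot(lambda0 > 0, lambda0 <= 1, delta0 > 0, delta0 <= 1, a > 0, b > 0)
  list(alpha = alpha, beta = beta, kappa = kappa, lambda0 = lambda0,
       delta0 = delta0, a = a, b = b,
       chi2_thresh = stats::qchisq(1 - fault_p, df = 1),
       q_relax_ms = q_relax_ms, r_relax_ms = r_relax_ms)
}

#' Scaled sigma points of a Gaussian
#'
#' Deterministic 2n+1 point set whose weighted mean and covariance reproduce
#' the input moments.
#'
#' @param mean mean vector.
#' @param cov covariance matrix (symmetric positive semidefinite; a small
#'   jitter is added if the factorization fails).
#' @param cfg a [raukf_config()] (only `alpha`, `beta`, `kappa` used).
#' @return list with `points` (n x (2n+1)), mean weights `wm`, covariance
#'   weights `wc`.
#' @export
sigma_points <- function(mean, cov, cfg = raukf_config()) {
  n <- length(mean)
  lam <- cfg$alpha^2 * (n + cfg$kappa) - n
  L <- tryCatch(t(chol(cov)), error = function(e) {
    jit <- 1e-12 * (1 + sum(diag(cov)) / n)
    for (i in 1:8) {
      out <- tryCatch(t(chol(cov + jit * diag(n))), error = function(e) NULL)
      if (!is.null(out)) return(out)
      jit <- jit * 100
    }
    stop("covariance decomposition failed")
  })
  gam <- sqrt(n + lam)
  pts <- cbind(mean, mean + gam * L, mean - gam * L)
  wm <- c(lam / (n + lam), rep(1 / (2 * (n + lam)), 2 * n))
  wc <- wm
  wc[1] <- wm[1] + 1 - cfg$alpha^2 + cfg$beta
  list(points = unname(pts), wm = wm, wc = wc)
}

#' Unscented Kalman filter with a direct (linear) observation
#'
#' Reference-grade UKF over an arbitrary one-step transition function,
#' observing one state component with additive Gaussian noise.  The
#' measurement update uses the predicted moments exactly (the observation
#' map is linear), so on a linear-Gaussian transition this filter coincides
#' with the closed-form Kalman filter.  Used as the slow cross-check engine
#' for the compiled filter and for oracle tests.
#'
#' @param fstep function(x, k) returning the propagated state for sample k.
#' @param x0,P0 initial mean and covariance.
#' @param Q process covariance (matrix).
#' @param R observation noise variance (scalar).
#' @param ys observations (first entry is the initial condition's
#'   observation and is not filtered, matching the compiled engine).
#' @param obs_index observed state component.
#' @param cfg a [raukf_config()].
#' @param adapt apply the fault-triggered Q/R adaptation (default FALSE).
#' @return list with means (samples x n), `P`, `Q`, `R` finals, innovations.
#' @export
ukf_filter <- function(fstep, x0, P0, Q, R, ys, obs_index = 1,
                       cfg = raukf_config(), adapt = FALSE) {
  n <- length(x0)
  x <- x0
  P <- P0
  N <- length(ys)
  means <- matrix(NA_real_, N, n)
  means[1, ] <- x
  innov <- rep(NA_real_, N)
  for (k in 2:N) {
    sp <- sigma_points(x, P, cfg)
    Xp <- matrix(vapply(seq_len(2 * n + 1),
                        function(i) fstep(sp$points[, i], k), numeric(n)),
                 nrow = n)
    xpred <- as.numeric(Xp %*% sp$wm)
    D <- Xp - xpred
    Ppred <- D %*% (sp$wc * t(D)) + Q
    Ppred <- (Ppred + t(Ppred)) / 2
    S <- Ppred[obs_index, obs_index] + R
    nu <- ys[k] - xpred[obs_index]
    K <- Ppred[, obs_index] / S
    x <- xpred + K * nu
    P <- Ppred - S * (K %o% K)
    P <- (P + t(P)) / 2
    innov[k] <- nu
    if (adapt) {
      eps <- nu^2 / S
      if (eps > cfg$chi2_thresh) {
        delta <- max(cfg$delta0, (eps - cfg$b) / eps)
        R <- (1 - delta) * R + delta * max(nu^2 - Ppred[obs_index, obs_index], 1e-6)
        lambda <- max(cfg$lambda0, (eps - cfg$a) / eps)
        Kn <- K * nu
        Q <- (1 - lambda) * Q + lambda * (Kn %o% Kn)
      }
    }
    means[k, ] <- x
  }
  list(means = means, P = P, Q = Q, R = R, innovations = innov)
}

theta_channels <- c("M", "Kdrf", "Ka", "Na")

#' Reference conductance vector of a model
#'
#' The estimated parameter vector theta = (gM, gKdrf, gKa, gNa) as
#' conductance densities (S/cm2).
#'
#' @param model a [membrane_model()].
#' @export
theta_true <- function(model) {
  cn <- channel_names(model)
  vapply(theta_channels, function(nm) model$channels[[match(nm, cn)]]$gbar, 1.0)
}

#' Order-of-magnitude ("poor") initialization of theta
#'
#' \eqn{\theta_0 = 10^{\lfloor \log_{10} \theta \rfloor}}.
#'
#' @param theta reference conductances.
#' @export
theta_poor <- function(theta) 10^floor(log10(theta))

# P/Q initial diagonals for the theta block, from theta's order of magnitude:
# P_ii = (magnitude)^2 = 10^(2 floor(log10 theta0)); the random-walk variance
# is a small fraction of P so the parameters can travel during the train
# without diffusing afterwards.
theta_init_cov <- function(theta0, q_frac = 1e-6) {
  m <- floor(log10(theta0))
  list(P = 10^(2 * m), Q = q_frac * 10^(2 * m))
}

#' Generate a synthetic voltage observation for conductance estimation
#'
#' Simulates the model under the noisy step train ([raukf_train()]) and adds
#' Gaussian measurement noise to the voltage, mimicking a current-clamp
#' recording.
#'
#' @param model a [membrane_model()].
#' @param seed integer seed (expanded into independent input-noise and
#'   measurement-noise streams).
#' @param dt time step (ms).
#' @param obs_noise_sd measurement noise sd (mV).
#' @param train optional list from [raukf_train()].
#' @return list with `y` (observed mV), `u` (injected pA), `V` (noise-free
#'   mV), `dt`, `obs_var`.
#' @export
make_observation <- function(model, seed = 1, dt = 0.025, obs_noise_sd = 0.25,
                             train = NULL) {
  sds <- derive_seeds(seed, 2)
  if (is.null(train)) train <- raukf_train(dt = dt, seed = sds[1])
  tr <- simulate_cell(model, train$current, dt = dt, record = "V")
  set.seed(sds[2])
  y <- tr$V + rnorm(length(tr$V), 0, obs_noise_sd)
  list(y = y, u = train$current, V = tr$V, dt = dt,
       obs_var = max(obs_noise_sd^2, 1e-6))
}

#' Estimate channel conductances from a voltage recording (RAUKF)
#'
#' Runs the robust adaptive unscented Kalman filter over the augmented state
#' (membrane voltage, gating variables, and the four conductance densities
#' gM, gKdrf, gKa, gNa propagated as a random walk), observing the voltage
#' at every sample with the injected current as known control input.  The
#' observation-voltage block of P and Q is initialized to 1e-4 and 1e-8; the
#' theta blocks are derived from the order of magnitude of the initial
#' estimate.  Q and R are re-estimated whenever the normalized innovation
#' squared flags a fault.
#'
#' @param model the model template (its four estimated conductances are
#'   overridden by the filter state; all other parameters are taken as
#'   known).
#' @param y observed voltage series (mV).
#' @param u injected current series (pA), aligned with `y`.
#' @param dt sample interval (ms).
#' @param theta0 initial conductance estimate: `"optimal"` (the template's
#'   values), `"poor"` (order of magnitude), or a numeric 4-vector.
#' @param cfg a [raukf_config()].
#' @param R0 initial observation-noise variance (mV^2); use the known
#'   measurement variance for synthetic observations.
#' @param store_every trajectory storage stride (samples).
#' @param reference conductances used for percent differences (defaults to
#'   the template's values).
#' @return an `estimate_trajectory`: final `theta` with `theta_se`, percent
#'   differences, the stored trajectory, fault count and innovation
#'   statistics.
#' @export
run_raukf <- function(model, y, u, dt = 0.025, theta0 = "poor",
                      cfg = raukf_config(), R0 = 1, store_every = 40,
                      reference = theta_true(model)) {
  stopifnot(length(y) == length(u))
  truth <- theta_true(model)
  th0 <- if (is.character(theta0)) {
    switch(match.arg(theta0, c("poor", "optimal")),
           poor = theta_poor(truth), optimal = truth)
  } else { stopifnot(length(theta0) == 4); theta0 }
  cn <- channel_names(model)
  idx <- match(theta_channels, cn) - 1L
  G <- length(gate_names(model))
  tc <- theta_init_cov(th0)
  P0 <- c(rep(1e-4, 1 + G), tc$P)
  Q0 <- c(rep(1e-8, 1 + G), tc$Q)
  out <- raukf_cpp(as_cpp_model(model), idx, model$area_cm2 * 1e6,
                   y, u, dt, th0, P0, Q0, R0,
                   cfg$alpha, cfg$beta, cfg$kappa,
                   cfg$lambda0, cfg$delta0, cfg$a, cfg$b,
                   cfg$chi2_thresh, cfg$q_relax_ms, cfg$r_relax_ms,
                   as.integer(store_every))
  theta <- stats::setNames(out$theta, theta_channels)
  colnames(out$theta_path) <- colnames(out$se_path) <- theta_channels
  structure(list(theta = theta,
                 theta_se = stats::setNames(out$theta_se, theta_channels),
                 pct_diff = percent_difference(theta, reference),
                 reference = stats::setNames(reference, theta_channels),
                 theta0 = stats::setNames(th0, theta_channels),
                 t_path = out$t_path, theta_path = out$theta_path,
                 se_path = out$se_path, vhat_path = out$vhat_path,
                 n_fault = out$n_fault, fault_idx = out$fault_idx,
                 R_final = out$R_final, mean_nis = out$mean_nis,
                 P_final = out$P_final, dt = dt),
            class = "estimate_trajectory")
}

#' @export
print.estimate_trajectory <- function(x, ...) {
  cat("<estimate_trajectory>\n")
  df <- data.frame(initial = x$theta0, final = x$theta, se = x$theta_se,
                   reference = x$reference, pct_diff = x$pct_diff)
  print(format(df, digits = 3))
  cat(sprintf("  %d faults, mean NIS %.2f, final R %.3g mV^2\n",
              x$n_fault, x$mean_nis, x$R_final))
  invisible(x)
}

#' Percent difference of an estimate from a reference
#'
#' \eqn{|est - ref| / ref \times 100} per component.
#'
#' @param estimate,reference numeric vectors.
#' @return percent differences (`NA` where the reference is zero).
#' @export
percent_difference <- function(estimate, reference) {
  ifelse(reference != 0, abs(estimate - reference) / reference * 100, NA_real_)
}
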