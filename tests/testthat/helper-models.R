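# Small models and utilities shared across tests.

bell_tau <- function(base, amp, v, k) {
  list(base = base, amp = amp, v1 = v, k1 = k, v2 = v, k2 = k)
}

# passive membrane: leak only (all gbar = 0 elsewhere)
passive_model <- function(gl = 1e-5, el = -70, area = 2e-4, cm = 1.0) {
  membrane_model(
    list(channel_spec("Na", 0, 90, list(
      gating_spec("m", 3, -40, 6, bell_tau(0.1, 0.3, -45, 12)),
      gating_spec("h", 1, -60, -5, bell_tau(1, 8, -50, 9))))),
    area_cm2 = area, cm = cm, leak_gbar = gl, leak_erev = el,
    v_init = -60, name = "passive")
}

# two-channel toy with fast kinetics (cheap to integrate)
toy_model <- function() {
  membrane_model(
    list(channel_spec("K", 1e-4, -90, list(
           gating_spec("n", 1, -50, 8, 5))),
         channel_spec("Na", 2e-4, 60, list(
           gating_spec("m", 2, -45, 6, 0.5),
           gating_spec("h", 1, -60, -6, bell_tau(2, 10, -55, 10))))),
    area_cm2 = 2e-4, cm = 1.0, leak_gbar = 1e-5, leak_erev = -70,
    v_init = -65, name = "toy")
}

# deterministic trace object from a voltage vector
fake_trace <- function(V, dt = 1, currents = NULL, stimulus = NULL) {
  structure(list(t = (seq_along(V) - 1) * dt, V = V, dt = dt,
                 currents = currents,
                 stimulus = stimulus %||% rep(0, length(V)),
                 gating = NULL, seed = NULL, model_name = "fake",
                 model_hash = "0"),
            class = "sim_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form Kalman filter for a linear-Gaussian system x' = A x + w,
# y = H x + v; the independent oracle for the UKF equivalence test
kf_linear <- function(A, Q, H, R, x0, P0, ys) {
  x <- x0; P <- P0
  means <- matrix(NA_real_, length(ys), length(x0))
  means[1, ] <- x
  for (k in 2:length(ys)) {
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
    S <- drop(H %*% P %*% t(H)) + R
    K <- (P %*% t(H)) / S
    nu <- ys[k] - drop(H %*% x)
    x <- x + K * nu
    P <- P - K %*% H %*% P
    means[k, ] <- x
  }
  list(means = means, P = P)
}

ref_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- olm_model()
    m
  }
})
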