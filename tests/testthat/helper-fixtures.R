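# Shared fixtures built in code at test time.

tone_trace <- function(freq, fs = 512, dur = 8, amp = 1, offset = 0) {
  t <- (0:(dur * fs - 1)) / fs
  trace(offset + amp * sin(2 * pi * freq * t), fs = fs)
}

# Short noise-driven simulation used by several suites.
quick_sim <- function(preset = "alpha", duration = 20, seed = 1, ...) {
  integrate_nmm(nmm_preset(preset),
                simulation_config(duration = duration, seed = seed, ...),
                burn_in = 2)
}

# Closed-form discrete Kalman filter on a linear-Gaussian system, the
# independent oracle for the unscented filter.  Discretization matches the
# tracker's convention: exact flow expm(A*dt), process noise Q*dt.
kalman_oracle <- function(y, A, H, Qdiag, R, dt, m0, P0) {
  Fm <- as.matrix(Matrix::expm(A * dt))
  Qd <- diag(Qdiag) * dt
  n <- length(m0)
  m <- m0
  P <- P0
  means <- matrix(NA_real_, length(y), n)
  covs <- array(NA_real_, c(length(y), n, n))
  for (t in seq_along(y)) {
    m <- Fm %*% m
    P <- Fm %*% P %*% t(Fm) + Qd
    S <- drop(H %*% P %*% H) + R
    K <- P %*% H / S
    m <- m + K * drop(y[t] - H %*% m)
    P <- P - K %*% (H %*% P)
    P <- (P + t(P)) / 2
    means[t, ] <- m
    covs[t, , ] <- P
  }
  list(means = means, covs = covs)
}

# Windowed-variance changepoint summary used by seizure-related checks.
window_variances <- function(x, window_s = 1) {
  wlen <- as.integer(round(window_s * x$fs))
  nw <- length(x$samples) %/% wlen
  vapply(seq_len(nw), function(i) {
    stats::var(x$samples[((i - 1) * wlen + 1):(i * wlen)])
  }, numeric(1))
}
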