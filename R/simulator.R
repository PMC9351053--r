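#' Simulation configuration
#'
#' @param dt Integration step (s).  The default `1/2048` s keeps the step
#'   near 0.5 ms while making the default 512 Hz output rate an exact
#'   integer decimation of the integration grid.
#' @param duration Total simulated time (s); must be a whole number of steps.
#' @param seed Integer seed for the noise stream (`NULL` = use the session
#'   RNG state).
#' @param output_rate Sampling rate (Hz) of the emitted trace; must divide
#'   `1/dt` to an integer thinning factor.
#' @param scheme `"stochastic-rk"` (RK4 drift plus additive noise increment,
#'   the default) or `"euler-maruyama"` (cross-validation scheme).
#' @param bound Divergence guard: any state magnitude above this aborts the
#'   run with an error naming the step.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1 / 2048, duration = 10, seed = NULL,
                              output_rate = 512,
                              scheme = c("stochastic-rk", "euler-maruyama"),
                              bound = 1e6) {
  scheme <- match.arg(scheme)
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be > 0")
  if (!is.finite(duration) || duration <= 0) stop_invalid("duration must be > 0")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop_invalid("duration must be a whole number of steps at dt = %g", dt)
  }
  if (output_rate > 1 / dt + 1e-9) {
    stop_invalid("output_rate (%g) cannot exceed 1/dt (%g)", output_rate, 1 / dt)
  }
  thin <- (1 / dt) / output_rate
  if (abs(thin - round(thin)) > 1e-8) {
    stop_invalid("output_rate must divide 1/dt to an integer factor")
  }
  structure(list(dt = dt, duration = duration, seed = seed,
                 output_rate = output_rate, scheme = scheme, bound = bound,
                 n_steps = as.integer(round(n_steps)),
                 thin = as.integer(round(thin))),
            class = "simulation_config")
}

scheme_code <- function(scheme) if (scheme == "stochastic-rk") 0L else 1L

#' Integrate the noise-driven neural mass model
#'
#' Advances the six-state model with endogenous input
#' `omega(t) = input_mean + xi(t)`, where `xi` is white noise of spectral
#' intensity `input_var` entering only the excitatory rate equation.  The
#' discretized increment added to `x_ex*` per step is
#' `a_ex * r_ex * sqrt(input_var * dt) * z`, `z ~ N(0,1)`, which makes the
#' output statistics invariant to the step size.  Identical seed and
#' configuration give bit-identical output.
#'
#' @param params [nmm_parameters()].
#' @param config [simulation_config()].
#' @param init Initial length-6 state; default is the deterministic
#'   equilibrium at `omega = input_mean` (see [find_equilibrium()]).
#' @param burn_in Seconds of initial transient discarded from the returned
#'   trace and states (simulated in addition to `config$duration`).
#' @param noise Optional explicit standard-normal increment sequence (one
#'   value per integration step, burn-in included); overrides the seed and
#'   enables common-random-number comparisons across step sizes.
#' @return A list with `trace` (the observed `x_ex - x_i` as a [trace()] at
#'   `output_rate`) and `states` (matrix, one thinned row per output sample).
#' @export
#' @examples
#' cfg <- simulation_config(duration = 2, seed = 1)
#' sim <- integrate_nmm(nmm_preset("alpha"), cfg)
#' sim$trace
integrate_nmm <- function(params, config, init = NULL, burn_in = 0,
                          noise = NULL) {
  stopifnot(inherits(params, "nmm_parameters"),
            inherits(config, "simulation_config"))
  if (is.null(init)) init <- find_equilibrium(params)$state
  if (length(init) != 6 || !all(is.finite(init))) {
    stop_invalid("init must be 6 finite numbers")
  }
  n_burn <- as.integer(round(burn_in / config$dt))
  n_tot <- config$n_steps + n_burn
  z <- if (is.null(noise)) {
    with_seed(config$seed, rnorm(n_tot))
  } else {
    if (length(noise) != n_tot) {
      stop_invalid("noise must have one increment per step (%d)", n_tot)
    }
    as.numeric(noise)
  }
  res <- cpp_integrate_nmm(pack_params(params), as.numeric(init),
                           config$dt, n_tot, z,
                           scheme_code(config$scheme), config$thin,
                           config$bound)
  keep <- seq_len(n_tot %/% config$thin) > (n_burn %/% config$thin)
  list(trace = trace(res$obs[keep], fs = config$output_rate,
                     label = "simulated membrane potential",
                     kind = "synthetic"),
       states = res$states[keep, , drop = FALSE])
}

#' Integrate the slow-fast model with dynamic inhibitory gain
#'
#' Co-integrates the six fast states with the slow gain equation
#' `dA_i/dt = epsilon * (-alpha * A_i + beta * sigmoid(V) + n(t))`, where
#' `V = x_ex - x_i` and `n` is white noise with variance `slow_noise_var`.
#' The instantaneous `A_i` replaces `params$a_i` in the fast drift at every
#' step, so gain excursions reshape both the oscillatory regime and the
#' baseline of the observed potential -- the mechanism that produces
#' seizure-like transitions accompanied by DC shifts.
#'
#' @inheritParams integrate_nmm
#' @param slow [slow_gain_parameters()].
#' @param a_i_init Initial gain (mV); defaults to `params$a_i`.
#' @return A list with `trace` (observed potential), `gain` (ground-truth
#'   `A_i(t)` as a [trace()] of kind `"ground_truth_gain"`), and `states`.
#' @export
integrate_slow_fast <- function(params, slow, config, init = NULL,
                                a_i_init = params$a_i, burn_in = 0) {
  stopifnot(inherits(params, "nmm_parameters"),
            inherits(slow, "slow_gain_parameters"),
            inherits(config, "simulation_config"))
  if (is.null(init)) init <- find_equilibrium(params)$state
  if (length(init) != 6 || !all(is.finite(init))) {
    stop_invalid("init must be 6 finite numbers")
  }
  if (!is.finite(a_i_init)) stop_invalid("a_i_init must be finite")
  n_burn <- as.integer(round(burn_in / config$dt))
  n_tot <- config$n_steps + n_burn
  zs <- with_seed(config$seed, {
    list(fast = rnorm(n_tot), slow = rnorm(n_tot))
  })
  res <- cpp_integrate_slow_fast(pack_params(params),
                                 c(slow$epsilon, slow$alpha, slow$beta,
                                   slow$slow_noise_var),
                                 as.numeric(init), a_i_init, config$dt,
                                 n_tot, zs$fast, zs$slow,
                                 scheme_code(config$scheme), config$thin,
                                 config$bound)
  keep <- seq_len(n_tot %/% config$thin) > (n_burn %/% config$thin)
  list(trace = trace(res$obs[keep], fs = config$output_rate,
                     label = "slow-fast membrane potential",
                     kind = "synthetic"),
       gain = trace(res$gain[keep], fs = config$output_rate,
                    label = "inhibitory gain", kind = "ground_truth_gain"),
       states = res$states[keep, , drop = FALSE])
}

#' Deterministic equilibrium of the neural mass model
#'
#' Finds a root of the drift field at constant input `omega` by damped
#' Newton iteration with the analytic Jacobian, starting from the origin.
#' If Newton fails to converge the problem is reduced to a scalar fixed
#' point in the pyramidal input `V = x_ex - x_i` and bracketed with
#' [stats::uniroot()].  All derivative components of an equilibrium are
#' exactly zero.
#'
#' @param params [nmm_parameters()].
#' @param omega Constant input (s^-1); default `input_mean`.
#' @param tol Convergence tolerance on the drift norm.
#' @param max_iter Newton iteration cap.
#' @return A list with `state` (length-6 equilibrium), `residual` (drift
#'   norm at the root) and `converged`.
#' @export
find_equilibrium <- function(params, omega = params$input_mean,
                             tol = 1e-9, max_iter = 100) {
  stopifnot(inherits(params, "nmm_parameters"))
  if (!is.finite(omega)) stop_invalid("omega must be finite")
  x <- numeric(6)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    f <- nmm_drift(x, params, omega)
    if (sqrt(sum(f^2)) < tol) {
      ok <- TRUE
      break
    }
    J <- nmm_jacobian(x, params, omega)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking line search on the residual norm
    lam <- 1
    f0 <- sum(f^2)
    repeat {
      xn <- x + lam * step
      fn <- sum(nmm_drift(xn, params, omega)^2)
      if (fn < f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  if (!ok && sqrt(sum(nmm_drift(x, params, omega)^2)) >= tol) {
    x <- equilibrium_scalar(params, omega, tol)
    if (is.null(x)) {
      stop_invalid("no equilibrium found after %d iterations", max_iter)
    }
  }
  list(state = nmm_state(x),
       residual = sqrt(sum(nmm_drift(x, params, omega)^2)),
       converged = TRUE)
}

# Reduce the equilibrium condition to a scalar fixed point in the pyramidal
# input v = x_ex - x_i: x_p = (a_p/r_p) sig(v) determines the interneuron
# drives, which in turn determine v.
equilibrium_scalar <- function(params, omega, tol) {
  sg <- params$sigmoid
  g <- function(v) {
    x_p <- params$a_p / params$r_p * sigmoid(v, sg)
    x_ex <- params$a_ex / params$r_ex *
      (omega + 0.8 * params$c * sigmoid(params$c * x_p, sg))
    x_i <- params$a_i / params$r_i *
      (0.25 * params$c * sigmoid(0.25 * params$c * x_p, sg))
    (x_ex - x_i) - v
  }
  lo <- -200
  hi <- 200
  if (g(lo) * g(hi) > 0) return(NULL)
  v <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
  x_p <- params$a_p / params$r_p * sigmoid(v, sg)
  x_ex <- params$a_ex / params$r_ex *
    (omega + 0.8 * params$c * sigmoid(params$c * x_p, sg))
  x_i <- params$a_i / params$r_i *
    (0.25 * params$c * sigmoid(0.25 * params$c * x_p, sg))
  c(x_p, 0, x_ex, 0, x_i, 0)
}

#' Equilibrium branch over an input sweep
#'
#' Continues the deterministic equilibrium across a monotone grid of
#' constant inputs, using each root as the initial guess for the next grid
#' point, and classifies local stability from the sign of the largest real
#' part of the drift Jacobian's eigenvalues.  A stability flip along the
#' sweep marks the onset of the oscillatory (limit-cycle) regime.  The
#' equilibrium curve is S-shaped in the input, so ascending and descending
#' sweeps can land on different branches around the folds; sweeping
#' downward from large inputs follows the branch that carries the
#' oscillatory window.
#'
#' @param params [nmm_parameters()].
#' @param omega_grid Monotone (ascending or descending) grid of constant
#'   inputs.
#' @return A data frame with columns `omega`, `output` (equilibrium
#'   `x_ex - x_i`), `stable`, `max_re_eig`, and `converged`.
#' @export
equilibrium_sweep <- function(params, omega_grid) {
  stopifnot(inherits(params, "nmm_parameters"))
  if (is.unsorted(omega_grid) && is.unsorted(rev(omega_grid))) {
    stop_invalid("omega_grid must be monotone")
  }
  x <- numeric(6)
  out <- data.frame(omega = omega_grid, output = NA_real_, stable = NA,
                    max_re_eig = NA_real_, converged = FALSE)
  for (i in seq_along(omega_grid)) {
    om <- omega_grid[i]
    xi <- tryCatch(
      newton_from(x, params, om),
      error = function(e) NULL
    )
    if (is.null(xi)) {
      xi <- equilibrium_scalar(params, om, 1e-12)
    }
    if (is.null(xi)) next
    x <- xi
    ev <- eigen(nmm_jacobian(x, params, om), only.values = TRUE)$values
    out$output[i] <- x[3] - x[5]
    out$max_re_eig[i] <- max(Re(ev))
    out$stable[i] <- out$max_re_eig[i] < 0
    out$converged[i] <- TRUE
  }
  out
}

newton_from <- function(x, params, omega, tol = 1e-9, max_iter = 60) {
  for (it in seq_len(max_iter)) {
    f <- nmm_drift(x, params, omega)
    if (sqrt(sum(f^2)) < tol) return(x)
    step <- solve(nmm_jacobian(x, params, omega), -f)
    lam <- 1
    f0 <- sum(f^2)
    repeat {
      xn <- x + lam * step
      if (sum(nmm_drift(xn, params, omega)^2) < f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- xn
  }
  stop("Newton did not converge")
}

#' Welch power spectral density of a trace
#'
#' Averaged modified periodogram: Hann-windowed segments of `window_s`
#' seconds with 50% overlap, per-segment mean removal, one-sided density
#' scaling.  Normalised so that the integral of the density over frequency
#' matches the trace variance (within a few percent for broadband signals).
#'
#' @param x A [trace()].
#' @param window_s Segment length in seconds; the trace must be at least two
#'   segments long.
#' @return A data frame with columns `freq` (Hz) and `power` (density,
#'   units^2 / Hz).
#' @export
power_spectrum <- function(x, window_s = 4) {
  stopifnot(inherits(x, "trace"))
  nper <- as.integer(round(window_s * x$fs))
  n <- length(x$samples)
  if (n < 2 * nper) stop_invalid("trace too short: need >= 2 windows of %g s", window_s)
  step <- nper %/% 2
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1)) # Hann
  u <- sum(w^2)
  acc <- numeric(nper %/% 2 + 1)
  for (s0 in starts) {
    seg <- x$samples[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / (x$fs * u)
    half <- sp[seq_len(nper %/% 2 + 1)]
    # one-sided: double everything except DC (and Nyquist for even nper)
    half[-1] <- 2 * half[-1]
    if (nper %% 2 == 0) half[length(half)] <- half[length(half)] / 2
    acc <- acc + half
  }
  acc <- acc / length(starts)
  data.frame(freq = (seq_along(acc) - 1) * x$fs / nper, power = acc)
}

#' Dominant spectral peak
#'
#' @param psd Data frame from [power_spectrum()].
#' @param fmin,fmax Search band (Hz).
#' @return Frequency (Hz) of the maximum density inside the band.
#' @export
spectral_peak <- function(psd, fmin = 1, fmax = Inf) {
  sel <- psd$freq >= fmin & psd$freq <= fmax
  if (!any(sel)) stop_invalid("empty frequency band")
  psd$freq[sel][which.max(psd$power[sel])]
}
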