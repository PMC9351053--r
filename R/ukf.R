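#' Tracker configuration
#'
#' Settings for the continuous-discrete unscented Kalman filter that jointly
#' estimates the six model states and the inhibitory gain from an observed
#' trace.
#'
#' The gain is given random-walk dynamics `dA_i = 0 dt + n*(t)`; the
#' per-update uncertainty injected into the gain is `param_noise_var * dt`.
#' The default intensity corresponds to adding variance 1e-8 per update at
#' the package's reference 512 Hz tracking rate -- the "very small"
#' uncertainty that lets the filter revise the gain without turning it into
#' a fast state.
#'
#' `state_noise` gives the process-noise intensities of the six states; when
#' `NULL` it is derived from the generative model at filter time: the
#' endogenous-input diffusion `(a_ex * r_ex)^2 * input_var` on the `x_ex*`
#' component and a small floor (1e-4) elsewhere.
#'
#' @param param_noise_var Process-noise intensity of the gain random walk
#'   (mV^2 / s).
#' @param state_noise `NULL` or six non-negative intensities.
#' @param meas_noise_var Observation-noise variance; `NULL` (default) means
#'   estimate it from the trace with [estimate_meas_noise()].
#' @param sigma_alpha,sigma_beta,sigma_kappa Scaled-unscented-transform
#'   spread parameters (defaults 1e-2, 2, 0).
#' @param inner_dt Sub-step (s) for the deterministic propagation of sigma
#'   points between observations; capped at the inter-sample interval.
#' @param bound Divergence guard on sigma-point magnitudes.
#' @return An object of class `ukf_config`.
#' @export
ukf_config <- function(param_noise_var = 1e-8 * 512, state_noise = NULL,
                       meas_noise_var = NULL, sigma_alpha = 1e-2,
                       sigma_beta = 2, sigma_kappa = 0,
                       inner_dt = 1e-3, bound = 1e6) {
  if (!is.finite(param_noise_var) || param_noise_var < 0) {
    stop_invalid("param_noise_var must be >= 0")
  }
  if (!is.null(state_noise)) {
    if (length(state_noise) != 6 || any(!is.finite(state_noise)) ||
        any(state_noise < 0)) {
      stop_invalid("state_noise must be 6 non-negative numbers")
    }
  }
  if (!is.null(meas_noise_var) &&
      (!is.finite(meas_noise_var) || meas_noise_var <= 0)) {
    stop_invalid("meas_noise_var must be > 0")
  }
  if (!is.finite(inner_dt) || inner_dt <= 0) stop_invalid("inner_dt must be > 0")
  structure(list(param_noise_var = param_noise_var,
                 state_noise = state_noise,
                 meas_noise_var = meas_noise_var,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 sigma_kappa = sigma_kappa, inner_dt = inner_dt,
                 bound = bound),
            class = "ukf_config")
}

#' Augmented filter state
#'
#' Mean and covariance of the 7-dimensional augmented state
#' `[x_p, x_p*, x_ex, x_ex*, x_i, x_i*, a_i]`.  The covariance is
#' re-symmetrized on construction; eigenvalues below `-1e-10` are rejected,
#' smaller negative ripple is clipped to zero.
#'
#' @param mean Length-7 numeric vector.
#' @param cov 7 x 7 covariance matrix.
#' @return An object of class `augmented_state`.
#' @export
augmented_state <- function(mean, cov) {
  mean <- as.numeric(mean)
  if (length(mean) != 7 || !all(is.finite(mean))) {
    stop_invalid("mean must be 7 finite numbers")
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(7, 7)) || !all(is.finite(cov))) {
    stop_invalid("cov must be a finite 7 x 7 matrix")
  }
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop_invalid("cov must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(ev))) {
    stop_invalid("cov must be positive semi-definite")
  }
  structure(list(mean = mean, cov = cov), class = "augmented_state")
}

# Default initial filter state: fast states at the deterministic
# equilibrium, gain at the parameter set's baseline, unit diagonal
# covariance.
default_init_state <- function(params) {
  eq <- find_equilibrium(params)$state
  augmented_state(c(as.numeric(eq), params$a_i), diag(7))
}

ukf_state_noise <- function(config, params) {
  if (!is.null(config$state_noise)) return(config$state_noise)
  q <- rep(1e-4, 6)
  q[4] <- (params$a_ex * params$r_ex)^2 * params$input_var
  q
}

#' Scaled sigma points
#'
#' Deterministic 2n+1 point set of the scaled unscented transform.  The
#' weighted mean and covariance of the points reproduce the input moments to
#' machine precision.
#'
#' @param state An [augmented_state()] (or any list with `mean` and `cov`).
#' @param config A [ukf_config()] supplying the spread parameters.
#' @return A list with `points` (n x 2n+1 matrix, one point per column),
#'   `wm` and `wc` (mean / covariance weights).
#' @export
sigma_points <- function(state, config = ukf_config()) {
  res <- cpp_sigma_points(state$mean, state$cov, config$sigma_alpha,
                          config$sigma_beta, config$sigma_kappa)
  list(points = res$points, wm = as.numeric(res$wm),
       wc = as.numeric(res$wc))
}

#' One unscented prediction step
#'
#' Propagates each sigma point through the deterministic augmented drift
#' (model drift with the point's own gain; `d a_i/dt = 0`; input frozen at
#' `input_mean`) by RK4 sub-stepping over `dt`, recombines, and adds the
#' discretized process noise `diag(state_noise, param_noise_var) * dt`.
#'
#' @param state An [augmented_state()].
#' @param params [nmm_parameters()].
#' @param config [ukf_config()].
#' @param dt Inter-sample interval (s).
#' @return The predicted [augmented_state()].
#' @export
ukf_predict <- function(state, params, config, dt) {
  stopifnot(inherits(params, "nmm_parameters"))
  if (!is.finite(dt) || dt <= 0) stop_invalid("dt must be > 0")
  n_sub <- max(1L, as.integer(ceiling(dt / config$inner_dt)))
  q <- c(ukf_state_noise(config, params), config$param_noise_var)
  res <- cpp_ukf_predict(state$mean, state$cov, 0L, pack_params(params),
                         matrix(0, 1, 1), q, dt, n_sub,
                         config$sigma_alpha, config$sigma_beta,
                         config$sigma_kappa, config$bound)
  augmented_state(res$mean, res$cov)
}

#' One measurement update
#'
#' Conditions the augmented state on an observed sample through the linear
#' observation `y = x_ex - x_i + e`.  Because the observation operator is
#' linear it is applied exactly rather than through sigma points.
#'
#' @param state An [augmented_state()].
#' @param y Observed sample (mV).
#' @param config [ukf_config()]; `meas_noise_var` must be set.
#' @return A list with `state` (posterior [augmented_state()]),
#'   `innovation`, and `innovation_var`.
#' @export
ukf_update <- function(state, y, config) {
  if (!is.finite(y)) stop_invalid("y must be finite")
  R <- config$meas_noise_var
  if (is.null(R) || !is.finite(R) || R <= 0) {
    stop_invalid("meas_noise_var must be set and > 0")
  }
  res <- cpp_ukf_update(state$mean, state$cov, y, obs_vector(), R)
  list(state = augmented_state(res$mean, res$cov),
       innovation = res$innovation, innovation_var = res$innovation_var)
}

#' Track the inhibitory gain from an observed trace
#'
#' Runs the continuous-discrete unscented Kalman filter over all samples of
#' a trace: unscented prediction through the model drift between samples,
#' exact linear measurement update at each sample.  The filter draws no
#' random numbers, so identical inputs give bit-identical results.  The
#' seventh posterior component is the tracked inhibitory gain.
#'
#' @param x Observed [trace()].
#' @param params [nmm_parameters()] fixing all constants except the gain.
#' @param config [ukf_config()].  A `NULL` `meas_noise_var` is filled by
#'   [estimate_meas_noise()] on `x`.
#' @param init Initial [augmented_state()]; default: fast states at the
#'   deterministic equilibrium, gain at `params$a_i`, unit covariance.
#' @return A `tracking_result`: list with `time` (s), `mean` / `sd`
#'   (n x 7 matrices), `gain` (the tracked `A_i(t)` as a [trace()]),
#'   `innovation`, `innovation_var`, `loglik`, and `flags` (currently:
#'   fraction of samples with negative tracked gain).
#' @export
#' @examples
#' \donttest{
#' cfg <- simulation_config(duration = 20, seed = 7)
#' sim <- integrate_nmm(nmm_preset("fitted"), cfg, burn_in = 5)
#' res <- track_gain(sim$trace, nmm_preset("fitted"))
#' tail(res$gain$samples, 1) # should approach 26.072
#' }
track_gain <- function(x, params, config = ukf_config(), init = NULL) {
  stopifnot(inherits(x, "trace"), inherits(params, "nmm_parameters"),
            inherits(config, "ukf_config"))
  if (is.null(init)) init <- default_init_state(params)
  stopifnot(inherits(init, "augmented_state"))
  R <- config$meas_noise_var
  if (is.null(R)) R <- estimate_meas_noise(x)
  dt <- 1 / x$fs
  n_sub <- max(1L, as.integer(ceiling(dt / config$inner_dt)))
  q <- c(ukf_state_noise(config, params), config$param_noise_var)
  res <- cpp_ukf_filter(x$samples, dt, 0L, pack_params(params),
                        matrix(0, 1, 1), q, R, obs_vector(),
                        init$mean, init$cov, n_sub,
                        config$sigma_alpha, config$sigma_beta,
                        config$sigma_kappa, config$bound)
  gain <- res$means[, 7]
  structure(list(
    time = x$t0 + (seq_along(x$samples) - 1) / x$fs,
    mean = res$means, sd = res$sds,
    gain = trace(gain, fs = x$fs, label = "tracked inhibitory gain",
                 kind = "ground_truth_gain", t0 = x$t0),
    innovation = as.numeric(res$innovation),
    innovation_var = as.numeric(res$innovation_var),
    loglik = res$loglik,
    meas_noise_var = R,
    flags = list(negative_gain_frac = mean(gain < 0))
  ), class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<tracking_result> %d samples over %.1f s\n", n,
              x$time[n] - x$time[1]))
  cat(sprintf("  final gain estimate: %.3f mV (sd %.3f)\n",
              x$mean[n, 7], x$sd[n, 7]))
  cat(sprintf("  log-likelihood: %.1f;  negative-gain fraction: %.3f\n",
              x$loglik, x$flags$negative_gain_frac))
  invisible(x)
}

#' Write a tracking result to delimited text plus a JSON summary
#'
#' @param x A `tracking_result` from [track_gain()].
#' @param path Output path for the table (tab-separated: time, 7 means,
#'   7 sds, innovation).  A sidecar `<path>.json` carries final estimates,
#'   the log-likelihood and diagnostic flags.
#' @return `path`, invisibly.
#' @export
write_tracking_result <- function(x, path) {
  stopifnot(inherits(x, "tracking_result"))
  tab <- data.frame(time = x$time, x$mean, x$sd, innovation = x$innovation)
  names(tab) <- c("time",
                  paste0("mean_", c("x_p", "x_p_dot", "x_ex", "x_ex_dot",
                                    "x_i", "x_i_dot", "a_i")),
                  paste0("sd_", c("x_p", "x_p_dot", "x_ex", "x_ex_dot",
                                  "x_i", "x_i_dot", "a_i")),
                  "innovation")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  n <- length(x$time)
  jsonlite::write_json(
    list(final_gain = x$mean[n, 7], final_gain_sd = x$sd[n, 7],
         loglik = x$loglik, meas_noise_var = x$meas_noise_var,
         flags = x$flags),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
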