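#' Sigmoid (potential-to-rate) parameters
#'
#' Parameters of the static sigmoid that converts a population's mean
#' membrane potential (mV) into a mean firing rate (s^-1):
#' \deqn{\sigma(v) = e_0 / (1 + \exp(-\rho (v - v_{th})))}
#'
#' @param e0 Maximum firing rate (s^-1).
#' @param rho Slope of the transformation (s^-1 mV^-1).
#' @param v_th Firing threshold (mV); the potential at which the rate reaches
#'   half of `e0`.  The physiological range is roughly 2--7 mV; values
#'   outside it trigger a warning, not an error, because fitted models can
#'   legitimately leave the canonical box.
#'
#' @return An object of class `sigmoid_parameters`.
#' @export
#' @examples
#' sp <- sigmoid_parameters()
#' sigmoid(sp$v_th, sp) # half of e0
sigmoid_parameters <- function(e0 = 5, rho = 0.56, v_th = 6) {
  stopifnot(is.numeric(e0), is.numeric(rho), is.numeric(v_th))
  if (!is.finite(e0) || e0 <= 0) stop_invalid("e0 must be finite and > 0")
  if (!is.finite(rho) || rho <= 0) stop_invalid("rho must be finite and > 0")
  if (!is.finite(v_th)) stop_invalid("v_th must be finite")
  if (v_th < 2 || v_th > 7) {
    warning("v_th = ", v_th, " mV is outside the usual [2, 7] mV range")
  }
  structure(list(e0 = e0, rho = rho, v_th = v_th),
            class = "sigmoid_parameters")
}

#' Jansen-Rit neural mass model parameters
#'
#' Fixed constants of the three-population (pyramidal / excitatory
#' interneuron / inhibitory interneuron) neural mass model.  Synaptic
#' responses are second-order kernels `h(t) = a r t exp(-r t)` with gain `a`
#' (mV, the maximum post-synaptic potential) and inverse time constant `r`
#' (s^-1).  The canonical alpha-rhythm values are `r_p = r_ex = 100` s^-1 and
#' `r_i = 50` s^-1.  Intrinsic coupling is parameterised by the single
#' connectivity constant `c`, scaled by the usual 0.8 / 0.25 / 0.25 factors
#' inside the drift.  The endogenous input to the excitatory population is a
#' Gaussian fluctuation with mean `input_mean` (s^-1) and white-noise
#' spectral intensity `input_var` (see [integrate_nmm()] for the
#' discretization convention).
#'
#' @param a_p,a_ex,a_i Maximum post-synaptic potentials (mV) of the
#'   pyramidal, excitatory and inhibitory synapses.
#' @param r_p,r_ex,r_i Inverse synaptic time constants (s^-1).
#' @param c Universal connectivity constant (dimensionless).
#' @param sigmoid A [sigmoid_parameters()] object.
#' @param input_mean,input_var Mean and intensity of the endogenous input.
#' @param validate_ranges If `TRUE` (default) warn when values leave the
#'   physiological ranges (a_p, a_ex in [2.5, 10] mV; a_i in [3, 100] mV;
#'   c in [60, 1350]).
#'
#' @return An object of class `nmm_parameters`.
#' @seealso [nmm_preset()] for the parameter sets used throughout the
#'   package's simulations.
#' @export
nmm_parameters <- function(a_p = 3.25, a_ex = 3.25, a_i = 22,
                           r_p = 100, r_ex = 100, r_i = 50,
                           c = 135, sigmoid = sigmoid_parameters(),
                           input_mean = 220, input_var = 1.5,
                           validate_ranges = TRUE) {
  vals <- c(a_p = a_p, a_ex = a_ex, a_i = a_i, r_p = r_p, r_ex = r_ex,
            r_i = r_i, c = c)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("all gains, rate constants and c must be finite and > 0")
  }
  if (!is.finite(input_mean)) stop_invalid("input_mean must be finite")
  if (!is.finite(input_var) || input_var < 0) {
    stop_invalid("input_var must be finite and >= 0")
  }
  stopifnot(inherits(sigmoid, "sigmoid_parameters"))
  if (validate_ranges) {
    rng_warn <- function(x, lo, hi, nm) {
      if (x < lo || x > hi) {
        warning(nm, " = ", x, " is outside the usual [", lo, ", ", hi,
                "] range", call. = FALSE)
      }
    }
    rng_warn(a_p, 2.5, 10, "a_p")
    rng_warn(a_ex, 2.5, 10, "a_ex")
    rng_warn(a_i, 3, 100, "a_i")
    rng_warn(c, 60, 1350, "c")
  }
  structure(list(a_p = a_p, a_ex = a_ex, a_i = a_i,
                 r_p = r_p, r_ex = r_ex, r_i = r_i, c = c,
                 sigmoid = sigmoid,
                 input_mean = input_mean, input_var = input_var),
            class = "nmm_parameters")
}

#' @export
print.nmm_parameters <- function(x, ...) {
  cat("<nmm_parameters>\n")
  cat(sprintf("  gains (mV):  a_p = %.4g  a_ex = %.4g  a_i = %.4g\n",
              x$a_p, x$a_ex, x$a_i))
  cat(sprintf("  rates (1/s): r_p = %.4g  r_ex = %.4g  r_i = %.4g\n",
              x$r_p, x$r_ex, x$r_i))
  cat(sprintf("  c = %.4g;  sigmoid e0 = %.4g, rho = %.4g, v_th = %.4g\n",
              x$c, x$sigmoid$e0, x$sigmoid$rho, x$sigmoid$v_th))
  cat(sprintf("  input ~ N(%.4g, %.4g)\n", x$input_mean, x$input_var))
  invisible(x)
}

# Flatten to the fixed-layout numeric vector expected by the C++ core.
pack_params <- function(params) {
  stopifnot(inherits(params, "nmm_parameters"))
  c(params$a_p, params$a_ex, params$a_i, params$r_p, params$r_ex,
    params$r_i, params$c, params$sigmoid$e0, params$sigmoid$rho,
    params$sigmoid$v_th, params$input_mean, params$input_var)
}

#' Named neural mass model parameter sets
#'
#' Three parameter sets used by the package's simulations and experiments:
#'
#' * `"alpha"`: the canonical alpha-rhythm regime (gains 3.25/3.25/22 mV,
#'   rates 100/100/50 s^-1, threshold 6 mV, input N(220, 1.5)); `c`
#'   defaults to 135, where the output has a dominant 7--14 Hz peak, and is
#'   the knob swept to move between rhythms.
#' * `"seizure"`: the regime used with the slow gain dynamics to produce
#'   transitions into and out of seizure-like discharges (rates
#'   110/110/50 s^-1, `c = 145`, input N(160, 1.5)).
#' * `"fitted"`: a baseline fitted to a stationary data segment (gains
#'   3.147/2.831/26.072 mV, threshold 5 mV, `c = 190`, input N(200, 1.2)),
#'   used as the tracking baseline.
#'
#' @param name One of `"alpha"`, `"seizure"`, `"fitted"`.
#' @param c Connectivity constant override (default: the preset's value).
#' @return An [nmm_parameters()] object.
#' @export
#' @examples
#' nmm_preset("alpha", c = 270)
nmm_preset <- function(name = c("alpha", "seizure", "fitted"), c = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    alpha = nmm_parameters(a_p = 3.25, a_ex = 3.25, a_i = 22,
                           r_p = 100, r_ex = 100, r_i = 50,
                           c = if (is.null(c)) 135 else c,
                           sigmoid = sigmoid_parameters(5, 0.56, 6),
                           input_mean = 220, input_var = 1.5),
    seizure = nmm_parameters(a_p = 3.25, a_ex = 3.25, a_i = 22,
                             r_p = 110, r_ex = 110, r_i = 50,
                             c = if (is.null(c)) 145 else c,
                             sigmoid = sigmoid_parameters(5, 0.56, 6),
                             input_mean = 160, input_var = 1.5),
    fitted = nmm_parameters(a_p = 3.147, a_ex = 2.831, a_i = 26.072,
                            r_p = 100, r_ex = 100, r_i = 50,
                            c = if (is.null(c)) 190 else c,
                            sigmoid = sigmoid_parameters(5, 0.56, 5),
                            input_mean = 200, input_var = 1.2)
  )
  p
}

#' Slow inhibitory-gain dynamics parameters
#'
#' The inhibitory gain `A_i` is promoted to a slow state with
#' \deqn{\dot A_i = \epsilon(-\alpha A_i + \beta \sigma(V) + n(t))}
#' where `V = x_ex - x_i` is the pyramidal membrane potential, `alpha` (Hz)
#' sets the recovery rate of the gain in the absence of input, `beta` couples
#' the fast firing rate into the slow equation, `epsilon` is the time-scale
#' separation, and `n(t)` is white noise with variance `slow_noise_var`.
#' Defaults are the values used for the seizure-transition simulations:
#' epsilon = 0.1, alpha = 0.06, beta = 5, noise variance 1e-6.
#'
#' @param epsilon Time-scale separation (dimensionless, > 0).
#' @param alpha Gain recovery rate (Hz, > 0).
#' @param beta Fast-to-slow coupling constant.
#' @param slow_noise_var Variance of the slow noise term (>= 0).
#' @return An object of class `slow_gain_parameters`.
#' @export
slow_gain_parameters <- function(epsilon = 0.1, alpha = 0.06, beta = 5,
                                 slow_noise_var = 1e-6) {
  if (!is.finite(epsilon) || epsilon <= 0) {
    stop_invalid("epsilon must be finite and > 0")
  }
  if (!is.finite(alpha) || alpha <= 0) stop_invalid("alpha must be > 0")
  if (!is.finite(beta)) stop_invalid("beta must be finite")
  if (!is.finite(slow_noise_var) || slow_noise_var < 0) {
    stop_invalid("slow_noise_var must be >= 0")
  }
  structure(list(epsilon = epsilon, alpha = alpha, beta = beta,
                 slow_noise_var = slow_noise_var),
            class = "slow_gain_parameters")
}
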