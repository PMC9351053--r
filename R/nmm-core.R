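#' Sigmoid potential-to-rate conversion
#'
#' Static conversion of a mean membrane potential into a mean population
#' firing rate, `e0 / (1 + exp(-rho * (v - v_th)))`.  Strictly increasing,
#' bounded in `(0, e0)`, equal to `e0 / 2` at the threshold, and point
#' symmetric about it: `sigmoid(v_th + d) + sigmoid(v_th - d) == e0`.
#'
#' @param v Membrane potential (mV); vectorised.
#' @param params A [sigmoid_parameters()] object.
#' @return Firing rate(s) in s^-1.
#' @export
#' @examples
#' sigmoid(6, sigmoid_parameters(e0 = 5, rho = 0.56, v_th = 6)) # 2.5
sigmoid <- function(v, params = sigmoid_parameters()) {
  stopifnot(inherits(params, "sigmoid_parameters"))
  if (!all(is.finite(v))) stop_invalid("v must be finite")
  params$e0 / (1 + exp(-params$rho * (v - params$v_th)))
}

#' Second-order synaptic impulse response
#'
#' Closed form of the post-synaptic kernel `h(t) = a * r * t * exp(-r * t)`
#' that converts a firing-rate impulse into a membrane potential deflection.
#' Peaks at `t = 1/r` with value `a / e`.  Exists mainly as the analytic
#' reference against the differential form embedded in [nmm_drift()].
#'
#' @param t Time since the impulse (s, >= 0); vectorised.
#' @param a Synaptic gain: maximum post-synaptic potential (mV).
#' @param r Inverse synaptic time constant (s^-1).
#' @return Potential (mV).
#' @export
synaptic_kernel <- function(t, a, r) {
  if (!all(is.finite(t)) || any(t < 0)) stop_invalid("t must be finite and >= 0")
  if (!is.finite(a) || a <= 0) stop_invalid("a must be > 0")
  if (!is.finite(r) || r <= 0) stop_invalid("r must be > 0")
  a * r * t * exp(-r * t)
}

#' Construct a six-component state vector
#'
#' The state order is part of the model contract:
#' `[x_p, x_p*, x_ex, x_ex*, x_i, x_i*]` -- synaptic potential and its first
#' derivative for the pyramidal, excitatory, and inhibitory populations.
#' The observation operator indexes into this order.
#'
#' @param x Numeric vector of length 6 (or nothing, for the origin).
#' @return A named numeric vector of class `nmm_state`.
#' @export
nmm_state <- function(x = numeric(6)) {
  if (length(x) != 6 || !all(is.finite(x))) {
    stop_invalid("state must be 6 finite numbers")
  }
  structure(as.numeric(x),
            names = c("x_p", "x_p_dot", "x_ex", "x_ex_dot", "x_i", "x_i_dot"),
            class = "nmm_state")
}

#' Drift field of the neural mass model
#'
#' Deterministic right-hand side of the six-state model.  Each population is
#' a second-order synaptic filter driven by a sigmoid-transformed input:
#' the pyramidal population by `sigmoid(x_ex - x_i)`, the excitatory by the
#' endogenous input `omega` plus `0.8 c * sigmoid(c * x_p)`, and the
#' inhibitory by `0.25 c * sigmoid(0.25 c * x_p)`.
#'
#' @param state Length-6 state vector (see [nmm_state()]).
#' @param params [nmm_parameters()].
#' @param omega Instantaneous endogenous input (s^-1); defaults to the
#'   parameter set's `input_mean`.
#' @return Length-6 derivative vector.
#' @export
nmm_drift <- function(state, params, omega = params$input_mean) {
  stopifnot(inherits(params, "nmm_parameters"))
  if (length(state) != 6 || !all(is.finite(state))) {
    stop_invalid("state must be 6 finite numbers")
  }
  if (!is.finite(omega)) stop_invalid("omega must be finite")
  as.numeric(cpp_nmm_drift(as.numeric(state), pack_params(params), omega))
}

#' Analytic Jacobian of the drift field
#'
#' @inheritParams nmm_drift
#' @return 6 x 6 Jacobian matrix of [nmm_drift()] with respect to the state.
#' @export
nmm_jacobian <- function(state, params, omega = params$input_mean) {
  stopifnot(inherits(params, "nmm_parameters"))
  s <- as.numeric(state)
  sg <- params$sigmoid
  # derivative of the sigmoid: rho * sig * (1 - sig / e0)
  dsig <- function(v) {
    sv <- sigmoid(v, sg)
    sg$rho * sv * (1 - sv / sg$e0)
  }
  J <- matrix(0, 6, 6)
  J[1, 2] <- 1
  J[3, 4] <- 1
  J[5, 6] <- 1
  d1 <- dsig(s[3] - s[5])
  J[2, 1] <- -params$r_p^2
  J[2, 2] <- -2 * params$r_p
  J[2, 3] <- params$a_p * params$r_p * d1
  J[2, 5] <- -params$a_p * params$r_p * d1
  d2 <- dsig(params$c * s[1]) * params$c
  J[4, 1] <- params$a_ex * params$r_ex * 0.8 * params$c * d2
  J[4, 3] <- -params$r_ex^2
  J[4, 4] <- -2 * params$r_ex
  d3 <- dsig(0.25 * params$c * s[1]) * 0.25 * params$c
  J[6, 1] <- params$a_i * params$r_i * 0.25 * params$c * d3
  J[6, 5] <- -params$r_i^2
  J[6, 6] <- -2 * params$r_i
  J
}

#' Observation operator
#'
#' Projects a state onto the recorded quantity, the pyramidal membrane
#' potential `x_ex - x_i`.  Equivalent to the inner product of the state with
#' `c(0, 0, 1, 0, -1, 0)`; for the 7-dim augmented state used by the tracker
#' the operator gains a trailing zero so the gain itself is never observed
#' directly.
#'
#' @param state Length-6 (or length-7 augmented) state vector.
#' @return Observed potential (mV).
#' @export
observe_state <- function(state) {
  s <- as.numeric(state)
  if (!length(s) %in% c(6, 7) || !all(is.finite(s))) {
    stop_invalid("state must be 6 (or 7, augmented) finite numbers")
  }
  s[3] - s[5]
}

# Observation vector for the augmented filter state [x(6), a_i].
obs_vector <- function() c(0, 0, 1, 0, -1, 0, 0)
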