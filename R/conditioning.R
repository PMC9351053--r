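#' High-pass filter specification
#'
#' @param cutoff_hz High-pass corner frequency (Hz); must be below the
#'   Nyquist frequency of the trace it is applied to.  The clinical
#'   AC-coupling emulation uses 0.3 Hz.
#' @param order Butterworth order (>= 1); the effective order doubles under
#'   zero-phase (forward-backward) application.
#' @param zero_phase Apply forward-backward (`TRUE`, default) to avoid phase
#'   distortion and latency between filtered and unfiltered comparisons.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz = 0.3, order = 4, zero_phase = TRUE) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0) {
    stop_invalid("cutoff_hz must be > 0")
  }
  if (!is.numeric(order) || order < 1) stop_invalid("order must be >= 1")
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Butterworth design in cascaded second-order sections.  At corners far
# below Nyquist (0.3 Hz at 512 Hz is 0.0012 of Nyquist) the single
# transfer-function form of a 4th-order filter is numerically degenerate
# (DC leaks through at ~1e-4 relative); the analytic pole placement plus
# per-biquad filtering keeps the response accurate to machine precision.
butter_sections <- function(order, cutoff_hz, fs, type = c("high", "low")) {
  type <- match.arg(type)
  wc <- 2 * fs * tan(pi * cutoff_hz / fs) # pre-warped analog corner
  k <- seq_len(order)
  s <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # analog prototype
  s <- if (type == "high") wc / s else wc * s
  p <- (2 * fs + s) / (2 * fs - s) # bilinear transform
  # conjugate pairing: prototype poles come in conjugate pairs (order even
  # here); take those with positive imaginary part and form biquads
  pp <- p[Im(p) > 0]
  real_p <- Re(p[abs(Im(p)) < 1e-12])
  sections <- lapply(pp, function(pk) {
    a1 <- -2 * Re(pk)
    a2 <- Mod(pk)^2
    if (type == "high") {
      b <- c(1, -2, 1)
      g <- (1 - a1 + a2) / 4 # unit gain at Nyquist
    } else {
      b <- c(1, 2, 1)
      g <- (1 + a1 + a2) / 4 # unit gain at DC
    }
    list(b = g * b, a = c(1, a1, a2))
  })
  for (pk in real_p) {
    a1 <- -pk
    if (type == "high") { # unit gain at z = -1
      sections <- c(sections, list(list(b = (1 - a1) / 2 * c(1, -1),
                                        a = c(1, a1))))
    } else { # unit gain at z = 1
      sections <- c(sections, list(list(b = (1 + a1) / 2 * c(1, 1),
                                        a = c(1, a1))))
    }
  }
  sections
}

# Each section starts at its DC steady state for the signal's first sample,
# which suppresses the step transient that plain zero initial conditions
# would inject (a constant input then yields an exactly constant output).
cascade_filter <- function(x, sections) {
  for (s in sections) {
    x0 <- x[1]
    y0 <- x0 * sum(s$b) / sum(s$a)
    x <- as.numeric(signal::filter(s$b, s$a, x,
                                   init.x = rep(x0, length(s$b) - 1),
                                   init.y = rep(y0, length(s$a) - 1)))
  }
  x
}

# Reflect-pad, filter (optionally forward-backward), trim.  Padding of 10
# corner periods absorbs the filter transient so segment interiors are
# unaffected by edge effects.
butter_apply <- function(samples, fs, sections, cutoff_hz, zero_phase) {
  n_pad <- min(length(samples) - 1,
               as.integer(ceiling(10 / cutoff_hz * fs)))
  padded <- c(rev(samples[seq_len(n_pad) + 1]), samples,
              rev(samples[length(samples) - seq_len(n_pad)]))
  out <- cascade_filter(padded, sections)
  if (zero_phase) {
    out <- rev(cascade_filter(rev(out), sections))
  }
  out[(n_pad + 1):(n_pad + length(samples))]
}

#' High-pass filter a trace
#'
#' Zero-phase Butterworth high-pass, the package's emulation of AC-coupled
#' clinical recordings.  Removes DC and infraslow content below the corner
#' while leaving content at and above ~3x the corner essentially untouched.
#' Length and sampling rate are preserved; the result is tagged
#' `kind = "highpass"`.
#'
#' @param x A [trace()].
#' @param spec A [filter_spec()]; default 0.3 Hz, order 4, zero phase.
#' @return The filtered [trace()].
#' @export
#' @examples
#' tr <- trace(5 + sin(2 * pi * 10 * (0:2047) / 512), fs = 512)
#' hp <- high_pass(tr)
#' abs(mean(hp$samples)) < 1e-6
high_pass <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "trace"), inherits(spec, "filter_spec"))
  if (spec$cutoff_hz >= x$fs / 2) {
    stop_invalid("cutoff (%g Hz) must be below Nyquist (%g Hz)",
                 spec$cutoff_hz, x$fs / 2)
  }
  sections <- butter_sections(spec$order, spec$cutoff_hz, x$fs, "high")
  out <- butter_apply(x$samples, x$fs, sections, spec$cutoff_hz,
                      spec$zero_phase)
  trace(out, fs = x$fs, label = x$label, kind = "highpass", t0 = x$t0)
}

#' Rescale a trace
#'
#' Element-wise multiplication by `factor`; used to bring raw recordings
#' (volts) into the millivolt range of the model output (factor 1e4 for the
#' original hardware).  Metadata other than the label suffix is unchanged.
#'
#' @param x A [trace()].
#' @param factor Finite, nonzero multiplier.
#' @return The rescaled [trace()].
#' @export
rescale_trace <- function(x, factor) {
  stopifnot(inherits(x, "trace"))
  if (!is.finite(factor) || factor == 0) {
    stop_invalid("factor must be finite and nonzero")
  }
  out <- x
  out$samples <- x$samples * factor
  out$label <- sprintf("%s [x%g]", x$label, factor)
  out
}

#' Decimate a trace to a lower sampling rate
#'
#' Anti-alias low-pass (8th-order Butterworth at 80% of the target Nyquist,
#' zero phase) followed by integer-factor subsampling.  The target rate must
#' divide the source rate exactly; rates such as 9600 -> 512 Hz require an
#' intermediate integer chain (e.g. 9600 -> 600) or resampling, and are
#' rejected.
#'
#' @param x A [trace()].
#' @param target_fs Target sampling rate (Hz); `fs / target_fs` must be an
#'   integer.
#' @return The decimated [trace()].
#' @export
decimate_trace <- function(x, target_fs) {
  stopifnot(inherits(x, "trace"))
  if (!is.finite(target_fs) || target_fs <= 0) {
    stop_invalid("target_fs must be > 0")
  }
  fac <- x$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) {
    stop_invalid("target_fs must divide fs exactly (fs = %g, target = %g)",
                 x$fs, target_fs)
  }
  fac <- as.integer(round(fac))
  if (fac == 1L) return(x)
  cut <- 0.8 * (target_fs / 2)
  sections <- butter_sections(8, cut, x$fs, "low")
  filtered <- butter_apply(x$samples, x$fs, sections, cut, zero_phase = TRUE)
  out <- x
  out$samples <- filtered[seq(1, length(filtered), by = fac)]
  out$fs <- target_fs
  out
}

#' Estimate measurement-noise variance from a trace
#'
#' Proxy estimate used to default the tracker's observation-noise variance:
#' the variance of the first `head_s` seconds after a 40 Hz high-pass,
#' corrected for the fraction of a white spectrum that survives the
#' high-pass.  Physiological content above 40 Hz is modest, so the residual
#' is dominated by broadband sensor noise.
#'
#' @param x A [trace()].
#' @param head_s Seconds of leading data to use (default 5).
#' @param corner_hz High-pass corner isolating the noise floor (default 40).
#' @return Estimated white-noise variance (same units as the trace, squared).
#' @export
estimate_meas_noise <- function(x, head_s = 5, corner_hz = 40) {
  stopifnot(inherits(x, "trace"))
  n <- min(length(x$samples), as.integer(round(head_s * x$fs)))
  if (n < 16) stop_invalid("trace too short for noise estimation")
  if (corner_hz >= x$fs / 2) stop_invalid("corner_hz must be below Nyquist")
  seg <- trace(x$samples[seq_len(n)], fs = x$fs)
  hp <- high_pass(seg, filter_spec(cutoff_hz = corner_hz, order = 4))
  frac <- 1 - corner_hz / (x$fs / 2)
  max(var(hp$samples) / frac, .Machine$double.eps)
}
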