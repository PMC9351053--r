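#' Uniformly sampled single-channel trace
#'
#' Light-weight container for a regularly sampled signal: the sample values,
#' the sampling rate `fs` (Hz), a free-text `label`, a `kind` tag recording
#' provenance (`"wideband"`, `"highpass"`, `"ground_truth_gain"`, or
#' `"synthetic"`), and the start time `t0` (s).
#'
#' @param samples Numeric vector of sample values (mV or a.u.); non-empty,
#'   finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Free-text channel label.
#' @param kind Provenance tag.
#' @param t0 Time of the first sample (s).
#' @return An object of class `trace`.
#' @export
#' @examples
#' tr <- trace(sin(2 * pi * 10 * (0:511) / 512), fs = 512, label = "tone")
#' trace_times(tr)[1:3]
trace <- function(samples, fs, label = "",
                  kind = c("synthetic", "wideband", "highpass",
                           "ground_truth_gain"),
                  t0 = 0) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) == 0 || !all(is.finite(samples))) {
    stop_invalid("samples must be non-empty and finite")
  }
  if (!is.finite(fs) || fs <= 0) stop_invalid("fs must be > 0")
  structure(list(samples = samples, fs = fs, label = as.character(label),
                 kind = kind, t0 = as.numeric(t0)),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz (%.3f s), kind = %s%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$kind,
              if (nzchar(x$label)) paste0(", label = \"", x$label, "\"") else ""))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)

#' @rdname trace
#' @param x A `trace`.
#' @return `trace_times()`: vector of sample times (s).
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' @export
plot.trace <- function(x, ...) {
  graphics::plot(x$t0 + (seq_along(x$samples) - 1) / x$fs, x$samples,
                 type = "l", xlab = "time (s)",
                 ylab = if (x$kind == "ground_truth_gain") "gain (mV)" else "potential (mV)",
                 main = x$label, ...)
  invisible(x)
}

#' Read and write traces as delimited text
#'
#' The on-disk format is two tab-separated columns (`time_s`, `value`)
#' preceded by `#`-prefixed header lines carrying `fs`, `label`, `kind`,
#' `t0`, and optionally `seed`.  Values are written with 15 significant
#' digits so a round trip is lossless at that precision.
#'
#' @param x A [trace()].
#' @param path File path.
#' @param seed Optional integer recorded in the header for provenance.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a `trace`.
#' @export
write_trace <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs: %.15g", x$fs),
    sprintf("# label: %s", x$label),
    sprintf("# kind: %s", x$kind),
    sprintf("# t0: %.15g", x$t0),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    "# columns: time_s\tvalue"
  ), con)
  t <- x$t0 + (seq_along(x$samples) - 1) / x$fs
  writeLines(sprintf("%.15g\t%.15g", t, x$samples), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name, default = NULL) {
    m <- grep(sprintf("^# %s:", name), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    sub(sprintf("^# %s:\\s*", name), "", m[1])
  }
  fs <- as.numeric(get_field("fs"))
  if (!length(fs) || is.na(fs)) stop_invalid("missing fs header in %s", path)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  vals <- vapply(strsplit(body, "\t", fixed = TRUE),
                 function(p) as.numeric(p[2]), numeric(1))
  trace(vals, fs = fs, label = get_field("label", ""),
        kind = get_field("kind", "synthetic"),
        t0 = as.numeric(get_field("t0", "0")))
}
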