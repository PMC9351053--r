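#' Recording scenario
#'
#' Describes a synthetic stand-in for a DC-coupled seizure recording: a
#' slow-fast simulation with seizure-like discharges, optionally carrying a
#' prominent infraslow DC component, plus additive sensor noise.
#'
#' Two DC-shift mechanisms are available when `with_dc_shift = TRUE`:
#'
#' * `"endogenous"`: the observation is used as produced by the slow-fast
#'   model, whose gain excursions shift the baseline potential -- the shift
#'   is mechanistically tied to the ground-truth gain.
#' * `"exogenous"`: the model's own infraslow component is first removed
#'   (zero-phase high-pass at `flatten_hz`, operating-point mean restored)
#'   and a smooth raised-cosine ramp of `ramp_amplitude` mV is added to the
#'   observation only -- a deliberately model-mismatched shift.
#'
#' With `with_dc_shift = FALSE` the flattened observation is used without a
#' ramp, emulating a seizure recording whose DC component is negligible.
#'
#' @param with_dc_shift Should the recording carry a prominent DC shift?
#' @param dc_shift_mode `"endogenous"` or `"exogenous"` (see Details).
#' @param ramp_amplitude Plateau amplitude (mV) of the exogenous ramp.
#' @param ramp_onset,ramp_offset Start and end (s) of the ramp rise.
#' @param seizure_window_hint Optional rough seizure time (s), recorded for
#'   downstream consumers; not used by the generator.
#' @param meas_noise_var Additive white measurement-noise variance (mV^2).
#' @param duration Recording length (s).
#' @param seed Integer seed; fully determines the recording.
#' @param flatten_hz Corner (Hz) of the infraslow-removal filter used by the
#'   flattened (no-shift / exogenous) observations.
#' @return An object of class `recording_scenario`.
#' @export
recording_scenario <- function(with_dc_shift = FALSE,
                               dc_shift_mode = c("endogenous", "exogenous"),
                               ramp_amplitude = 8,
                               ramp_onset = 3, ramp_offset = 20,
                               seizure_window_hint = NULL,
                               meas_noise_var = 1e-2,
                               duration = 300, seed = 1,
                               flatten_hz = 0.25) {
  dc_shift_mode <- match.arg(dc_shift_mode)
  if (!is.finite(duration) || duration <= 0) stop_invalid("duration must be > 0")
  if (!is.finite(ramp_amplitude)) stop_invalid("ramp_amplitude must be finite")
  if (ramp_onset < 0 || ramp_offset > duration || ramp_onset >= ramp_offset) {
    stop_invalid("ramp window must satisfy 0 <= onset < offset <= duration")
  }
  if (!is.finite(meas_noise_var) || meas_noise_var < 0) {
    stop_invalid("meas_noise_var must be >= 0")
  }
  structure(list(with_dc_shift = isTRUE(with_dc_shift),
                 dc_shift_mode = dc_shift_mode,
                 ramp_amplitude = ramp_amplitude,
                 ramp_onset = ramp_onset, ramp_offset = ramp_offset,
                 seizure_window_hint = seizure_window_hint,
                 meas_noise_var = meas_noise_var,
                 duration = duration, seed = as.integer(seed),
                 flatten_hz = flatten_hz),
            class = "recording_scenario")
}

#' Annotate seizure epochs by windowed variance
#'
#' Operational seizure marking: non-overlapping windows of `window_s`
#' seconds are flagged when their variance exceeds `threshold` times the
#' median window variance (the robust baseline); runs of flagged windows
#' form epochs.
#'
#' @param x A [trace()].
#' @param window_s Window length (s).
#' @param threshold Variance ratio defining an ictal window.
#' @return A data frame with columns `onset`, `offset` (s, relative to
#'   `t0 = 0`) and `peak_ratio` (max window variance / baseline within the
#'   epoch); zero rows if nothing crosses the threshold.
#' @export
annotate_seizures <- function(x, window_s = 1, threshold = 5) {
  stopifnot(inherits(x, "trace"))
  wlen <- as.integer(round(window_s * x$fs))
  nw <- length(x$samples) %/% wlen
  if (nw < 3) stop_invalid("trace too short for seizure annotation")
  wv <- vapply(seq_len(nw), function(i) {
    var(x$samples[((i - 1) * wlen + 1):(i * wlen)])
  }, numeric(1))
  base <- median(wv)
  hot <- wv > threshold * base
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  data.frame(
    onset = (starts[sel] - 1) * window_s,
    offset = ends[sel] * window_s,
    peak_ratio = vapply(sel, function(j) {
      max(wv[starts[j]:ends[j]]) / base
    }, numeric(1))
  )
}

#' Generate a synthetic DC-coupled seizure recording
#'
#' Runs the slow-fast model, applies the scenario's DC-shift mechanism (see
#' [recording_scenario()]), adds white measurement noise, and annotates
#' seizure epochs.  Everything is deterministic given the scenario seed.
#' The slow-fast dynamics start at the stated initial gain, which lies in
#' the ictal band, so recordings open with a seizure cluster and settle into
#' post-ictal quiescence as the gain recovers -- if no epoch crosses the
#' annotation threshold a generation-failure warning is raised and flagged
#' in the result.
#'
#' @param scenario A [recording_scenario()].
#' @param params [nmm_parameters()]; default [nmm_preset()] `"seizure"`.
#' @param slow [slow_gain_parameters()].
#' @param output_rate Sampling rate (Hz) of the recording.
#' @return A list of class `synthetic_recording` with `wideband` ([trace()],
#'   kind `"wideband"`), `gain` (ground-truth gain trace), `annotations`
#'   (from [annotate_seizures()]), `scenario`, and `failed` (TRUE when no
#'   seizure epoch was detected).
#' @export
generate_recording <- function(scenario,
                               params = nmm_preset("seizure"),
                               slow = slow_gain_parameters(),
                               output_rate = 512) {
  stopifnot(inherits(scenario, "recording_scenario"),
            inherits(params, "nmm_parameters"),
            inherits(slow, "slow_gain_parameters"))
  cfg <- simulation_config(duration = scenario$duration,
                           seed = scenario$seed, output_rate = output_rate)
  sim <- integrate_slow_fast(params, slow, cfg)
  obs <- sim$trace

  flatten <- function(tr) {
    out <- high_pass(tr, filter_spec(cutoff_hz = scenario$flatten_hz,
                                     order = 2))
    out$samples <- out$samples + mean(tr$samples)
    out$kind <- "wideband"
    out
  }
  if (scenario$with_dc_shift && scenario$dc_shift_mode == "endogenous") {
    obs$kind <- "wideband"
  } else {
    obs <- flatten(obs)
    if (scenario$with_dc_shift) {
      tt <- (seq_along(obs$samples) - 1) / obs$fs
      rise <- (tt - scenario$ramp_onset) /
        (scenario$ramp_offset - scenario$ramp_onset)
      ramp <- scenario$ramp_amplitude *
        ifelse(tt < scenario$ramp_onset, 0,
               ifelse(tt > scenario$ramp_offset, 1,
                      0.5 * (1 - cos(pi * rise))))
      obs$samples <- obs$samples + ramp
    }
  }
  if (scenario$meas_noise_var > 0) {
    obs$samples <- obs$samples + with_seed(
      scenario$seed + 1000L,
      rnorm(length(obs$samples), 0, sqrt(scenario$meas_noise_var))
    )
  }
  obs$label <- sprintf("synthetic recording (seed %d)", scenario$seed)

  ann <- annotate_seizures(obs)
  failed <- nrow(ann) == 0
  if (failed) {
    warning("generation failure: no seizure epoch detected within ",
            scenario$duration, " s", call. = FALSE)
  }
  structure(list(wideband = obs, gain = sim$gain, annotations = ann,
                 scenario = scenario, failed = failed),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %.0f s @ %g Hz, seed %d\n",
              x$scenario$duration, x$wideband$fs, x$scenario$seed))
  cat(sprintf("  DC shift: %s%s;  seizure epochs: %d%s\n",
              if (x$scenario$with_dc_shift) "yes" else "no",
              if (x$scenario$with_dc_shift) {
                paste0(" (", x$scenario$dc_shift_mode, ")")
              } else "",
              nrow(x$annotations),
              if (x$failed) " [GENERATION FAILURE]" else ""))
  invisible(x)
}

#' Build the wideband / high-pass condition pair
#'
#' Pairs a wideband trace with its 0.3 Hz zero-phase high-pass twin, the
#' emulation of the same recording seen through a conventional AC-coupled
#' amplifier.  Both share sampling rate, length and time base.
#'
#' @param wideband A [trace()].
#' @param spec The high-pass [filter_spec()] (default: 0.3 Hz, order 4,
#'   zero phase).
#' @return A list with elements `wideband` and `highpass`.
#' @export
make_condition_set <- function(wideband, spec = filter_spec()) {
  stopifnot(inherits(wideband, "trace"))
  if (wideband$fs <= 2 * spec$cutoff_hz) {
    stop_invalid("sampling rate too low for a %g Hz high-pass",
                 spec$cutoff_hz)
  }
  list(wideband = wideband, highpass = high_pass(wideband, spec))
}

#' Write a fixture bundle to disk
#'
#' Persists a set of traces plus annotations and the scenario in a JSON
#' manifest.  Trace files use the delimited-text container of
#' [write_trace()] with deterministic names `<stem>_<seed>_<kind>.tsv`;
#' samples round-trip at 15 significant digits, and re-generating from the
#' manifest's scenario reproduces the traces exactly.
#'
#' @param path Directory to write into (created if missing).
#' @param rec A `synthetic_recording` from [generate_recording()].
#' @param extra Optional named list of additional [trace()]s to include.
#' @param stem File-name stem; default derived from the scenario.
#' @return The manifest path, invisibly.
#' @export
write_fixture_bundle <- function(path, rec, extra = list(), stem = NULL) {
  stopifnot(inherits(rec, "synthetic_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sc <- rec$scenario
  if (is.null(stem)) {
    stem <- sprintf("%s", if (sc$with_dc_shift) {
      paste0("shift-", sc$dc_shift_mode)
    } else "noshift")
  }
  traces <- c(list(wideband = rec$wideband, gain = rec$gain), extra)
  files <- character(0)
  for (nm in names(traces)) {
    f <- sprintf("%s_%d_%s.tsv", stem, sc$seed, nm)
    write_trace(traces[[nm]], file.path(path, f), seed = sc$seed)
    files[nm] <- f
  }
  manifest <- list(
    scenario = unclass(sc),
    files = as.list(files),
    annotations = rec$annotations,
    failed = rec$failed,
    package_version = as.character(utils::packageVersion("gaintrack"))
  )
  mf <- file.path(path, sprintf("%s_%d_manifest.json", stem, sc$seed))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a fixture bundle manifest
#'
#' @param manifest Path to a manifest written by [write_fixture_bundle()].
#' @return A list with `scenario` (a [recording_scenario()]), `traces`
#'   (named list of [trace()]s), `annotations`, and `failed`.
#' @export
read_fixture_bundle <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  sc <- m$scenario
  scenario <- recording_scenario(
    with_dc_shift = sc$with_dc_shift, dc_shift_mode = sc$dc_shift_mode,
    ramp_amplitude = sc$ramp_amplitude, ramp_onset = sc$ramp_onset,
    ramp_offset = sc$ramp_offset,
    seizure_window_hint = sc$seizure_window_hint,
    meas_noise_var = sc$meas_noise_var, duration = sc$duration,
    seed = sc$seed, flatten_hz = sc$flatten_hz)
  dirn <- dirname(manifest)
  traces <- lapply(m$files, function(f) read_trace(file.path(dirn, f)))
  list(scenario = scenario, traces = traces,
       annotations = as.data.frame(m$annotations), failed = m$failed)
}
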