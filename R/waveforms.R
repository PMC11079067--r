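## Waveform layer: render an averaged BAEP trace from an indicator vector and
## measure the indicators back from a trace. Serves as a round-trip fixture
## for the feature-extraction conventions (positive peak latency; amplitude =
## positive peak to next negative trough).

DEFAULT_SEARCH_WINDOWS <- list(la_i = c(1.2, 2.2), la_ii = c(2.3, 3.3),
                               la_iii = c(3.4, 4.5), la_iv = c(4.6, 5.4),
                               la_v = c(5.4, 6.8))

## Fraction of peak-to-trough amplitude carried by the positive lobe, and the
## trough delay in units of the lobe sd. At 4 sd the two Gaussian lobes
## interact negligibly, so constructed peak/trough values are exact to well
## under one quantization step.
WAVE_POS_FRAC <- 0.6
WAVE_TROUGH_DELAY_SD <- 4

#' Synthesize an averaged BAEP waveform from wave indicators
#'
#' Each wave with a present latency contributes a positive Gaussian lobe
#' centred at that latency followed by a matched negative lobe, scaled so the
#' positive-peak-to-next-trough distance equals the wave's amplitude.
#' Residual averaged noise has sd `noise_sd / sqrt(averages)`, reflecting
#' sweep averaging; samples are quantized to `quantum` uV.
#'
#' @param features Named list or one-row data frame with latencies `la_i` ..
#'   `la_v` (ms; `NA` = wave absent) and amplitudes `am_i`, `am_v` (uV).
#'   Waves II-IV, whose amplitudes are not tracked, are rendered at
#'   `default_amplitude`.
#' @param peak_widths Named vector of Gaussian lobe sds per wave, ms
#'   (default 0.07 for all five waves).
#' @param noise_sd Pre-averaging noise sd, uV.
#' @param averages Number of averaged sweeps (default 2000).
#' @param sampling_rate Hz; must resolve 0.1 ms latency steps (>= 10 kHz).
#'   The default oversamples heavily so that amplitude quantization, not the
#'   sample grid, limits measurement resolution.
#' @param window_ms Length-2 analysis window, ms post-stimulus.
#' @param default_amplitude Amplitude for waves without a tracked amplitude, uV.
#' @param quantum Amplitude quantization step, uV.
#' @param side,timestamp Carried through to the waveform object.
#' @return Object of class `baep_waveform`: list with `samples` (uV),
#'   `time_ms`, `sampling_rate`, `window_ms`, `quantum`, `side`, `timestamp`.
#' @seealso [extract_wave_features()]
#' @export
synthesize_waveform <- function(features, peak_widths = NULL, noise_sd = 0,
                                averages = 2000, sampling_rate = 100000,
                                window_ms = c(0, 10), default_amplitude = 0.2,
                                quantum = 0.0025, side = NA_character_,
                                timestamp = NA_real_) {
  if (sampling_rate < 10000)
    stop_config("sampling_rate must be >= 10 kHz to resolve 0.1 ms latencies")
  if (averages < 1) stop_config("averages must be >= 1")
  features <- as.list(features)
  if (is.null(peak_widths))
    peak_widths <- stats::setNames(rep(0.07, 5), BAEP_WAVES)

  amps <- c(la_i = features$am_i %||% NA_real_,
            la_ii = default_amplitude, la_iii = default_amplitude,
            la_iv = default_amplitude, la_v = features$am_v %||% NA_real_)
  dt <- 1000 / sampling_rate
  time_ms <- seq(window_ms[1], window_ms[2], by = dt)
  x <- numeric(length(time_ms))
  for (w in BAEP_WAVES) {
    lat <- features[[w]]
    if (is.null(lat) || is.na(lat)) next
    a <- amps[[w]]
    if (is.na(a)) a <- default_amplitude
    if (a <= 0) stop_config("wave %s present with non-positive amplitude", w)
    sigma <- peak_widths[[w]]
    trough <- lat + WAVE_TROUGH_DELAY_SD * sigma
    if (lat < window_ms[1] || trough + 3 * sigma > window_ms[2])
      stop_config("window [%g, %g] ms too short for wave %s at %g ms",
                  window_ms[1], window_ms[2], w, lat)
    x <- x + WAVE_POS_FRAC * a * exp(-(time_ms - lat)^2 / (2 * sigma^2)) -
      (1 - WAVE_POS_FRAC) * a * exp(-(time_ms - trough)^2 / (2 * sigma^2))
  }
  if (noise_sd > 0)
    x <- x + stats::rnorm(length(x)) * noise_sd / sqrt(averages)
  x <- round(x / quantum) * quantum
  structure(list(samples = x, time_ms = time_ms,
                 sampling_rate = sampling_rate, window_ms = window_ms,
                 quantum = quantum, side = side, timestamp = timestamp),
            class = "baep_waveform")
}

#' @export
print.baep_waveform <- function(x, ...) {
  cat(sprintf("BAEP waveform: %d samples @ %g kHz, window %g-%g ms\n",
              length(x$samples), x$sampling_rate / 1000,
              x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

empty_wave_features <- function(side = NA_character_, timestamp = NA_real_,
                                phase = NA_character_) {
  df <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(baep_indicators())), baep_indicators())))
  df$side <- side
  df$timestamp_s <- timestamp
  df$phase <- phase
  df
}

#' Extract wave indicators from an averaged BAEP waveform
#'
#' For each wave, the latency is the time of the maximal positive peak within
#' its search window (the centre of the maximal plateau if quantization has
#' flattened the peak; among distinct equal peaks the earlier one wins) and
#' the amplitude is that
#' peak minus the following local minimum, searched up to the start of the
#' next wave's window (for wave V, up to 1.5 ms past the peak). A wave whose
#' peak-to-trough amplitude falls below `min_amplitude` is marked absent
#' (`NA`); absence is a value, not an error. Interpeak latencies are derived
#' from the detected components.
#'
#' @param w A `baep_waveform`.
#' @param search_windows Named list of `c(start, end)` ms windows per wave
#'   (half-open, `start <= t < end`); must lie inside the waveform window, be
#'   ordered, and not overlap.
#' @param min_amplitude Peak-to-trough threshold (uV) below which a wave is
#'   declared absent ("wave disappearance"). Default 0.05 uV.
#' @return One-row data frame in the [cohort_features()] indicator layout
#'   (plus `side`, `timestamp_s`, `phase`).
#' @export
extract_wave_features <- function(w, search_windows = DEFAULT_SEARCH_WINDOWS,
                                  min_amplitude = 0.05) {
  stopifnot(inherits(w, "baep_waveform"))
  wins <- search_windows[BAEP_WAVES]
  if (any(vapply(wins, is.null, TRUE)))
    stop_config("search_windows must name all of %s",
                paste(BAEP_WAVES, collapse = ", "))
  starts <- vapply(wins, `[`, 0, 1)
  ends <- vapply(wins, `[`, 0, 2)
  if (any(starts < w$window_ms[1]) || any(ends > w$window_ms[2]))
    stop_config("search windows must lie within the waveform window")
  if (any(diff(starts) <= 0) || any(starts[-1] < ends[-length(ends)]))
    stop_config("search windows must be ordered and non-overlapping")

  out <- empty_wave_features(w$side, w$timestamp, NA_character_)
  t <- w$time_ms
  for (k in seq_along(BAEP_WAVES)) {
    wave <- BAEP_WAVES[k]
    idx <- which(t >= starts[k] & t < ends[k])
    if (!length(idx)) next
    seg <- w$samples[idx]
    cand <- idx[seg == max(seg)]
    # quantization flattens peaks into plateaus: use the centre of the first
    # maximal plateau; distinct equal peaks resolve to the earliest one
    brk <- which(diff(cand) > 1L)
    run <- if (length(brk)) cand[seq_len(brk[1])] else cand
    peak_i <- run[ceiling(length(run) / 2)]
    trough_end <- if (k < length(BAEP_WAVES)) starts[k + 1] else
      min(t[peak_i] + 1.5, w$window_ms[2])
    reg <- which(t >= t[peak_i] & t <= trough_end)
    amp <- w$samples[peak_i] - min(w$samples[reg])
    if (amp < min_amplitude) next
    out[[wave]] <- t[peak_i]
    if (wave == "la_i") out$am_i <- amp
    if (wave == "la_v") out$am_v <- amp
  }
  out$la_i_iii <- out$la_iii - out$la_i
  out$la_iii_v <- out$la_v - out$la_iii
  out$la_i_v <- out$la_v - out$la_i
  out
}

#' Write / read a waveform as two-column plain text
#'
#' Columns `time_ms`, `amplitude_uv`, tab-separated, with a schema comment
#' line carrying the sampling rate and quantum.
#'
#' @param w A `baep_waveform`.
#' @param path Output / input file path.
#' @return `write_waveform_txt()` the path invisibly;
#'   `read_waveform_txt()` a `baep_waveform`.
#' @export
write_waveform_txt <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# baepstd waveform v1 sampling_rate=%g quantum=%g",
                     w$sampling_rate, w$quantum), con)
  utils::write.table(data.frame(time_ms = w$time_ms,
                                amplitude_uv = w$samples),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_txt
#' @export
read_waveform_txt <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  hdr <- readLines(path, n = 1)
  sr <- 10000
  qm <- 0.0025
  if (startsWith(hdr, "#")) {
    m <- regmatches(hdr, regexec("sampling_rate=([0-9.eE+-]+)", hdr))[[1]]
    if (length(m) == 2) sr <- as.numeric(m[2])
    m <- regmatches(hdr, regexec("quantum=([0-9.eE+-]+)", hdr))[[1]]
    if (length(m) == 2) qm <- as.numeric(m[2])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(samples = df$amplitude_uv, time_ms = df$time_ms,
                 sampling_rate = sr,
                 window_ms = range(df$time_ms), quantum = qm,
                 side = NA_character_, timestamp = NA_real_),
            class = "baep_waveform")
}
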