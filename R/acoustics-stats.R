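stat_block <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(list(mean = NA_real_, sd = NA_real_,
                              min = NA_real_, max = NA_real_))
  list(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       min = min(x), max = max(x))
}

#' Call repetition rate from a mean inter-call interval
#'
#' The repetition rate in calls/s is the reciprocal of the mean inter-call
#' interval, reported at two decimals. A mean interval of 790.0 ms thus
#' gives 1.27 calls/s.
#'
#' @param mean_interval_ms mean inter-call interval in ms (> 0).
#' @return calls per second, rounded half-up to 2 decimals.
#' @export
repetition_rate <- function(mean_interval_ms) {
  if (!is.finite(mean_interval_ms) || mean_interval_ms <= 0)
    return(NA_real_)
  round_half_up(1000 / mean_interval_ms, 2)
}

#' Summarize call windows, pulse counts and dominant frequencies
#'
#' Produces the per-recording acoustic summary used to compare advertisement
#' calls between species: call-duration statistics, inter-call-interval
#' statistics, repetition rate, pulses per call and dominant frequency.
#' Standard deviations are sample (n-1) statistics.
#'
#' Under the default `interval_convention = "gap"` the i-th interval is
#' `onset[i+1] - offset[i]`; under `"onset_to_onset"` it is
#' `onset[i+1] - onset[i]`. The repetition rate is the reciprocal of the
#' mean interval (exact before the 2-decimal display rounding), so the two
#' conventions yield different rates for the same windows.
#'
#' @param windows a `call_windows` data.frame from [segment_calls()].
#' @param pulse_counts integer vector, pulses per call (optional).
#' @param dom_freqs_khz numeric vector, dominant frequency per call in kHz
#'   (optional).
#' @param interval_convention `"gap"` or `"onset_to_onset"`.
#' @return an object of class `call_stats`: `n_calls`, blocks `duration_ms`,
#'   `interval_ms`, `pulses_per_call`, `dominant_freq_khz` (each
#'   mean/sd/min/max), and `repetition_rate_cps`. With a single window the
#'   interval block and the rate are `NA` and `interval_defined` is `FALSE`.
#' @export
summarize_calls <- function(windows, pulse_counts = NULL,
                            dom_freqs_khz = NULL,
                            interval_convention = c("gap", "onset_to_onset")) {
  interval_convention <- match.arg(interval_convention)
  n <- nrow(windows)
  if (n < 1) stopf("no call windows to summarize")
  dur_ms <- (windows$offset_s - windows$onset_s) * 1000
  if (n >= 2) {
    int_ms <- switch(interval_convention,
      gap = (windows$onset_s[-1] - windows$offset_s[-n]) * 1000,
      onset_to_onset = diff(windows$onset_s) * 1000)
  } else int_ms <- numeric(0)
  structure(list(
    n_calls = n,
    duration_ms = stat_block(dur_ms),
    interval_ms = stat_block(int_ms),
    interval_defined = n >= 2,
    interval_convention = interval_convention,
    repetition_rate_cps = if (n >= 2) repetition_rate(mean(int_ms))
                          else NA_real_,
    pulses_per_call = stat_block(as.numeric(pulse_counts %||% numeric(0))),
    dominant_freq_khz = stat_block(dom_freqs_khz %||% numeric(0))),
    class = "call_stats")
}

fmt_block <- function(b, digits) {
  if (!is.finite(b$mean)) return("--")
  f <- function(v) formatC(round_half_up(v, digits), format = "f",
                           digits = digits)
  sprintf("%s ± %s (%s–%s)", f(b$mean),
          if (is.finite(b$sd)) f(b$sd) else "NA", f(b$min), f(b$max))
}

#' @export
print.call_stats <- function(x, ...) {
  cat(sprintf("Number of call groups measured\t%d\n", x$n_calls))
  cat(sprintf("Call duration (ms)\t%s\n", fmt_block(x$duration_ms, 1)))
  cat(sprintf("Intercall interval (ms)\t%s\n", fmt_block(x$interval_ms, 1)))
  cat(sprintf("Call repetition rate (calls/s)\t%s\n",
              if (is.finite(x$repetition_rate_cps))
                format(x$repetition_rate_cps) else "undefined"))
  cat(sprintf("Pulses/call\t%s\n",
              if (is.finite(x$pulses_per_call$min))
                sprintf("%g–%g", x$pulses_per_call$min,
                        x$pulses_per_call$max) else "--"))
  cat(sprintf("Dominant frequency (kHz)\t%s\n",
              fmt_block(x$dominant_freq_khz, 2)))
  invisible(x)
}

#' Write call statistics to JSON or TSV
#'
#' Row labels follow the conventional comparison-table wording: "Call
#' duration (ms)", "Intercall interval (ms)", "Call repetition rate
#' (calls/s)", "Pulses/call", "Dominant frequency (kHz)".
#'
#' @param stats a [summarize_calls()] result.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_call_stats <- function(stats, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    lines <- c(
      sprintf("Number of call groups measured\t%d", stats$n_calls),
      sprintf("Call duration (ms)\t%s", fmt_block(stats$duration_ms, 1)),
      sprintf("Intercall interval (ms)\t%s", fmt_block(stats$interval_ms, 1)),
      sprintf("Call repetition rate (calls/s)\t%s",
              format(stats$repetition_rate_cps)),
      sprintf("Pulses/call\t%s",
              if (is.finite(stats$pulses_per_call$min))
                sprintf("%g–%g", stats$pulses_per_call$min,
                        stats$pulses_per_call$max) else "--"),
      sprintf("Dominant frequency (kHz)\t%s",
              fmt_block(stats$dominant_freq_khz, 2)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Full acoustic measurement pipeline for one recording
#'
#' Denoises the clip, segments call groups by amplitude threshold, counts
#' pulses per call, extracts per-call dominant frequency and returns the
#' summary statistics together with the intermediate products.
#'
#' @param clip an [audio_clip()] or a path to a WAV file.
#' @param denoise_par a [denoise_params()].
#' @param segment_par a [segment_params()].
#' @param pulse_par a [pulse_params()].
#' @param interval_convention passed to [summarize_calls()].
#' @return list with `windows`, `pulse_trains` (list of pulse-time vectors),
#'   `pulse_counts`, `dom_freq_khz` and `stats` (a `call_stats`).
#' @export
analyze_recording <- function(clip,
                              denoise_par = denoise_params(),
                              segment_par = segment_params(),
                              pulse_par = pulse_params(),
                              interval_convention = c("gap",
                                                      "onset_to_onset")) {
  interval_convention <- match.arg(interval_convention)
  if (is.character(clip)) clip <- read_wav(clip)
  den <- denoise(clip, denoise_par)
  windows <- segment_calls(den, segment_par)
  if (!nrow(windows)) {
    return(list(windows = windows, pulse_trains = list(),
                pulse_counts = integer(0), dom_freq_khz = numeric(0),
                stats = NULL))
  }
  pulse_trains <- lapply(seq_len(nrow(windows)), function(i)
    count_pulses(den, windows[i, ], pulse_par))
  dom <- vapply(seq_len(nrow(windows)), function(i)
    as.numeric(dominant_frequency(den, windows[i, ])), numeric(1))
  counts <- vapply(pulse_trains, length, integer(1))
  list(windows = windows, pulse_trains = pulse_trains,
       pulse_counts = counts, dom_freq_khz = dom,
       stats = summarize_calls(windows, counts, dom,
                               interval_convention))
}
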