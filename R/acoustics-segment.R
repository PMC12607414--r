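#' Call-segmentation parameters
#'
#' Defaults are sized for megophryid advertisement calls of a few hundred ms
#' separated by several hundred ms of silence: a 5 ms RMS frame resolves
#' onsets to a couple of ms, a threshold at 10% of the global envelope peak
#' sits well above the residual noise floor of a denoised recording, and a
#' 100 ms merge gap bridges the few-ms inter-pulse dips inside one call
#' group without bridging true inter-call silences.
#'
#' @param envelope_frame_ms RMS envelope frame, ms.
#' @param threshold_frac segmentation threshold as a fraction of the global
#'   envelope peak, in (0, 1).
#' @param min_call_ms minimum call-group duration, ms; shorter runs are
#'   discarded.
#' @param min_gap_ms runs separated by less than this are merged, ms.
#' @return a `segment_params` list.
#' @export
segment_params <- function(envelope_frame_ms = 5, threshold_frac = 0.1,
                           min_call_ms = 50, min_gap_ms = 100) {
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stopf("threshold_frac must lie in (0, 1)")
  if (envelope_frame_ms <= 0 || min_call_ms <= 0 || min_gap_ms <= 0)
    stopf("durations must be > 0")
  structure(list(envelope_frame_ms = envelope_frame_ms,
                 threshold_frac = threshold_frac,
                 min_call_ms = min_call_ms, min_gap_ms = min_gap_ms),
            class = "segment_params")
}

#' Amplitude-threshold call segmentation
#'
#' Isolates call groups as maximal runs where the RMS envelope meets or
#' exceeds `threshold_frac` times its global peak. Runs separated by less
#' than `min_gap_ms` are merged (inter-pulse dips within one call group),
#' and merged runs shorter than `min_call_ms` are discarded. The threshold
#' is relative, so segmentation is invariant to positive rescaling of the
#' recording.
#'
#' @param clip an [audio_clip()], typically denoised first.
#' @param params a [segment_params()].
#' @return a data.frame of class `call_windows` with columns `onset_s` and
#'   `offset_s`, sorted and non-overlapping; zero rows for silence.
#' @export
segment_calls <- function(clip, params = segment_params()) {
  env <- amplitude_envelope(clip, params$envelope_frame_ms)
  peak <- max(env$values)
  if (peak <= 0) return(empty_windows())
  above <- env$values >= params$threshold_frac * peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs)) return(empty_windows())
  # frame-edge times of each run
  on <- env$times_s[runs[, 1]] - env$frame_s / 2
  off <- env$times_s[runs[, 2]] + env$frame_s / 2
  # merge runs separated by < min_gap_ms
  min_gap <- params$min_gap_ms / 1000
  keep_on <- on[1]; keep_off <- off[1]
  if (length(on) > 1) {
    for (i in 2:length(on)) {
      if (on[i] - keep_off[length(keep_off)] < min_gap) {
        keep_off[length(keep_off)] <- off[i]
      } else {
        keep_on <- c(keep_on, on[i]); keep_off <- c(keep_off, off[i])
      }
    }
  }
  long_enough <- (keep_off - keep_on) * 1000 >= params$min_call_ms
  w <- data.frame(onset_s = pmax(0, keep_on[long_enough]),
                  offset_s = keep_off[long_enough])
  class(w) <- c("call_windows", "data.frame")
  w
}

empty_windows <- function() {
  w <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  class(w) <- c("call_windows", "data.frame")
  w
}

#' Pulse-detection parameters
#'
#' @param envelope_frame_ms RMS frame for the fine (pulse-scale) envelope,
#'   ms; must be short relative to the pulse spacing.
#' @param min_prominence_frac minimum peak prominence as a fraction of the
#'   within-window envelope peak, in (0, 1).
#' @param min_pulse_spacing_ms minimum spacing between detected pulses, ms.
#' @param bandpass_hz optional `c(low, high)` band, Hz; when given, the
#'   window is brick-wall bandpass filtered (FFT zeroing) before the
#'   envelope is taken, restricting pulse detection to the carrier band.
#' @return a `pulse_params` list.
#' @export
pulse_params <- function(envelope_frame_ms = 1, min_prominence_frac = 0.25,
                         min_pulse_spacing_ms = 2, bandpass_hz = NULL) {
  if (min_prominence_frac <= 0 || min_prominence_frac >= 1)
    stopf("min_prominence_frac must lie in (0, 1)")
  structure(list(envelope_frame_ms = envelope_frame_ms,
                 min_prominence_frac = min_prominence_frac,
                 min_pulse_spacing_ms = min_pulse_spacing_ms,
                 bandpass_hz = bandpass_hz), class = "pulse_params")
}

#' Count pulses within one call window
#'
#' Pulses — the distinct sound units inside a call group — are detected as
#' peaks of the fine-scale RMS envelope of the window, kept when their
#' topographic prominence reaches `min_prominence_frac` of the window's
#' envelope peak and they are at least `min_pulse_spacing_ms` apart.
#' Pulses spaced below the minimum spacing are merged into one detection;
#' that undercount is the documented behaviour, not an error.
#'
#' @param clip an [audio_clip()].
#' @param window one row of a `call_windows` data.frame (or any list with
#'   `onset_s` and `offset_s`).
#' @param params a [pulse_params()].
#' @return numeric vector of pulse times in seconds (clip time axis), class
#'   `pulse_train`; empty for a degenerate window of fewer than two
#'   envelope frames.
#' @export
count_pulses <- function(clip, window, params = pulse_params()) {
  sr <- clip$sample_rate_hz
  i0 <- max(1L, as.integer(floor(window$onset_s * sr)) + 1L)
  i1 <- min(length(clip$samples), as.integer(ceiling(window$offset_s * sr)))
  if (i1 <= i0) return(structure(numeric(0), class = "pulse_train"))
  seg <- clip$samples[i0:i1]
  if (!is.null(params$bandpass_hz)) {
    seg <- fft_bandpass(seg, sr, params$bandpass_hz[1], params$bandpass_hz[2])
  }
  env <- amplitude_envelope(audio_clip(seg, sr), params$envelope_frame_ms)
  if (length(env$values) < 2)
    return(structure(numeric(0), class = "pulse_train"))
  spacing_frames <- max(1, (params$min_pulse_spacing_ms / 1000) / env$hop_s)
  idx <- find_peaks(env$values,
                    min_prominence = params$min_prominence_frac *
                      max(env$values),
                    min_spacing = spacing_frames)
  structure((i0 - 1) / sr + env$times_s[idx], class = "pulse_train")
}

fft_bandpass <- function(x, sr, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sr / n
  f <- pmin(f, sr - f)  # fold to two-sided frequencies
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Dominant frequency of a call window
#'
#' Averages 512-point Hann-windowed magnitude-squared spectra over
#' 50%-overlapping segments of the window (a Welch periodogram) and returns
#' the bin-center frequency of the maximum-energy bin in kHz. The spectral
#' resolution is `sample_rate / 512` (187.5 Hz at 96 kHz).
#'
#' @param clip an [audio_clip()].
#' @param window a list with `onset_s`, `offset_s`.
#' @param n_fft FFT length (default 512).
#' @return dominant frequency in kHz with attributes `bin_width_hz` and
#'   `low_resolution` (`TRUE` when the window was shorter than `n_fft` and
#'   a single zero-padded segment was used).
#' @export
dominant_frequency <- function(clip, window, n_fft = 512L) {
  sr <- clip$sample_rate_hz
  i0 <- max(1L, as.integer(floor(window$onset_s * sr)) + 1L)
  i1 <- min(length(clip$samples), as.integer(ceiling(window$offset_s * sr)))
  x <- clip$samples[i0:i1]
  low_res <- length(x) < n_fft
  if (low_res) x <- c(x, numeric(n_fft - length(x)))
  w <- hann_window(n_fft)
  starts <- seq.int(1L, length(x) - n_fft + 1L, by = n_fft %/% 2L)
  psd <- numeric(n_fft)
  for (s in starts) {
    psd <- psd + Mod(stats::fft(x[s:(s + n_fft - 1L)] * w))^2
  }
  half <- psd[seq_len(n_fft %/% 2L + 1L)]
  k <- which.max(half) - 1L
  structure(k * sr / n_fft / 1000,
            bin_width_hz = sr / n_fft, low_resolution = low_res)
}
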