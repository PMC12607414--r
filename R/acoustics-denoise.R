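#' Spectral-gating denoiser parameters
#'
#' @param enabled if `FALSE`, [denoise()] is the identity.
#' @param noise_quantile fraction of lowest-energy STFT frames used to
#'   estimate the stationary noise spectrum (in (0, 1)).
#' @param reduction_db maximum per-bin attenuation applied to sub-threshold
#'   time-frequency cells, dB.
#' @param n_fft STFT frame length in samples (Hann window, 50% overlap).
#' @return a `denoise_params` list.
#' @export
denoise_params <- function(enabled = TRUE, noise_quantile = 0.1,
                           reduction_db = 20, n_fft = 512L) {
  if (noise_quantile <= 0 || noise_quantile >= 1)
    stopf("noise_quantile must lie in (0, 1)")
  if (reduction_db < 0) stopf("reduction_db must be >= 0")
  structure(list(enabled = isTRUE(enabled), noise_quantile = noise_quantile,
                 reduction_db = reduction_db, n_fft = as.integer(n_fft)),
            class = "denoise_params")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Spectral-gating noise reduction
#'
#' Stationary spectral gating in the style of the classic broadband
#' noise-gate: the noise magnitude spectrum is estimated per frequency bin
#' from the lowest-energy STFT frames, a per-bin threshold is set at the
#' noise mean plus 1.5 standard deviations, and time-frequency cells below
#' threshold are attenuated by up to `reduction_db`. The gain mask is
#' smoothed along time to limit musical noise, and the signal is
#' reconstructed by Hann overlap-add, preserving length and sample rate.
#'
#' Because the gate threshold is derived from the clip's own spectra, the
#' operation commutes with positive rescaling of the input.
#'
#' @param clip an [audio_clip()].
#' @param params a [denoise_params()].
#' @return a denoised [audio_clip()] of identical length and sample rate.
#'   An all-zero clip is returned unchanged with a warning.
#' @export
denoise <- function(clip, params = denoise_params()) {
  if (!params$enabled) return(clip)
  x <- clip$samples
  if (!length(x)) stopf("empty clip")
  if (all(x == 0)) {
    warnf("all-zero clip: nothing to denoise")
    return(clip)
  }
  n_fft <- params$n_fft
  hop <- n_fft %/% 2L
  # pad half a frame each side so every sample gets full overlap-add weight
  xp <- c(numeric(hop), x, numeric(n_fft))
  starts <- seq.int(1L, length(xp) - n_fft + 1L, by = hop)
  w <- hann_window(n_fft)
  frames <- vapply(starts, function(s) xp[s:(s + n_fft - 1L)] * w,
                   numeric(n_fft))
  spec <- stats::mvfft(frames)
  mag <- Mod(spec)

  energy <- colSums(mag^2)
  n_noise <- max(1L, as.integer(floor(params$noise_quantile * length(starts))))
  noise_idx <- order(energy)[seq_len(n_noise)]
  nm <- mag[, noise_idx, drop = FALSE]
  nsd <- apply(nm, 1, stats::sd)
  nsd[!is.finite(nsd)] <- 0
  thresh <- rowMeans(nm) + 1.5 * nsd

  floor_gain <- 10^(-params$reduction_db / 20)
  gain <- ifelse(mag > thresh, 1, floor_gain)
  if (ncol(gain) >= 3) {  # temporal smoothing of the mask
    gain <- t(apply(gain, 1, function(g)
      stats::filter(g, c(0.25, 0.5, 0.25), sides = 2) |>
        (\(s) ifelse(is.na(s), g, s))()))
  }
  rec <- Re(stats::mvfft(spec * gain, inverse = TRUE)) / n_fft
  y <- numeric(length(xp))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + n_fft - 1L)
    y[idx] <- y[idx] + rec[, k]
  }
  audio_clip(y[(hop + 1):(hop + length(x))], clip$sample_rate_hz)
}
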