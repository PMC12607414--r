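#' Specification for a synthetic advertisement-call recording
#'
#' Parameterizes a pulse-train call simulator whose defaults mirror the
#' advertisement call of a male *Boulenophrys lushanensis*-type horned toad:
#' about 300 ms call groups separated by about 800 ms of silence, 48 pulses
#' per call, and a 2.56 kHz carrier, recorded at 96 kHz.
#'
#' @param n_calls number of call groups (>= 0).
#' @param call_duration_ms nominal call-group duration, ms.
#' @param intercall_interval_ms nominal silent interval, ms. Under the default
#'   `interval_convention = "gap"` this is the offset-to-next-onset gap, so
#'   onset-to-onset spacing is `call_duration_ms + intercall_interval_ms`;
#'   under `"onset_to_onset"` it is the onset-to-onset spacing itself.
#' @param pulses_per_call pulses per call group (>= 1 when `n_calls > 0`).
#' @param pulse_duration_ms duration of each raised-cosine pulse, ms.
#' @param carrier_freq_hz tone carrier frequency, Hz; must be below Nyquist.
#' @param snr_db signal-to-noise ratio, dB: RMS of the calls over RMS of the
#'   white Gaussian background.
#' @param sample_rate_hz sampling rate, Hz.
#' @param lead_silence_ms noise-only lead-in, ms.
#' @param jitter_frac relative jitter in \[0, 0.5\]: each realized duration and
#'   interval is the nominal value times `1 + U(-jitter_frac, jitter_frac)`.
#' @param interval_convention `"gap"` or `"onset_to_onset"` (see above).
#' @param seed RNG seed; identical spec and seed give identical samples.
#' @return an object of class `call_sim_spec`.
#' @seealso [generate_calls()]
#' @export
call_sim_spec <- function(n_calls = 7,
                          call_duration_ms = 298,
                          intercall_interval_ms = 790,
                          pulses_per_call = 48,
                          pulse_duration_ms = 4,
                          carrier_freq_hz = 2560,
                          snr_db = 20,
                          sample_rate_hz = 96000,
                          lead_silence_ms = 500,
                          jitter_frac = 0.05,
                          interval_convention = c("gap", "onset_to_onset"),
                          seed = 1L) {
  interval_convention <- match.arg(interval_convention)
  spec <- structure(list(
    n_calls = as.integer(n_calls),
    call_duration_ms = call_duration_ms,
    intercall_interval_ms = intercall_interval_ms,
    pulses_per_call = as.integer(pulses_per_call),
    pulse_duration_ms = pulse_duration_ms,
    carrier_freq_hz = carrier_freq_hz,
    snr_db = snr_db,
    sample_rate_hz = sample_rate_hz,
    lead_silence_ms = lead_silence_ms,
    jitter_frac = jitter_frac,
    interval_convention = interval_convention,
    seed = as.integer(seed)), class = "call_sim_spec")
  validate_call_sim_spec(spec)
  spec
}

validate_call_sim_spec <- function(spec) {
  if (spec$n_calls < 0) stopf("n_calls must be >= 0")
  if (spec$carrier_freq_hz >= spec$sample_rate_hz / 2)
    stopf("carrier (%g Hz) at or above Nyquist (%g Hz): aliasing",
          spec$carrier_freq_hz, spec$sample_rate_hz / 2)
  if (spec$n_calls > 0 && spec$pulses_per_call < 1)
    stopf("pulses_per_call must be >= 1 when n_calls > 0")
  if (spec$n_calls > 0 &&
      spec$pulse_duration_ms * spec$pulses_per_call > spec$call_duration_ms)
    stopf("pulse packing infeasible: %g ms x %d pulses > %g ms call",
          spec$pulse_duration_ms, spec$pulses_per_call, spec$call_duration_ms)
  if (spec$jitter_frac < 0 || spec$jitter_frac > 0.5)
    stopf("jitter_frac must lie in [0, 0.5]")
  invisible(spec)
}

#' Generate a synthetic advertisement-call clip with exact ground truth
#'
#' Synthesizes a train of call groups, each a sequence of raised-cosine
#' (Hann-enveloped) tone bursts at the carrier frequency with evenly spaced
#' pulse onsets, embedded in white Gaussian noise scaled to the requested
#' signal-to-noise ratio. All realized (post-jitter) times are snapped to the
#' sample grid and returned as ground truth, so detector output can be scored
#' exactly.
#'
#' @param spec a [call_sim_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{clip}{an [audio_clip()]; the last call is followed by one
#'       trailing interval of background noise.}
#'     \item{truth}{a `call_ground_truth` list: `call_onsets_s`,
#'       `call_offsets_s`, `pulse_times_s` (a list per call of pulse-peak
#'       times), and `carrier_freq_hz`.}
#'   }
#' @export
generate_calls <- function(spec) {
  validate_call_sim_spec(spec)
  sr <- spec$sample_rate_hz
  ms2smp <- function(ms) as.integer(round(ms / 1000 * sr))
  with_seed(spec$seed, {
    lead <- ms2smp(spec$lead_silence_ms)
    n <- spec$n_calls
    if (n == 0) {
      noise <- rnorm(max(lead, 1L), sd = 0.01)
      return(list(
        clip = audio_clip(noise, sr),
        truth = structure(list(call_onsets_s = numeric(0),
                               call_offsets_s = numeric(0),
                               pulse_times_s = list(),
                               carrier_freq_hz = spec$carrier_freq_hz),
                          class = "call_ground_truth")))
    }
    jit <- function(k) {
      if (spec$jitter_frac == 0) rep(1, k)
      else 1 + runif(k, -spec$jitter_frac, spec$jitter_frac)
    }
    dur_smp <- ms2smp(spec$call_duration_ms * jit(n))
    nominal_gap <- switch(spec$interval_convention,
      gap = spec$intercall_interval_ms,
      onset_to_onset = spec$intercall_interval_ms - spec$call_duration_ms)
    if (nominal_gap <= 0)
      stopf("onset_to_onset interval must exceed call duration")
    gap_smp <- ms2smp(nominal_gap * jit(n))
    onset_smp <- lead + c(0L, cumsum(dur_smp + gap_smp))[seq_len(n)]
    total <- lead + sum(dur_smp) + sum(gap_smp)

    pdur_smp <- ms2smp(spec$pulse_duration_ms)
    k <- spec$pulses_per_call
    pulse <- sin(pi * (seq_len(pdur_smp) - 0.5) / pdur_smp)^2 *
      sin(2 * pi * spec$carrier_freq_hz * (seq_len(pdur_smp) - 1) / sr)

    sig <- numeric(total)
    pulse_times <- vector("list", n)
    for (i in seq_len(n)) {
      if (k > 1) {
        step <- (dur_smp[i] - pdur_smp) / (k - 1)
        p_on <- onset_smp[i] + as.integer(round((seq_len(k) - 1) * step))
      } else {
        p_on <- onset_smp[i] + as.integer(round((dur_smp[i] - pdur_smp) / 2))
      }
      for (po in p_on) {
        idx <- po + seq_len(pdur_smp)
        sig[idx] <- sig[idx] + pulse
      }
      pulse_times[[i]] <- (p_on + pdur_smp / 2) / sr
    }

    in_call <- unlist(lapply(seq_len(n), function(i)
      onset_smp[i] + seq_len(dur_smp[i])))
    call_rms <- rms(sig[in_call])
    noise_sd <- call_rms / 10^(spec$snr_db / 20)
    x <- sig + rnorm(total, sd = noise_sd)
    peak <- max(abs(x))
    if (peak > 0) x <- x * (0.9 / max(peak, 1))

    list(
      clip = audio_clip(x, sr),
      truth = structure(list(
        call_onsets_s = onset_smp / sr,
        call_offsets_s = (onset_smp + dur_smp) / sr,
        pulse_times_s = pulse_times,
        carrier_freq_hz = spec$carrier_freq_hz), class = "call_ground_truth"))
  })
}

#' Write ground-truth call annotations as TSV interval files
#'
#' @param truth the `truth` element returned by [generate_calls()].
#' @param dir output directory; `calls.tsv` (columns `call_index, onset_s,
#'   offset_s, n_pulses`) and `pulses.tsv` (columns `call_index, pulse_index,
#'   time_s`) are written there.
#' @return `dir`, invisibly.
#' @export
write_call_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(truth$call_onsets_s)
  calls <- data.frame(
    call_index = seq_len(n),
    onset_s = truth$call_onsets_s,
    offset_s = truth$call_offsets_s,
    n_pulses = vapply(truth$pulse_times_s, length, integer(1)))
  utils::write.table(calls, file.path(dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pulses <- data.frame(
    call_index = rep(seq_len(n), times = calls$n_pulses),
    pulse_index = unlist(lapply(calls$n_pulses, seq_len)),
    time_s = unlist(truth$pulse_times_s))
  utils::write.table(pulses, file.path(dir, "pulses.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
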