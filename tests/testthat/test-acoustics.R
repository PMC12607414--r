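test_that("RMS envelope is constant on constant input and homogeneous", {
  clip <- audio_clip(rep(0.4, 9600), 96000)
  env <- amplitude_envelope(clip, 5)
  expect_true(all(abs(env$values - 0.4) < 1e-12))
  set.seed(2)
  x <- rnorm(9600)
  e1 <- amplitude_envelope(audio_clip(x, 96000), 5)
  e2 <- amplitude_envelope(audio_clip(2 * x, 96000), 5)
  expect_equal(e2$values, 2 * e1$values)
  # frame longer than clip degenerates to one whole-clip frame
  short <- amplitude_envelope(audio_clip(x[1:100], 96000), 50)
  expect_length(short$values, 1)
})

test_that("silence yields no call windows", {
  expect_equal(nrow(segment_calls(audio_clip(numeric(9600), 96000))), 0)
})

test_that("segmentation recovers call count and onsets within 5 ms", {
  g <- generate_calls(call_sim_spec(n_calls = 7, snr_db = 30, seed = 9))
  w <- segment_calls(g$clip)
  expect_equal(nrow(w), 7)
  expect_true(all(abs(w$onset_s - g$truth$call_onsets_s) <= 0.005))
  expect_true(all(abs(w$offset_s - g$truth$call_offsets_s) <= 0.010))
  # windows sorted and non-overlapping
  expect_true(all(diff(w$onset_s) > 0))
  expect_true(all(w$onset_s[-1] >= w$offset_s[-nrow(w)]))
})

test_that("calls separated by less than min_gap_ms merge into one window", {
  g <- generate_calls(call_sim_spec(n_calls = 2, intercall_interval_ms = 50,
                                    jitter_frac = 0, snr_db = 30, seed = 5))
  w <- segment_calls(g$clip)  # default min_gap_ms = 100
  expect_equal(nrow(w), 1)
})

test_that("raising the threshold never increases the window count", {
  g <- generate_calls(quick_call_spec())
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8), function(th)
    nrow(segment_calls(g$clip, segment_params(threshold_frac = th))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pulse counting is exact on clean pulse trains", {
  g <- generate_calls(quick_call_spec())
  w <- segment_calls(g$clip)
  for (i in seq_len(nrow(w))) {
    train <- count_pulses(g$clip, w[i, ])
    expect_length(train, 48)
    expect_true(all(diff(train) > 0))
  }
})

test_that("a single-pulse call yields one detection", {
  g <- generate_calls(call_sim_spec(n_calls = 1, pulses_per_call = 1,
                                    call_duration_ms = 100,
                                    pulse_duration_ms = 80,
                                    snr_db = 30, jitter_frac = 0, seed = 3))
  w <- segment_calls(g$clip)
  expect_equal(nrow(w), 1)
  expect_length(count_pulses(g$clip, w[1, ]), 1)
})

test_that("pulses spaced below the minimum spacing are undercounted", {
  # 120 pulses in 298 ms: spacing ~2.5 ms, below a 4 ms minimum
  g <- generate_calls(call_sim_spec(n_calls = 1, pulses_per_call = 120,
                                    pulse_duration_ms = 2, snr_db = 30,
                                    jitter_frac = 0, seed = 8))
  w <- segment_calls(g$clip)
  n <- length(count_pulses(g$clip, w[1, ],
                           pulse_params(min_pulse_spacing_ms = 4)))
  expect_lt(n, 120)
})

test_that("degenerate windows give an empty pulse train", {
  g <- generate_calls(quick_call_spec())
  tiny <- list(onset_s = 0.1, offset_s = 0.1001)
  expect_length(count_pulses(g$clip, tiny), 0)
})

test_that("dominant frequency lands on the FFT bin grid", {
  sr <- 96000
  t <- (0:(sr / 10)) / sr
  on_grid <- audio_clip(sin(2 * pi * 1875 * t), sr)  # bin 10 exactly
  f <- dominant_frequency(on_grid, list(onset_s = 0, offset_s = 0.1))
  expect_equal(as.numeric(f), 1.875)
  expect_equal(attr(f, "bin_width_hz"), 187.5)

  off_grid <- audio_clip(sin(2 * pi * 2500 * t), sr)
  f2 <- dominant_frequency(off_grid, list(onset_s = 0, offset_s = 0.1))
  expect_equal(as.numeric(f2), 2.4375)  # nearest bin center, 13 * 187.5 Hz

  # short window: zero-padded single segment, flagged low-resolution
  f3 <- dominant_frequency(on_grid, list(onset_s = 0, offset_s = 0.003))
  expect_true(attr(f3, "low_resolution"))
})

test_that("synthetic carrier is recovered within one bin width", {
  g <- generate_calls(quick_call_spec())
  w <- segment_calls(g$clip)
  for (i in seq_len(nrow(w))) {
    f <- dominant_frequency(g$clip, w[i, ])
    expect_lt(abs(as.numeric(f) * 1000 - 2560), 187.5)
  }
})

test_that("the pipeline is invariant to positive rescaling", {
  g <- generate_calls(quick_call_spec())
  r1 <- analyze_recording(g$clip, denoise_par = denoise_params(enabled = FALSE))
  scaled <- audio_clip(g$clip$samples * 3.7, g$clip$sample_rate_hz)
  r2 <- analyze_recording(scaled, denoise_par = denoise_params(enabled = FALSE))
  expect_equal(r1$windows, r2$windows)
  expect_equal(r1$pulse_counts, r2$pulse_counts)
  expect_equal(r1$dom_freq_khz, r2$dom_freq_khz)
})

test_that("disabled denoiser is the identity; silence cannot gain energy", {
  g <- generate_calls(quick_call_spec())
  expect_identical(denoise(g$clip, denoise_params(enabled = FALSE)), g$clip)
  set.seed(4)
  noise <- audio_clip(rnorm(48000, sd = 0.05), 96000)
  expect_lte(rms(denoise(noise)$samples), rms(noise$samples))
  zero <- audio_clip(numeric(4800), 96000)
  expect_warning(out <- denoise(zero), "all-zero")
  expect_identical(out$samples, zero$samples)
})

test_that("spectral gating improves the SNR of a noisy tone burst", {
  # the gate learns the noise spectrum from the lowest-energy frames, so the
  # clip must contain signal-free stretches, as a field recording does
  sr <- 96000
  set.seed(6)
  t <- (0:(sr / 2)) / sr
  tone <- sin(2 * pi * 2500 * t)
  tone[t < 0.1 | t > 0.4] <- 0
  noise <- rnorm(length(t), sd = rms(tone[tone != 0]) / 10^(10 / 20))
  clip <- audio_clip(tone + noise, sr)
  band_snr <- function(x) {
    p <- Mod(fft(x))^2
    f <- (seq_along(p) - 1) / length(p) * sr
    inband <- f > 2300 & f < 2700
    half <- f < sr / 2
    10 * log10(sum(p[inband & half]) / sum(p[!inband & half]))
  }
  expect_gt(band_snr(denoise(clip)$samples), band_snr(clip$samples))
})

test_that("summaries reproduce hand-computed statistics", {
  w <- data.frame(onset_s = c(0, 1, 2.1), offset_s = c(0.3, 1.25, 2.5))
  st <- summarize_calls(w, pulse_counts = c(40, 50, 45),
                        dom_freqs_khz = c(2.5, 2.6, 2.55))
  expect_equal(st$n_calls, 3)
  expect_equal(st$duration_ms$mean, mean(c(300, 250, 400)))
  expect_equal(st$duration_ms$sd, sd(c(300, 250, 400)))
  gaps <- c(700, 850)
  expect_equal(st$interval_ms$mean, mean(gaps))
  expect_equal(st$repetition_rate_cps, round_half_up(1000 / mean(gaps), 2))
  expect_equal(st$pulses_per_call$min, 40)
  expect_equal(st$dominant_freq_khz$max, 2.6)
  # onset-to-onset convention
  st2 <- summarize_calls(w, interval_convention = "onset_to_onset")
  expect_equal(st2$interval_ms$mean, mean(c(1000, 1100)))
})

test_that("a single call window leaves interval and rate undefined", {
  st <- summarize_calls(data.frame(onset_s = 0, offset_s = 0.3))
  expect_false(st$interval_defined)
  expect_true(is.na(st$repetition_rate_cps))
  expect_true(is.na(st$interval_ms$mean))
})

test_that("repetition rate is the reciprocal of the mean interval", {
  for (ms in c(100, 165.1, 737.7, 790, 834.4, 1500)) {
    expect_equal(repetition_rate(ms), round_half_up(1000 / ms, 2))
  }
  expect_true(is.na(repetition_rate(NA)))
})

test_that("call statistics serialize to TSV and JSON", {
  w <- data.frame(onset_s = c(0, 1), offset_s = c(0.3, 1.3))
  st <- summarize_calls(w, c(48, 48), c(2.56, 2.56))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_call_stats(st, tsv, "tsv")
  lines <- readLines(tsv)
  expect_true(any(grepl("^Call duration \\(ms\\)\t", lines)))
  expect_true(any(grepl("^Dominant frequency \\(kHz\\)\t", lines)))
  js <- withr::local_tempfile(fileext = ".json")
  write_call_stats(st, js, "json")
  expect_equal(jsonlite::read_json(js)$n_calls, 2)
})
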