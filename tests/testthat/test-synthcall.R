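test_that("jitter-free timing model places onsets at duration + interval", {
  s <- call_sim_spec(n_calls = 3, call_duration_ms = 298,
                     intercall_interval_ms = 790, jitter_frac = 0,
                     lead_silence_ms = 100, seed = 7)
  g <- generate_calls(s)
  expect_equal(g$truth$call_onsets_s, c(0.100, 1.188, 2.276))
  # onset-to-onset spacing exact to one sample
  expect_equal(diff(g$truth$call_onsets_s), rep(1.088, 2),
               tolerance = 1 / s$sample_rate_hz)
  expect_equal(g$truth$call_offsets_s - g$truth$call_onsets_s,
               rep(0.298, 3), tolerance = 1 / s$sample_rate_hz)
  # clip spans lead + n * (duration + interval)
  expect_equal(length(g$clip$samples) / s$sample_rate_hz, 0.1 + 3 * 1.088,
               tolerance = 1e-9)
  # every pulse lies inside its call window
  for (i in 1:3) {
    expect_true(all(g$truth$pulse_times_s[[i]] >= g$truth$call_onsets_s[i]))
    expect_true(all(g$truth$pulse_times_s[[i]] <= g$truth$call_offsets_s[i]))
    expect_length(g$truth$pulse_times_s[[i]], s$pulses_per_call)
  }
})

test_that("zero-call spec yields noise-only clip with empty ground truth", {
  g <- generate_calls(call_sim_spec(n_calls = 0, lead_silence_ms = 500,
                                    seed = 1))
  expect_equal(length(g$clip$samples), 48000)  # 0.5 s at 96 kHz
  expect_length(g$truth$call_onsets_s, 0)
  expect_length(g$truth$pulse_times_s, 0)
})

test_that("identical spec and seed give byte-identical output", {
  s <- quick_call_spec()
  g1 <- generate_calls(s)
  g2 <- generate_calls(s)
  expect_identical(g1$clip$samples, g2$clip$samples)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_calls(quick_call_spec(seed = 43))
  expect_false(identical(g1$clip$samples, g3$clip$samples))
})

test_that("realized SNR matches the requested SNR within 1 dB", {
  for (snr in c(10, 20)) {
    s <- call_sim_spec(n_calls = 7, snr_db = snr, jitter_frac = 0, seed = 11)
    g <- generate_calls(s)
    sr <- s$sample_rate_hz
    in_call <- rep(FALSE, length(g$clip$samples))
    for (i in seq_along(g$truth$call_onsets_s)) {
      idx <- seq(floor(g$truth$call_onsets_s[i] * sr) + 1,
                 floor(g$truth$call_offsets_s[i] * sr))
      in_call[idx] <- TRUE
    }
    p_call <- mean(g$clip$samples[in_call]^2)
    p_noise <- mean(g$clip$samples[!in_call]^2)
    measured <- 10 * log10((p_call - p_noise) / p_noise)
    expect_lt(abs(measured - snr), 1)
  }
})

test_that("infeasible specs are rejected", {
  expect_error(call_sim_spec(carrier_freq_hz = 48000), "Nyquist")
  expect_error(call_sim_spec(pulse_duration_ms = 10, pulses_per_call = 48,
                             call_duration_ms = 298), "packing")
  expect_error(call_sim_spec(jitter_frac = 0.6), "jitter")
  expect_error(call_sim_spec(n_calls = -1), "n_calls")
})

test_that("ground truth round-trips through the TSV interval files", {
  g <- generate_calls(quick_call_spec())
  dir <- withr::local_tempdir()
  write_call_truth(g$truth, dir)
  calls <- read.delim(file.path(dir, "calls.tsv"))
  expect_equal(calls$onset_s, g$truth$call_onsets_s)
  expect_equal(calls$n_pulses, rep(48, 3))
  pulses <- read.delim(file.path(dir, "pulses.tsv"))
  expect_equal(nrow(pulses), 3 * 48)
})

test_that("zero-divergence alignment is a set of identical sequences", {
  aln <- generate_alignment(seq_sim_spec(c(3, 3), 100, 0, 0, seed = 2))
  expect_length(unique(aln$sequences), 1)
})

test_that("two-group alignment realizes round(p * L) mutated sites exactly", {
  sp <- seq_sim_spec(c(1, 1), 632, target_between_p = 0.037,
                     target_within_p = 0, seed = 3)
  aln <- generate_alignment(sp)
  d <- p_distance(aln$sequences[1], aln$sequences[2])
  expect_equal(as.numeric(d) * 632, 23)            # round(0.037 * 632)
  expect_equal(attr(d, "comparable_sites"), 632)
  # deterministic
  aln2 <- generate_alignment(sp)
  expect_identical(aln$sequences, aln2$sequences)
})

test_that("between-group distances stay within 3/L of target across groups", {
  for (seed in 1:3) {
    sp <- seq_sim_spec(c(2, 2, 2), 500, target_between_p = 0.05,
                       target_within_p = 0, seed = seed)
    m <- p_distance_matrix(generate_alignment(sp))
    between <- m$d[m$group_of == "g1", m$group_of == "g2"]
    expect_true(all(abs(between - 0.05) <= 3 / 500))
  }
})

test_that("gap_frac controls the share of gapped columns", {
  aln <- generate_alignment(seq_sim_spec(c(2, 2), 500, 0.05, 0,
                                         gap_frac = 0.1, seed = 5))
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  gapped <- mean(apply(m, 2, function(col) any(col == "-")))
  expect_equal(gapped, 0.1, tolerance = 0.02)
  # p-distance still defined under pairwise deletion
  d <- p_distance(aln$sequences[1], aln$sequences[3])
  expect_true(is.finite(as.numeric(d)))
  expect_lt(attr(d, "comparable_sites"), 500)
})

test_that("saturating divergence targets are rejected", {
  expect_error(seq_sim_spec(c(1, 1), 100, target_between_p = 0.8),
               "saturat")
  expect_error(seq_sim_spec(c(1, 1), 100, target_between_p = 0.1,
                            target_within_p = 0.2), "within")
})
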