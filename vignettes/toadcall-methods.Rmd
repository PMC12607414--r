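---
title: "Methods behind toadcall: call analysis, divergence and diagnosability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind toadcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toadcall)
```

# The problem

Asian horned toads (*Boulenophrys*, Megophryidae) are a species-rich genus
in which many lineages are morphologically cryptic. Modern descriptions
therefore rest on three concordant evidence lines: a well-supported
mitochondrial clade with interspecific-level divergence, a diagnostic
combination of morphological characters, and quantitatively distinct
advertisement calls. `toadcall` packages the computational side of that
workflow — everything after fieldwork, sequencing and tree inference — as
testable, reusable functions, and pairs it with a synthetic-data module so
each stage can be validated against exact ground truth.

# Acoustic pipeline

## Signal model

The synthetic generator (`call_sim_spec()`, `generate_calls()`) treats an
advertisement call as a *pulse train*: a call group of duration $D$
containing $k$ pulses, each a tone burst at carrier frequency $f_c$ with a
raised-cosine (Hann) amplitude envelope of duration $d_p$, pulse onsets
evenly spaced so the last pulse ends at the call offset. Call groups repeat
with a silent gap $G$ (offset-to-next-onset), and the clip is embedded in
white Gaussian noise scaled so that the RMS ratio of call windows to
background equals the requested SNR. Realized durations and gaps are the
nominal values times $1 + U(-j, j)$ with relative jitter $j$
(`jitter_frac`, default 0.05 — of the order of the duration variability
seen in real call series), and all realized times are snapped to the
sample grid, so ground truth is exact to one sample.

Defaults mirror a *B. lushanensis*-type male: $D = 298$ ms, $G = 790$ ms,
$k = 48$, $f_c = 2.56$ kHz, 96 kHz sampling, SNR 20 dB. The pulse shape,
4 ms duration and white (rather than colored) background are modelling
choices, not inferences about the species: real pulse envelopes are not
described in the descriptive literature. Consequences: synthetic pulses
are band-limited and equal-amplitude, so pulse counting on synthetic data
is easier than on field recordings with amplitude-modulated pulses,
overlapping callers or colored stream noise. Passing the recovery tests
shows the measurement chain is self-consistent and unbiased at realistic
SNR; it does not certify performance on degraded field tape.

## Measurement chain

1. **Denoising** (`denoise()`): stationary spectral gating. The STFT
   (Hann, 512 samples, 50% hop) magnitude of the lowest-energy
   `noise_quantile` (default 10%) of frames estimates the per-bin noise
   spectrum; cells below mean + 1.5 sd are attenuated by `reduction_db`
   (default 20 dB), the mask is smoothed along time, and the clip is
   rebuilt by Hann overlap-add. The gate needs signal-free stretches to
   learn the noise floor — true for inter-call silences, not for a
   continuous tone. Thresholds derive from the clip's own spectra, so the
   operation commutes with rescaling.
2. **Segmentation** (`segment_calls()`): the RMS envelope (5 ms frame,
   half-frame hop) is thresholded at `threshold_frac` (default 0.1) of its
   global peak; supra-threshold runs closer than `min_gap_ms` (100 ms) are
   merged — this is what absorbs the few-ms dips between pulses inside one
   call group — and merged runs shorter than `min_call_ms` (50 ms) are
   dropped. The defaults segment ~300 ms calls separated by ~800 ms gaps
   unambiguously at SNR ≥ 10 dB after denoising; onsets land within a few
   ms of truth (the envelope hop quantizes timing at 2.5 ms). Note the
   threshold is *relative*: a clip containing only noise has its envelope
   peak in the noise and will be reported as one long "call"; silence
   yields none.
3. **Pulse counting** (`count_pulses()`): peaks of a fine 1 ms-frame
   envelope of the window, kept when topographic prominence reaches
   `min_prominence_frac` (0.25) of the window's envelope peak and spacing
   exceeds `min_pulse_spacing_ms` (2 ms). Pulses packed tighter than the
   minimum spacing merge into single detections — an undercount by design.
   Detection operates on the amplitude envelope (pulses are amplitude
   events and the canonical peak-finder is one-dimensional); an optional
   `bandpass_hz` restricts the envelope to the carrier band first.
4. **Dominant frequency** (`dominant_frequency()`): average of 512-point
   Hann-windowed magnitude-squared spectra over 50%-overlapping segments
   of the window (a Welch periodogram — more stable than one long FFT and
   consistent with a fixed 512-point window), reported as the bin-center
   frequency of the maximal bin. Resolution is $f_s/512$ = 187.5 Hz at
   96 kHz; a 2560 Hz carrier is therefore reported as 2.625 kHz, the
   nearest bin center. Windows shorter than 512 samples are zero-padded
   and flagged low-resolution.
5. **Summary** (`summarize_calls()`): sample (n−1) standard deviations;
   display rounding half-up at 1 decimal for ms, 2 for kHz and for the
   repetition rate, matching how such tables are printed.

## The inter-call-interval convention

Published call tables are ambiguous about whether "inter-call interval"
means the silent gap (offset → next onset) or the onset-to-onset period:
printed repetition rates in the source comparison table equal the
reciprocal of the printed mean interval (1/790.0 ms = 1.27 calls/s,
1/737.7 = 1.36, 1/834.4 = 1.20, 1/165.1 = 6.06), which is arithmetically
the onset-to-onset reading even though "interval" reads like a gap. The
package does not resolve this: both the generator and `summarize_calls()`
expose `interval_convention = c("gap", "onset_to_onset")` with `gap` as
the default, and the repetition rate is always the reciprocal of the mean
interval under the chosen convention (exact before display rounding).

## Recovery guarantees tested

Over 20 seeded synthetic clips at the defaults (seven 298 ms calls, 48
pulses, 2.56 kHz, 20 dB SNR — about 8 s of 96 kHz audio per clip, sized so
the whole acoustic suite runs in well under a minute), the test suite
requires: exact call count in ≥ 95% of clips, exact pulse count in ≥ 90%
of calls, dominant frequency within one 187.5 Hz bin always, and mean
duration within ±10% (segmentation at a 10% threshold slightly overhangs
the Hann pulse ramps, a ~2% positive bias).

# Molecular divergence

`p_distance()` computes the uncorrected proportion of differing sites.
Sites where either sequence carries a gap, `N` or an IUPAC ambiguity code
are excluded per pair (*pairwise deletion*) — the convention of the
standard distance tools in this literature; *complete deletion* is
available via `p_distance_matrix(..., deletion = "complete")`. Ambiguity
codes are excluded outright rather than fractionally matched: the simplest
defensible reading of an "uncorrected" distance. Group ranges
(`group_range()`) report min–max percent over all cross pairs at 1
decimal, the form used for statements like "3.4–3.7%, consistent with
interspecific divergence".

The generator (`generate_alignment()`) builds two-group alignments by
mutating a reference at exactly `round(p × L)` ungapped sites, so a 632 bp
alignment targeted at 3.7% realizes 23/632 ≈ 3.6% exactly; with more than
two groups each consensus gets its own disjoint site set of half that
size, keeping pairwise divergences within one site of target. Within-group
variation and gap columns are layered on top without touching the mutated
sites. The correctness oracle is dual: a deliberately naive per-site loop
(1000 random 30 bp pairs with gaps and Ns) and an independent
cross-check against `ape::dist.dna(model = "raw", pairwise.deletion =
TRUE)`. Genus-wide divergence ranges require the full public sequence
sampling and are out of scope offline.

# Morphometrics and diagnosability

The 13 linear measurements (SVL, HL, HW, SL, IND, IOD, ED, TD, TED, HNL,
FAL, TL, FTL; mm at 0.1 mm precision) are read from either table
orientation. Ratios round half-up at 2 decimals — every published holotype
ratio is consistent with plain rounding of the measurement quotients, and
`round_half_up()` avoids R's banker's rounding at ties. Sex-grouped size
summaries report n/min/max at 1 decimal; sex is taken from the table, not
inferred. Where the source's own numbers disagree (the abstract's female
maximum 50.3 mm vs the diagnosis's 50.2 mm), the package reports what the
measurement table implies (50.3) and leaves adjudication to the reader.

The trait matrix codes six categorical characters with states `T`/`N`/`F`
(meaning differs per character), `X/Y` polymorphism and `/` missing.
Diagnosability is set disjointness: a character distinguishes two species
only if their state sets share no atom, so overlapping polymorphism never
diagnoses, and missing data never diagnoses. SVL is compared within sex
only and only strict range disjointness counts — size ranges of close
relatives overlap, and overlap must not be called diagnostic.
`partition_by_state()` reproduces the structure of a comparison paragraph;
`audit_consistency()` checks every published list placement against the
matrix and *reports* incompatibilities as data rather than failing: with
the packaged transcription, the heel-posture column disagrees
systematically with the heel groupings of the comparison lists (15
placements, e.g. *B. fanjingmontis* listed under "heels overlapping" but
coded "just meeting"), while the 49-species vomerine-teeth list agrees
exactly. One spelling divergence (*B. huangniushiensis* vs *B.
huangnniushienensis*) is bridged by an explicit, flagged alias table.

# Pipeline and reproducibility

`run_integrative()` runs any subset of the four sections from one config
(list or YAML), records seeds, a config hash and input-file digests, and
writes a JSON + text report with no timestamps, so identical configs give
byte-identical bodies. Sections fail independently; an audit mismatch is a
finding, not an error. All randomness flows through per-spec seeds with
the caller's RNG state restored, so generation is reproducible and
side-effect-free.

# Known limitations

- Synthetic calls are stationary, single-note, equal-amplitude pulse
  trains in white noise: no frequency modulation, chorus overlap,
  reverberation or colored noise. Detector defaults are tuned to this
  call scale (~100–1000 ms groups); very different taxa need different
  `segment_params()`.
- The relative segmentation threshold presumes the recording contains
  calls; signal-free recordings should be screened first.
- p-distances carry no substitution-model correction by design; they are
  comparative evidence, not a species-delimitation criterion on their own.
- The character matrix is only as good as its transcription; the audit
  quantifies, but cannot resolve, source-internal inconsistencies.
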