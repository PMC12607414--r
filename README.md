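# toadcall

Integrative species-delimitation tools for Asian horned toads
(*Boulenophrys*, Megophryidae) — and, more generally, for any anuran
taxonomy workflow that combines three evidence lines:

- **Bioacoustics**: advertisement-call measurement from WAV recordings —
  spectral-gating denoise, amplitude-threshold segmentation of call
  groups, envelope-based pulse counting, and dominant-frequency
  estimation by a 512-point Hann-windowed averaged periodogram
  (resolution $f_s/512$; 187.5 Hz at 96 kHz). Summaries report call
  duration, inter-call interval, repetition rate
  $r = 1/\overline{\mathrm{interval}}$, pulses/call and dominant
  frequency as `mean ± sd (min–max)`.
- **Molecular divergence**: uncorrected p-distances
  $p = \text{mismatches}/\text{comparable sites}$ over aligned
  mitochondrial fragments, with pairwise deletion of gaps/ambiguities and
  group-wise min–max percent ranges.
- **Morphology**: the 13 standard linear measurements (SVL, HL, HW, …),
  diagnostic ratios (HW/HL, ED/HL, TD/ED, FAL/SVL, HNL/SVL, TL/SVL,
  FTL/SVL), sex-grouped size summaries, and a polymorphism-aware
  diagnosability engine over categorical character matrices: a character
  separates two species only when their state sets are disjoint, and SVL
  only when same-sex ranges are disjoint.

A first-class synthetic-data module generates pulse-train call audio with
exact sample-accurate ground truth and aligned sequence sets with exact
target divergences, so every downstream stage is testable without
recordings or sequence downloads. Packaged fixtures transcribe the type
series, trait matrix and comparison lists of the Lushan horned toad
(*Boulenophrys lushanensis*).

## Worked example

Simulate a holotype-like recording (seven 298 ms call groups, 790 ms
gaps, 48 pulses/call, 2.56 kHz carrier, 20 dB SNR at 96 kHz) and measure
it back:

```r
library(toadcall)
g <- generate_calls(call_sim_spec(seed = 4))
res <- analyze_recording(g$clip)
res$stats
#> Number of call groups measured  7
#> Call duration (ms)      302.1 ± 8.5 (290.0–315.0)
#> Intercall interval (ms) 784.2 ± 31.9 (750.0–817.5)
#> Call repetition rate (calls/s)  1.28
#> Pulses/call     48–48
#> Dominant frequency (kHz)        2.63 ± 0.00 (2.63–2.63)
```

All 7 call groups and all 48 pulses per call are recovered; 2.63 kHz is
the FFT bin center nearest the 2.56 kHz carrier (one 187.5 Hz bin).

Morphometrics from the packaged type-series table — the holotype's
diagnostic ratios and the sex-grouped size ranges:

```r
tab <- read_measurements(toadcall_example("table1_lushanensis.tsv"))
holotype_report(tab[tab$specimen_id == "JXNU 21042803", ])
#>   HW/HL   ED/HL   TD/ED FAL/SVL HNL/SVL  TL/SVL FTL/SVL
#>    1.04    0.36    0.41    0.23    0.23    0.42    0.41
group_summary(tab, "male", "SVL")    # n = 5, 40.5–44.7 mm
group_summary(tab, "female", "SVL")  # n = 4, 46.0–50.3 mm
```

A two-group 632 bp alignment built for 3.7% divergence realizes exactly
`round(0.037 * 632) = 23` substituted sites:

```r
aln <- generate_alignment(seq_sim_spec(c(3, 3), 632, target_between_p = 0.037))
group_range(p_distance_matrix(aln), "g1", "g2")
#> min max
#> 3.6 3.6
```

Diagnosability against the closest relative, and the consistency audit of
the published comparison lists against the trait matrix:

```r
claims <- read_claims(toadcall_example("claims_lushanensis.json"))
m <- load_trait_matrix(toadcall_example("table2_boulenophrys.tsv"),
                       aliases = claims$aliases)
distinguishing_characters(m, "B. lushanensis", "B. jinggangensis")
#>               character focal_state other_state
#> 1           svl_male_mm   40.5–44.7   35.1–36.7
#> 2         svl_female_mm   46.0–50.2   38.4–41.6
#> 3 eyelid_tubercle_large           F           T
#> 4                 heels           F           T
nrow(audit_consistency(m, claims))   # 15 heel-placement findings
```

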