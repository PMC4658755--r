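# dfprint: differential DNase-seq footprinting

DNase-seq maps accessible chromatin: within a DNase hypersensitive site
(DHS), short windows protected from DNaseI cleavage by a bound transcription
factor leave "footprints" at sub-30 bp resolution. In double-hit DNase-seq
libraries a bound site has a characteristic strand signature — sequenced 5′
ends (cuts) on the positive strand pile up immediately *upstream* of the
site and negative-strand cuts immediately *downstream*. Standard
footprinters analyse one dataset at a time; `dfprint` asks the comparative
question: **at which footprints does TF occupancy differ between two
DNase-seq datasets?**

## The statistics

**Footprint score.** For a candidate window `FP` of width `w` with shoulders
`U` (upstream) and `D` (downstream) of width `s`, let `X_f` be the
positive-strand cuts in `U` and `N_f` those in `U ∪ FP` (mirrored on the
negative strand downstream: `X_r`, `N_r`). With `q = s/(s+w)`,

    S = −[ log₁₀ P(Bin(N_f, q) ≥ X_f) + log₁₀ P(Bin(N_r, q) ≥ X_r) ]

computed with exact binomial tails. `S` is large when cuts concentrate in
the shoulders with the protocol's strand polarity.

**Differential (bootstrap percentile) score.** For a footprint locus
detected in dataset A, pool B's cuts with A's over the scored window and
recompute `S` (`S_real`). Then shuffle B's per-base counts within the window
— independently on each strand — 1000 times, pooling and re-scoring each
time (`S_k`). The differential footprint (DFP) score is the percentile

    DFP = 100 · #{k : S_k ≥ S_real} / 1000 .

If B genuinely contributes footprint structure, the real pooled arrangement
beats the shuffles and the score is *low* (non-differential); if B's cuts
carry no arrangement, the score is *high* (over-footprinted in A). Reversing
the roles of A and B gives the sites over-footprinted in B. The default call
threshold is 10. Pooling at individual loci makes the test robust to
sequencing-depth differences.

Companion computations: a cuts-per-million ΔDHS score (the read-count
baseline), hexamer cleavage-bias corrected average profiles, shared-DHS
overlap summaries, a relative motif-frequency matrix with
Euclidean/complete-linkage clustering, a minimal PWM scanner, a
Mann–Whitney expression-shift test, and a synthetic-data generator with
planted ground truth.

## Worked example

```r
library(dfprint)

# simulate a two-condition experiment: one shared, one A-only, one B-only
# footprint, 100 signal cuts each, written to SAM and read back
plants <- function(cs) data.frame(center = cs, width = 15L, occupancy = 1)
sim <- simulate_pair(4000L, shared = plants(800L), a_only = plants(2000L),
                     b_only = plants(3200L), seed = 7)
sam_a <- tempfile(fileext = ".sam"); sam_b <- tempfile(fileext = ".sam")
emit_sam(sim$profile_a, sam_a); emit_sam(sim$profile_b, sam_b)

dhs <- intervals("chrS", c(700L, 1900L, 3100L), c(900L, 2100L, 3300L))
calls <- differential_footprints(read_source(sam_a), read_source(sam_b),
                                 dhs, dhs, cfg = shuffle_config(1000, seed = 7))
calls
#> <dfp_call_set> threshold 10: 1 over-footprinted in A, 1 in B (2/2 loci scored)
calls$over_in_A
#>   chrom start  end best_size wellington_score dfp_score comparator_cuts low_coverage
#> 2  chrS  1993 2008        15         16.72941      39.5              41        FALSE
```

The caller finds the planted A-only footprint (truth window 1993–2008),
scores it `S = 16.7` in A, and its DFP score of 39.5 — 395 of 1000 shuffled
comparators matched or beat the real pooled arrangement — is above the
threshold: B's cuts do not support the footprint. The shared plant is scored
but not called (its comparator does contribute structure), and the reversed
run calls the B-only plant.

The bundled overlap-count table for seven primary cell types reproduces the
shared-DHS headline numbers:

```r
pct <- shared_dhs_percentages()
round(mean(pct$pct_shared), 1)  #> 43.9
max(pct$pct_shared)             #> 98.5
```

A command-line wrapper ships at `inst/scripts/dfprint`
(subcommands `cuts`, `wellington`, `bootstrap`, `ddhs`, `simulate`; see
`?dfprint_cli`).

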