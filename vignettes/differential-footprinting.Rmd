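---
title: "Differential footprinting: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential footprinting: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfprint)
```

## The problem

Digital genomic footprinting reads transcription factor (TF) occupancy off
DNase-seq data: inside a hypersensitive site, a bound protein shields a
short window (< 30 bp) from DNaseI, and in double-hit libraries the
size-selection step leaves a strand-polarised signature — positive-strand
5′ cut pile-ups immediately upstream of the protected window,
negative-strand pile-ups immediately downstream. Single-dataset
footprinters report *where* binding occurs but cannot say *where occupancy
differs* between two cell types or conditions. `dfprint` implements a
pairwise differential test at footprint resolution, together with the
companion computations needed to interpret its output (read-count ΔDHS
baseline, bias-corrected cleavage profiles, motif-frequency clustering,
shared-DHS summaries).

## Footprint model

All data reduce to one currency: the `cut_profile`, per-base counts of 5′
read ends on each strand over an interval. A positive-strand read's cut is
its leftmost aligned base; a negative-strand read's is its rightmost. The
negative-strand convention deliberately applies no ±1 bp offset — the
literature is not unanimous here, so the choice is fixed, documented, and
covered by a SAM fixture so any downstream shift would surface immediately.
Duplicate reads are retained (footprint signal is concentrated by nature;
deduplication would truncate it); unmapped, secondary and supplementary
alignments are excluded.

The footprint score at a window of width $w$ with shoulders of width $s$
treats each strand's cuts in (shoulder ∪ window) as Bernoulli trials that
land in the shoulder with probability $q = s/(s+w)$ under no protection:

$$S = -\left[\log_{10} P\!\left(\mathrm{Bin}(N_f, q) \ge X_f\right)
      + \log_{10} P\!\left(\mathrm{Bin}(N_r, q) \ge X_r\right)\right]$$

with $X_f$ the upstream-shoulder positive-strand cuts (and the mirrored
quantities downstream on the negative strand). Tails are exact (`pbinom`
on the log scale; no normal approximation), so scores are reproducible to
machine precision and valid at any depth. A scan maximises $S$ over
candidate widths at every center and greedily selects a non-overlapping
set in decreasing score order (ties: leftmost first, then smallest width).

## The bootstrap percentile test

At each footprint locus detected in the primary dataset A, the comparator
B's window counts are pooled with A's and $S$ recomputed. To separate "B
adds reads" from "B adds footprint structure", B's per-base counts within
the scored window (footprint plus both shoulders) are randomly permuted,
independently per strand, 1000 times; each shuffle is pooled and re-scored.
The DFP score is the percentile of shuffles scoring at least the real
pooled score. Orientation matters and the source text states only its
semantics ("low = non-differential"): counting shuffles **≥** real is the
orientation consistent with that reading, and ties count toward ≥, which is
conservative toward calling degenerate loci differential. Because absence
of reads is not evidence of absent binding, loci whose comparator window
holds fewer than 10 cuts are flagged `low_coverage` rather than silently
trusted.

Further choices, each of which the source leaves open:

* **Shuffle window = scored window.** Permuting counts outside the region
  the statistic reads cannot change it, so nothing larger is shuffled.
* **Fixed width at re-scoring.** The locus is re-scored at its detected
  width only; flexible width/position search was reported to add cost
  without benefit.
* **Determinism.** Each locus derives an RNG substream from
  `(seed, locus index)`, so serial and per-locus evaluations agree
  bit-for-bit and whole call sets are reproducible from one seed.
* **Exact oracle.** `exhaustive_bootstrap_score()` replaces sampling by
  complete enumeration over permutations (reduced to segment-sum
  distributions, combined across the two independent strands) and anchors
  the Monte-Carlo implementation in tests: at 1000 shuffles the two agree
  within 3 percentile points on enumerable loci.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `footprint_sizes` | 11–25 bp, odd | candidate protected widths; sub-30 bp TF scale |
| `shoulder_size` | 35 bp | flanking high-cleavage reference window |
| `score_threshold` | 10 | minimum $S$ (≈ combined p ≤ 10⁻¹⁰) to report a footprint |
| `n_shuffles` | 1000 | DFP scores granular to 0.1 |
| DFP `threshold` | 10 | percentile above which a locus is called differential |
| `min_comparator_cuts` | 10 | below this the call is flagged `low_coverage` |

All are configurable; the defaults are the working values used throughout
the tests.

## ΔDHS baseline

The read-count alternative scores each DHS by the library-normalised cut
difference $10^6 (c_A/T_A - c_B/T_B)$. The exact normalisation used by the
originating method is not fully specified in the source material, so the
simplest scheme consistent with "comparisons of total read numbers" —
counts per million — is the default, with a `normalize` hook for
quantile-style replacements. Counts are 5′ cuts (both strands) rather than
overlapping reads, consistent with the package's data model; ordering
semantics, not bit-compatibility, is the contract. Promoter-proximal
filtering keeps sites whose midpoint lies within 2 kb of *exactly one*
TSS, so every retained site has an unambiguous target gene.

## Hexamer bias correction

DNaseI's sequence preference is modelled by a weight per 6-mer. A cut at
position $i$ on the plus strand takes its context from bases $i-3..i+2$;
minus-strand lookups use the reverse complement of the mirrored window
($i-2..i+3$). The specific offsets are a convention the source does not
print; they are fixed here and exercised by hand-computed tests. Expected
counts distribute the observed total over positions proportionally to the
weights ($\sum_i e_i = $ total, conservation tested); correction is
observed/expected; positions whose hexamer leaves the ACGT alphabet or the
table propagate as `NA`, never as silent zeros. Average profiles correct
each locus *before* averaging (the alternative — correcting the averaged
counts — is not equivalent; per-locus totals differ). SNVs from a VCF can
be substituted into the reference before lookup. No bias table ships; a
flat model is provided for nulls, and tests build a synthetic truth model.

## Motif-frequency matrix

With $n_{ij}$ the number of differential footprints in set $j$ occupied
(≥ 1 bp overlap, strand-collapsed, multiple hits count once) by motif $i$,
and $M_j$ the set size, the relative frequency is
$(n_{ij}/M_j)\,(C\sum_j M_j/\sum_j n_{ij})$ with scaling constant $C = 1$
by default ($C$ is stated but left unvalued at the source; it is exposed).
Every row then satisfies $\sum_j v_{ij} M_j = C \sum_j M_j$ exactly — a
test invariant. Rows and columns are clustered with Euclidean distance and
complete linkage via `stats::hclust`; tie-breaking among equal merge
heights follows `hclust`'s deterministic input-order rule rather than a
bespoke smallest-index rule — given a fixed input order the leaf order is
reproducible, which is the property downstream consumers need.

## What the generator emulates — and what it does not

`simulate_profile()` draws independent per-base Poisson background on each
strand (default 0.25 cuts/bp/strand, a deeply sequenced DHS), and for each
planted footprint realised with its occupancy probability adds
Poisson(`depth` = 100) signal cuts: a fraction $\frac{5}{6}$ (imbalance 5)
of each shoulder's share goes to the signature strand (positive upstream,
negative downstream) over 20 bp pile-ups, while interior background is
thinned to 10 %. `emit_sam()` writes one read per cut so that
`extract_cuts()` inverts it exactly — the module's round-trip contract and
the anchor for all BAM-path tests.

Deliberate simplifications: background counts are independent across
positions (no read-length autocorrelation, no local chromatin structure),
the genome is uniform random, fragment size selection itself is not
modelled (only its observable strand signature), and depths are uniform
across loci. A green recovery test therefore establishes that the
algorithm detects the stated signature at the stated depth — not that it
is robust to replicate variability, mappability artefacts, or real bias
landscapes (the bias module is tested against a synthetic truth model for
the same reason).

One consequence worth stating: at a locus present only in A, the
comparator's window is pure exchangeable background, so its DFP score is
approximately uniform on [0, 100] (inflated upward by ties). At threshold
10 the expected recovery of condition-specific plants is therefore ~90 %,
and the recovery test sits at that boundary by construction — it measures
the stated world, not a tuned one.

## Numerical and degenerate-input policy

* Binomial tails on the log scale; $X = 0$ gives $p = 1$ exactly; an
  all-zero window scores $S = 0$.
* An empty comparator ties every shuffle (score 100) and is flagged
  `low_coverage` — reported, not suppressed, and never a division by zero.
* Shared-DHS percentages with a zero denominator are `NA`.
* Greedy footprint selection and top/bottom ΔDHS selection break ties by
  coordinate for cross-platform determinism.
* Intervals are 0-based half-open everywhere internally (BED convention);
  BED round trips bit-exactly and malformed lines fail with their line
  number.

## Known limitations

Strictly pairwise (no multi-way designs); no DHS calling, alignment, or
FPKM estimation (those are inputs); no genome-wide FDR for single-dataset
footprints (the bootstrap percentile replaces it in the differential
setting); the PWM scanner is plumbing for tests and small jobs, not a
replacement for a dedicated motif suite.
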