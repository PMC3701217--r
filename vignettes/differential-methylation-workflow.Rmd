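---
title: "Differential methylation and small-RNA integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation and small-RNA integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

## The problem

MeDIP-chip experiments immunoprecipitate methylated DNA and hybridise it,
against total input, to a promoter tiling array. Each probe reports a
log2(MeDIP/Input) enrichment; differential methylation between a treated
and a control group appears as a coherent shift of that enrichment over a
run of neighbouring probes. `medipdmr` implements the full analysis path
from probe-level log ratios to filtered differential enrichment peaks
(DEPs), and integrates the result with small-RNA and gene expression:
inverse miRNA–target pairing, promoter/expression concordance,
imprinted-region mapping, and ΔΔCt qPCR quantitation. A synthetic-data
generator with planted truth makes every stage testable end to end
without array downloads.

## The M′ statistic and peak model

For probe $i$, with $E$ the treated (exposed) and $C$ the control group,

$$M'_i = \overline{\log_2(\mathrm{MeDIP}_E/\mathrm{Input}_E)}_i -
         \overline{\log_2(\mathrm{MeDIP}_C/\mathrm{Input}_C)}_i,$$

the difference of within-group replicate means. `compute_mprime()` also
carries each group's per-probe mean and coefficient of variability
(CV = sd/|mean| across replicates). A group mean within 1e−8 of zero
gives CV = ∞, which can never satisfy the CV filter; the ratio is simply
undefined there and treating it as a failure is the conservative choice.

Peaks are maximal runs of individually qualifying probes. A probe
qualifies when its sliding-window p-value satisfies
$-\log_{10} p \ge 2$; runs split where consecutive qualifying probes are
more than 500 bp apart (midpoint to midpoint) and must hold at least 2
probes. The PeakScore is $-\log_{10}$ of the *mean* member p-value, so
PeakScore ≥ 2 is exactly "average p ≤ 0.01". These four parameters
(750 bp window, 2 probes, cutoff 2, 500 bp gap) are the published
vendor settings for this array class and are the `peak_params()`
defaults.

### Per-probe p-values

The vendor's probe-scoring scheme is proprietary; we use a one-sided
Wilcoxon rank-sum test of the probes inside the centred 750 bp window
against all remaining probes of the track. This is nonparametric,
matches the "−log10 p per probe" interface that PeakScore requires, and
is exactly reproducible. Ties take midranks; the p-value uses the
tie-corrected, continuity-corrected normal approximation (comparison
sets here always hold dozens of probes, where the approximation is
excellent — the test suite checks it against `stats::wilcox.test` to
1e−10) and is never exactly zero. Windows are centred per probe and
never cross chromosomes; a probe with an empty comparison set gets
p = 1.

One consequence worth knowing: because the score of a probe summarises
its *window*, probes up to half a window outside a true signal block
also qualify, so peak boundaries overshoot narrow signals by up to
~375 bp per side. For a 750 bp planted region this can halve the
fraction of genuine signal probes inside the called peak and dilute the
peak-median filter statistics below; it is the dominant cause of the few
missed planted DMRs at realistic noise.

## DEP calling and the two-stage filter

`call_deps()` scans M′ twice — once as-is (methylation gains) and once
negated (losses) — so directionality is preserved rather than collapsed
into |M′|. Every peak is then flagged by two criteria:

* **(i) median ratio**: at least one group's within-peak median
  log2(MeDIP/Input) is ≥ 0.3, *and* the peak-median M′ agrees in sign
  with the called direction. The "at least one group" clause is read
  literally: a loss peak is admissible when the control group alone is
  enriched.
* **(ii) replicate consistency**: at least half the member probes have
  CV ≤ 0.8 in *both* groups.

Rejected peaks stay in the output with `accepted = FALSE` and a reason
code (`median_ratio`, `cv`, or both), so filtering is auditable.
`top_peak_filter()` afterwards shortlists peaks lying in both the top
20% by PeakScore and the top 20% by |PeakDMValue|, breaking rank ties by
genomic position for determinism. PeakDMValue has no published
definition; we define it as the median member M′ (robust, single-number,
sign-preserving) and document rather than assert equivalence.

The ordering matters: criteria (i)/(ii) define the accepted DEP set, and
the top-20% step is a *shortlisting* of the strongest peaks on top of
it. Planted-DMR recovery is therefore measured on accepted DEPs — a
selection step that by construction keeps one peak in five cannot be
part of a recall definition.

## Normalisation and smoothing

`quantile_normalize()` maps every sample column onto the per-rank mean
distribution (midranks for ties) and then median-centres each column —
the standard two-colour treatment, applied before any cross-group
comparison. It is idempotent. `linear_smooth()` is a fixed-width running
mean (default 300 bp, per sample, never crossing chromosomes); the
smoothing step in this array literature is named only by package
("linear smoothing"), so the kernel is an explicit, configurable choice
here rather than a claimed reproduction.

## Clustering

`hcluster()` is UPGMA (average linkage) on Euclidean distances via
`stats::hclust`; the test suite verifies merge heights against an
exhaustive average-pairwise-distance oracle on small instances.
`cluster_purity()` cuts the tree into two clusters and reports the
best-matching accuracy against the treated/control labels — the
operational form of "samples group by exposure". `peak_score_matrix()`
recomputes, per sample, the PeakScore of every accepted DEP region and
is the matrix fed to clustering and to `plot_score_heatmap()`.

## Expression and qPCR

`differential_expression()` runs a per-feature one-way ANOVA (for two
groups, identical to the equal-variance t-test, which the suite checks
numerically) and reports the signed linear fold change
($2^{\Delta\log_2}$, with ratios below 1 reported as negative
reciprocals, e.g. −1.24). The default stringency — |fold change| ≥ 1.2
and p ≤ 0.05, no multiplicity correction — mirrors the per-feature
filtering convention of this array literature; Benjamini–Hochberg is
available (`adjust = "BH"`) and off by default.

`ddct_fold_change()` averages technical replicates per sample and assay,
forms per-sample ΔCt (target − endogenous control), ΔΔCt as the
difference of group means, fold change $2^{-\Delta\Delta Ct}$, and an
unpaired equal-variance t-test on per-sample ΔCt. Fold change is exactly
invariant to any per-sample Ct offset because ΔCt cancels it.

## Integration

`inverse_pair_filter()` retains predicted miRNA→gene pairs where both
members pass their expression filters, fold changes are opposite in
sign, confidence is at least `moderate` on the ordinal scale
predicted < low < moderate < high, and the tissue label matches
(`brain` by default; the tissue filter is a label comparison because
the upstream knowledge base is an input here, not a dependency).
`promoter_concordance()` and `map_to_regions()` are half-open interval
overlaps (≥ 1 bp; abutting intervals do not touch) computed with
GenomicRanges. `region_enrichment()` is a permutation test drawing
same-size feature sets from the universe, with the add-one estimator
$(1+b)/(n_{perm}+1)$, so p is never zero and is super-uniform under the
null; its seed is a required argument.

## The synthetic generator

`simulate_tiling()` emulates the array design: each promoter is tiled
from 8.2 kb upstream to 3 kb downstream of its TSS (50 bp probes every
100 bp), on its own synthetic chromosome so windows cannot bleed across
promoters and planted truth stays unambiguous. Three biological
replicates per group match the methylation design; expression matrices
default to three arrays per group (the voluntary-drinking design; the
injection models used two). A planted DMR is one 750 bp interval per
selected promoter (default 20% of promoters) with:

* a baseline enrichment of 0.5 log2 units in *both* groups — planted
  DMRs sit on methylated sequence, so a methylation *loss* still leaves
  the control group enriched, as filter criterion (i) presumes;
* a signed treated-group shift of 1.0 log2 units (sign random);
* iid Gaussian replicate noise, default sd 0.3 log2 units.

Noise is deliberately iid on the log2 scale: no probe-affinity
structure, no dye bias, no spatial artefacts. Passing tests therefore
demonstrate the pipeline's statistical behaviour under its own model
assumptions, not robustness to platform artefacts of real arrays.

`simulate_expression()` plants signed log2 fold changes (default 0.5,
i.e. ~1.41-fold, comfortably above the 1.2-fold filter at noise sd
0.15), forces opposite signs on the planted inverse pairs, and seeds the
target table with decoys — same-direction, null, low-confidence and
non-brain pairs — that the downstream filter must reject. Genes whose
promoters carry a planted DMR are preferred when choosing planted DE
genes, so the methylation and expression truths cohere and promoter
concordance is a meaningful end-to-end readout. A quarter of the DE
miRNAs are placed inside the three imprinted-region analogues of
`make_catalogs()` (three regions on distinct chromosomes, after the
canonical brain-expressed imprinted ncRNA clusters), matching the
~25% mapping fraction this kind of study reports.

`simulate_qpcr()` emulates the validation assay: 6 biological samples
per group, 3 technical replicates, a true fold change of 1.45, technical
Ct sd 0.12 and biological ΔCt sd 0.35 cycles. The biological sd is
chosen so that the t-test's sampling uncertainty matches what a
borderline-significant (p ≈ 0.02) 1.45-fold result at n = 6 implies;
individual simulated estimates therefore scatter roughly between 1.2 and
1.8, which is the honest precision of the assay at this design size.

## Problem sizes and determinism

Default study size is 40 promoters × 112 probes × 6 samples
(4480 probes), at which the full pipeline runs in a few seconds; the
recovery and calibration properties are pooled over 20 independent
simulations. All generator randomness is drawn under temporary RNG
states derived from the single config seed, so identical configs give
byte-identical outputs and the caller's RNG stream is untouched.

## Worked example

```{r example, eval = FALSE}
report <- run_pipeline(sim_config(seed = 1))
report
glance(report)

# individual stages compose with the pipe
sim <- simulate_tiling(sim_config(seed = 1))
deps <- sim$track |>
  quantile_normalize() |>
  linear_smooth(300) |>
  compute_mprime() |>
  call_deps()
glance(deps)
```

## Known limitations

* Peak boundaries overshoot narrow signals by up to half a window per
  side (window-centred probe scores); for 750 bp planted DMRs this
  dilutes the peak-median filters and accounts for the small fraction
  of missed loss-DMRs at noise sd 0.3.
* The probe-level null is the whole-track score distribution; on arrays
  where most of the genome is differentially methylated the reference
  distribution itself shifts.
* No probe-affinity or GC model; raw vendor pair files and
  CEL-level summarisation are out of scope (the package consumes
  summarised matrices).
* The CV criterion divides by |mean|, so probes with near-zero group
  means always fail it; this is a documented convention, not a claim
  about the vendor's handling.
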