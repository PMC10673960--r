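---
title: "Linkage mapping and binary-trait scans for a full-sib snail cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping and binary-trait scans for a full-sib snail cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snailmap)
```

## The design this package models

`snailmap` analyses a single full-sib cross of the grove snail *Cepaea
nemoralis*: two outbred parents, two grandparents of the informative parent,
and 75 offspring, whole-genome sequenced to roughly 10-fold depth. The cross
segregates for two Mendelian shell loci: the shell ground colour locus *C*
(pink dominant over yellow, inside the colour-and-banding supergene) and the
unlinked mid-banded locus *U* (mid-band dominant). The informative parent is
heterozygous at both loci and at every retained marker; the other parent is
homozygous recessive at the trait loci, so each trait segregates 1:1 among
offspring.

The pipeline runs the classical stages in order: marker retention from a
VCF, informative-marker selection, two-point linkage grouping and ordering,
map pruning, sex-averaged map statistics, hidden-Markov-model genotype
probabilities, binary-trait genome scans with permutation thresholds, Bayes
credible intervals and allele effects, Mendelian segregation validation of
candidate positions, and a power calculation for trait-locus detection.

## The synthetic cross generator

Raw reads are not needed: `simulate_cross()` generates the design from the
genotype-call level down, with ground truth retained for every stage.

* **Map function.** Haldane throughout: crossover counts are Poisson in the
  group length (cM/100), breakpoints uniform, no interference. This matches
  the Markov assumption of the downstream HMM, and nothing in the analysis
  depends on an interference model.
* **Marker scaffold.** Positions are uniform within each group (defaults:
  the 22 published group lengths, 20 markers per group — a desk-scale
  stand-in for the published 215,593-marker density); contigs span
  contiguous runs of markers, emulating a fragmented assembly.
* **Noise model.** A called genotype is replaced by a uniformly chosen
  wrong phased genotype with probability `genotyping_error` (default 0.002,
  the error rate the scan HMM assumes); calls are masked completely at
  random at `missing_rate` (default 0.05, inside the 10% retention cap);
  per-call depth is negative binomial with mean 10 (Poisson in the
  zero-dispersion limit). Site quality is the maximum (999) because the
  simulator starts at confidently called SNPs; the filter fixtures exercise
  the quality rule separately.
* **Both-parent heterozygosity.** The study does not report how many
  markers were heterozygous in the second parent; `both_parent_het_fraction`
  (default 0.3) is an exposed knob, and only affects how much the maternal
  map and the AB/AA/BB split benefit from maternal meioses.

What the generator does **not** emulate: read-level artefacts (alignment,
paralogy, allele balance), linked-error structure, segregation distortion,
and the supergene's internal multi-locus structure (zero recombinants were
observed within it, so a single locus suffices). Passing tests therefore
validate the statistical machinery on clean Mendelian data, not robustness
to assembly artefacts.

## Two-point mapping choices

Pairwise recombination fractions are maximum-likelihood counts of
recombinant meioses per parent (pooled across parents), with LOD against
r = 0.5. When parental phase is unknown the orientation maximising the
likelihood is used — the fixed point an EM over phase converges to in this
binomial setting. Grouping is single-linkage transitive closure at
`lod_limit` 9.5 with `size_limit` dissolution and LOD-5 singleton joining,
the parameters of the published map. Ordering is greedy nearest-neighbour
seriation refined by 2-opt with 20 restarts, minimising the sum of adjacent
recombination fractions; it replaces a full multipoint pedigree likelihood,
which is out of scope. At desk scale the printed `size_limit` of 600 would
dissolve every group, so `pipeline_config()` defaults it to 5 while
`grouping_params()` keeps the study-scale default.

Two pruning rules follow the published map exactly: per map location,
SNPs whose normalised maximum LOD falls below the location mean minus one
standard deviation are removed (sample SD; per-location max normalisation —
the published description fixes neither, and the choice does not change any
of the worked examples); and contigs split across groups lose either all
their SNPs (10 or fewer mapped) or their sub-10% minority assignments. A
split contig with more than 10 SNPs and at least 10% on every group is
removed entirely — the published rule is silent there, and removal is the
conservative reading (logged distinctly).

## Phase, genotype codes and the scan

Offspring genotypes enter the scan as grandparental-origin codes
(`1 2`/`2 1` = AB, `1 1` = AA, `2 2` = BB, digits = paternal, maternal
strand), which are phase-consistent along the map; raw allele labels are
phase-arbitrary per marker and would scramble the dominance pattern. Where
a parent is homozygous at a marker its transmitted strand is unobserved, so
a two-state per-parent HMM (`phase_impute()`) completes the strand matrix
from flanking informative markers — the role the pedigree phasing step
plays in the reference pipeline. Posterior-mode imputation is used; a
parent with no informative markers on a group contributes a constant strand
(the group degrades gracefully to a one-parent backcross coding).

`calc_genoprob()` is a three-state forward–backward pass per offspring and
group (error rate 0.002 by default); `binary_scan()` fits, per position, a
logistic regression of the phenotype on the P(AB) and P(BB) covariates by
IRLS and reports LOD against the intercept-only model. Under complete
separation the likelihood is bounded by clamping fitted probabilities to
[1e-12, 1-1e-12] (iteration cap 100); allele effects are capped at ±20
log-odds. Thresholds come from seeded phenotype permutations (1000 by
default, 5% genome-wide); peaks are split only where the LOD drops at
least 1.8 below the lower of two adjacent maxima; credible intervals take
the smallest contiguous span of map positions holding 95% of the
10^LOD mass around the peak (observed marker positions only — no
pseudomarker grid, matching a dense map where positions are already
closely spaced).

One structural point the simulations reproduce: because each trait
segregates only through the informative parent, heterozygous codes are
phenotype-uninformative (the "AB individuals split" pattern). Peak LODs for
a fully penetrant locus at n = 75 therefore sit near 11 — the same
magnitude as the published peaks — and the argmax carries several cM of
sampling noise. Candidate regions are therefore validated not by the LOD
alone but by the segregation check: a position is consistent only if every
homozygote's phenotype matches the dominance model (heterozygotes exempt),
with the homozygote-to-phenotype orientation inferred from the sign of the
allele-effect contrast at the peak.

## Map statistics

`summarize_map()` implements the standard map arithmetic: average
inter-marker interval `s = L/(M − G)`, expected genome length
`Σ(Lᵢ + 2s)`, coverage `L/expected`, and genome-wide recombination rate
`L / genome size (Mb)` (default 3500 Mb). The published per-group table is
shipped as a plain-text input (`cnemoralis_lg_summary()`); feeding it back
through these formulas reproduces the published totals, mean interval
(0.0099 cM), rate (0.61 cM/Mb) and marker share of the largest group
(~27%). The published *expected* length (2187 cM) is not reproducible from
the published `s` and group lengths by the stated formula (2143 + 44·s ≈
2143.4), so no check is pinned to it or to the derived 98% coverage.

## Power

`qtl_power()` computes the power to detect a trait locus lying in a
candidate interval of width *d* cM: a one-degree-of-freedom
dominant-genotype contrast tested up to *d*/2 from the locus, with
noncentrality `n·(1−2r)²·h²/(1−h²)`, `r = haldane_r(d/2)`, compared against
the central chi-square critical value at α. At n = 75, α = 0.01 and full
trait variance this gives 100% power for both the 2 and 5 cM intervals,
and the 1%-grid threshold at which power first drops below 95% is 21%
trait variance. The companion threshold at which rounded power first drops
below 100% computes to 29% under this model; no noncentral chi-square
power curve with noncentrality proportional to h²/(1−h²) can place that
threshold near 40% while keeping the 95% threshold near 21% (the two would
require a noncentrality ratio of ~2.5 between the 99.5% and 95% power
levels, where chi-square families allow at most ~1.5), so the pair of
published round-number thresholds cannot both be met by one curve; the
implementation keeps the curve that reproduces the 95% threshold exactly.

## Problem sizes and numerics

The shipped tests run the full stack at desk scale: crosses of 75
offspring on one to three groups with 15–60 markers each, 100-replicate
coverage and localisation studies, a 200-replicate null study at 200
permutations each, exhaustive oracles for the HMM (≤4 markers, 3^m
enumeration), ordering (≤8 markers, all permutations) and credible
intervals (span enumeration), and connected-component cross-checks on
100-marker fixtures. Adjacent recombination fractions are capped at 0.49
before Haldane inversion; degenerate groups (zero length, all pairs
uninformative, single markers) take documented fallbacks rather than
failing. Known desk-scale limitations: with ~1 cM marker spacing and 75
meioses, adjacent orders are noise-limited, and posterior-mode imputation
then smooths over locally misordered markers, biasing map length short by
roughly a quarter; at the published marker density this regime does not
arise for the ordering engine used there.
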