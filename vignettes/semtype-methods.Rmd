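---
title: "Community typing of the seminal microbiome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community typing of the seminal microbiome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`semtype` reimplements, as a tested pipeline, an analysis strategy for
relating seminal bacterial communities to clinical semen quality: paired-end
16S rRNA (V4) amplicon reads are quality-filtered and assigned to reference
taxa, per-sample genus/species proportion profiles are compared by weighted
UniFrac, samples are grouped into community types by hierarchical
clustering with the Calinski–Harabasz pseudo-F, and community types are
related to clinical status by enrichment statistics, differential
abundance under FDR control, co-occurrence networks, and a decision-rule
classifier over genus-ratio features. Because the original cohort's raw
sequence data are not available, the package ships a synthetic-cohort
generator that reproduces the statistical structure those analyses assume;
the generator is first-class, tested code, and every downstream module is
validated against it and against independent oracles.

This vignette documents the models, the tunable parameters, the numerical
conventions, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the package's test
suite or `scripts/acceptance.R` does not itself compute.

## The synthetic cohort

### What it emulates

The generator produces a self-contained analogue of a 96-man cohort:

* a **reference database** of one ~250-nt 16S fragment per species,
  grouped into genera, with a rooted branch-length phylogeny whose leaves
  are the reference sequences;
* per sample, a **true composition** over species, paired-end
  **reads** with substitution errors and realistic Phred profiles, a
  **barcode**, and a **clinical record** (seven semen-quality criteria
  plus nine CASA metrics);
* three **community types**. Type means are anchored to the cohort the
  analysis models: the predominant genus means are Pseudomonas 16.1% in
  G1, Lactobacillus 32.3% in G2, and Prevotella 26.3% in G3, and the
  probability that a sample is clinically normal is 0.20, 0.527 and 0.125
  in G1, G2 and G3. The default group sizes are 25/55/16.

Sample-to-sample variation of genus proportions is Dirichlet with
precision 25 (`concentration`), i.e. `alpha = 25 * genus_means`. At this
precision a genus with mean 0.32 has a standard deviation of about 0.09,
so the marginal distributions of the three types visibly overlap while the
joint composition remains separable. Each genus's mass is split among its
species by weights fixed at database-build time (a geometric 4:2:1 split),
so species-level variation tracks genus-level variation rather than adding
independent noise.

The secondary and background genus means are type-specific: each
community type carries its own co-occurring background flora. This mirrors
the co-occurrence structure of real seminal communities (each community
state has characteristic partner genera) and it is what makes the three
planted types identifiable through the full pipeline: with a background
shared across types, the Dirichlet noise on large shared components
dominates the weighted-UniFrac distances and hierarchical clustering
cannot reliably separate the types at precision 25. The chosen means keep
the cohort-level averages realistic (Lactobacillus ~20%, Pseudomonas and
Prevotella ~6–8%, roughly half of all mass in minor "Other" genera).

### Reads and qualities

Reads are substitution-only (no indels, chimeras or length variation —
deliberate non-goals): the forward mate is the 5' prefix of the species
reference, the reverse mate the reverse complement of the 3' end, with
i.i.d. substitution errors at `error_rate` (default 0.005/base, at most
0.01). Phred strings follow a two-state model: bases start in a good state
(Q38) and fall into an absorbing bad state (Q15) with hazard
`qual_hazard * (i/read_len)^3` at read position `i` (default
`qual_hazard = 0.0015`). The cubic hazard concentrates quality decay at
the 3' end, as on real Illumina runs, so the Q30-truncation rule is
genuinely exercised while more than 95% of pairs survive default QC.

The clinical simulator draws, with probability `p_normal(type)`, a fully
normal record; otherwise it draws at least two abnormal criteria (so the
sample is a case under the default class rule), choosing which criteria
with probabilities proportional to the abnormality margins of the modeled
population (morphology abnormalities most common). Raw values for
abnormal flags are uniform beyond the clinical threshold — only the flags,
not the raw distributions, are pinned down by the modeled study. Head
elongation increases linearly in the sample's Lactobacillus proportion
(slope 20 on a ~50-unit scale, noise SD 3), planting the
morphology–microbiome link that the CASA association module is tested
against.

A cohort of 96 samples at the default 5,000 read pairs per sample is a
desk-scale stand-in for the tens of thousands of reads per participant in
a real run; all sampling-noise bounds in the tests are computed at this
depth. All randomness flows from one cohort seed through
`derive_seeds()`, so identical seeds give byte-identical cohorts.

### What passing tests do and do not show

The generator reproduces the *statistical skeleton* the analysis assumes:
anchored type means, type-coupled clinical rates, planted monotone links,
realistic QC attrition. It does not reproduce PCR chimeras, indel errors,
variable read lengths, contaminant taxa, compositional zero-inflation, or
the taxonomic breadth (hundreds of genera) of real semen microbiomes.
Passing recovery tests therefore demonstrates that the pipeline's
inference machinery is correct and calibrated under its stated model, not
that the biological conclusions would replicate on new clinical material.

## Read QC

Demultiplexing matches the leading bases of the forward read against the
barcode map (default 0 mismatches; reads matching no barcode, or more
than one at the allowed mismatch count, go to an unassigned bin) and
strips the barcode. Quality filtering then 3'-truncates each mate at its
first base below Q30 and keeps a pair iff both truncated mates are at
least 100 nt and contain only A/C/G/T. Truncation-then-length-filter
reconciles the two natural readings of "retain reads above Q30" and
"discard reads under 100 nt": a read whose quality collapses early is
truncated below the length floor and discarded as short. A whole-read
mean-quality rule is available behind `quality_mode = "mean"`. The length
filter is applied *after* truncation; ambiguous characters beyond the
truncation point do not count against a read. If either mate fails, the
pair is discarded, because assignment requires concordant mates
downstream. Only Phred+33 input is supported. Every run satisfies the
accounting identity `input = retained + discarded_short +
discarded_ambiguous + discarded_quality` per sample, and filtering is
per-pair independent, hence order-invariant.

## Taxonomic assignment and profiles

Reads are aligned by exact 15-mer seeding against an index of the
reference set; every candidate (reference, diagonal) is scored by gapless
identity, and candidates falling below the threshold by at most
`rescue_margin` (default 0.03) are re-scored with a banded semi-global
alignment (band half-width 8) that can absorb small indels. **Identity is
defined as matches divided by aligned read length**, with soft-clipped
read ends excluded from the denominator; this convention matters for
borderline calls and is therefore part of the documented contract. A hit
requires identity ≥ 0.97 — inclusive, so a 120-nt read with exactly 3
mismatches (identity 0.975) maps and one with 4 (0.9667) does not.

A pair is assigned only if both mates hit the same reference (mate
concordance); among common references the best mean identity wins, with
ties broken by higher minimum mate identity and then lexicographic
sequence id. Deterministic tie-breaking (rather than LCA climbing) keeps
profiles integer-valued and runs reproducible; an LCA variant would be
the natural extension. Profiles are proportion-based — counts divided by
assigned reads per sample — because proportions, unlike raw counts, are
comparable across samples with different sequencing depths. Samples with
zero assigned reads are flagged invalid and excluded downstream with a
warning. Minor taxa can be pooled into an "Others" column by cohort-mean
threshold; pooling everything is refused.

## Community typing

**Weighted UniFrac.** For two profiles on the tips of a rooted
branch-length tree, the raw distance is `sum_b l_b * |A_b - B_b|` over
branches `b`, where `A_b` is the fraction of community A descending
through `b`. The default normalization divides by
`sum_j d_j (p_Aj + p_Bj)` with `d_j` the root-to-tip path length, which
bounds the distance in [0, 1]; the raw variant is available via
`normalized = FALSE`. The implementation is validated against an
independent branch-enumeration oracle on hundreds of random trees.

**Clustering and k selection.** The dendrogram is average-linkage UPGMA
with ultrametric node heights (a pair at distance d merges at height
d/2). UPGMA was chosen because cutting the tree into groups requires
ultrametric heights; neighbour-joining is out of scope. The number of
community types is chosen by cutting the dendrogram at each k in 2..10
and maximizing the Calinski–Harabasz pseudo-F,
`F = [(TSS − WSS)/(k − 1)] / [WSS/(n − k)]`, with ties going to the
smallest k. Because UniFrac matrices need not be Euclidean, the pseudo-F
is computed on the positive-eigenvalue PCoA axes of the distance matrix
(the default); a purely distance-based variant (`from = "distance"`) is
provided. PCoA uses Gower double-centering of −D²/2, retains eigenvalues
above 1e-10, scales axes by the square root of their eigenvalue, orients
each axis so its largest-magnitude coordinate is positive, and reports
the worst-case reconstruction error for non-Euclidean input.

**Alpha diversity.** Shannon entropy uses the natural log (the log base
is a convention; nats are the package contract). Chao1 uses the
bias-corrected form `S_obs + F1(F1−1)/(2(F2+1))`, which is defined even
with no doubletons, and requires integer read counts — richness
estimation from proportions is refused.

## Association statistics

Clinical flags follow the clinical thresholds: volume abnormal outside
(1.2, 6.4) ml (inclusive at both cut-offs), concentration < 15×10⁶/ml,
motility < 40%, Kruger strict morphology ≤ 5%, IgA > 30%, atypical
(small-head) forms ≥ 1%, and leukocytes observed at ≥ 10⁶ cells/ml.
Samples with no abnormal criterion are *normal*; samples with at least
`min_abnormal_case` (default 2) are *cases*; the remainder are excluded
from supervised comparisons. The verbal rule "more than two abnormal
values" conflicts with the printed group sizes once excluded samples
exist, so the threshold is an explicit parameter rather than a silent
resolution.

Differential abundance applies a strict cohort-mean abundance filter
(> 0.25%; the mean, rather than a per-sample rule, is the documented
choice and is configurable), a two-sided Mann–Whitney U test per taxon —
exact enumeration for pooled samples of at most 20 without ties,
otherwise the normal approximation with tie and continuity corrections —
and the **adaptive two-stage Benjamini–Hochberg** procedure: stage one
runs BH at α/(1+α) and estimates the number of true nulls as m₀ = m − r₁
(m if nothing is rejected); stage two reruns BH at α·m/m₀. The adaptive
rejection set provably contains the plain BH set at the same level; the
test suite checks this on a thousand random p-vectors. "Adaptive BH" is
ambiguous between variants in the literature; the two-stage linear
step-up is implemented and documented, and the reported q-values are the
BH-adjusted values scaled by m₀/m. Significance tiers (0.05/0.01/0.001 on
the raw p) are reported only for taxa that survive the FDR screen,
matching the two-step description of the modeled analysis.

Fisher's exact test uses the two-sided minimum-likelihood tail convention
(this convention reproduces the printed group-comparison p-values from
the published counts); the odds ratio is the sample cross-product ratio
with a 0.5 Haldane–Anscombe correction when a cell is zero. Co-occurrence
networks link genera with |Spearman ρ| strictly above 0.4 (average ranks
under ties); constant genera are excluded with a warning. CASA
associations are Spearman correlations of each abundance-filtered taxon
against each numeric CASA metric, corrected adaptively across the whole
taxon × metric family; zero-variance metrics are skipped.

## The decision-rule classifier

Features per sample are the proportions of the five marker genera
(Lactobacillus, Gardnerella, Prevotella, Pseudomonas, Haemophilus), all
20 ordered pairwise ratios, each genus against the sum of the other four,
and the composite ratio Lactobacillus/(Prevotella + Pseudomonas +
Haemophilus) — the published rule is expressible in this space, which is
why the set is wider than any single printed rule. Ratios with zero
denominators are encoded as a large sentinel (10⁶) and flagged rather
than dropping samples: absence of a genus is biologically meaningful.

The reference classifier is the **fixed published rule**: composite ratio
> 0.57 ⇒ G2; otherwise Prevotella/Pseudomonas > 1.37 ⇒ G3, else G1. It is
scale-invariant (ratios only); an infinite composite ratio goes to G2 and
an all-zero marker profile is flagged and sent to G1 with a warning.

The learned classifier is a C4.5-style tree: numeric splits at midpoints
of consecutive distinct feature values, chosen by **gain ratio**
(information gain over split information) to honor the J48 lineage —
Gini-based CART would not be faithful — with a minimum leaf size of 2 and
optional reduced-error pruning on a held-out quarter of the training
data. Exact J48 pruning heuristics (confidence-interval error estimates,
subtree raising) are not replicated; this is a documented divergence.
Evaluation is stratified k-fold cross-validation (default 5, seeded,
refolding with a warning if a class is missing from a training split)
with per-class one-vs-rest ROC AUC computed from leaf class-frequency
scores **pooled over folds** (not averaged per fold) by rank-sum
integration, which equals trapezoidal ROC integration.

On data labelled by the fixed rule, the learned tree's root split
recovers the composite-ratio feature with a threshold within ±0.05 of
0.57 and its decision regions agree with the rule on ≥99% of fresh
samples; the test suite computes both.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes simulate → QC → profile → cluster → diversity →
assoc → classify under a single validated configuration
(`pipeline_config()`; unknown keys are rejected, YAML round-trip is
lossless). One global seed is fanned out to per-stage seeds by a
documented derivation (`derive_seeds()`), so any stage can be reproduced
in isolation; a rerun under the same configuration is bit-identical,
which the test suite asserts. Stage artifacts are written as TSV/Newick/
FASTA text files with provenance headers. A thin command-line wrapper
(`inst/exec/semtype.R`) exposes `simulate` and `run`; all other
functionality is the R API.

Problem sizes used by the tests and the acceptance script — 96 samples at
5,000 pairs/sample for the end-to-end run, 50 replicates for detection
power, 200 for null calibration, 200 random trees for the UniFrac oracle
— were chosen so the whole suite completes in a few minutes on one core
while keeping Monte-Carlo error well inside the asserted bounds.

## Known limitations

* The aligner is a seeded, banded, substitution-oriented mapper designed
  for amplicon reads against a compact reference; it is not a general
  read aligner (no spliced or local alignment, no quality-aware scoring).
* UPGMA cluster labels are arbitrary (G1..Gk in cut order); they
  correspond to predominant genera only through the typing summary.
* The adaptive-BH m₀ estimate, the 0.25% mean-abundance filter, the
  UniFrac normalization, the Shannon log base, and the case-definition
  threshold are all conventions exposed as parameters; alternative
  choices change borderline results and should be reported alongside any
  analysis.
* Proportions are analyzed on the raw simplex, not log-ratio transformed;
  compositional effects (one taxon's rise depressing all others) are
  inherent to the modeled methodology.
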