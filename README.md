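# semtype

Community typing of the seminal microbiome and its association with semen
quality, as a tested R pipeline.

Bacteriospermia is a suspected contributor to male-factor infertility, but
culture- and PCR-based assays see only a handful of taxa. Profiling the
whole seminal bacterial community from paired-end 16S rRNA (V4) amplicon
reads makes it possible to ask sharper questions: do semen samples fall
into discrete community types, is the Lactobacillus-dominated type
enriched in clinically normal samples, which genera differ between
low-quality ("case") and normal semen, and can a simple decision rule
over a few marker genera classify a sample's community type? `semtype`
implements that full analysis — and, because the original cohort's raw
reads are not publicly available, a synthetic-cohort generator with the
same statistical structure, so every stage is testable end to end. It is
aimed at microbiome bioinformaticians and reproducibility-minded
clinicians who want the complete path from FASTQ to statistics in
auditable, seedable code.

## What it computes

* **Read QC** — barcode demultiplexing, 3' truncation at the first base
  below Q30, discarding of truncated mates under 100 nt or containing
  ambiguous characters; pairs are kept only if both mates survive.
* **Taxonomic profiles** — k-mer-seeded banded alignment of both mates,
  assignment when both mates map to the same reference at identity ≥ 0.97
  (identity = matches / aligned read length), proportion-based genus and
  species profiles.
* **Community typing** — weighted UniFrac
  `d(A,B) = Σ_b l_b |A_b − B_b| / Σ_j d_j (p_Aj + p_Bj)`
  over a rooted reference phylogeny, UPGMA dendrogram, and selection of
  the number of types k by the Calinski–Harabasz pseudo-F
  `F = [(TSS−WSS)/(k−1)] / [WSS/(n−k)]` on PCoA coordinates.
* **Diversity** — Shannon entropy (nats) and bias-corrected Chao1
  `S_obs + F₁(F₁−1)/(2(F₂+1))`, compared between groups by Mann–Whitney.
* **Associations** — case/normal class construction from seven clinical
  criteria, Mann–Whitney differential abundance over taxa above a 0.25%
  mean-proportion filter with adaptive (two-stage) Benjamini–Hochberg FDR
  control, Fisher exact enrichment of normal samples across community
  types, Spearman co-occurrence networks (|ρ| > 0.4), and CASA-metric
  correlations.
* **Rule classifier** — a C4.5-style (gain-ratio) decision tree over
  five-genus proportion and ratio features, evaluated by stratified
  5-fold cross-validation with pooled one-vs-rest ROC AUC, plus the fixed
  published rule: Lactobacillus/(Prevotella+Pseudomonas+Haemophilus)
  > 0.57 ⇒ G2, else Prevotella/Pseudomonas > 1.37 ⇒ G3, else G1.

## Worked example

```r
library(semtype)

report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> cohort_report: 96 samples
#>   chosen k = 3 (ARI vs planted types: 1.000)
#>   G1: n=25, normal 16.0%, fisher p=1.27e-02, OR=4.4
#>   G2: n=55, normal 45.5% (predominant)
#>   G3: n=16, normal 6.2%, fisher p=3.50e-03, OR=12.5
#>   classifier: accuracy 0.979, AUC G1=0.973 G2=1.000 G3=0.963
#>   4 differentially abundant genera (FDR 0.05)
```

Reading the output: the pseudo-F selected three community types, and they
match the generator's planted types exactly (adjusted Rand index 1.0).
The Lactobacillus-predominant group (G2) holds most of the clinically
normal samples; the other two groups are significantly depleted of normal
samples by Fisher's exact test, with odds ratios of non-normality of 4.4
and 12.5 relative to G2. The cross-validated decision tree recovers the
community type from five marker genera with per-class ROC areas above
0.96, and four genera pass the case-vs-normal differential-abundance
screen at FDR 0.05. (Group percentages fluctuate with the cohort seed
around the generator's planted rates of 20%, 52.7% and 12.5%.)

The same statistics can be computed from printed group counts alone:

```r
labels  <- rep(c("G1", "G2", "G3"), c(25, 55, 16))
classes <- c(rep(c("normal", "case"), c(5, 20)),
             rep(c("normal", "case"), c(29, 26)),
             rep(c("normal", "case"), c(2, 14)))
summarize_typing(labels, classes)
#>   group size n_normal normal_fraction    fisher_p odds_ratio
#> 1    G1   25        5       0.2000000 0.007377214   4.461538
#> 2    G2   55       29       0.5272727          NA         NA
#> 3    G3   16        2       0.1250000 0.004484675   7.807692
```

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/semtype.R", package="semtype"))')" \
    run --seed 1 --outdir semtype_out
```

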