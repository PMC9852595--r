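---
title: "Methods: methylation and expression classifiers for Richter syndrome"
author: "rsclassify authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation and expression classifiers for Richter syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsclassify)
```

# The problem

Richter syndrome (RS) is the transformation of chronic lymphocytic leukemia
(CLL) into an aggressive lymphoma, most often with diffuse large B-cell
lymphoma (DLBCL) histology. Two molecularly distinct situations hide behind
that single diagnosis: a true clonal transformation of the patient's CLL
(CLL-derived RS, which keeps the CLL epigenetic imprint) and a de novo
DLBCL arising independently in a CLL patient (DLBCL-like RS). The package
implements two classifiers that separate them — one from DNA methylation
arrays, one from gene expression — plus the methylome–transcriptome
integration that nominates the methylation-regulated genes distinguishing
the subgroups.

# The methylation linear predictor score (LPS)

## Statistical engine

Differential methylation runs on M-values, `M = log2(beta / (1 - beta))`,
which are roughly homoskedastic across the (0, 1) beta range; beta-values
are kept for effect sizes and scoring because they are interpretable as
methylation fractions. Per-CpG linear models (group contrast plus optional
additive covariates such as estimated B-cell fractions) are fitted by
limma; residual variances are shrunk toward a scaled inverse-chi-square
prior estimated by moments on the log variances, giving the moderated
t-statistic with `df + d0` total degrees of freedom. P-values are two-sided
and adjusted by Benjamini–Hochberg.

## Selection cascade

Scoring CpGs are selected in a fixed order:

1. CLL vs DLBCL moderated t, keep `q < 0.01`; the t-statistics become the
   scoring weights;
2. remove CpGs that are also differential between IGHV-unmutated and
   IGHV-mutated CLL at `q < 0.01` — de novo DLBCL is typically
   IGHV-mutated, so IGHV-driven methylation would leak maturation state
   into the CLL/DLBCL axis. The *intersection* of the two differential sets
   is removed (removing the full IGHV-differential set regardless of
   overlap would discard CpGs that were never CLL/DLBCL-differential in the
   first place and is arithmetically inconsistent with treating step 1 as
   the scoring universe);
3. keep CpGs with `|Δβ| > 0.30` between the group means — the absolute
   value is used, as hypo- and hypermethylated CpGs are equally
   informative and the score weights already carry the direction.

## Scoring and calling

`LPS(S) = Σ tᵢ Sᵢ` over the scoring CpGs with beta-values `Sᵢ`. Gaussian
distributions (sample mean, unbiased variance) fitted to the reference CLL
and DLBCL scores give the posterior as a two-density ratio. The posterior
is computed in log space, `p_CLL = 1 / (1 + exp(log φ_DLBCL − log φ_CLL))`,
because the raw densities underflow to 0/0 for well-separated groups; the
complement `p_DLBCL = 1 − p_CLL` then holds exactly by construction.
Labels use an inclusive threshold of 0.98 on either posterior;
samples in between are reported as `intermediate` (no silent relabeling:
treating intermediates as low-score CLL-derived is a reporting choice left
to the caller).

# RNA-seq preparation

Counts are filtered before normalization (features must be non-zero in at
least 2 samples and average at least `max(20, mean library size / 5e6)`
reads — the depth-scaled rule with an explicit 20-read floor, exposed as a
parameter because the two published rules disagree at typical depths).
TMM factors (edgeR, canonical 30%/5% trims) are renormalized to geometric
mean 1, and expression is transformed as
`log2((count + 0.5) / (effective library + 1) × 1e6)`. A prior count of
0.5 keeps zeros finite without noticeably biasing expressed genes.

# The expression linear classifier score (LCS)

The signature is a ±1-weighted gene list derived from expression
clustering: after median-centering, genes are clustered under the
*uncentered* Pearson correlation distance
`d = 1 − Σxy / (√Σx² √Σy²)` — sensitive to each profile's offset from
zero, which is exactly what median-centered up/down profiles encode. The
tree is cut into k flat clusters and the pair with the most extreme
positive and negative mean contrast between the CLL-derived and DLBCL-like
sides becomes the up/down source clusters (the cut rule is a package
choice; the derivation procedure, not a specific dendrogram height, is
what the source describes). The clusters are reduced to protein-coding
genes (portable to platforms without ncRNAs) supported by the integrome.

Scoring steps: features are summed per gene, genes scaled to mean 0 / sd 1
(unbiased sd throughout — the convention is applied consistently rather
than guessed per stage), positive outliers trimmed at the matrix-wide
99.9th percentile, and the score is the signature-weighted mean. The
percentile is the empirical order statistic (quantile type 1) rather than
an interpolated quantile: that choice makes trimming exactly idempotent
and matches a sort-based definition of "the last permille value".
Trimming is matrix-wide because a per-gene 99.9th percentile is undefined
for cohorts far below 1,000 samples. Negative values are never trimmed.

Z-standardization is cohort-relative; the p-value is the upper tail of the
standard normal ("one-way" read as one-sided toward high scores, which is
the direction of the CLL-derived imprint), applied to the raw p by default
with multiplicity adjustment available as an option. Cohort-relative
scoring is a documented limitation: a sample's z-score depends on the
cohort it is scored in, so single samples cannot be classified in
isolation.

The packaged `rs_signature()` fixture carries the published signature's
*structure* (215 genes: 122 at +1, 93 at −1) with synthetic gene
identifiers, so the scoring machinery can be exercised at realistic size;
it is labeled synthetic in the file name and documentation.

# The methylome–transcriptome integrome

CpG–transcript associations are the union of identifier links (annotation
feature classes TSS200/TSS1500/FirstExon/…) and coordinate links within an
inclusive 2 kb window around the TSS (labeled `TSSoverlap2kb`; identifier
links take precedence on duplicates). Spearman correlations use mid-ranks;
p-values use the t-approximation `t = rho√((n−2)/(1−rho²))` for n ≥ 10 and
an exact permutation null for 5 ≤ n < 10, where the approximation cannot
reach the `p < 0.001` gate. Candidate regions need at least three
same-direction CpGs with `|rho| > 1/3` and `p < 0.001` in promoter-class
features; the rho threshold is exactly 1/3 (printed 0.33 treated as
display rounding). Negative direction means higher methylation with lower
expression. A transcript can be a candidate in both directions; the unique
gene list deduplicates after direction-specific counting. Enrichment
statistics are observed/expected frequency ratios with Fisher (exact
hypergeometric) or Pearson chi-square (no continuity correction) p-values.

# The synthetic cohort generator

The generator produces the statistical structure the analysis assumes, with
ground truth for every planted feature. Baseline CpG M-values come from a
bimodal mixture `0.5·N(−3,1) + 0.5·N(3,1)` (beta modes near 0.11/0.89,
as in array data). All effects are applied on the M scale and transformed
back — additive beta effects would saturate near 0 and 1. Defaults, chosen
once as the study conditions:

| parameter | default | meaning |
|---|---|---|
| group sizes | 20+20 CLL (U/M), 40 DLBCL, 30+10 RS | reference and query groups |
| `delta_beta_effect` | 0.35 | planted CLL/DLBCL beta-differential |
| `frac_diff` / `frac_ighv` | 5% / 3% | planted differential CpG fractions |
| `rs_shift` | −0.3 (M units) | global RS hypomethylation |
| `noise_sd` | 0.5 (M units) | per-sample array noise |
| `nb_dispersion` | 0.1 | bulk RNA-seq negative-binomial dispersion |
| `mean_library_size` | 2e7 reads | sequencing depth scale |
| `target_rho` | −0.6 | planted promoter–expression Spearman rho |

Planted differential CpGs draw a baseline such that the two group means
differ by exactly the target beta-differential before noise; the achieved
differential is reported and a warning is raised if saturation pulls it
more than 0.1 off target. RS samples inherit the methylation regime of
their true subgroup (CLL or DLBCL) plus the global hypomethylation shift;
IGHV CpGs shift only IGHV-unmutated samples. Promoter blocks of 3–5 CpGs
share a per-promoter latent factor (loading 0.9, residual sd 0.3) that the
expression simulator couples into the log-mean of the matching gene.

The coupling coefficient is calibrated so the realized CpG–expression
Spearman correlation lands on `target_rho`: a closed-form coefficient
(from the latent-correlation identity `a = σ·r/√(1−r²)`, attenuated for
the CpG-side loading and the rank transform) is refined by a seeded pilot
of 1,000 synthetic draws per gene that measures the realized attenuation
— including what the closed form cannot see, such as log compression at
low counts — and refits the coefficient. Counts are then drawn once from
the corrected coefficients; everything is a deterministic function of the
config seed.

What the generator does **not** emulate: probe-level artifacts (type I/II
chemistry, cross-reactive probes), cell-composition mixtures beyond a
single optional leaked covariate, batch structure, copy-number effects on
methylation or expression, and correlated null CpGs. Passing tests
therefore demonstrate that the algorithms recover the structure they
assume, not that they are robust to every artifact of real cohorts.

# Numerical choices

* Beta clipping `eps = 1e-6` before the logit keeps M-values finite at
  fully (un)methylated sites.
* Zero-residual-variance features are excluded before variance shrinkage
  (with a reported count) instead of receiving infinite t-statistics.
* Matrix TSV writers emit the shortest decimal representation that
  round-trips the double exactly; the reader uses the base parser, so
  write/read is bit-for-bit.
* Top-quartile LCS ties are broken by sample order and reported.
* Consensus k-means aggregates 20 seeded restarts by co-assignment
  frequency and cuts the average-linkage tree of the consensus distance,
  making the assignment deterministic given the seed.
* Hierarchical clustering ties (exactly equal merge heights) follow the
  platform agglomeration order; continuous expression data makes exact
  ties a measure-zero event.

# Problem sizes

The validation suites run at desk scale, chosen to keep each property
measurable with comfortable margins: LPS recovery uses 20 cohorts of
20,000 CpGs with 40-sample reference groups; moderated-t calibration uses
2,000 null features at n = 10+10; LCS calibration and ranking use
100-sample cohorts (20 replicates); integration recovery uses 10 cohorts
of 6,000 CpGs / 1,500 genes with 50 planted promoters and 40 RS samples.
The `small` gold preset (2,000 CpGs, 500 genes, 60 samples) backs the fast
unit tests; the `medium` preset (20,000 CpGs, 5,000 genes, 200 samples)
exercises the full pipeline end to end.

# Interfaces and limitations

The package is an R-native toolkit: the exported functions, the
`run_rs_pipeline()` orchestrator and this vignette are the interface;
artifacts (TSV tables, versioned JSON models, manifest-stamped cohort
bundles) are written by the corresponding `write_*` functions. Known
limitations: classifiers are cohort-relative (LCS) or reference-dependent
(LPS); probe-level preprocessing (IDAT parsing, within-array
normalization, SNP-probe filtering, imputation) is out of scope and
assumed done upstream; differential models support additive covariates
only, with no interactions; and survival analysis of score strata is
deliberately not included.
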