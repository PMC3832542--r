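---
title: "Mapping trans-acting RNA stability variation with rank-based stability scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping trans-acting RNA stability variation with rank-based stability scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rstab)
```

## The model

Steady-state RNA abundance balances transcription against decay. When a
*trans*-acting factor stabilizes many transcripts at once — as hnRNPs and
core spliceosomal proteins do — a change in its activity shifts the
abundance of long-lived transcripts relative to short-lived ones across the
whole transcriptome. That relative shift is detectable from expression data
alone, without knowing the factor or its targets.

`rstab` quantifies it with the RNA stability score. Genes are partitioned
into long-lived and short-lived groups; within each sample the classified
genes are ranked by expression, and the score is the difference in mean rank
between the groups. The score is a two-sample rank statistic per sample (a
rescaled Mann–Whitney statistic), which makes it:

- invariant to any strictly increasing transformation of a sample's
  expression values, hence robust to normalization and scale choices;
- bounded, with |score| ≤ N/2 for N classified genes, attained exactly when
  the groups separate completely;
- zero in expectation when long- and short-lived genes are exchangeable.

Treating the score as a quantitative trait, SNPs are tested one at a time by
ordinary least squares with an additive dosage coding, sex, and the top
genotype principal components as covariates. Genome-wide significance is
assessed both by Bonferroni adjustment and by an empirical min-p permutation
test. Candidate loci are followed up with Spearman rank-correlation eQTL
scans — cis within a window centered on the SNP, trans against all genes
under Benjamini–Hochberg FDR control — and with knockdown comparisons that
ask whether perturbing a candidate factor moves the score in the predicted
direction.

### Assumptions

The association model assumes an additive dosage effect on the score,
approximately normal residuals (the score averages ranks over hundreds of
genes, so this is mild), and population structure that is captured by a few
genotype principal components. The eQTL scans are rank-based and assume only
monotone dosage–expression relationships. The knockdown tests assume matched
replicate pairs and, for the Wilcoxon shift test, exchangeability of per-gene
log-ratios within each group.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| half-life threshold | 4 | hours | the conventional long/short dichotomy for mammalian transcripts; the boundary is inclusive (a gene at exactly 4 h is long-lived) |
| MAF threshold | 0.01 | frequency | SNPs with cohort MAF ≤ 1% are excluded; the filter is computed inside the analysis cohort because minor-allele identity is cohort-relative |
| number of PCs | 5 | — | enough to absorb continental-scale structure in multi-population panels; configurable |
| permutations | 1000 | — | resolves empirical p down to 0.001 in a full analysis; tests and the acceptance script use 200 to bound runtime while retaining 0.005 resolution |
| FDR threshold | 0.1 | proportion | the standard discovery threshold for trans-eQTL screens, where per-gene effects are weak |
| cis window | 1e6 | bases | "1 Mb window centered on the SNP" is read as ±500 kb, boundary-inclusive |

## What the generator emulates — and what it does not

`sim_config()` defines a synthetic study whose defaults are the conditions
under which the pipeline is validated: 2 populations × 100 samples,
Balding–Nichols allele-frequency divergence at Fst = 0.1, 2,000 independent
SNPs with ancestral MAF uniform on (0.05, 0.5), 1,000 genes half of which
are long-lived, log-normal expression with residual SD 0.5 around per-gene
baselines (SD 1), and one causal SNP whose dosage shifts the log-expression
of every long-lived gene.

The causal effect size defaults to 0.04 log-units per dosage. This is a free
parameter — no interpretable per-dosage effect is available to anchor it —
and it was calibrated once so that, at the default study size, the causal
SNP reaches Bonferroni significance in roughly 80–90% of replicate studies
and is the top hit in nearly all of them; it was then frozen. Scenario
analyses that need a strongly stability-variable cohort (trans-eQTL
enrichment, cross-scheme concordance) use 0.2 instead: concordance between
grouping schemes is only identifiable when inter-sample stability variation
actually exists, and 0.2 produces score variation comparable to a
large-effect locus.

Annotation flags are generated with realistic associations: housekeeping and
coding status are enriched among long-lived genes at 3:1 odds, and putative
AU-rich-element decay targets are enriched among short-lived genes. Sex is
Bernoulli(0.5) with an optional additive effect on long-lived expression
(default 0), and an optional population-level shift (`pop_effect`) creates a
stratification confound for diagnostics: with PCs omitted and a shift of
0.05, the genomic inflation factor rises far above the conventional 1.05
warning level, while the PC-adjusted scan of the same structure stays near 1.

The generator deliberately omits: linkage disequilibrium (SNPs are
independent, so the min-p permutation null is sharper than in real data),
probe- and batch-level artifacts, expression–half-life correlation in
baselines, cell-type dependence of half-lives, and any transcription-driven
covariation among genes. Passing tests therefore demonstrate correctness of
the statistics and recovery under the assumed generative model — not
robustness to the correlated noise structure of real arrays.

## Numerical conventions

- **Ties** receive average ranks everywhere (score, Spearman, Wilcoxon).
- **Only classified genes are ranked** for the score, so the N/2 bound is
  exact and scores are comparable across half-life sources; duplicate probes
  are collapsed by mean expression at read time.
- **Decay-rate classification**: long-lived means *below*-mean decay rate
  (lower decay, longer life). The opposite sign convention is exposed as
  `long_is_low_decay = FALSE` for compatibility with data sets whose decay
  scores are oriented the other way.
- **PCA** uses the Patterson normalization with posterior allele-frequency
  estimate (1 + Σdosage)/(2 + 2n), which avoids division by zero at
  monomorphic SNPs; missing dosages are mean-imputed inside PCA only, while
  regressions drop them pairwise per SNP. PC signs are arbitrary.
- **Permutations** shuffle the phenotype only; covariates stay attached to
  their samples, preserving the genotype–covariate structure (conservative
  for stratification). The permutation p is the proportion of permutation
  minima ≤ the observed minimum and admits an exact zero, printed as
  "< 1/n_perm" with the raw count retained.
- **Degenerate fits are flagged, not silently assigned p-values**: constant
  dosage, exact (zero-residual) fits, constant Spearman inputs, zero-variance
  t tests, and all-equal log-ratio Wilcoxon inputs each return an explicit
  flag with `NA` p.
- **Two-sided p-values** throughout; Spearman p uses the t approximation on
  n − 2 df; Wilcoxon is exact below 20 per group without ties, otherwise
  normal with continuity correction.
- **Minor-allele orientation**: VCF genotypes are recoded so dosage counts
  the cohort minor allele (sites with ALT frequency > 0.5 are flipped and
  the counted allele recorded); the TSV dosage dialect is treated as already
  oriented, which makes TSV round trips bit-lossless.
- Positions are 1-based; the cis window test is `|tss − snp| ≤ window/2`
  with the gene anchored at its TSS (annotation-configurable).

## Problem sizes used in validation

The test-suite and acceptance computations run at the generator's default
scale (200 samples, 2,000 SNPs, 1,000 genes), with 10–100 replicate studies
for calibration checks and 200 permutations per permutation test; oracle
comparisons use exhaustive enumeration on up to 6 genes and brute-force
reimplementations on matrices up to 50 × 10. These sizes were chosen to make
the full validation cycle run in about a minute while keeping every
statistical check at the scale where its asymptotics are already
representative.

## Known limitations

- Effect sizes are reported in rank units (ranks per dosage), which depend
  on the number of classified genes; they are comparable within a study but
  not across gene sets of different size.
- The parameter-recovery check compares the causal slope against its
  large-sample mean rather than the log-scale simulation parameter: the
  map from log-expression shift to rank-unit slope is nonlinear and has no
  closed form.
- Per-sample standard errors for single-sample knockdown designs would
  require a within-sample resampling scheme; only across-replicate standard
  errors are computed.
- The min-p permutation machinery requires complete dosages (the batched
  linear algebra has no pairwise-deletion path); impute or drop missing
  SNPs first.
- With very few genes per group (< 5) the score's discreteness makes the
  normal approximations in downstream t tests rough; the scans are intended
  for hundreds of genes per group.
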