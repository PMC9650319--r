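---
title: "APOE-stratified SNP-metabolite association analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APOE-stratified SNP-metabolite association analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoemqtl)
```

## The scientific problem

The APOE epsilon-2/epsilon-3/epsilon-4 polymorphism, defined jointly by
rs429358 and rs7412 on chromosome 19q13.3, modulates lipid metabolism and
the risk of Alzheimer's disease and cardiovascular disease. Variants across
the surrounding ~1 Mb gene cluster (NECTIN2, TOMM40, APOE, APOC1/2/4,
CLPTM1, BCL3, CKM, DMPK, ...) may therefore associate with plasma
metabolite concentrations *differently* depending on which APOE alleles a
person carries — associations that a pooled analysis averages away.

`apoemqtl` implements the two-stage stratified design used to detect such
genetic heterogeneity in family cohorts:

1. **Stage one.** Within each APOE group — E2 (epsilon-2/epsilon-2 or
   epsilon-2/epsilon-3), E3 (epsilon-3/epsilon-3), E4
   (epsilon-3/epsilon-4 or epsilon-4/epsilon-4); epsilon-2/epsilon-4
   compound heterozygotes excluded — every SNP is tested against every
   log-transformed metabolite with an additive linear mixed model, and
   discoveries are declared at Benjamini-Hochberg q < 0.05.
2. **Stage two.** For each discovery, the per-group effects are contrasted
   with the 1-df chi-square
   $$\chi^2 = \frac{(b_1 - b_2)^2}{SE_1^2 + SE_2^2}$$
   at a Bonferroni threshold of $\alpha$ divided by the total discovery
   count, corroborated by SNP-by-group interaction models, contrasted
   between sexes, and re-examined in the pooled sample.

Because the motivating cohort data (Framingham Heart Study, dbGaP
restricted) cannot ship with software, the package includes a first-class
synthetic cohort generator that reproduces the statistical structure the
analysis assumes, so every stage can be validated by parameter recovery
against planted ground truth.

## The stage-one model

For a metabolite with concentration $c_i$ in subject $i$ of one stratum,

$$\log c_i = \mathbf{x}_i^\top \beta + g_i \gamma + u_i + e_i,
  \qquad u \sim N(0, \sigma_g^2 K), \quad e \sim N(0, \sigma_e^2 I)$$

where $g_i$ is the minor-allele dosage (0/1/2), $\mathbf{x}_i$ collects the
intercept, sex, birth year, smoking, BMI, DBP, SBP, fasting glucose, TC,
LDL-C, HDL-C, TG, eGFR, AD status and the top five genetic principal
components, and $K$ is the expected relationship matrix ($2\times$ kinship)
from the pedigree. The natural log is used; the base only rescales
$\gamma$, not its p-value.

Fitting follows the mixed-model association convention of large-scale
tools: the variance components are estimated **once per (metabolite,
stratum) under the null** (no SNP) by REML, then held fixed while every SNP
is tested by generalized least squares. The REML problem is reduced to a
one-dimensional search: with the eigendecomposition $K = U D U^\top$, the
rotated model has diagonal covariance $\sigma_e^2(\delta D + I)$ in
$\delta = \sigma_g^2/\sigma_e^2$, the scale and fixed effects profile out
in closed form, and `optimize()` handles $\log\delta \in [-12, 12]$ with an
explicit boundary check at $\delta = 0$. One eigendecomposition per stratum
serves all 217 analytes because the complete-case pattern is shared.

Two numerical choices matter:

* **Per-model scale re-profiling.** The scan fixes only the variance
  *ratio* from the null fit and re-estimates the residual scale per SNP
  model (weighted least squares on the rotated data). This makes the
  degenerate case $K = I$, $\sigma_g^2 = 0$ reduce *exactly* to ordinary
  least squares — the package's strongest correctness anchor, tested to
  1e-8 — while differing from a fixed-scale scan only by an $O(1/n)$
  factor.
* **Wald tests with asymptotic-normal reference**, matching large-sample
  mixed-model practice. At the stratum sizes of interest (>200) the
  difference from a t reference is negligible; very small strata trigger a
  warning (`min_stratum`, default 50).

Eigenvalues of $K$ are clipped at zero (a "small ridge") so that nearly
singular pedigree blocks cannot produce negative weights.

The FDR family is, by default, all SNP x metabolite tests within one
stratum; a per-metabolite family is available
(`fdr_family = "metabolite"`). The published analysis does not state its
choice; the per-stratum family is the more conservative reading and is the
default. Genetic PCs are computed once on the pooled cohort — on founders
only, with relatives projected onto the founder loadings, which prevents
large families from dominating the leading components — and reused across
strata.

## The stage-two contrasts

`contrast_chisq()` implements the displayed statistic exactly as printed;
`find_group_specific()` applies it to the three pairs (E2 vs E3, E4 vs E3,
E2 vs E4) of every deduplicated discovery. The Bonferroni denominator is
the **discovery count across strata** (70 in the motivating study, giving
the printed 7.14E-04), not the SNP count: the study's Methods mention the
SNP count but its Results use 0.05/70, and only the discovery-count
denominator reproduces the printed threshold. Both denominators are
reported (attributes `threshold` and `threshold_snps`).

Interaction corroboration pools the two contrasted strata and adds group,
dosage and dosage-by-group fixed effects to the stage-one model (kinship
from the pooled pedigree subset). A three-level pooled variant would test
a different null; the pairwise model gives one interaction p per contrast,
matching how contrasts are reported. Contrast and interaction p-values are
rank-concordant by construction and this is enforced as a property test
(Spearman correlation > 0.9 over a planted-effect batch).

## What the synthetic cohort emulates

The generator (`simulate_cohort()` and friends) reproduces, under a single
seed that fixes all randomness:

* **Pedigrees**: 450 nuclear families (two founders, offspring count
  1 + min(Poisson(1), 3)), ~1,790 subjects — the scale of the emulated
  cohort's 1,798 analyzed subjects.
* **Regional genotypes**: 94 SNPs in contiguous LD blocks (default 6 SNPs
  per block). Each haplotype carries one latent U(0,1) draw per block; a
  site copies it with probability 1 - `mutation_prob` (default 0.3) or
  draws fresh, and the allele indicator is u < MAF-target. This construction
  hits the target frequencies exactly in expectation, produces positive
  within-block and zero across-block correlation, and degenerates to
  perfect LD at mutation 0 — properties a literal allele-copying model
  cannot deliver jointly. Founder haplotypes are dropped through the
  pedigree without recombination (a ~1 Mb region; a per-meiosis crossover
  probability is available for stress tests), so Mendel errors are zero by
  construction.
* **APOE genotypes**: founder haplotype frequencies (0.08, 0.80, 0.12) for
  epsilon-2/3/4. After excluding epsilon-2/epsilon-4 carriers
  (Hardy-Weinberg mass 2 x 0.08 x 0.12 = 1.92%), the expected group shares
  are E2 13.7%, E3 65.3%, E4 21.0%, matching the emulated cohort's
  234/1,185/379. These frequencies were chosen once from the published
  group counts, which report counts rather than allele frequencies.
* **Covariates**: drawn at the published cohort means/SDs (TC
  203.81 (32.63) mg/dl, etc.); triglycerides log-normal (moment-matched)
  to keep positivity, everything else normal, binaries Bernoulli. Sex
  comes from the pedigree, so founder couples pin the founder sex ratio at
  1/2 and the female-prevalence parameter (0.53) applies to offspring; the
  realized cohort share lies between 0.50 and the parameter. Covariates
  are independent of genotype by default so that null calibration is
  clean; an optional confounding hook shifts mean LDL-C per epsilon-4 copy
  (off by default), emulating the LDL gradient across APOE groups.
* **Metabolites**: 217 analytes (140 lipid / 77 polar — the published
  total is 217 but the split is not stated; the labels only affect
  reporting and enrichment grouping). Log concentration = intercept +
  small nuisance covariate effects + planted stratum-specific SNP effects
  + a family polygenic effect with covariance $\sigma_g^2 K$ + residual.
  Defaults $\sigma_g^2 = \sigma_e^2 = 0.5$ give full siblings a log-scale
  correlation of 0.25 and reproduce the printed standard-error scale
  (~0.15-0.2 per allele copy in the ~234-subject stratum).

What it does **not** emulate: LC/MS measurement artifacts, realistic
metabolite-metabolite correlation networks, population stratification
beyond what the LD blocks induce, X-chromosome inheritance, or assortative
mating. Passing tests therefore demonstrate that the *statistical
machinery* is correct and calibrated under the assumed model — not that
the pipeline is robust to every pathology of real cohort data.

## Quality control

`apply_qc()` applies the published thresholds — MAF >= 1%, exact
Hardy-Weinberg p >= 1E-06, missingness <= 5% (SNPs and subjects), Mendel
error rate <= 2% (SNPs, subjects, families) — in a fixed order: subject
missingness, SNP missingness, MAF, HWE, Mendel by SNP/subject/family, each
recomputed on the survivors of the previous step. The source analysis
states thresholds but not an order; missingness-first mirrors common
practice and stabilizes the MAF/HWE denominators. The HWE exact test uses
probability-mass ordering (two-sided, no mid-p) and is evaluated on
founders only, since relatedness inflates the test. Mendel checks test
both duos and trios; the denominator is the number of (unit, SNP)
combinations with the relevant calls non-missing.

Effect alleles are aligned to the **pooled** minor allele before any scan
(`align_effect_alleles()`), so that $b_1$ and $b_2$ in a contrast count the
same allele; an exact 0.5/0.5 tie keeps the lexicographically smaller
allele and is logged.

## Diagnostics and enrichment

LD is computed on founders (relatedness inflates LD), from phased
haplotypes when available and otherwise by two-locus haplotype-frequency
EM (50 iterations or change < 1e-10); the output matrix carries r-squared
in the lower triangle and D-prime in the upper, the reporting layout of
the motivating study. VIFs regress each dosage on the full covariate set.
CI overlap for metabolite summaries means non-empty interval intersection
of normal-approximation 95% intervals, the informal usage being emulated.

Enrichment is a plain hypergeometric over-representation test against a
user-supplied GMT library. The background metabolome size is an explicit
parameter (default: the union of library members) because the proprietary
background of the web tool used in the motivating study is not
recoverable; its printed enrichment p-values are reproducible only
conditional on that unknown background, and are therefore not reproduced
here.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11, n_lipid = 8, n_polar = 4)
plan <- effect_plan(c("snp_020", "snp_020"), c("pol_001", "pol_001"),
                    c("E2", "E3"), c(0.8, -0.1))
run <- run_pipeline(cfg, plan, gmt = synthetic_gmt())
report(run)
```

On this seed the planted pair is recovered as an E2 discovery
(beta 0.77, SE 0.18 against a truth of 0.8) and its E2-vs-E3 contrast is
flagged at the 7.14E-04 threshold (chi-square 22.7); see the README for
the printed output.

## Problem sizes used in validation

Simulation-backed tests use the full 94-SNP panel and the full ~1,800-
subject cohort but a reduced analyte panel (4-12 metabolites per run):
with planted effects at the published scale the discovery and contrast
behavior is insensitive to the analyte count (which only sets the BH
family size), while per-analyte REML fits dominate runtime. Calibration
tests use 10,000 null tests (contrast size; Wald uniformity under family
structure), parameter recovery uses 20 replicates of 500 sib pairs
(heritability ratio 0.5 recovered within 0.1), and end-to-end recovery
uses 20 seeded cohorts (planted beta_E2 = 0.8 vs beta_E3 = -0.1 flagged in
at least 70% — in practice all — of seeds). Group-share checks average 5
replicates at n ~ 1,798 because a single draw carries ~1.6 points of
Monte-Carlo noise from family clustering.

## Known limitations

* Stage-one SEs come from a scan that fixes the variance ratio at its
  null-model estimate; very strong single-SNP effects slightly inflate the
  ratio's denominator, a standard and conservative approximation.
* The exact HWE test on founders ignores the (slight) information in
  non-founder genotypes.
* The interaction model assumes shared variance components across the two
  pooled strata.
* Genetic PCs from 94 regional SNPs capture regional structure only; in
  the motivating study PCs came from genome-wide data. With the synthetic
  generator's single homogeneous population they are nuisance-only, and
  small marker panels (tests use >= 94 SNPs) would otherwise let the PCs
  absorb appreciable single-SNP variance.
* Monomorphic-in-stratum SNPs yield missing results with a reason rather
  than a numeric placeholder; contrasts involving them are flagged
  untestable.
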