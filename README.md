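# apoemqtl

APOE-allele-stratified SNP–metabolite association and effect-heterogeneity
analysis for family cohorts.

## The problem

Variants in the chromosome 19q13.3 gene cluster around *APOE* (*NECTIN2*,
*TOMM40*, *APOC1/2/4*, *CLPTM1*, *BCL3*, *CKM*, ...) can associate with
plasma metabolite concentrations differently depending on which APOE
ε-alleles a subject carries — heterogeneity that pooled analyses average
away. This package is for statistical geneticists and epidemiologists who
want to run the stratified two-stage design on family data:

1. **Stage one** — within each APOE group (E2 = ε2ε2/ε2ε3, E3 = ε3ε3,
   E4 = ε3ε4/ε4ε4; ε2ε4 excluded), an additive linear mixed model per
   (SNP, metabolite) pair:

   log c = Xβ + g·γ + u + e,  u ~ N(0, σg² K),  e ~ N(0, σe² I)

   with covariate adjustment (sex, birth year, smoking, BMI, blood
   pressure, glucose, lipids, eGFR, AD status, 5 genetic PCs), a pedigree
   kinship random effect K, and Benjamini–Hochberg discovery at
   q < 0.05.

2. **Stage two** — per-discovery cross-group contrasts

   χ² = (b₁ − b₂)² / (SE₁² + SE₂²)  (1 df)

   at a Bonferroni threshold α / (number of discoveries), corroborated by
   SNP×group interaction models, contrasted between sexes, and
   re-examined in the pooled sample.

Because the motivating cohort (Framingham Offspring, dbGaP-restricted)
cannot ship with code, the package includes a full synthetic family-cohort
generator — pedigrees, LD-blocked regional haplotypes, rs429358/rs7412
APOE genotypes, calibrated covariates, metabolites with planted
stratum-specific effects — so every stage is validated by parameter
recovery against known ground truth. Genotype QC (MAF, exact
Hardy–Weinberg, missingness, Mendel errors), LD/VIF diagnostics and
hypergeometric pathway over-representation are included.

## Worked example

Simulate a ~1,750-subject cohort with an E2-specific effect planted at
the scale seen in real stratified analyses (β_E2 = 0.8, β_E3 = −0.1 on
log concentration per minor-allele copy), then run the whole pipeline:

```r
library(apoemqtl)
cfg  <- sim_config(seed = 11, n_lipid = 8, n_polar = 4)
plan <- effect_plan(c("snp_020", "snp_020"), c("pol_001", "pol_001"),
                    c("E2", "E3"), c(0.8, -0.1))
run  <- run_pipeline(cfg, plan, gmt = synthetic_gmt())
report(run)
#> subjects: 1753 (E2/E3/E4 = 257/1137/331)
#> SNPs after QC: 96
#> stage-one discoveries: 2 (E2 1, E3 0, E4 1)
#> group-specific contrasts (Bonferroni): 3
#> interaction corroborations fitted: 3
#> pooled-sample replications: 0
```

The stratum sizes mirror the emulated cohort's 234/1,185/379. The planted
pair is recovered in stage one —

```r
r <- run$scan$results
r[r$snp_id == "snp_020" & r$metabolite_id == "pol_001" & r$stratum == "E2",
  c("beta", "se", "p", "q")]
#>          beta        se            p          q
#> 788 0.7673679 0.1768274 1.427131e-05 0.01626929
```

— an estimate of 0.77 (SE 0.18) against a truth of 0.8, discovered at
q = 0.016. Stage two flags its E2-vs-E3 contrast far beyond the 7.14E−04
threshold, with opposite effect directions in the two groups, and the
interaction model corroborates it:

```r
run$contrasts[run$contrasts$significant,
              c("snp_id", "metabolite_id", "group_a", "group_b", "chi2", "p")]
#>    snp_id metabolite_id group_a group_b     chi2            p
#> 1 snp_020       pol_001      E2      E3 22.67033 1.923150e-06
#> 3 snp_020       pol_001      E2      E4 10.04787 1.525243e-03
#> 5 snp_034       pol_002      E4      E3 18.51798 1.683087e-05

run$interactions[1, ]
#>    snp_id metabolite_id  pair beta_int    se_int        p_int n_used
#> 1 snp_020       pol_001 E2-E3 1.037840 0.1769914 4.524297e-09   1394
```

(The `snp_034` row is a chance discovery in the small E4 stratum — a
reminder of why stage two exists.) The bundled
`published_group_specific()` table carries reported per-group estimates
from a published APOE-stratified Framingham analysis for the worked
contrast examples, e.g. the dimethylglycine E2-vs-E3 contrast:

```r
pub <- published_group_specific()
dmg <- pub[pub$metabolite == "Dimethylglycine", ]
contrast_chisq(dmg$beta_e2, dmg$se_e2, dmg$beta_e3, dmg$se_e3)
#> [1] 20.03889        # printed value from unrounded inputs: 20.013
```

See `vignettes/stratified-metabolite-qtl.Rmd` for the models, the
synthetic generator's design, and the numerical choices.

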