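# Shared simulated cohorts, built once per test run.

.cohort_cache <- new.env()

# Mid-size cohort (~500 subjects, 30 SNPs) for structural tests.
small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    cfg <- sim_config(n_families = 130, n_snps = 30, n_lipid = 12,
                      n_polar = 8, seed = 101)
    plan <- effect_plan(rep("snp_005", 2), rep("pol_002", 2),
                        c("E2", "E3"), c(0.9, -0.1))
    .cohort_cache$small <- simulate_cohort(cfg, plan)
  }
  .cohort_cache$small
}

# Full-scale cohort (~1,800 subjects, 94 SNPs, reduced analyte panel) with
# a planted E2-specific effect at the published effect scale; QC'd and
# effect-allele aligned, ready for association scans.
full_cohort <- function() {
  if (is.null(.cohort_cache$full)) {
    cfg <- sim_config(n_snps = 94, n_lipid = 4, n_polar = 4, seed = 2024)
    plan <- effect_plan(c("snp_020", "snp_020"), c("pol_001", "pol_001"),
                        c("E2", "E3"), c(0.8, -0.1))
    co <- simulate_cohort(cfg, plan)
    qc <- apply_qc(co$genotypes, co$pedigree)
    co$genotypes <- align_effect_alleles(qc$genotypes, co$strata)
    .cohort_cache$full <- co
  }
  .cohort_cache$full
}

full_scan <- function() {
  if (is.null(.cohort_cache$full_scan))
    .cohort_cache$full_scan <- run_stratified_scan(full_cohort())
  .cohort_cache$full_scan
}

# Hand-built four-subject genotype fixture: two founders and two offspring.
toy_genotypes <- function(dosage, n_snps = ncol(dosage)) {
  snps <- data.frame(
    snp_id = paste0("s", seq_len(n_snps)), chromosome = "19",
    position = seq_len(n_snps) * 1000L,
    allele_minor = "A", allele_major = "G",
    gene_label = "GENE", stringsAsFactors = FALSE)
  genotype_matrix(dosage, snps)
}

toy_trio_pedigree <- function(n_extra_founders = 0) {
  ped <- data.frame(
    family_id = "F1",
    individual_id = c("fa", "mo", "kid"),
    father_id = c(NA, NA, "fa"),
    mother_id = c(NA, NA, "mo"),
    sex = c("male", "female", "female"),
    stringsAsFactors = FALSE)
  if (n_extra_founders > 0) {
    extra <- data.frame(
      family_id = paste0("FX", seq_len(n_extra_founders)),
      individual_id = paste0("x", seq_len(n_extra_founders)),
      father_id = NA_character_, mother_id = NA_character_,
      sex = "male", stringsAsFactors = FALSE)
    ped <- rbind(ped, extra)
  }
  ped
}

# Independent step-up BH oracle (direct definition).
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  q <- p[o] * m / seq_along(p)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Exact HWE oracle by explicit enumeration with choose() products.
hwe_oracle <- function(a, h, b) {
  n <- a + h + b
  n_minor <- 2 * b + h
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  prob <- sapply(hets, function(hh) {
    bb <- (n_minor - hh) / 2
    aa <- n - hh - bb
    # multinomial genotype count x 2^het over constant allele-permutation term
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(hh) - lfactorial(bb) +
          hh * log(2))
  })
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(h, hets)] * (1 + 1e-12)])
}
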