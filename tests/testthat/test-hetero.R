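test_that("the heterogeneity chi-square reproduces reported statistics", {
  pub <- published_group_specific()
  dmg <- pub[pub$metabolite == "Dimethylglycine", ]
  chi_dmg <- contrast_chisq(dmg$beta_e2, dmg$se_e2, dmg$beta_e3, dmg$se_e3)
  expect_lt(abs(chi_dmg - dmg$chi2_1) / dmg$chi2_1, 0.003)  # 20.013 printed
  prop <- pub[pub$metabolite == "Propionate", ]
  chi_prop <- contrast_chisq(prop$beta_e4, prop$se_e4,
                             prop$beta_e3, prop$se_e3)
  expect_lt(abs(chi_prop - prop$chi2_2) / prop$chi2_2, 0.003)  # 11.716

  expect_equal(contrast_chisq(0.5, 0.1, 0.5, 0.2), 0)
  expect_equal(contrast_chisq(1.0, 0.5, 0.0, 0.5), 2.0)
  # symmetric in the two groups, exactly
  expect_identical(contrast_chisq(0.813, 0.196, -0.102, 0.058),
                   contrast_chisq(-0.102, 0.058, 0.813, 0.196))
  expect_error(contrast_chisq(1, 0, 0, 1), "input")
})

test_that("df-1 tail probabilities match the normal identity and reports", {
  x <- seq(0, 40, by = 0.25)
  expect_equal(chisq_pvalue_df1(x), 2 * (1 - pnorm(sqrt(x))),
               tolerance = 1e-12)
  expect_equal(chisq_pvalue_df1(0), 1)
  # printed chi-square / p pairs from the reported contrast tables
  pub <- published_group_specific()
  chis <- c(pub$chi2_1, pub$chi2_2)
  ps <- c(pub$p_1, pub$p_2)
  expect_equal(chisq_pvalue_df1(chis), ps, tolerance = 5e-3)
  expect_error(chisq_pvalue_df1(-1), "input")
})

test_that("Bonferroni thresholds divide the level by the family size", {
  expect_equal(bonferroni_threshold(0.05, 70), 7.142857e-4,
               tolerance = 1e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "input")
})

test_that("group-specific detection flags the reported heterogeneity pattern", {
  # stage-one results seeded with the reported dimethylglycine estimates
  pub <- published_group_specific()
  dmg <- pub[pub$metabolite == "Dimethylglycine", ]
  res <- data.frame(
    stratum = c("E2", "E3", "E4"), snp_id = dmg$snp_id,
    metabolite_id = "dimethylglycine",
    beta = c(dmg$beta_e2, dmg$beta_e3, dmg$beta_e4),
    se = c(dmg$se_e2, dmg$se_e3, dmg$se_e4),
    p = c(3.36e-5, 8.06e-2, 7.14e-2), n_used = c(234, 1185, 379),
    reason = NA_character_, stringsAsFactors = FALSE)
  disc <- res[1, ]
  disc$q <- 0.01
  scan <- structure(list(results = res, discoveries = disc, fdr = 0.05),
                    class = "stratified_scan")
  gs <- find_group_specific(scan, alpha = 0.05, m = 70)
  expect_equal(attr(gs, "threshold"), 0.05 / 70)
  e2e3 <- gs[gs$group_a == "E2" & gs$group_b == "E3", ]
  expect_true(e2e3$significant)
  expect_true(e2e3$opposite_direction)
  expect_lt(abs(e2e3$chi2 - 20.013) / 20.013, 0.003)
  # E2 vs E4 contrast (9.778 printed) is not Bonferroni-significant at /70
  e2e4 <- gs[gs$group_a == "E2" & gs$group_b == "E4", ]
  expect_false(e2e4$significant)
  expect_true(e2e4$nominal)

  # identical estimates in all strata: nothing significant
  res2 <- res
  res2$beta <- 0.2; res2$se <- 0.05
  scan2 <- structure(list(results = res2, discoveries = disc, fdr = 0.05),
                     class = "stratified_scan")
  gs2 <- find_group_specific(scan2, alpha = 0.05, m = 70)
  expect_true(all(gs2$chi2 == 0))
  expect_false(any(gs2$significant))

  # a stratum with no estimate makes that contrast untestable
  res3 <- res[res$stratum != "E4", ]
  scan3 <- structure(list(results = res3, discoveries = disc, fdr = 0.05),
                     class = "stratified_scan")
  gs3 <- find_group_specific(scan3, alpha = 0.05, m = 70)
  expect_true(all(gs3$untestable[gs3$group_b == "E4" |
                                   gs3$group_a == "E4"]))
})

test_that("the contrast test holds its nominal type-I error", {
  set.seed(314)
  n_sim <- 10000
  se1 <- 0.2; se2 <- 0.08
  b1 <- rnorm(n_sim, 0, se1)
  b2 <- rnorm(n_sim, 0, se2)
  p <- chisq_pvalue_df1(contrast_chisq(b1, se1, b2, se2))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.044)
  expect_lte(rate, 0.056)
})

test_that("interaction models corroborate planted effect differences", {
  co <- full_cohort()
  it <- interaction_test(co, co$strata, pair = c("E2", "E3"),
                         snp_id = "snp_020", metabolite_id = "pol_001")
  # planted difference 0.8 - (-0.1) = 0.9
  expect_lt(abs(it$beta_int - 0.9), 3 * it$se_int)
  expect_lt(it$p_int, 7.14e-4)
  # relabeling the groups negates the coefficient, keeps the p-value
  it_sw <- interaction_test(co, co$strata, pair = c("E3", "E2"),
                            snp_id = "snp_020", metabolite_id = "pol_001")
  expect_equal(it_sw$beta_int, -it$beta_int, tolerance = 1e-8)
  expect_equal(it_sw$p_int, it$p_int, tolerance = 1e-8)
  # a pair with no planted difference: interaction consistent with zero
  it0 <- interaction_test(co, co$strata, pair = c("E4", "E3"),
                          snp_id = "snp_040", metabolite_id = "lip_002")
  expect_lt(abs(it0$beta_int), 3.5 * it0$se_int)
})

test_that("contrast and interaction p-values agree in rank", {
  # batch of pairs with graded planted E2-vs-E3 effect differences, so the
  # two corroborating tests must order them the same way
  betas <- seq(0, 1.1, by = 0.1)
  snps <- sprintf("snp_%03d", seq(7, 84, by = 7))
  mets <- c(sprintf("lip_%03d", 1:6), sprintf("pol_%03d", 1:6))
  cfg <- sim_config(n_snps = 94, n_lipid = 6, n_polar = 6,
                    maf_targets = rep(0.3, 94), seed = 777)
  plan <- effect_plan(snps, mets, rep("E2", 12), betas)
  co <- simulate_cohort(cfg, plan)
  qc <- apply_qc(co$genotypes, co$pedigree)
  co$genotypes <- align_effect_alleles(qc$genotypes, co$strata)
  sc <- run_stratified_scan(co)
  res <- sc$results
  pcs <- genotype_pcs(co$genotypes, k = 5, pedigree = co$pedigree)
  p_contrast <- p_int <- numeric(0)
  for (i in seq_along(snps)) {
    a <- res[res$snp_id == snps[i] & res$metabolite_id == mets[i] &
               res$stratum == "E2", ]
    b <- res[res$snp_id == snps[i] & res$metabolite_id == mets[i] &
               res$stratum == "E3", ]
    if (is.na(a$beta) || is.na(b$beta)) next
    p_contrast <- c(p_contrast,
                    chisq_pvalue_df1(contrast_chisq(a$beta, a$se,
                                                    b$beta, b$se)))
    it <- interaction_test(co, co$strata, pair = c("E2", "E3"),
                           snp_id = snps[i], metabolite_id = mets[i],
                           pcs = pcs)
    p_int <- c(p_int, it$p_int)
  }
  expect_gte(length(p_contrast), 10)
  expect_gt(cor(p_contrast, p_int, method = "spearman"), 0.9)
})

test_that("sex contrasts flag only subgroup-specific effects", {
  co <- full_cohort()
  targets <- data.frame(snp_id = "snp_020", metabolite_id = "pol_001",
                        stratum = "E2", stringsAsFactors = FALSE)
  sx <- sex_contrast(co, co$strata, targets, n_pcs = 2)
  expect_false(sx$untestable)
  # the planted effect is sex-homogeneous: no significance beyond chance
  expect_gt(sx$p, 1e-4)
  # tiny subgroup bound flags untestable
  sx2 <- sex_contrast(co, co$strata, targets, min_subgroup = 1e5)
  expect_true(sx2$untestable)
})

test_that("pooled re-analysis gains power for homogeneous effects and loses
           it under effect cancellation", {
  cfg <- sim_config(n_snps = 94, n_lipid = 2, n_polar = 2, seed = 3001)
  plan <- effect_plan(
    c("snp_030", "snp_060", "snp_060"),
    c("pol_001", "pol_002", "pol_002"),
    c("all", "E2", "E4"),
    c(0.25, 0.8, -0.8))
  co <- simulate_cohort(cfg, plan)
  qc <- apply_qc(co$genotypes, co$pedigree)
  co$genotypes <- align_effect_alleles(qc$genotypes, co$strata)
  sc <- run_stratified_scan(co)
  pl <- pooled_scan(co, co$strata, discoveries = sc$discoveries)
  res_p <- pl$results
  # homogeneous effect: pooled p beats the best stratum p (larger n)
  p_pool <- res_p$p[res_p$snp_id == "snp_030" &
                      res_p$metabolite_id == "pol_001"]
  p_strata <- sc$results$p[sc$results$snp_id == "snp_030" &
                             sc$results$metabolite_id == "pol_001"]
  expect_lt(p_pool, min(p_strata, na.rm = TRUE))
  # opposite-sign effects cancel in the pool
  p_pool2 <- res_p$p[res_p$snp_id == "snp_060" &
                       res_p$metabolite_id == "pol_002"]
  p_e2 <- sc$results$p[sc$results$snp_id == "snp_060" &
                         sc$results$metabolite_id == "pol_002" &
                         sc$results$stratum == "E2"]
  expect_gt(p_pool2, p_e2)
  # empty discovery set yields an empty overlap report
  pl0 <- pooled_scan(co, co$strata,
                     discoveries = sc$discoveries[0, , drop = FALSE])
  expect_equal(nrow(pl0$overlap), 0)
})
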