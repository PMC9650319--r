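test_that("pedigree simulation produces nuclear families deterministically", {
  cfg <- sim_config(n_families = 1, offspring_lambda = 0, offspring_min = 2,
                    offspring_max = 2, seed = 5)
  ped <- simulate_pedigrees(cfg)
  expect_equal(nrow(ped), 4)
  expect_equal(sum(is.na(ped$father_id) & is.na(ped$mother_id)), 2)
  expect_silent(validate_pedigree(ped))

  cfg2 <- sim_config(n_families = 600, seed = 9)
  ped2 <- simulate_pedigrees(cfg2)
  # expected size 600 * (2 + E[1 + min(Pois(1), 3)]) ~ 600 * 3.98; the
  # oracle is the direct count of the realized draw
  n_off <- nrow(ped2) - 2 * 600
  expect_equal(nrow(ped2), 1200 + n_off)
  expect_gt(nrow(ped2), 600 * 3.7)
  expect_lt(nrow(ped2), 600 * 4.3)

  expect_identical(simulate_pedigrees(cfg2), ped2)
  expect_error(sim_config(n_families = 0), "configuration")
})

test_that("founder haplotypes hit MAF targets with block-local LD", {
  # degenerate block: zero mutation, equal targets -> r^2 = 1 pairwise
  cfg <- sim_config(n_families = 50, n_snps = 4, block_size = 4,
                    mutation_prob = 0, maf_targets = rep(0.3, 4),
                    n_haplotypes = 400, seed = 2)
  H <- simulate_founder_haplotypes(cfg)$haplotypes
  expect_true(all(abs(cor(H)) > 0.999))

  # two blocks of 5: across-block r^2 vanishes, realized MAF near target
  cfg2 <- sim_config(n_families = 500, n_snps = 10, block_size = 5,
                     maf_targets = rep(0.3, 10), n_haplotypes = 2000,
                     seed = 3)
  pool <- simulate_founder_haplotypes(cfg2)
  H2 <- pool$haplotypes
  r2 <- cor(H2)^2
  across <- r2[1:5, 6:10]
  expect_lt(mean(across), 0.01)
  within <- r2[1:5, 1:5][upper.tri(diag(5))]
  expect_gt(mean(within), 0.1)
  freqs <- colMeans(H2)
  expect_true(all(freqs > 0.25 & freqs < 0.35))
  expect_true(all(abs(freqs - pool$maf_targets) < 0.05))
  expect_error(sim_config(n_snps = 2, maf_targets = c(0.3, 1.2)),
               "configuration")
})

test_that("gene dropping transmits Mendelianly and matches pedigree kinship", {
  co <- small_cohort()
  # zero Mendel errors by construction
  m <- compute_qc_metrics(co$genotypes, co$pedigree)
  expect_true(all(m$mendel$snp == 0))
  expect_true(all(m$mendel$subject == 0))
  expect_true(all(m$mendel$family == 0))

  # forced transmission: both parents homozygous reference -> offspring too
  ped <- toy_trio_pedigree()
  pool <- structure(list(
    haplotypes = matrix(0L, 4, 3,
                        dimnames = list(NULL, paste0("snp_00", 1:3))),
    ld_blocks = list(1:3), maf_targets = rep(0.1, 3)),
    class = "haplotype_pool")
  g <- gene_drop(ped, pool, sim_config(n_families = 1, seed = 1))
  expect_true(all(g$dosage == 0))

  # empirical relatedness of dosages converges to pedigree 2*Phi
  cfg <- sim_config(n_families = 150, n_snps = 500, block_size = 1, seed = 8)
  co2 <- simulate_cohort(cfg)
  K_emp <- empirical_grm(co2$genotypes)
  K_ped <- pedigree_kinship(co2$pedigree)
  rel <- K_ped[upper.tri(K_ped)]
  emp <- K_emp[upper.tri(K_emp)]
  expect_lt(abs(mean(emp[rel == 0.5]) - 0.5), 0.05)   # parent-offspring/sibs
  expect_lt(abs(mean(emp[rel == 0])), 0.05)           # unrelated
})

test_that("APOE simulation reproduces expected group shares", {
  # degenerate frequencies: everyone epsilon-3 homozygous
  cfg0 <- sim_config(n_families = 40, apoe_hap_freqs = c(0, 1, 0), seed = 4)
  ped0 <- simulate_pedigrees(cfg0)
  st0 <- assign_apoe_groups(simulate_apoe(ped0, cfg0))
  expect_true(all(st0$stratum == "E3"))

  # default frequencies at the emulated cohort scale: shares match the
  # renormalized multinomial expectation (E2 13.7%, E3 65.3%, E4 21.0%)
  co <- small_cohort()
  big <- simulate_cohort(sim_config(seed = 31))
  tt <- table(big$strata$stratum)
  analyzed <- sum(tt[c("E2", "E3", "E4")])
  shares <- 100 * tt[c("E2", "E3", "E4")] / analyzed
  expect_lt(abs(shares[["E2"]] - 13.7), 2)
  # family clustering widens the sampling noise of the larger groups
  expect_lt(abs(shares[["E3"]] - 65.3), 3.5)
  expect_lt(abs(shares[["E4"]] - 21.0), 3.5)
  # epsilon-2/epsilon-4 exclusion mass: 2 * 0.08 * 0.12 = 1.92% expected
  excl <- big$strata
  e2e4 <- mean(excl$reason == "e2e4", na.rm = FALSE)
  expect_lt(abs(sum(excl$reason == "e2e4", na.rm = TRUE) /
                  nrow(excl) - 0.0192), 0.012)
  expect_error(sim_config(apoe_hap_freqs = c(0.5, 0.4, 0.2)),
               "configuration")
})

test_that("covariates are calibrated to the configured moments", {
  co <- simulate_cohort(sim_config(seed = 17))
  cv <- co$covariates
  n <- nrow(cv)
  expect_lt(abs(mean(cv$TC) - 203.81), 2)       # SE = 32.63 / sqrt(n) ~ 0.77
  expect_lt(abs(mean(cv$LDLC) - 128.07), 2)
  expect_true(mean(cv$female) > 0.50 && mean(cv$female) < 0.56)
  expect_true(all(cv$TG > 0))
  expect_lt(abs(mean(cv$TG) - 119.57), 6)

  # zero-SD parameter gives a constant column
  cp <- apoemqtl:::default_covariate_params()
  cp$continuous$sd[cp$continuous$name == "BMI"] <- 0
  cfg <- sim_config(n_families = 30, covariate_params = cp, seed = 1)
  ped <- simulate_pedigrees(cfg)
  cv2 <- simulate_covariates(ped, cfg)
  expect_equal(length(unique(cv2$BMI)), 1)

  cp$continuous <- cp$continuous[cp$continuous$name != "TC", ]
  expect_error(simulate_covariates(ped, sim_config(n_families = 30,
                                                   covariate_params = cp)),
               "configuration")
})

test_that("metabolites are positive with the planted covariance structure", {
  co <- small_cohort()
  expect_true(all(co$metabolites$values > 0))
  expect_equal(nrow(co$metabolites$annotation), 20)
  expect_equal(sum(co$metabolites$annotation$class == "lipid"), 12)

  # null analytes under sigma_g2 = 0: i.i.d. log-normal, slope ~ 0
  cfg <- sim_config(n_families = 200, n_snps = 10, n_lipid = 3, n_polar = 3,
                    sigma_g2 = 0, seed = 23)
  co0 <- simulate_cohort(cfg)
  lv <- log(co0$metabolites$values)
  sl <- summary(lm(lv[, 1] ~ co0$genotypes$dosage[, 3]))$coefficients[2, ]
  expect_lt(abs(sl[1]), 3 * sl[2])

  # full siblings share half the family variance: corr ~ 0.25 at 0.5/0.5
  big <- simulate_cohort(sim_config(n_lipid = 20, n_polar = 20, seed = 29))
  ped <- big$pedigree
  lv2 <- log(big$metabolites$values)
  sibs <- do.call(rbind, lapply(split(ped, ped$family_id), function(f) {
    k <- f$individual_id[!is.na(f$father_id)]
    if (length(k) >= 2) t(utils::combn(k, 2)) else NULL
  }))
  r <- mean(vapply(seq_len(ncol(lv2)), function(j)
    cor(lv2[sibs[, 1], j], lv2[sibs[, 2], j]), numeric(1)))
  expect_lt(abs(r - 0.25), 0.07)

  expect_error(
    simulate_metabolites(co$genotypes, co$covariates, co$strata,
                         effect_plan("no_such_snp", "lip_001", "E2", 1),
                         co$config, co$pedigree),
    "configuration")
})

test_that("effect plans reject inconsistent entries", {
  expect_error(effect_plan("s1", "m1", "everyone", 1), "configuration")
  expect_error(effect_plan(c("s1", "s1"), c("m1", "m1"), c("E2", "E2"),
                           c(1, 2)), "duplicate")
  expect_error(effect_plan(c("s1", "s1"), c("m1", "m1"), c("all", "E2"),
                           c(1, 2)), "coexist")
})

test_that("fixtures round-trip losslessly and are reproducible", {
  co <- simulate_cohort(
    sim_config(n_families = 25, n_snps = 8, n_lipid = 3, n_polar = 2,
               seed = 77),
    effect_plan("snp_002", "lip_001", "E3", 0.4))
  d1 <- withr::local_tempdir()
  write_fixture(co, d1)
  fx <- read_fixture(d1)
  expect_identical(unname(fx$genotypes$dosage), unname(co$genotypes$dosage))
  expect_equal(fx$genotypes$snps$snp_id, co$genotypes$snps$snp_id)
  # .map rows = regional SNPs + rs429358 + rs7412
  expect_equal(nrow(read.table(file.path(d1, "cohort.map"))), 8 + 2)
  expect_equal(nrow(fx$plan), nrow(co$plan))
  expect_equal(fx$metabolites$values, co$metabolites$values,
               tolerance = 1e-12)

  # identical config (incl. seed) -> byte-identical fixtures
  co2 <- simulate_cohort(
    sim_config(n_families = 25, n_snps = 8, n_lipid = 3, n_polar = 2,
               seed = 77),
    effect_plan("snp_002", "lip_001", "E3", 0.4))
  d2 <- withr::local_tempdir()
  write_fixture(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
})
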