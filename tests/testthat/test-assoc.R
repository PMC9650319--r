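test_that("log transform is exact and refuses non-positive values", {
  panel <- structure(list(
    values = matrix(c(1, exp(2), 4, 9), 2, 2,
                    dimnames = list(c("a", "b"), c("m1", "m2"))),
    annotation = data.frame(metabolite_id = c("m1", "m2"),
                            class = c("lipid", "polar"))),
    class = "metabolite_panel")
  lg <- log_transform(panel)
  expect_equal(lg$values["a", "m1"], 0)
  expect_equal(lg$values["b", "m1"], 2)
  panel$values[1, 2] <- 0
  expect_error(log_transform(panel), "m2")
})

test_that("pedigree kinship reproduces textbook and Monte-Carlo values", {
  ped <- data.frame(
    family_id = "F",
    individual_id = c("gf", "gm", "fa", "mo", "k1", "k2", "mo2", "h1"),
    father_id = c(NA, NA, "gf", NA, "fa", "fa", NA, "fa"),
    mother_id = c(NA, NA, "gm", NA, "mo", "mo", NA, "mo2"),
    sex = c("male", "female", "male", "female", "female", "male",
            "female", "male"),
    stringsAsFactors = FALSE)
  K <- pedigree_kinship(ped)
  expect_equal(K["fa", "k1"], 0.5)    # parent-offspring
  expect_equal(K["k1", "k2"], 0.5)    # full siblings
  expect_equal(K["k1", "h1"], 0.25)   # half siblings
  expect_equal(K["gf", "k1"], 0.25)   # grandparent
  expect_equal(unname(diag(K)), rep(1, 8))

  # Monte-Carlo identity-by-descent oracle: drop founder alleles 1e5 times
  set.seed(7)
  R <- 1e5
  ord <- apoemqtl:::pedigree_order(ped)
  idx <- setNames(seq_len(nrow(ped)), ped$individual_id)
  A1 <- A2 <- matrix(0L, R, nrow(ped))
  lab <- 0L
  for (i in ord) {
    if (is.na(ped$father_id[i])) {
      A1[, i] <- lab + 1L; A2[, i] <- lab + 2L; lab <- lab + 2L
    } else {
      fa <- idx[[ped$father_id[i]]]; mo <- idx[[ped$mother_id[i]]]
      pick <- runif(R) < 0.5
      A1[, i] <- ifelse(pick, A1[, fa], A2[, fa])
      pick <- runif(R) < 0.5
      A2[, i] <- ifelse(pick, A1[, mo], A2[, mo])
    }
  }
  for (pair in list(c("fa", "k1"), c("k1", "k2"), c("k1", "h1"),
                    c("gf", "k2"))) {
    i <- idx[[pair[1]]]; j <- idx[[pair[2]]]
    phi <- mean((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                  (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])) / 4
    expect_lt(abs(2 * phi - K[pair[1], pair[2]]), 0.01)
  }

  bad <- ped
  bad$father_id[1] <- "k1"; bad$mother_id[1] <- "gm"
  expect_error(pedigree_kinship(bad), "structural|cycle")
})

test_that("empirical GRM matches its definition", {
  set.seed(5)
  d <- matrix(rbinom(200 * 50, 2, 0.4), 200, 50,
              dimnames = list(paste0("s", 1:200), NULL))
  d[200, ] <- d[199, ]  # duplicate individual
  g <- toy_genotypes(d, 50)
  G <- empirical_grm(g)
  expect_equal(G[199, 200], G[199, 199], tolerance = 1e-9)
  expect_true(isSymmetric(G))
  # single-SNP matrix equals the standardized outer product
  g1 <- toy_genotypes(d[, 1:2, drop = FALSE], 2)
  G1 <- empirical_grm(g1)
  f <- colMeans(d[, 1:2]) / 2
  Z <- sweep(d[, 1:2], 2, 2 * f) %*% diag(1 / sqrt(2 * f * (1 - f)))
  expect_equal(unname(G1), unname(tcrossprod(Z) / 2), tolerance = 1e-12)
  # unrelated founders concentrate near zero off-diagonal
  co <- simulate_cohort(sim_config(n_families = 150, n_snps = 500,
                                   block_size = 1, seed = 12))
  founders <- co$pedigree$individual_id[
    is.na(co$pedigree$father_id)]
  Gf <- empirical_grm(co$genotypes)[founders, founders]
  off <- Gf[upper.tri(Gf)]
  expect_lt(max(abs(off)), 0.35)
  expect_lt(mean(abs(off)), 0.06)
})

test_that("genotype PCs are founder-anchored, orthogonal and sign-fixed", {
  co <- small_cohort()
  pcs <- genotype_pcs(co$genotypes, k = 3, pedigree = co$pedigree)
  founders <- co$pedigree$individual_id[is.na(co$pedigree$father_id)]
  G <- crossprod(pcs[founders, ])
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))

  # rank-1 case: single polymorphic SNP -> PC1 is an affine map of dosage
  set.seed(2)
  d <- cbind(rbinom(100, 2, 0.5), 1L)
  d[1, 2] <- 0L  # second SNP nearly constant; keep matrix rank 2
  rownames(d) <- paste0("s", 1:100)
  sc <- genotype_pcs(toy_genotypes(d, 2), k = 1)
  expect_gt(abs(cor(sc[, 1], d[, 1])), 0.99)

  # two divergent ancestry clusters separate on PC1
  set.seed(3)
  n <- 200; S <- 60
  grp <- rep(0:1, each = n / 2)
  maf <- cbind(runif(S, 0.05, 0.25), runif(S, 0.55, 0.85))
  d2 <- sapply(seq_len(S), function(j) rbinom(n, 2, maf[j, grp + 1]))
  rownames(d2) <- paste0("i", 1:n)
  sc2 <- genotype_pcs(toy_genotypes(d2, S), k = 2)
  expect_gt(abs(cor(sc2[, 1], grp)), 0.9)

  expect_error(genotype_pcs(toy_genotypes(d, 2), k = 5), "rank")
})

test_that("REML reduces to OLS when kinship is the identity", {
  set.seed(11)
  n <- 120
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  y <- drop(X %*% c(1, 0.5, 0, -0.2)) + rnorm(n)
  K <- diag(n)
  fit <- fit_null_reml(y, X, K)
  expect_true(fit$converged)
  # with K = I the total variance is identified, not the split
  expect_equal(fit$sigma_g2 + fit$sigma_e2,
               summary(lm(y ~ X[, -1]))$sigma^2, tolerance = 1e-6)

  # SNP scan with the ratio pinned at zero matches closed-form OLS
  d <- matrix(rbinom(n * 8, 2, 0.3), n, 8,
              dimnames = list(paste0("s", 1:n), NULL))
  g <- toy_genotypes(d, 8)
  fit0 <- fit
  fit0$delta <- 0
  fit0$rotation$weights <- rep(1, n)
  sc <- snp_scan(fit0, g)
  for (j in 1:8) {
    co <- summary(lm(y ~ X[, -1] + d[, j]))$coefficients
    expect_equal(sc$beta[j], co[5, 1], tolerance = 1e-8)
    expect_equal(sc$se[j], co[5, 2], tolerance = 1e-8)
  }

  # degenerate response: zero residual variance is flagged
  y0 <- drop(X %*% c(1, 2, 3, 4))
  fit_bad <- fit_null_reml(y0, X, K)
  expect_false(fit_bad$converged)
})

test_that("allele flips negate betas and preserve inference exactly", {
  set.seed(21)
  n <- 150
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  K <- diag(n)
  d <- matrix(rbinom(n * 3, 2, 0.4), n, 3,
              dimnames = list(paste0("s", 1:n), NULL))
  fit <- fit_null_reml(y, X, K)
  sc1 <- snp_scan(fit, toy_genotypes(d, 3))
  sc2 <- snp_scan(fit, toy_genotypes(2L - d, 3))
  expect_equal(sc1$beta, -sc2$beta, tolerance = 1e-12)
  expect_equal(sc1$se, sc2$se, tolerance = 1e-12)
  expect_equal(sc1$p, sc2$p, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.04), 4),
               c(0.004, 0.02, 0.02667, 0.04), tolerance = 1e-3)
  expect_equal(bh_fdr(rep(0.05, 3), 3), rep(0.05, 3))
  expect_equal(bh_fdr(0.013), 0.013)
  set.seed(9)
  for (i in 1:40) {
    len <- sample(1:50, 1)
    p <- runif(len)
    m <- len + sample(0:5, 1)
    expect_equal(bh_fdr(p, m), bh_oracle(p, m), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "input")
  expect_error(bh_fdr(runif(10), m = 5), "input")
})

test_that("Wald tests are calibrated under the family-structured null", {
  # 10,000 null tests on a cohort with real family structure: the kinship
  # random effect must absorb the family confounding
  cfg <- sim_config(n_families = 100, n_snps = 100, n_lipid = 50,
                    n_polar = 50, block_size = 1, seed = 606)
  co <- simulate_cohort(cfg)
  ids <- co$pedigree$individual_id
  K <- pedigree_kinship(co$pedigree)
  eig <- apoemqtl:::kinship_eigen(K)
  X <- cbind(1, co$covariates$female, scale(co$covariates$BMI))
  rownames(X) <- ids
  lv <- log(co$metabolites$values)
  ps <- unlist(lapply(seq_len(ncol(lv)), function(j) {
    fit <- fit_null_reml(lv[, j], X, K, eig = eig)
    snp_scan(fit, co$genotypes)$p
  }))
  ps <- ps[!is.na(ps)]
  expect_gte(length(ps), 10000)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("stratified scans are deterministic and recover planted effects", {
  sc <- full_scan()
  co <- full_cohort()
  r <- sc$results
  planted <- r[r$snp_id == "snp_020" & r$metabolite_id == "pol_001", ]
  b_e2 <- planted[planted$stratum == "E2", ]
  expect_lt(abs(b_e2$beta - 0.8), 3 * b_e2$se)  # parameter recovery
  # the planted pair is an E2 discovery and not an E3 discovery
  disc_key <- paste(sc$discoveries$stratum, sc$discoveries$snp_id,
                    sc$discoveries$metabolite_id)
  expect_true("E2 snp_020 pol_001" %in% disc_key)
  expect_false("E3 snp_020 pol_001" %in% disc_key)
  # q is a valid BH adjustment within the stratum family
  e2 <- r[r$stratum == "E2" & !is.na(r$p), ]
  expect_equal(e2$q, bh_oracle(e2$p), tolerance = 1e-12)
  expect_true(all(r$q >= r$p, na.rm = TRUE))

  sc2 <- run_stratified_scan(co)
  expect_identical(sc$results, sc2$results)
})
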