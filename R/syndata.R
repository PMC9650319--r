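# Synthetic family-cohort generator: nuclear-family pedigrees, block-LD
# regional haplotypes, APOE-defining SNPs, Table-1-calibrated covariates and
# log-normal metabolites with planted stratum-specific SNP effects.

# Genes of the 19q13.3 cluster used to label simulated markers.
REGION_GENES <- c(
  "CEACAM22P", "BCL3", "CBLC", "BCAM", "NECTIN2", "TOMM40", "APOE",
  "APOC1", "APOC1P1", "APOC4", "APOC2", "CLPTM1", "RELB", "CLASRP",
  "ZNF296", "GEMIN7", "PPP1R37", "NKPD1", "TRAPPC6A", "BLOC1S3",
  "EXOC3L2", "CKM", "KLC3", "ERCC2", "PPP1R13L", "CD3EAP", "ERCC1",
  "FOSB", "RTN2", "PPM1N", "VASP", "OPA3", "EML2", "GIPR", "SNRPD2",
  "QPCTL", "FBXO46", "SIX5", "DMPK", "DMWD", "RSPH6A"
)

default_covariate_params <- function() {
  list(
    continuous = data.frame(
      name = c("birth_year", "FBG", "TC", "LDLC", "HDLC", "TG",
               "BMI", "DBP", "SBP", "eGFR"),
      mean = c(1935.12, 95.97, 203.81, 128.07, 50.42, 119.57,
               26.28, 77.36, 122.79, 66.46),
      sd = c(9.66, 20.07, 32.63, 31.61, 12.95, 77.04,
             4.38, 7.97, 13.74, 21.54),
      dist = c("normal", "normal", "normal", "normal", "normal", "lognormal",
               "normal", "normal", "normal", "normal"),
      stringsAsFactors = FALSE
    ),
    binary = data.frame(
      name = c("female", "smoker", "ad"),
      prevalence = c(0.53, 0.614, 0.0434),
      stringsAsFactors = FALSE
    )
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic family-cohort
#' generator. Defaults emulate the cohort the analysis is designed for:
#' ~1,800 subjects of a family-based study in nuclear families, 94 regional
#' SNPs in LD blocks around the APOE gene cluster, APOE haplotype
#' frequencies reproducing observed E2/E3/E4 group shares, covariates
#' calibrated to published cohort means/SDs, and 217 metabolites (140 lipid,
#' 77 polar) with log-scale family and residual variance components.
#'
#' @param n_families number of nuclear families (two founder parents each).
#' @param offspring_lambda,offspring_min,offspring_max offspring count per
#'   family is `min(offspring_min + Poisson(offspring_lambda), offspring_max)`.
#' @param n_snps number of regional SNPs (APOE-defining rs429358/rs7412 are
#'   simulated separately and appended).
#' @param block_size target LD-block length in SNPs.
#' @param mutation_prob per-site probability that a haplotype draws its
#'   allele independently of the block latent rather than copying it;
#'   0 gives perfect within-block correlation, 1 gives linkage equilibrium.
#' @param maf_targets per-SNP minor-allele frequency targets in (0, 1);
#'   default drawn uniformly in [0.05, 0.5] under the seed.
#' @param n_haplotypes founder haplotype pool size; default `4 * n_families`
#'   (two haplotypes per founder).
#' @param apoe_hap_freqs frequencies of the epsilon-2/3/4 APOE haplotypes,
#'   summing to 1. The default (0.08, 0.80, 0.12) reproduces observed
#'   post-exclusion group shares E2 ~ 13.7%, E3 ~ 65.3%, E4 ~ 21.0%.
#' @param recomb_prob probability of a single crossover per transmitted
#'   regional haplotype (default 0: no recombination within the ~1 Mb
#'   region).
#' @param sigma_g2,sigma_e2 additive-family and residual variance components
#'   of log metabolite concentrations.
#' @param n_lipid,n_polar number of lipid and polar analytes (140 + 77).
#' @param covariate_params list with `continuous` (name/mean/sd/dist) and
#'   `binary` (name/prevalence) data frames; see
#'   `apoemqtl:::default_covariate_params`.
#' @param apoe_ldl_shift optional confounding hook: added to mean LDL-C per
#'   epsilon-4 haplotype copy (and subtracted per epsilon-2 copy). Off (0)
#'   by default so that null calibration is clean.
#' @param seed integer fixing all downstream randomness.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_families = 450,
                       offspring_lambda = 1,
                       offspring_min = 1,
                       offspring_max = 4,
                       n_snps = 94,
                       block_size = 6,
                       mutation_prob = 0.3,
                       maf_targets = NULL,
                       n_haplotypes = NULL,
                       apoe_hap_freqs = c(e2 = 0.08, e3 = 0.80, e4 = 0.12),
                       recomb_prob = 0,
                       sigma_g2 = 0.5,
                       sigma_e2 = 0.5,
                       n_lipid = 140,
                       n_polar = 77,
                       covariate_params = default_covariate_params(),
                       apoe_ldl_shift = 0,
                       seed = 1L) {
  if (length(n_families) != 1 || is.na(n_families) || n_families < 1)
    stop_config("n_families must be a positive count")
  if (n_snps < 1) stop_config("n_snps must be >= 1")
  if (length(apoe_hap_freqs) != 3 || any(apoe_hap_freqs < 0) ||
      abs(sum(apoe_hap_freqs) - 1) > 1e-9)
    stop_config("apoe_hap_freqs must be three non-negative frequencies summing to 1")
  if (sigma_g2 < 0 || sigma_e2 < 0)
    stop_config("variance components must be >= 0")
  if (mutation_prob < 0 || mutation_prob > 1)
    stop_config("mutation_prob must be in [0, 1]")
  if (!is.null(maf_targets)) {
    if (length(maf_targets) != n_snps)
      stop_config("maf_targets must have length n_snps")
    if (any(maf_targets <= 0 | maf_targets >= 1))
      stop_config("maf targets must be inside (0, 1)")
  }
  cfg <- list(
    n_families = as.integer(n_families),
    offspring_lambda = offspring_lambda,
    offspring_min = as.integer(offspring_min),
    offspring_max = as.integer(offspring_max),
    n_snps = as.integer(n_snps),
    block_size = as.integer(block_size),
    mutation_prob = mutation_prob,
    maf_targets = maf_targets,
    n_haplotypes = if (is.null(n_haplotypes)) NULL else as.integer(n_haplotypes),
    apoe_hap_freqs = stats::setNames(as.numeric(apoe_hap_freqs),
                                     c("e2", "e3", "e4")),
    recomb_prob = recomb_prob,
    sigma_g2 = sigma_g2,
    sigma_e2 = sigma_e2,
    n_lipid = as.integer(n_lipid),
    n_polar = as.integer(n_polar),
    covariate_params = covariate_params,
    apoe_ldl_shift = apoe_ldl_shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate nuclear-family pedigrees
#'
#' Each family has two unrelated founder parents and a number of offspring
#' drawn from the configured truncated-Poisson distribution. Offspring sex
#' is Bernoulli with the configured female prevalence (founder couples pin
#' the founder sex ratio at 1/2).
#'
#' @param config a [sim_config()].
#' @return data.frame pedigree (family_id, individual_id, father_id,
#'   mother_id, sex).
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p_female <- config$covariate_params$binary$prevalence[
    config$covariate_params$binary$name == "female"]
  if (length(p_female) == 0) p_female <- 0.5
  local_seed(config$seed + 0L, {
    n_off <- pmin(config$offspring_min +
                    stats::rpois(config$n_families, config$offspring_lambda),
                  config$offspring_max)
    rows <- vector("list", config$n_families)
    for (i in seq_len(config$n_families)) {
      fam <- sprintf("FAM%04d", i)
      fa <- paste0(fam, "_1")
      mo <- paste0(fam, "_2")
      kid_ids <- if (n_off[i] > 0) paste0(fam, "_", 2 + seq_len(n_off[i]))
                 else character(0)
      kid_sex <- ifelse(stats::runif(n_off[i]) < p_female, "female", "male")
      rows[[i]] <- data.frame(
        family_id = fam,
        individual_id = c(fa, mo, kid_ids),
        father_id = c(NA, NA, rep(fa, n_off[i])),
        mother_id = c(NA, NA, rep(mo, n_off[i])),
        sex = c("male", "female", kid_sex),
        stringsAsFactors = FALSE
      )
    }
    ped <- do.call(rbind, rows)
    rownames(ped) <- NULL
    ped
  })
}

#' Simulate founder haplotypes with LD-block structure
#'
#' SNPs are partitioned into contiguous blocks. Within a block every
#' haplotype carries a latent uniform draw; each site copies that latent
#' with probability `1 - mutation_prob` and otherwise draws its own, and the
#' allele is the indicator that the (copied or fresh) uniform falls below
#' the site's frequency target. Marginals therefore hit the MAF targets
#' exactly in expectation, within-block correlation is positive (r² = 1 at
#' mutation 0 with equal targets) and across-block correlation is zero.
#'
#' @param config a [sim_config()].
#' @return a `haplotype_pool`: list(haplotypes (pool x SNP 0/1 matrix),
#'   ld_blocks (list of index vectors), maf_targets).
#' @export
simulate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  S <- config$n_snps
  n_hap <- if (is.null(config$n_haplotypes)) 4L * config$n_families
           else config$n_haplotypes
  blocks <- split(seq_len(S), ceiling(seq_len(S) / config$block_size))
  names(blocks) <- NULL
  local_seed(config$seed + 1L, {
    maf <- config$maf_targets
    if (is.null(maf)) maf <- stats::runif(S, 0.05, 0.5)
    if (any(maf <= 0 | maf >= 1))
      stop_config("maf targets must be inside (0, 1)")
    H <- matrix(0L, nrow = n_hap, ncol = S)
    for (b in blocks) {
      u_block <- stats::runif(n_hap)
      for (j in b) {
        fresh <- stats::runif(n_hap) < config$mutation_prob
        u <- ifelse(fresh, stats::runif(n_hap), u_block)
        H[, j] <- as.integer(u < maf[j])
      }
    }
    colnames(H) <- sprintf("snp_%03d", seq_len(S))
    structure(list(haplotypes = H, ld_blocks = blocks, maf_targets = maf),
              class = "haplotype_pool")
  })
}

# Allocate marker metadata for the simulated regional panel: chromosome 19
# positions flanking the APOE gene, contiguous gene labels, allele letters.
region_snp_table <- function(S, seed) {
  local_seed(seed, {
    pos <- 44350000L + seq_len(S) * 9000L
    genes <- REGION_GENES[ceiling(seq_len(S) / max(1, ceiling(S / length(REGION_GENES))))]
    alle <- t(vapply(seq_len(S),
                     function(i) sample(c("A", "C", "G", "T"), 2),
                     character(2)))
    data.frame(
      snp_id = sprintf("snp_%03d", seq_len(S)),
      chromosome = "19",
      position = pos,
      allele_minor = alle[, 1],
      allele_major = alle[, 2],
      gene_label = genes,
      stringsAsFactors = FALSE
    )
  })
}

# Transmit one haplotype from a parent; optional single crossover.
transmit <- function(h1, h2, recomb_prob) {
  S <- length(h1)
  pick <- stats::runif(1) < 0.5
  if (recomb_prob > 0 && S > 1 && stats::runif(1) < recomb_prob) {
    x <- sample.int(S - 1L, 1L)
    if (pick) c(h1[seq_len(x)], h2[(x + 1L):S])
    else c(h2[seq_len(x)], h1[(x + 1L):S])
  } else if (pick) h1 else h2
}

# Drop haplotypes down a pedigree. `founder_haps` is a (2 * n_founders) x S
# 0/1 matrix; rows are consumed two per founder in pedigree order.
drop_haplotypes <- function(ped, founder_haps, recomb_prob, seed_offset, seed) {
  S <- ncol(founder_haps)
  n <- nrow(ped)
  ord <- pedigree_order(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  founders <- is_founder(ped)
  local_seed(seed + seed_offset, {
    H1 <- matrix(0L, n, S)
    H2 <- matrix(0L, n, S)
    next_hap <- 1L
    for (i in ord) {
      if (founders[i]) {
        H1[i, ] <- founder_haps[next_hap, ]
        H2[i, ] <- founder_haps[next_hap + 1L, ]
        next_hap <- next_hap + 2L
      } else {
        fa <- idx[[as.character(ped$father_id[i])]]
        mo <- idx[[as.character(ped$mother_id[i])]]
        H1[i, ] <- transmit(H1[fa, ], H2[fa, ], recomb_prob)
        H2[i, ] <- transmit(H1[mo, ], H2[mo, ], recomb_prob)
      }
    }
    rownames(H1) <- rownames(H2) <- ped$individual_id
    list(H1 = H1, H2 = H2)
  })
}

#' Gene-drop founder haplotypes through the pedigree
#'
#' Founders receive two pool haplotypes each; every offspring receives one
#' randomly chosen haplotype from each parent. By default there is no
#' recombination within the simulated ~1 Mb region, and the resulting
#' genotypes carry zero Mendel errors by construction.
#'
#' @param pedigree pedigree data.frame.
#' @param pool a `haplotype_pool` from [simulate_founder_haplotypes()].
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with phased haplotypes retained.
#' @export
gene_drop <- function(pedigree, pool, config) {
  validate_pedigree(pedigree)
  n_founders <- sum(is_founder(pedigree))
  if (nrow(pool$haplotypes) < 2L * n_founders)
    stop_input("haplotype pool has fewer than 2 haplotypes per founder")
  snps <- region_snp_table(ncol(pool$haplotypes), config$seed + 7L)
  haps <- drop_haplotypes(pedigree, pool$haplotypes,
                          config$recomb_prob, 2L, config$seed)
  genotype_matrix(dosage = haps$H1 + haps$H2, snps = snps,
                  haplotypes = haps)
}

#' Simulate APOE-defining SNPs rs429358 and rs7412
#'
#' Founder APOE haplotypes are drawn as epsilon-2 = (rs429358-T, rs7412-T),
#' epsilon-3 = (T, C), epsilon-4 = (C, C) with the configured frequencies
#' and transmitted by gene dropping.
#'
#' @param pedigree pedigree data.frame.
#' @param config a [sim_config()]; uses `apoe_hap_freqs`.
#' @return a [genotype_matrix()] with the two APOE SNPs (dosage counts the
#'   minor allele: C at rs429358, T at rs7412), phased haplotypes retained.
#' @export
simulate_apoe <- function(pedigree, config) {
  validate_pedigree(pedigree)
  f <- config$apoe_hap_freqs
  if (abs(sum(f) - 1) > 1e-9)
    stop_config("apoe_hap_freqs must sum to 1")
  n_founders <- sum(is_founder(pedigree))
  founder_eps <- local_seed(config$seed + 3L, {
    sample(c("e2", "e3", "e4"), 2L * n_founders, replace = TRUE, prob = f)
  })
  # haplotype coded as minor-allele indicators: rs429358 minor C (1 for e4),
  # rs7412 minor T (1 for e2)
  hap_code <- cbind(rs429358 = as.integer(founder_eps == "e4"),
                    rs7412 = as.integer(founder_eps == "e2"))
  haps <- drop_haplotypes(pedigree, hap_code, 0, 4L, config$seed)
  snps <- data.frame(
    snp_id = c("rs429358", "rs7412"),
    chromosome = "19",
    position = c(44908684L, 44908822L),
    allele_minor = c("C", "T"),
    allele_major = c("T", "C"),
    gene_label = "APOE",
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosage = haps$H1 + haps$H2, snps = snps, haplotypes = haps)
}

#' Simulate Table-calibrated covariates
#'
#' Continuous covariates are drawn normal (triglycerides log-normal, moment
#' matched, to keep positivity); binary covariates Bernoulli. Sex is taken
#' from the pedigree so parental roles stay consistent. Covariates are
#' independent of genotype unless the `apoe_ldl_shift` confounding hook is
#' enabled, in which case LDL-C mean shifts by that amount per epsilon-4
#' copy (and by its negative per epsilon-2 copy).
#'
#' @param pedigree pedigree data.frame.
#' @param config a [sim_config()].
#' @param apoe optional APOE [genotype_matrix()] (required if
#'   `apoe_ldl_shift != 0`).
#' @return data.frame of covariates, one row per pedigree record.
#' @export
simulate_covariates <- function(pedigree, config, apoe = NULL) {
  validate_pedigree(pedigree)
  cp <- config$covariate_params
  need <- c("birth_year", "FBG", "TC", "LDLC", "HDLC", "TG",
            "BMI", "DBP", "SBP", "eGFR")
  if (!all(need %in% cp$continuous$name))
    stop_config("missing continuous covariate parameters: ",
                paste(setdiff(need, cp$continuous$name), collapse = ", "))
  if (!all(c("female", "smoker", "ad") %in% cp$binary$name))
    stop_config("missing binary covariate parameters")
  n <- nrow(pedigree)
  local_seed(config$seed + 5L, {
    out <- data.frame(individual_id = pedigree$individual_id,
                      female = as.integer(pedigree$sex == "female"),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cp$continuous))) {
      nm <- cp$continuous$name[i]
      m <- cp$continuous$mean[i]
      s <- cp$continuous$sd[i]
      if (s == 0) {
        out[[nm]] <- rep(m, n)  # constant; dropped as non-informative downstream
      } else if (cp$continuous$dist[i] == "lognormal") {
        sdlog <- sqrt(log(1 + (s / m)^2))
        meanlog <- log(m) - sdlog^2 / 2
        out[[nm]] <- stats::rlnorm(n, meanlog, sdlog)
      } else {
        out[[nm]] <- stats::rnorm(n, m, s)
      }
    }
    for (i in seq_len(nrow(cp$binary))) {
      nm <- cp$binary$name[i]
      if (nm == "female") next
      out[[nm]] <- stats::rbinom(n, 1, cp$binary$prevalence[i])
    }
    if (config$apoe_ldl_shift != 0) {
      if (is.null(apoe))
        stop_config("apoe genotypes required when apoe_ldl_shift != 0")
      d4 <- apoe$dosage[out$individual_id, "rs429358"]
      d2 <- apoe$dosage[out$individual_id, "rs7412"]
      out$LDLC <- out$LDLC + config$apoe_ldl_shift * (d4 - d2)
    }
    out
  })
}

#' Construct an effect plan of planted SNP effects
#'
#' @param snp_id,metabolite_id,stratum,beta_true vectors (recycled) defining
#'   planted per-minor-allele-copy effects on log concentration; `stratum`
#'   is one of `"E2"`, `"E3"`, `"E4"` or `"all"`.
#' @return data.frame with class `effect_plan`.
#' @export
effect_plan <- function(snp_id = character(0), metabolite_id = character(0),
                        stratum = character(0), beta_true = numeric(0)) {
  plan <- data.frame(snp_id = snp_id, metabolite_id = metabolite_id,
                     stratum = stratum, beta_true = beta_true,
                     stringsAsFactors = FALSE)
  if (!all(plan$stratum %in% c("E2", "E3", "E4", "all")))
    stop_config("effect plan stratum must be E2, E3, E4 or all")
  if (anyDuplicated(plan[c("snp_id", "metabolite_id", "stratum")]))
    stop_config("duplicate (snp, metabolite, stratum) in effect plan")
  key <- paste(plan$snp_id, plan$metabolite_id)
  all_keys <- key[plan$stratum == "all"]
  if (any(key %in% all_keys & plan$stratum != "all"))
    stop_config("'all' entries may not coexist with stratum-specific entries ",
                "for the same (snp, metabolite)")
  class(plan) <- c("effect_plan", "data.frame")
  plan
}

#' Simulate metabolite concentrations
#'
#' For each analyte, log concentration = intercept + covariate effects +
#' planted stratum-specific SNP effects + a family polygenic effect with
#' covariance `sigma_g2 * 2 * kinship` + residual N(0, sigma_e2);
#' concentrations are the exponentials, hence strictly positive. Analytes
#' are labeled lipid/polar per the configured split.
#'
#' @param genotypes [genotype_matrix()] holding every SNP the plan refers to.
#' @param covariates covariate data.frame from [simulate_covariates()].
#' @param strata stratum assignment from [assign_apoe_groups()] (may be NULL
#'   when the plan has only `"all"` entries or is empty).
#' @param plan an [effect_plan()].
#' @param config a [sim_config()].
#' @param pedigree pedigree data.frame (for the family effect).
#' @return a `metabolite_panel`: list(values (subject x analyte matrix of
#'   positive concentrations), annotation (metabolite_id, class)).
#' @export
simulate_metabolites <- function(genotypes, covariates, strata, plan, config,
                                 pedigree) {
  validate_pedigree(pedigree)
  n <- nrow(pedigree)
  ids <- pedigree$individual_id
  M <- config$n_lipid + config$n_polar
  met_ids <- c(sprintf("lip_%03d", seq_len(config$n_lipid)),
               sprintf("pol_%03d", seq_len(config$n_polar)))
  classes <- c(rep("lipid", config$n_lipid), rep("polar", config$n_polar))
  if (nrow(plan) > 0) {
    if (!all(plan$snp_id %in% genotypes$snps$snp_id))
      stop_config("effect plan references unknown SNP")
    if (!all(plan$metabolite_id %in% met_ids))
      stop_config("effect plan references unknown metabolite")
    if (!all(plan$stratum %in% c("E2", "E3", "E4", "all")))
      stop_config("effect plan references unknown stratum")
  }
  K <- pedigree_kinship(pedigree)
  local_seed(config$seed + 6L, {
    intercept <- stats::rnorm(M, 0, 1)
    # standardized covariate design for nuisance effects
    cv <- covariates[match(ids, covariates$individual_id),
                     setdiff(names(covariates), "individual_id"),
                     drop = FALSE]
    Z <- scale(as.matrix(cv))
    Z[, apply(as.matrix(cv), 2, stats::sd) == 0] <- 0
    B <- matrix(stats::rnorm(ncol(Z) * M, 0, 0.05), ncol(Z), M)
    L <- matrix(intercept, n, M, byrow = TRUE) + Z %*% B
    # planted genetic effects
    if (nrow(plan) > 0) {
      strat <- if (is.null(strata)) rep(NA_character_, n)
               else strata$stratum[match(ids, strata$individual_id)]
      for (r in seq_len(nrow(plan))) {
        in_stratum <- if (plan$stratum[r] == "all") rep(TRUE, n)
                      else !is.na(strat) & strat == plan$stratum[r]
        d <- genotypes$dosage[ids, plan$snp_id[r]]
        j <- match(plan$metabolite_id[r], met_ids)
        L[in_stratum, j] <- L[in_stratum, j] +
          d[in_stratum] * plan$beta_true[r]
      }
    }
    # family polygenic effect: per-family Cholesky of sigma_g2 * K block
    if (config$sigma_g2 > 0) {
      U <- matrix(stats::rnorm(n * M), n, M)
      for (fam in unique(pedigree$family_id)) {
        fi <- which(pedigree$family_id == fam)
        Lc <- t(chol(config$sigma_g2 * K[fi, fi, drop = FALSE]))
        U[fi, ] <- Lc %*% U[fi, , drop = FALSE]
      }
      L <- L + U
    }
    L <- L + matrix(stats::rnorm(n * M, 0, sqrt(config$sigma_e2)), n, M)
    V <- exp(L)
    dimnames(V) <- list(ids, met_ids)
    structure(list(values = V,
                   annotation = data.frame(metabolite_id = met_ids,
                                           class = classes,
                                           stringsAsFactors = FALSE)),
              class = "metabolite_panel")
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running pedigree, haplotype, gene-drop, APOE,
#' covariate and metabolite simulation, plus APOE group assignment.
#'
#' @param config a [sim_config()].
#' @param plan an [effect_plan()] of planted effects (default: empty).
#' @return list(pedigree, genotypes (regional + APOE SNPs, position-sorted),
#'   covariates, metabolites, strata, plan, config).
#' @export
simulate_cohort <- function(config = sim_config(), plan = effect_plan()) {
  ped <- simulate_pedigrees(config)
  pool <- simulate_founder_haplotypes(config)
  g_region <- gene_drop(ped, pool, config)
  g_apoe <- simulate_apoe(ped, config)
  geno <- combine_genotypes(g_region, g_apoe)
  strata <- assign_apoe_groups(geno)
  covars <- simulate_covariates(ped, config, apoe = g_apoe)
  mets <- simulate_metabolites(geno, covars, strata, plan, config, ped)
  list(pedigree = ped, genotypes = geno, covariates = covars,
       metabolites = mets, strata = strata, plan = plan, config = config)
}
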