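# Stage two: cross-stratum effect contrasts (chi-square on the difference
# of per-group betas), Bonferroni control, interaction-model corroboration,
# sex contrasts and the pooled-sample re-analysis.

#' Effect-heterogeneity chi-square statistic
#'
#' chi2 = (b1 - b2)^2 / (se1^2 + se2^2): the squared difference of a SNP's
#' effect estimates in two contrasted groups over the sum of their squared
#' standard errors; 1 degree of freedom, symmetric in the two groups.
#'
#' @param b1,se1 effect and standard error in the first group.
#' @param b2,se2 effect and standard error in the second group.
#' @return chi-square statistic (vectorized).
#' @export
contrast_chisq <- function(b1, se1, b2, se2) {
  if (any(se1 <= 0, na.rm = TRUE) || any(se2 <= 0, na.rm = TRUE))
    stop_input("standard errors must be positive")
  (b1 - b2)^2 / (se1^2 + se2^2)
}

#' Upper-tail chi-square probability, 1 df
#'
#' @param chi2 non-negative statistic (vectorized).
#' @return upper-tail probability; equals 2 * (1 - Phi(sqrt(chi2))).
#' @export
chisq_pvalue_df1 <- function(chi2) {
  if (any(chi2 < 0, na.rm = TRUE))
    stop_input("chi-square statistic must be >= 0")
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests (>= 1).
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must be in (0, 1)")
  if (m < 1) stop_input("m must be >= 1")
  alpha / m
}

#' Identify group-specific associations
#'
#' For every stage-one discovery (deduplicated over strata), computes the
#' three pairwise contrasts E2 vs E3, E4 vs E3 and E2 vs E4 from the full
#' stage-one results, flags Bonferroni significance at `alpha / m` (m =
#' total discovery count across strata by default), nominal significance
#' (p < 0.05), and direction opposition.
#'
#' @param scan a `stratified_scan` from [run_stratified_scan()].
#' @param alpha family-wise level (default 0.05).
#' @param m Bonferroni denominator; default the number of stage-one
#'   discoveries across strata. The number of scanned SNPs is also
#'   recorded as attribute `m_snps` with its own threshold for reference.
#' @return data.frame of class `contrast_result` (snp_id, metabolite_id,
#'   group_a, group_b, b1, se1, b2, se2, chi2, p, significant, nominal,
#'   opposite_direction, untestable); attributes `threshold`, `m`,
#'   `m_snps`, `threshold_snps`.
#' @export
find_group_specific <- function(scan, alpha = 0.05, m = NULL) {
  disc <- scan$discoveries
  res <- scan$results
  if (is.null(m)) m <- nrow(disc)
  pairs_def <- list(c("E2", "E3"), c("E4", "E3"), c("E2", "E4"))
  if (nrow(disc) == 0) {
    out <- data.frame(snp_id = character(0), metabolite_id = character(0),
                      group_a = character(0), group_b = character(0),
                      b1 = numeric(0), se1 = numeric(0), b2 = numeric(0),
                      se2 = numeric(0), chi2 = numeric(0), p = numeric(0),
                      significant = logical(0), nominal = logical(0),
                      opposite_direction = logical(0),
                      untestable = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("contrast_result", "data.frame")
    return(out)
  }
  thr <- bonferroni_threshold(alpha, m)
  uniq <- unique(disc[c("snp_id", "metabolite_id")])
  rows <- list()
  lookup <- function(snp, met, grp) {
    i <- which(res$snp_id == snp & res$metabolite_id == met &
                 res$stratum == grp)
    if (length(i) == 0) return(NULL)
    res[i[1], c("beta", "se")]
  }
  for (r in seq_len(nrow(uniq))) {
    snp <- uniq$snp_id[r]; met <- uniq$metabolite_id[r]
    for (pr in pairs_def) {
      a <- lookup(snp, met, pr[1]); b <- lookup(snp, met, pr[2])
      untestable <- is.null(a) || is.null(b) || is.na(a$beta) || is.na(b$beta)
      if (untestable) {
        chi2 <- p <- NA_real_
        b1 <- se1 <- b2 <- se2 <- NA_real_
        opp <- NA
      } else {
        b1 <- a$beta; se1 <- a$se; b2 <- b$beta; se2 <- b$se
        chi2 <- contrast_chisq(b1, se1, b2, se2)
        p <- chisq_pvalue_df1(chi2)
        opp <- sign(b1) != sign(b2)
      }
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = snp, metabolite_id = met,
        group_a = pr[1], group_b = pr[2],
        b1 = b1, se1 = se1, b2 = b2, se2 = se2, chi2 = chi2, p = p,
        significant = !is.na(p) & p < thr,
        nominal = !is.na(p) & p < 0.05,
        opposite_direction = opp, untestable = untestable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m_snps <- length(unique(res$snp_id))
  attr(out, "threshold") <- thr
  attr(out, "m") <- m
  attr(out, "m_snps") <- m_snps
  attr(out, "threshold_snps") <- bonferroni_threshold(alpha, m_snps)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' SNP-by-group interaction test
#'
#' Pools the two contrasted strata and fits the stage-one mixed model with
#' fixed effects covariates + group indicator + dosage + dosage-by-group,
#' kinship from the pooled pedigree subset, and reports the Wald test of
#' the interaction coefficient. A significant interaction corroborates a
#' group-specific association independent of the per-group sample sizes.
#'
#' @param cohort list with `genotypes`, `pedigree`, `covariates`,
#'   `metabolites`.
#' @param strata stratum assignment.
#' @param pair two strata to contrast, e.g. `c("E2", "E3")`; the group
#'   indicator is 1 for the first element.
#' @param snp_id,metabolite_id the association under test.
#' @param n_pcs,covariate_names as in [run_stratified_scan()].
#' @param pcs optional precomputed PC score matrix.
#' @return data.frame(snp_id, metabolite_id, pair, beta_int, se_int, p_int,
#'   n_used).
#' @export
interaction_test <- function(cohort, strata, pair, snp_id, metabolite_id,
                             n_pcs = 5, covariate_names = NULL, pcs = NULL) {
  g <- cohort$genotypes
  ids <- intersect(rownames(g$dosage),
                   strata$individual_id[strata$stratum %in% pair])
  grp <- as.integer(strata$stratum[match(ids, strata$individual_id)] ==
                      pair[1])
  if (is.null(pcs) && n_pcs > 0)
    pcs <- genotype_pcs(g, k = n_pcs, pedigree = cohort$pedigree)
  X <- build_design(cohort$covariates, ids, covariate_names, pcs)
  X <- cbind(X, group = grp)
  if (qr(X)$rank < ncol(X))
    stop_input("group indicator is collinear with the covariates")
  y <- log(cohort$metabolites$values[ids, metabolite_id])
  K <- pedigree_kinship(cohort$pedigree)[ids, ids]
  fit <- fit_null_reml(y, X, K)
  keep <- fit$rotation$keep
  d <- g$dosage[ids, snp_id][keep]
  d[is.na(d)] <- mean(d, na.rm = TRUE)
  Z <- cbind(dosage = d, interaction = d * grp[keep])
  Zt <- crossprod(fit$rotation$vectors, Z)
  # joint WLS of [X, dosage, dosage x group] on the rotated data
  sw <- 1 / sqrt(fit$rotation$weights)
  Xf <- cbind(fit$rotation$Xt, Zt) * sw
  yf <- fit$rotation$yt * sw
  qr_ <- qr(Xf)
  cf <- qr.coef(qr_, yf)
  res <- qr.resid(qr_, yf)
  df <- length(yf) - qr_$rank
  s2 <- sum(res^2) / df
  R <- qr.R(qr_)
  XtXinv <- chol2inv(R)
  se_all <- sqrt(diag(XtXinv) * s2)
  k <- ncol(Xf)
  beta_int <- cf[k]
  se_int <- se_all[qr_$pivot == k]
  p_int <- 2 * stats::pnorm(-abs(beta_int / se_int))
  data.frame(snp_id = snp_id, metabolite_id = metabolite_id,
             pair = paste(pair, collapse = "-"), beta_int = beta_int,
             se_int = se_int, p_int = p_int, n_used = fit$n_used,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Male-female effect contrast for group-specific SNPs
#'
#' Refits the stage-one scan within males and within females of the
#' relevant stratum for each (SNP, metabolite) and contrasts the two
#' estimates with the heterogeneity chi-square, reported at nominal 0.05.
#'
#' @param cohort cohort list (covariates must include `female`).
#' @param strata stratum assignment.
#' @param targets data.frame(snp_id, metabolite_id, stratum).
#' @param min_subgroup sex subgroups smaller than this are flagged
#'   untestable (default 30).
#' @param n_pcs,covariate_names as in [run_stratified_scan()].
#' @return data.frame(snp_id, metabolite_id, stratum, b_male, se_male,
#'   b_female, se_female, chi2, p, significant, untestable).
#' @export
sex_contrast <- function(cohort, strata, targets, min_subgroup = 30,
                         n_pcs = 5, covariate_names = NULL) {
  g <- cohort$genotypes
  if (!"female" %in% names(cohort$covariates))
    stop_input("covariates must include 'female'")
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(cohort$covariates),
                               c("individual_id", "female"))
  pcs <- if (n_pcs > 0) genotype_pcs(g, k = n_pcs,
                                     pedigree = cohort$pedigree) else NULL
  K_all <- pedigree_kinship(cohort$pedigree)
  logged <- log_transform(cohort$metabolites)
  fem <- cohort$covariates$female[
    match(rownames(g$dosage), cohort$covariates$individual_id)]
  one_fit <- function(ids, snp, met) {
    X <- build_design(cohort$covariates, ids, covariate_names, pcs)
    keep <- stats::complete.cases(X)
    ids <- ids[keep]
    fit <- fit_null_reml(logged$values[ids, met], X[keep, , drop = FALSE],
                         K_all[ids, ids])
    sc <- snp_scan(fit, subset_genotypes(g, subjects = ids))
    sc[sc$snp_id == snp, c("beta", "se")]
  }
  rows <- list()
  for (r in seq_len(nrow(targets))) {
    snp <- targets$snp_id[r]; met <- targets$metabolite_id[r]
    s <- targets$stratum[r]
    sids <- intersect(rownames(g$dosage),
                      strata$individual_id[strata$stratum == s])
    males <- sids[fem[match(sids, rownames(g$dosage))] == 0]
    females <- sids[fem[match(sids, rownames(g$dosage))] == 1]
    if (length(males) < min_subgroup || length(females) < min_subgroup) {
      rows[[r]] <- data.frame(snp_id = snp, metabolite_id = met,
                              stratum = s, b_male = NA_real_,
                              se_male = NA_real_, b_female = NA_real_,
                              se_female = NA_real_, chi2 = NA_real_,
                              p = NA_real_, significant = NA,
                              untestable = TRUE, stringsAsFactors = FALSE)
      next
    }
    em <- one_fit(males, snp, met)
    ef <- one_fit(females, snp, met)
    untestable <- is.na(em$beta) || is.na(ef$beta)
    chi2 <- if (untestable) NA_real_
            else contrast_chisq(em$beta, em$se, ef$beta, ef$se)
    p <- if (untestable) NA_real_ else chisq_pvalue_df1(chi2)
    rows[[r]] <- data.frame(snp_id = snp, metabolite_id = met, stratum = s,
                            b_male = em$beta, se_male = em$se,
                            b_female = ef$beta, se_female = ef$se,
                            chi2 = chi2, p = p,
                            significant = !is.na(p) & p < 0.05,
                            untestable = untestable,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled-sample re-analysis
#'
#' Re-runs the stage-one model on the pooled E2 u E3 u E4 sample (epsilon-2/
#' epsilon-4 compound heterozygotes stay excluded), applies
#' Benjamini-Hochberg over the pooled family, and reports which per-stratum
#' discoveries replicate at `q < fdr` in the pooled sample.
#'
#' @param cohort cohort list.
#' @param strata stratum assignment.
#' @param discoveries stage-one discovery table (from a `stratified_scan`).
#' @param group_specific optional `contrast_result` used to flag whether
#'   any group-specific association replicates in the pooled sample.
#' @param ... passed to [run_stratified_scan()] (fdr, n_pcs,
#'   covariate_names, fdr_family).
#' @return list(results, discoveries, overlap) where `overlap` marks each
#'   per-stratum discovery with its pooled q and replication flag.
#' @export
pooled_scan <- function(cohort, strata, discoveries = NULL,
                        group_specific = NULL, ...) {
  pooled_strata <- strata
  pooled_strata$stratum[pooled_strata$stratum %in% c("E2", "E3", "E4")] <-
    "pooled"
  sc <- run_stratified_scan(cohort, strata = pooled_strata,
                            strata_levels = "pooled", ...)
  overlap <- NULL
  if (!is.null(discoveries) && nrow(discoveries) > 0) {
    key <- paste(sc$results$snp_id, sc$results$metabolite_id)
    i <- match(paste(discoveries$snp_id, discoveries$metabolite_id), key)
    overlap <- data.frame(
      snp_id = discoveries$snp_id,
      metabolite_id = discoveries$metabolite_id,
      stratum = discoveries$stratum,
      pooled_q = sc$results$q[i],
      replicated = !is.na(sc$results$q[i]) & sc$results$q[i] < sc$fdr,
      stringsAsFactors = FALSE)
    if (!is.null(group_specific) && nrow(group_specific) > 0) {
      gs_key <- unique(paste(group_specific$snp_id[group_specific$significant],
                             group_specific$metabolite_id[group_specific$significant]))
      overlap$group_specific <-
        paste(overlap$snp_id, overlap$metabolite_id) %in% gs_key
    }
  } else {
    overlap <- data.frame(snp_id = character(0),
                          metabolite_id = character(0),
                          stratum = character(0), pooled_q = numeric(0),
                          replicated = logical(0), stringsAsFactors = FALSE)
  }
  list(results = sc$results, discoveries = sc$discoveries, overlap = overlap)
}
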