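# Stage one: per-stratum additive linear mixed-model association of every
# SNP with every log-transformed metabolite, covariate-adjusted, with a
# pedigree-kinship random effect and Benjamini-Hochberg discovery.

#' Log-transform a metabolite panel
#'
#' Natural log applied elementwise; missing values preserved. Any value
#' <= 0 is a hard error naming the analyte and subject (no silent
#' pseudocount).
#'
#' @param panel a `metabolite_panel` (list with `values` matrix and
#'   `annotation`).
#' @return the panel with log-transformed values.
#' @export
log_transform <- function(panel) {
  V <- panel$values
  bad <- which(!is.na(V) & V <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("non-positive concentration for analyte ",
               colnames(V)[bad[1, 2]], ", subject ", rownames(V)[bad[1, 1]],
               "; log transform requires strictly positive values")
  panel$values <- log(V)
  panel
}

#' Expected relationship matrix from a pedigree
#'
#' Recursive kinship computation: founders are unrelated and non-inbred,
#' Phi(i,i) = (1 + Phi(father, mother)) / 2, and for j preceding i in a
#' parents-first ordering Phi(i,j) = (Phi(father_i, j) + Phi(mother_i, j))
#' / 2. The returned matrix is 2 * Phi (parent-offspring and full siblings
#' 0.5; diagonal 1 + inbreeding), block-diagonal by family.
#'
#' @param ped pedigree data.frame.
#' @return symmetric matrix with subject-id dimnames.
#' @export
pedigree_kinship <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$individual_id,
                                         ped$individual_id))
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  ord <- pedigree_order(ped)
  founder <- is_founder(ped)
  done <- integer(0)
  for (i in ord) {
    if (founder[i]) {
      phi[i, i] <- 0.5
    } else {
      fa <- idx[[as.character(ped$father_id[i])]]
      mo <- idx[[as.character(ped$mother_id[i])]]
      if (length(done)) {
        v <- (phi[fa, done] + phi[mo, done]) / 2
        phi[i, done] <- v
        phi[done, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[fa, mo])
    }
    done <- c(done, i)
  }
  2 * phi
}

#' Empirical genomic relationship matrix
#'
#' Standardized-dosage cross-product averaged over polymorphic SNPs:
#' entries are the mean over SNPs of
#' (d_i - 2f)(d_j - 2f) / (2f(1 - f)). Monomorphic SNPs are skipped with a
#' warning; missing dosages are mean-imputed.
#'
#' @param g [genotype_matrix()].
#' @return symmetric relationship matrix.
#' @export
empirical_grm <- function(g) {
  D <- g$dosage
  f <- colMeans(D, na.rm = TRUE) / 2
  poly <- !is.na(f) & f > 0 & f < 1
  if (sum(poly) < 2) stop_input("at least 2 polymorphic SNPs required")
  if (any(!poly))
    warning("skipping ", sum(!poly), " monomorphic SNP(s) in GRM")
  D <- D[, poly, drop = FALSE]
  f <- f[poly]
  Z <- sweep(D, 2, 2 * f)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  tcrossprod(Z) / ncol(Z)
}

#' Genetic principal components
#'
#' PCs of the centered, variance-standardized dosage matrix computed on
#' founders, with non-founders projected onto the founder loadings (this
#' mitigates the inflation of leading components by family structure).
#' Deterministic up to sign; the sign is fixed by making each loading
#' vector's largest-magnitude entry positive.
#'
#' @param g [genotype_matrix()].
#' @param k number of components.
#' @param pedigree pedigree data.frame; NULL treats all subjects as
#'   founders (plain PCA).
#' @return subjects x k score matrix (columns `PC1`..`PCk`).
#' @export
genotype_pcs <- function(g, k = 5, pedigree = NULL) {
  if (k < 1) stop_input("k must be >= 1")
  D <- g$dosage
  founders <- if (is.null(pedigree)) rownames(D)
              else intersect(rownames(D),
                             pedigree$individual_id[is_founder(pedigree)])
  Df <- D[founders, , drop = FALSE]
  f <- colMeans(Df, na.rm = TRUE) / 2
  s <- sqrt(2 * f * (1 - f))
  poly <- !is.na(f) & f > 0 & f < 1
  std <- function(X) {
    Z <- sweep(X[, poly, drop = FALSE], 2, 2 * f[poly])
    Z[is.na(Z)] <- 0
    sweep(Z, 2, s[poly], "/")
  }
  Zf <- std(Df)
  sv <- svd(Zf)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) stop_input("k exceeds the rank of the genotype matrix (",
                           rank, ")")
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  scores <- std(D) %*% V
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(D)
  scores
}

# Eigendecomposition wrapper reused across metabolites within a stratum.
kinship_eigen <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  e$values <- pmax(e$values, 0)  # small-ridge stabilization at the boundary
  e
}

# REML log-likelihood profile in delta = sigma_g2 / sigma_e2, on rotated
# data (yt = U'y, Xt = U'X, lambda = eigenvalues of K).
reml_profile <- function(delta, yt, Xt, lambda) {
  w <- delta * lambda + 1
  sw <- 1 / sqrt(w)
  Xs <- Xt * sw
  ys <- yt * sw
  qr_ <- qr(Xs)
  p <- qr_$rank
  n <- length(ys)
  res <- qr.resid(qr_, ys)
  rss <- sum(res^2)
  sigma_e2 <- rss / (n - p)
  logdet_xwx <- 2 * sum(log(abs(diag(qr.R(qr_))[seq_len(p)])))
  ll <- -0.5 * ((n - p) * (log(2 * pi * sigma_e2) + 1) + sum(log(w)) +
                  logdet_xwx)
  list(ll = ll, sigma_e2 = sigma_e2, delta = delta)
}

#' REML fit of the null (no-SNP) mixed model
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma_g2 K), e ~ N(0, sigma_e2 I)
#' by restricted maximum likelihood: a one-dimensional search over the
#' variance ratio delta = sigma_g2 / sigma_e2 with the scale profiled out
#' in closed form, via a single eigendecomposition of K. Boundary estimates
#' (sigma_g2 = 0) are permitted. Rows with missing y or X are dropped
#' (listwise).
#'
#' @param y numeric response (log metabolite), named by subject id or
#'   aligned with rows of X and K.
#' @param X design matrix including the intercept; constant columns beyond
#'   the first are dropped.
#' @param K kinship/relationship matrix aligned with y.
#' @param eig optional precomputed `eigen(K)` (only valid with complete
#'   cases).
#' @return object of class `lmm_fit`: sigma_g2, sigma_e2, delta,
#'   loglik_reml, converged, n_used, plus the rotation (eigenvectors,
#'   weights, rotated y and X) reused by [snp_scan()].
#' @export
fit_null_reml <- function(y, X, K, eig = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(y) & stats::complete.cases(X)
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    K <- K[keep, keep, drop = FALSE]
    eig <- NULL
  }
  n <- length(y)
  # drop constant non-intercept columns
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                            function(v) stats::sd(v) > 0))
  X <- X[, keep_col, drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop_input("covariate design is rank deficient after dropping constants")
  if (n <= ncol(X) + 1)
    stop_input("too few complete cases (", n, ") for the design")
  if (is.null(eig)) eig <- kinship_eigen(K)
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  lambda <- eig$values
  obj <- function(ld) reml_profile(exp(ld), yt, Xt, lambda)$ll
  opt <- stats::optimize(obj, interval = c(-12, 12), maximum = TRUE,
                         tol = 1e-8)
  cand <- list(reml_profile(exp(opt$maximum), yt, Xt, lambda),
               reml_profile(0, yt, Xt, lambda))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "ll"))]]
  converged <- is.finite(best$ll) && best$sigma_e2 > 1e-12
  structure(list(
    sigma_g2 = best$delta * best$sigma_e2,
    sigma_e2 = best$sigma_e2,
    delta = best$delta,
    loglik_reml = best$ll,
    converged = converged,
    n_used = n,
    rotation = list(vectors = eig$vectors, lambda = lambda,
                    weights = best$delta * lambda + 1,
                    yt = yt, Xt = Xt, keep = keep)
  ), class = "lmm_fit")
}

# Generalized-least-squares scan of many predictors given a null fit:
# the variance ratio is fixed from the fit and the residual scale is
# re-profiled per model (weighted least squares on the rotated data, so
# that the K = I, sigma_g2 = 0 case reduces exactly to OLS). Gt holds the
# rotated predictors (one column per SNP). Returns beta, se, p per column.
gls_scan <- function(fit, Gt) {
  rot <- fit$rotation
  sw <- 1 / sqrt(rot$weights)
  Xs <- rot$Xt * sw
  ys <- rot$yt * sw
  Gs <- Gt * sw
  qr_ <- qr(Xs)
  p <- qr_$rank
  n <- length(ys)
  yr <- qr.resid(qr_, ys)
  Gr <- qr.resid(qr_, Gs)
  gss <- colSums(Gr^2)
  testable <- gss > n * 1e-12
  beta <- se <- pval <- rep(NA_real_, ncol(Gt))
  b <- colSums(Gr * yr)[testable] / gss[testable]
  rss0 <- sum(yr^2)
  rss <- pmax(rss0 - b^2 * gss[testable], 0)
  s2 <- rss / (n - p - 1)
  beta[testable] <- b
  se[testable] <- sqrt(s2 / gss[testable])
  pval[testable] <- 2 * stats::pnorm(-abs(beta[testable] / se[testable]))
  data.frame(beta = beta, se = se, p = pval,
             reason = ifelse(testable, NA_character_,
                             "monomorphic or collinear with covariates"),
             stringsAsFactors = FALSE)
}

#' Per-SNP mixed-model association scan
#'
#' Variance components are fixed from the null REML fit; each SNP's dosage
#' coefficient is then estimated by generalized least squares alongside the
#' covariates, with a Wald test (asymptotic normal). SNPs monomorphic in
#' the stratum, or collinear with the covariates, yield missing results
#' with a reason.
#'
#' @param fit a converged [fit_null_reml()] result.
#' @param g [genotype_matrix()] (aligned effect alleles), subjects matching
#'   the rows used in the fit.
#' @param stratum label recorded in the output.
#' @param metabolite_id label recorded in the output.
#' @return data.frame(stratum, snp_id, metabolite_id, beta, se, p, n_used,
#'   reason).
#' @export
snp_scan <- function(fit, g, stratum = "all", metabolite_id = NA_character_) {
  if (!fit$converged)
    stop_input("null model did not converge; SNP tests are untestable")
  D <- g$dosage[fit$rotation$keep, , drop = FALSE]
  D[is.na(D)] <- NA_real_
  # mean-impute missing dosages within the stratum so the rotation applies
  cm <- colMeans(D, na.rm = TRUE)
  for (j in which(colSums(is.na(D)) > 0)) D[is.na(D[, j]), j] <- cm[j]
  Gt <- crossprod(fit$rotation$vectors, D)
  res <- gls_scan(fit, Gt)
  data.frame(stratum = stratum, snp_id = g$snps$snp_id,
             metabolite_id = metabolite_id, beta = res$beta, se = res$se,
             p = res$p, n_used = fit$n_used, reason = res$reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment q(i) = min over j >= rank(i) of p(j) * m / j, capped
#' at 1; `m` may exceed the number of observed p-values when untested
#' hypotheses are counted in the family.
#'
#' @param p p-values in \[0, 1\] (NA allowed, returned as NA).
#' @param m family size (>= number of non-missing p-values).
#' @return adjusted values.
#' @export
bh_fdr <- function(p, m = sum(!is.na(p))) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_input("p-values must lie in [0, 1]")
  if (m < sum(!is.na(p)))
    stop_input("family size m must be >= number of p-values")
  stats::p.adjust(p, method = "BH", n = m)
}

# Build the fixed-effect design used by stage one: intercept, covariates,
# genetic PCs. `covariate_names` defaults to every covariate column.
build_design <- function(covariates, ids, covariate_names = NULL,
                         pcs = NULL) {
  cv <- covariates[match(ids, covariates$individual_id), , drop = FALSE]
  if (is.null(covariate_names))
    covariate_names <- setdiff(names(covariates), "individual_id")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(cv[, covariate_names, drop = FALSE]))
  if (!is.null(pcs)) X <- cbind(X, pcs[ids, , drop = FALSE])
  rownames(X) <- ids
  X
}

# Scan one stratum: null REML per metabolite (shared kinship rotation for
# the common complete-case pattern), then the SNP scan. Y is the
# subjects x metabolites log-concentration matrix.
scan_stratum <- function(Y, X, K, g, label) {
  ids <- rownames(X)
  eig <- kinship_eigen(K)
  out <- vector("list", ncol(Y))
  fits <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    met <- colnames(Y)[j]
    fit <- if (anyNA(y)) fit_null_reml(y, X, K)  # own complete cases
           else fit_null_reml(y, X, K, eig = eig)
    fits[[j]] <- fit
    out[[j]] <- if (fit$converged)
      snp_scan(fit, g, stratum = label, metabolite_id = met)
    else
      data.frame(stratum = label, snp_id = g$snps$snp_id,
                 metabolite_id = met, beta = NA_real_, se = NA_real_,
                 p = NA_real_, n_used = fit$n_used,
                 reason = "null model not converged",
                 stringsAsFactors = FALSE)
  }
  names(fits) <- colnames(Y)
  list(results = do.call(rbind, out), fits = fits)
}

#' Stratified stage-one association scan
#'
#' For each APOE stratum: a per-metabolite null REML fit followed by the
#' SNP scan over all (SNP, metabolite) pairs, Benjamini-Hochberg adjustment
#' within the declared family, and discovery at `q < fdr`.
#'
#' @param cohort list with `genotypes` (QC'd, aligned), `pedigree`,
#'   `covariates`, `metabolites` (raw positive concentrations).
#' @param strata assignment from [assign_apoe_groups()].
#' @param fdr discovery threshold on q (default 0.05).
#' @param n_pcs number of genetic PCs included as covariates (default 5).
#' @param covariate_names covariate columns to adjust for; default all.
#' @param fdr_family `"stratum"` (all SNP x metabolite tests within a
#'   stratum, the default) or `"metabolite"` (per-metabolite families).
#' @param min_stratum warn when a stratum is smaller than this (default 50).
#' @param strata_levels strata to scan.
#' @return list of class `stratified_scan`: `results` (all tests with q),
#'   `discoveries` (q < fdr, sorted by stratum then q), `variance_components`.
#' @export
run_stratified_scan <- function(cohort, strata = cohort$strata, fdr = 0.05,
                                n_pcs = 5, covariate_names = NULL,
                                fdr_family = c("stratum", "metabolite"),
                                min_stratum = 50,
                                strata_levels = c("E2", "E3", "E4")) {
  fdr_family <- match.arg(fdr_family)
  g <- cohort$genotypes
  ids_all <- rownames(g$dosage)
  logged <- log_transform(cohort$metabolites)
  pcs <- if (n_pcs > 0) genotype_pcs(g, k = n_pcs, pedigree = cohort$pedigree)
         else NULL
  K_all <- pedigree_kinship(cohort$pedigree)
  results <- list()
  vc <- list()
  for (s in strata_levels) {
    sids <- intersect(ids_all,
                      strata$individual_id[strata$stratum == s])
    X <- build_design(cohort$covariates, sids, covariate_names, pcs)
    cc <- stats::complete.cases(X)
    sids <- sids[cc]
    if (length(sids) < min_stratum)
      warning("stratum ", s, " has only ", length(sids),
              " subjects; results may be unstable")
    X <- X[sids, , drop = FALSE]
    Y <- logged$values[sids, , drop = FALSE]
    K <- K_all[sids, sids]
    gs <- subset_genotypes(g, subjects = sids)
    sc <- scan_stratum(Y, X, K, gs, s)
    vc[[s]] <- data.frame(
      stratum = s, metabolite_id = names(sc$fits),
      sigma_g2 = vapply(sc$fits, `[[`, numeric(1), "sigma_g2"),
      sigma_e2 = vapply(sc$fits, `[[`, numeric(1), "sigma_e2"),
      converged = vapply(sc$fits, `[[`, logical(1), "converged"),
      stringsAsFactors = FALSE, row.names = NULL)
    res <- sc$results
    if (fdr_family == "stratum") {
      res$q <- bh_fdr(res$p)
    } else {
      res$q <- NA_real_
      for (met in unique(res$metabolite_id)) {
        i <- res$metabolite_id == met
        res$q[i] <- bh_fdr(res$p[i])
      }
    }
    results[[s]] <- res
  }
  results <- do.call(rbind, c(results, make.row.names = FALSE))
  disc <- results[!is.na(results$q) & results$q < fdr, , drop = FALSE]
  disc <- disc[order(match(disc$stratum, strata_levels), disc$q), ,
               drop = FALSE]
  rownames(disc) <- NULL
  structure(list(results = results, discoveries = disc,
                 variance_components = do.call(rbind, c(vc, make.row.names = FALSE)),
                 fdr = fdr),
            class = "stratified_scan")
}
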