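# Supporting analyses: LD matrices (r-squared / D-prime), SNP-covariate
# multicollinearity (VIF), per-stratum metabolite distribution summaries,
# and gene-by-stratum clustering of discoveries.

# LD measures from four haplotype frequencies (pA, pB, pAB).
ld_from_freqs <- function(pA, pB, pAB) {
  pA <- unname(pA); pB <- unname(pB); pAB <- unname(pAB)
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(c(r2 = NA_real_, d_prime = NA_real_))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  c(r2 = D^2 / denom,
    d_prime = if (dmax == 0) NA_real_ else abs(D) / dmax)
}

# Two-locus haplotype-frequency EM on unphased genotype pairs. Only the
# double heterozygote is phase-ambiguous; iterate until the AB frequency
# moves < tol or max_iter is hit.
em_two_locus <- function(dA, dB, max_iter = 50, tol = 1e-10) {
  keep <- !is.na(dA) & !is.na(dB)
  dA <- dA[keep]; dB <- dB[keep]
  n <- length(dA)
  if (n == 0) return(c(pA = NA, pB = NA, pAB = NA))
  pA <- mean(dA) / 2; pB <- mean(dB) / 2
  dh <- dA == 1 & dB == 1
  n_dh <- sum(dh)
  # AB-haplotype count from phase-unambiguous subjects: a first-locus
  # homozygote pairs each second-locus allele with a known allele; a
  # heterozygote paired with a second-locus homozygote contributes dB/2.
  nAB_fix <- sum(ifelse(dA[!dh] == 2, dB[!dh],
                        ifelse(dA[!dh] == 1, dB[!dh] / 2, 0)))
  pAB <- pA * pB
  for (it in seq_len(max_iter)) {
    # E-step: split double heterozygotes between AB/ab and Ab/aB phases
    pAb <- pA - pAB; paB <- pB - pAB
    pab <- 1 - pA - pB + pAB
    w <- pAB * pab
    denom <- w + pAb * paB
    frac <- if (denom <= 0) 0.5 else w / denom
    new_pAB <- (nAB_fix + n_dh * frac) / (2 * n)
    if (abs(new_pAB - pAB) < tol) { pAB <- new_pAB; break }
    pAB <- new_pAB
  }
  c(pA = pA, pB = pB, pAB = pAB)
}

#' Pairwise linkage disequilibrium matrix
#'
#' Computes r-squared and D-prime for every SNP pair, from phased
#' haplotypes when available, otherwise from founder genotypes via
#' two-locus haplotype-frequency EM. The returned square matrix carries
#' r-squared in the lower-left triangle, D-prime in the upper-right, and
#' 1 on the diagonal.
#'
#' @param g a [genotype_matrix()] (phased haplotypes used if present) or a
#'   haplotype 0/1 matrix.
#' @param pedigree optional pedigree; when supplied, only founders enter
#'   (relatedness inflates LD).
#' @param use_haplotypes set FALSE to force the unphased EM path.
#' @return square matrix of class `ld_matrix`; monomorphic pairs are NA.
#' @export
ld_matrix <- function(g, pedigree = NULL, use_haplotypes = TRUE) {
  if (inherits(g, "genotype_matrix")) {
    ids <- rownames(g$dosage)
    if (!is.null(pedigree))
      ids <- intersect(ids, pedigree$individual_id[is_founder(pedigree)])
    if (use_haplotypes && !is.null(g$haplotypes)) {
      H <- rbind(g$haplotypes$H1[ids, , drop = FALSE],
                 g$haplotypes$H2[ids, , drop = FALSE])
      mode <- "phased"
    } else {
      D <- g$dosage[ids, , drop = FALSE]
      mode <- "unphased"
    }
    snp_ids <- g$snps$snp_id
  } else {
    H <- as.matrix(g)
    mode <- "phased"
    snp_ids <- colnames(H)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(H)))
  }
  S <- length(snp_ids)
  if (S < 2) stop_input("at least 2 SNPs required")
  out <- matrix(NA_real_, S, S, dimnames = list(snp_ids, snp_ids))
  diag(out) <- 1
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      fr <- if (mode == "phased") {
        a <- H[, i]; b <- H[, j]
        keep <- !is.na(a) & !is.na(b)
        c(pA = mean(a[keep]), pB = mean(b[keep]),
          pAB = mean(a[keep] * b[keep]))
      } else em_two_locus(D[, i], D[, j])
      ld <- ld_from_freqs(fr["pA"], fr["pB"], fr["pAB"])
      out[j, i] <- ld["r2"]       # lower-left
      out[i, j] <- ld["d_prime"]  # upper-right
    }
  }
  class(out) <- c("ld_matrix", class(out))
  out
}

#' SNP-covariate variance inflation factors
#'
#' Regresses each SNP's dosage on the full stage-one covariate set and
#' reports the squared multiple correlation and VIF = 1 / (1 - R^2), with
#' a min/max summary across SNPs.
#'
#' @param g [genotype_matrix()].
#' @param covariates covariate data.frame.
#' @param covariate_names columns to use; default all.
#' @return data.frame(snp_id, r2_covariates, vif); attribute `summary`
#'   with min/max of both.
#' @export
vif <- function(g, covariates, covariate_names = NULL) {
  ids <- intersect(rownames(g$dosage), covariates$individual_id)
  X <- build_design(covariates, ids, covariate_names)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  X <- X[, c(TRUE, apply(X[, -1, drop = FALSE], 2,
                         function(v) stats::sd(v) > 0)), drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop_input("covariate design is rank deficient")
  D <- g$dosage[ids, , drop = FALSE][keep, , drop = FALSE]
  qr_ <- qr(X)
  r2 <- vapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]
    ok <- !is.na(d)
    if (stats::sd(d[ok]) == 0) return(NA_real_)
    dd <- d[ok] - mean(d[ok])
    res <- qr.resid(qr(X[ok, , drop = FALSE]), dd)
    1 - sum(res^2) / sum(dd^2)
  }, numeric(1))
  out <- data.frame(snp_id = g$snps$snp_id, r2_covariates = r2,
                    vif = 1 / (1 - r2), stringsAsFactors = FALSE)
  ok <- !is.na(out$vif)
  attr(out, "summary") <- data.frame(
    r2_min = min(out$r2_covariates[ok]), r2_max = max(out$r2_covariates[ok]),
    vif_min = min(out$vif[ok]), vif_max = max(out$vif[ok]))
  out
}

#' Per-stratum metabolite summaries and CI overlap
#'
#' Mean and normal-approximation 95% confidence interval of every analyte
#' per stratum, a one-sample test that the mean differs from zero (guards
#' against technical-variability artifacts), and a cross-stratum overlap
#' flag per analyte and stratum pair (intervals intersecting).
#'
#' @param panel `metabolite_panel` (values on the scale to summarize).
#' @param strata stratum assignment.
#' @param metabolite_ids analytes to summarize; default all.
#' @return list(summaries, overlap) data.frames.
#' @export
metabolite_summaries <- function(panel, strata,
                                 metabolite_ids = colnames(panel$values)) {
  levels_ <- c("E2", "E3", "E4")
  sums <- list()
  for (met in metabolite_ids) {
    for (s in levels_) {
      ids <- intersect(rownames(panel$values),
                       strata$individual_id[strata$stratum == s])
      v <- panel$values[ids, met]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n < 2) {
        sums[[length(sums) + 1]] <- data.frame(
          metabolite_id = met, stratum = s, n = n,
          mean = if (n == 1) v else NA_real_, ci_lo = NA_real_,
          ci_hi = NA_real_, p_mean_zero = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      se <- stats::sd(v) / sqrt(n)
      m <- mean(v)
      sums[[length(sums) + 1]] <- data.frame(
        metabolite_id = met, stratum = s, n = n, mean = m,
        ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se,
        p_mean_zero = stats::t.test(v, mu = 0)$p.value,
        stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, sums)
  rownames(summaries) <- NULL
  pairs_ <- utils::combn(levels_, 2)
  ov <- list()
  for (met in metabolite_ids) {
    for (k in seq_len(ncol(pairs_))) {
      a <- summaries[summaries$metabolite_id == met &
                       summaries$stratum == pairs_[1, k], ]
      b <- summaries[summaries$metabolite_id == met &
                       summaries$stratum == pairs_[2, k], ]
      overl <- if (nrow(a) == 0 || nrow(b) == 0 || is.na(a$ci_lo) ||
                   is.na(b$ci_lo)) NA
               else a$ci_lo <= b$ci_hi && b$ci_lo <= a$ci_hi
      ov[[length(ov) + 1]] <- data.frame(
        metabolite_id = met, stratum_a = pairs_[1, k],
        stratum_b = pairs_[2, k], overlapping = overl,
        stringsAsFactors = FALSE)
    }
  }
  overlap <- do.call(rbind, ov)
  rownames(overlap) <- NULL
  list(summaries = summaries, overlap = overlap)
}

#' Gene-by-stratum clustering of discoveries
#'
#' Tabulates, per stratum, the genes whose SNPs carry at least one
#' stage-one discovery: one incidence table for all metabolites, one for
#' lipid analytes only, one for polar analytes only, with per-stratum
#' unique-gene counts.
#'
#' @param discoveries stage-one discovery table (snp_id, metabolite_id,
#'   stratum).
#' @param snp_annotation data.frame(snp_id, gene_label).
#' @param metabolite_annotation data.frame(metabolite_id, class).
#' @return list(tables = list(all, lipid, polar) of gene x stratum 0/1
#'   incidence matrices, counts = per-stratum gene and unique-gene counts).
#' @export
gene_group_clustering <- function(discoveries, snp_annotation,
                                  metabolite_annotation) {
  levels_ <- c("E2", "E3", "E4")
  d <- discoveries
  gene <- snp_annotation$gene_label[match(d$snp_id, snp_annotation$snp_id)]
  gene[is.na(gene)] <- "unassigned"
  cls <- metabolite_annotation$class[
    match(d$metabolite_id, metabolite_annotation$metabolite_id)]
  make_table <- function(sel) {
    if (!any(sel)) return(matrix(0L, 0, length(levels_),
                                 dimnames = list(NULL, levels_)))
    tab <- table(gene[sel], factor(d$stratum[sel], levels = levels_))
    m <- (unclass(tab) > 0) * 1L
    m[order(rownames(m)), , drop = FALSE]
  }
  tables <- list(all = make_table(rep(TRUE, nrow(d))),
                 lipid = make_table(!is.na(cls) & cls == "lipid"),
                 polar = make_table(!is.na(cls) & cls == "polar"))
  counts <- do.call(rbind, lapply(names(tables), function(nm) {
    m <- tables[[nm]]
    data.frame(
      set = nm, stratum = levels_,
      n_genes = if (nrow(m)) colSums(m > 0) else rep(0L, length(levels_)),
      n_unique = if (nrow(m))
        vapply(levels_, function(s)
          sum(m[, s] > 0 & rowSums(m[, setdiff(levels_, s), drop = FALSE]) == 0),
          numeric(1))
      else rep(0L, length(levels_)),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(tables = tables, counts = counts)
}
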