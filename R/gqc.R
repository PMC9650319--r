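# Genotype quality control: MAF, exact Hardy-Weinberg, missingness and
# Mendel-error filters; APOE group assignment; effect-allele alignment.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test of genotype proportions given the allele counts:
#' the p-value is the sum of probabilities of all heterozygote counts (same
#' parity, fixed allele counts) whose conditional probability does not
#' exceed that of the observed table. Two-sided, probability-mass ordering,
#' no mid-p correction.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_input("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop_input("at least one genotype required")
  n_minor <- 2 * n_hom_minor + n_het
  if (n_minor > n) return(hwe_exact_test(n_hom_minor, n_het, n_hom_major))
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log P(het | allele counts) up to a shared constant
  logp <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2      # minor homozygotes
    b <- n - h - a              # major homozygotes
    h * log(2) - lgamma(h + 1) - lgamma(a + 1) - lgamma(b + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Minor-allele frequency from non-missing dosages (dosage counts the coded
# allele; maf is folded to <= 0.5 when requested)
dosage_maf <- function(d, fold = FALSE) {
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  f <- sum(d) / (2 * length(d))
  if (fold) min(f, 1 - f) else f
}

# Enumerate parent-offspring duos and trios with pedigree row indices.
mendel_units <- function(g, ped) {
  ids <- rownames(g$dosage)
  gi <- stats::setNames(seq_along(ids), ids)
  child <- fa <- mo <- integer(0)
  fam <- character(0)
  for (i in seq_len(nrow(ped))) {
    cid <- ped$individual_id[i]
    if (!(cid %in% ids)) next
    f <- ped$father_id[i]; m <- ped$mother_id[i]
    fi <- if (!is.na(f) && f %in% ids) gi[[f]] else NA_integer_
    mi <- if (!is.na(m) && m %in% ids) gi[[m]] else NA_integer_
    if (is.na(fi) && is.na(mi)) next
    child <- c(child, gi[[cid]]); fa <- c(fa, fi); mo <- c(mo, mi)
    fam <- c(fam, ped$family_id[i])
  }
  list(child = child, father = fa, mother = mo, family = fam)
}

# Trio impossibility under Mendelian transmission of a biallelic SNP;
# any argument may be NA (reduces to duo/no test).
mendel_violation <- function(dc, df, dm) {
  duo_bad <- function(dp, dc) !is.na(dp) & !is.na(dc) &
    ((dp == 0 & dc == 2) | (dp == 2 & dc == 0))
  bad <- duo_bad(df, dc) | duo_bad(dm, dc)
  trio <- !is.na(dc) & !is.na(df) & !is.na(dm)
  # both parents homozygous: child fully determined up to sum/2
  bad[trio & df == 0 & dm == 0 & dc != 0] <- TRUE
  bad[trio & df == 2 & dm == 2 & dc != 2] <- TRUE
  bad[trio & ((df == 0 & dm == 2) | (df == 2 & dm == 0)) & dc != 1] <- TRUE
  bad
}

#' Mendel error rates per SNP, subject and family
#'
#' An error is any duo/trio genotype configuration impossible under
#' Mendelian transmission of a biallelic SNP. Rates divide errors by
#' informative tests (the (unit, SNP) combinations with the relevant calls
#' non-missing) for each margin; empty denominators yield rate 0 with a
#' flag.
#'
#' @param g [genotype_matrix()].
#' @param ped pedigree data.frame.
#' @return list(snp, subject, family) of named rate vectors; attribute
#'   `no_tests` flags margins with empty denominators.
#' @export
mendel_error_rates <- function(g, ped) {
  units <- mendel_units(g, ped)
  S <- ncol(g$dosage)
  ids <- rownames(g$dosage)
  snp_err <- snp_tot <- stats::setNames(numeric(S), colnames(g$dosage))
  sub_err <- sub_tot <- stats::setNames(numeric(length(ids)), ids)
  fams <- unique(ped$family_id)
  fam_err <- fam_tot <- stats::setNames(numeric(length(fams)), fams)
  if (length(units$child) > 0) {
    D <- g$dosage
    fam_idx <- match(units$family, fams)
    n_sub <- length(ids)
    acc_sub <- function(store, idx, flag) {
      for (v in idx) {
        ok <- !is.na(v) & flag
        if (any(ok)) {
          t <- tabulate(v[ok], nbins = n_sub)
          store <- store + t
        }
      }
      store
    }
    member_idx <- list(units$child, units$father, units$mother)
    for (j in seq_len(S)) {
      dc <- D[units$child, j]
      df <- D[ifelse(is.na(units$father), 1L, units$father), j]
      df[is.na(units$father)] <- NA
      dm <- D[ifelse(is.na(units$mother), 1L, units$mother), j]
      dm[is.na(units$mother)] <- NA
      informative <- !is.na(dc) & (!is.na(df) | !is.na(dm))
      bad <- mendel_violation(dc, df, dm) & informative
      snp_err[j] <- sum(bad); snp_tot[j] <- sum(informative)
      sub_tot <- acc_sub(sub_tot, member_idx, informative)
      sub_err <- acc_sub(sub_err, member_idx, bad)
      fam_tot <- fam_tot + tabulate(fam_idx[informative], nbins = length(fams))
      fam_err <- fam_err + tabulate(fam_idx[bad], nbins = length(fams))
    }
  }
  rate <- function(e, t) ifelse(t == 0, 0, e / t)
  structure(list(snp = rate(snp_err, snp_tot),
                 subject = rate(sub_err, sub_tot),
                 family = rate(fam_err, fam_tot)),
            no_tests = list(snp = snp_tot == 0, subject = sub_tot == 0,
                            family = fam_tot == 0))
}

#' Compute per-SNP and per-subject QC metrics
#'
#' MAF and the exact Hardy-Weinberg p-value are computed from non-missing
#' calls (HWE on founders only, to avoid relatedness inflation); missing
#' rates per SNP and per subject; Mendel error rates from parent-offspring
#' duos and trios.
#'
#' @param g [genotype_matrix()].
#' @param ped pedigree data.frame (genotyped subjects must be a subset).
#' @return list of class `qc_metrics`: maf, hwe_p, snp_missing_rate,
#'   subject_missing_rate, mendel (list snp/subject/family).
#' @export
compute_qc_metrics <- function(g, ped) {
  ids <- rownames(g$dosage)
  if (!all(ids %in% ped$individual_id))
    stop_input("genotyped subjects must be a subset of the pedigree")
  D <- g$dosage
  maf <- apply(D, 2, dosage_maf, fold = TRUE)
  if (anyNA(maf))
    warning("SNPs with all calls missing have undefined MAF: ",
            paste(colnames(D)[is.na(maf)], collapse = ", "))
  founders <- ped$individual_id[is_founder(ped)]
  Df <- D[intersect(ids, founders), , drop = FALSE]
  if (nrow(Df) == 0) Df <- D   # no founders genotyped: fall back to everyone
  hwe_p <- apply(Df, 2, function(d) {
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  })
  structure(list(
    maf = maf,
    hwe_p = hwe_p,
    snp_missing_rate = colMeans(is.na(D)),
    subject_missing_rate = rowMeans(is.na(D)),
    mendel = mendel_error_rates(g, ped)
  ), class = "qc_metrics")
}

#' Apply genotype quality-control filters
#'
#' Filters in fixed order -- subject missingness, SNP missingness, MAF,
#' HWE, Mendel per SNP, Mendel per subject, Mendel per family -- each
#' recomputed on the survivors of the previous step. Default thresholds:
#' MAF >= 0.01, HWE p >= 1e-6, missingness <= 0.05, Mendel rate <= 0.02.
#'
#' @param g [genotype_matrix()].
#' @param ped pedigree data.frame.
#' @param maf_min,hwe_min,miss_max,mendel_max thresholds.
#' @return list(genotypes = filtered [genotype_matrix()], report =
#'   data.frame(step, criterion, threshold, items_removed, removed_ids)).
#' @export
apply_qc <- function(g, ped, maf_min = 0.01, hwe_min = 1e-6,
                     miss_max = 0.05, mendel_max = 0.02) {
  report <- data.frame(step = integer(0), criterion = character(0),
                       threshold = numeric(0), items_removed = integer(0),
                       removed_ids = character(0), stringsAsFactors = FALSE)
  note <- function(step, criterion, threshold, removed) {
    rbind(report, data.frame(
      step = step, criterion = criterion, threshold = threshold,
      items_removed = length(removed),
      removed_ids = paste(removed, collapse = ","),
      stringsAsFactors = FALSE))
  }
  drop_subjects <- function(g, bad) {
    if (length(bad)) subset_genotypes(g, subjects = setdiff(rownames(g$dosage), bad))
    else g
  }
  drop_snps <- function(g, bad) {
    out <- if (length(bad)) subset_genotypes(g, snps = setdiff(g$snps$snp_id, bad))
           else g
    if (ncol(out$dosage) == 0)
      stop("all SNPs removed by QC; see report", call. = FALSE)
    out
  }

  m <- compute_qc_metrics(g, ped)
  bad <- names(which(m$subject_missing_rate > miss_max))
  report <- note(1L, "subject_missingness", miss_max, bad)
  g <- drop_subjects(g, bad)

  m <- compute_qc_metrics(g, ped)
  bad <- names(which(m$snp_missing_rate > miss_max))
  report <- note(2L, "snp_missingness", miss_max, bad)
  g <- drop_snps(g, bad)

  m <- compute_qc_metrics(g, ped)
  bad <- names(which(is.na(m$maf) | m$maf < maf_min))
  report <- note(3L, "maf", maf_min, bad)
  g <- drop_snps(g, bad)

  m <- compute_qc_metrics(g, ped)
  bad <- names(which(!is.na(m$hwe_p) & m$hwe_p < hwe_min))
  report <- note(4L, "hwe", hwe_min, bad)
  g <- drop_snps(g, bad)

  m <- compute_qc_metrics(g, ped)
  bad <- names(which(m$mendel$snp > mendel_max))
  report <- note(5L, "mendel_snp", mendel_max, bad)
  g <- drop_snps(g, bad)

  m <- compute_qc_metrics(g, ped)
  bad <- names(which(m$mendel$subject > mendel_max))
  bad <- intersect(bad, rownames(g$dosage))
  report <- note(6L, "mendel_subject", mendel_max, bad)
  g <- drop_subjects(g, bad)

  m <- compute_qc_metrics(g, ped)
  badfam <- names(which(m$mendel$family > mendel_max))
  bad <- ped$individual_id[ped$family_id %in% badfam]
  bad <- intersect(bad, rownames(g$dosage))
  report <- note(7L, "mendel_family", mendel_max, bad)
  g <- drop_subjects(g, bad)

  list(genotypes = g, report = report)
}

#' Assign APOE genotype groups from rs429358 and rs7412
#'
#' Joint genotypes at the two APOE-defining SNPs determine the epsilon
#' genotype: (TT, TT) -> e2e2 and (TT, CT) -> e2e3 form the E2 group;
#' (TT, CC) -> e3e3 is E3; (TC, CC) -> e3e4 and (CC, CC) -> e4e4 form E4.
#' The ambiguous double heterozygote (TC, CT) is resolved as e2e4 and
#' excluded; configurations requiring an epsilon-1 haplotype are excluded
#' as implausible; subjects missing either call are excluded.
#'
#' @param g either a [genotype_matrix()] containing rs429358 and rs7412, or
#'   a character vector of rs429358 genotypes (e.g. "TT", "TC", "CC").
#' @param rs7412 character vector of rs7412 genotypes when `g` is a vector.
#' @return data.frame(individual_id, stratum in E2/E3/E4/excluded, reason).
#' @export
assign_apoe_groups <- function(g, rs7412 = NULL) {
  if (inherits(g, "genotype_matrix")) {
    if (!all(c("rs429358", "rs7412") %in% g$snps$snp_id))
      stop_input("rs429358 and rs7412 must both be present")
    geno_string <- function(snp) {
      k <- match(snp, g$snps$snp_id)
      d <- g$dosage[, k]
      mi <- g$snps$allele_minor[k]; ma <- g$snps$allele_major[k]
      ifelse(is.na(d), NA,
             c(paste0(ma, ma), paste0(ma, mi), paste0(mi, mi))[d + 1L])
    }
    g429 <- geno_string("rs429358")
    g7412 <- geno_string("rs7412")
    ids <- rownames(g$dosage)
  } else {
    g429 <- as.character(g)
    g7412 <- as.character(rs7412)
    ids <- names(g429)
    if (is.null(ids)) ids <- paste0("subject_", seq_along(g429))
  }
  norm <- function(x) {
    x <- toupper(x)
    bad <- !is.na(x) & !grepl("^[TC]{2}$", x)
    if (any(bad)) stop_input("non-T/C allele in APOE genotype: ",
                             paste(unique(x[bad]), collapse = ", "))
    ifelse(is.na(x), NA,
           vapply(strsplit(x, ""), function(a) paste(sort(a), collapse = ""),
                  character(1)))
  }
  g429 <- norm(g429); g7412 <- norm(g7412)
  stratum <- rep("excluded", length(g429))
  reason <- rep(NA_character_, length(g429))
  miss <- is.na(g429) | is.na(g7412)
  reason[miss] <- "missing APOE genotype"
  ok <- !miss
  key <- paste(g429, g7412)
  stratum[ok & key == "TT TT"] <- "E2"   # e2e2
  stratum[ok & key == "TT CT"] <- "E2"   # e2e3
  stratum[ok & key == "TT CC"] <- "E3"   # e3e3
  stratum[ok & key == "CT CC"] <- "E4"   # e3e4
  stratum[ok & key == "CC CC"] <- "E4"   # e4e4
  e2e4 <- ok & key == "CT CT"
  reason[e2e4] <- "e2e4"
  implaus <- ok & stratum == "excluded" & !e2e4
  reason[implaus] <- "implausible (requires epsilon-1 haplotype)"
  data.frame(individual_id = ids, stratum = stratum, reason = reason,
             stringsAsFactors = FALSE)
}

#' Align effect alleles across strata
#'
#' The effect allele of every SNP is set to the minor allele in the pooled
#' analyzed sample (E2 u E3 u E4), applied uniformly to all strata, so that
#' per-stratum effect estimates entering cross-group contrasts refer to the
#' same allele. Dosages are recoded 2 - d where flipping is needed; an
#' exact 0.5 frequency tie keeps the lexicographically smaller allele.
#'
#' @param g [genotype_matrix()].
#' @param strata stratum assignment from [assign_apoe_groups()]; NULL pools
#'   all subjects.
#' @return [genotype_matrix()] with attribute `flip_log`
#'   (data.frame(snp_id, pooled_freq, flipped, tie)).
#' @export
align_effect_alleles <- function(g, strata = NULL) {
  ids <- rownames(g$dosage)
  pool <- if (is.null(strata)) ids
          else intersect(ids, strata$individual_id[strata$stratum %in%
                                                   c("E2", "E3", "E4")])
  if (length(pool) == 0) stop_input("pooled sample is empty")
  D <- g$dosage
  freq <- apply(D[pool, , drop = FALSE], 2, dosage_maf)
  tie <- !is.na(freq) & abs(freq - 0.5) < 1e-12
  flip <- !is.na(freq) & freq > 0.5
  # ties: effect allele is the lexicographically smaller allele
  flip[tie] <- g$snps$allele_minor[tie] > g$snps$allele_major[tie]
  if (any(flip)) {
    D[, flip] <- 2L - D[, flip, drop = FALSE]
    tmp <- g$snps$allele_minor[flip]
    g$snps$allele_minor[flip] <- g$snps$allele_major[flip]
    g$snps$allele_major[flip] <- tmp
    if (!is.null(g$haplotypes)) {
      g$haplotypes$H1[, flip] <- 1L - g$haplotypes$H1[, flip, drop = FALSE]
      g$haplotypes$H2[, flip] <- 1L - g$haplotypes$H2[, flip, drop = FALSE]
    }
  }
  out <- genotype_matrix(D, g$snps, g$haplotypes)
  attr(out, "flip_log") <- data.frame(snp_id = g$snps$snp_id,
                                      pooled_freq = freq, flipped = flip,
                                      tie = tie, stringsAsFactors = FALSE)
  out
}
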