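# GenotypeMatrix container and PLINK-text / TSV readers and writers.

#' Construct a genotype matrix
#'
#' Subjects x SNPs minor-allele dosage with SNP metadata; the additive
#' genetic predictor of every downstream model.
#'
#' @param dosage integer matrix of minor-allele counts in \{0, 1, 2, NA\},
#'   rows named by subject id, columns by SNP id.
#' @param snps data.frame with columns snp_id, chromosome, position,
#'   allele_minor, allele_major, gene_label; positions strictly increasing
#'   within chromosome.
#' @param haplotypes optional list(H1, H2) of phased 0/1 minor-allele
#'   indicator matrices.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps, haplotypes = NULL) {
  stopifnot(is.matrix(dosage), nrow(snps) == ncol(dosage))
  colnames(dosage) <- snps$snp_id
  if (!all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)))
    stop_input("dosage values must be 0, 1, 2 or missing")
  if (any(snps$allele_minor == snps$allele_major))
    stop_input("allele_minor must differ from allele_major")
  for (ch in unique(snps$chromosome)) {
    p <- snps$position[snps$chromosome == ch]
    if (any(diff(p) <= 0))
      stop_input("positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosage = dosage, snps = snps,
                 subjects = rownames(dosage), haplotypes = haplotypes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "subjects x",
      ncol(x$dosage), "SNPs",
      if (!is.null(x$haplotypes)) "(phased)" else "(unphased)", "\n")
  invisible(x)
}

#' Combine two genotype matrices over the same subjects
#'
#' Columns are merged and reordered by chromosome/position so the position
#' invariant holds (used to append the APOE-defining SNPs to the regional
#' panel).
#'
#' @param a,b `genotype_matrix` objects with identical subject sets.
#' @return combined `genotype_matrix`.
#' @export
combine_genotypes <- function(a, b) {
  stopifnot(identical(rownames(a$dosage), rownames(b$dosage)))
  snps <- rbind(a$snps, b$snps)
  d <- cbind(a$dosage, b$dosage)
  haps <- NULL
  if (!is.null(a$haplotypes) && !is.null(b$haplotypes))
    haps <- list(H1 = cbind(a$haplotypes$H1, b$haplotypes$H1),
                 H2 = cbind(a$haplotypes$H2, b$haplotypes$H2))
  ord <- order(snps$chromosome, snps$position)
  if (!is.null(haps))
    haps <- list(H1 = haps$H1[, ord, drop = FALSE],
                 H2 = haps$H2[, ord, drop = FALSE])
  genotype_matrix(d[, ord, drop = FALSE], snps[ord, , drop = FALSE], haps)
}

# Subset a genotype matrix to subjects (character ids) and/or SNP ids.
subset_genotypes <- function(g, subjects = NULL, snps = NULL) {
  ri <- if (is.null(subjects)) seq_len(nrow(g$dosage))
        else match(subjects, rownames(g$dosage))
  ci <- if (is.null(snps)) seq_len(ncol(g$dosage))
        else match(snps, g$snps$snp_id)
  ci <- ci[order(g$snps$chromosome[ci], g$snps$position[ci])]
  haps <- g$haplotypes
  if (!is.null(haps))
    haps <- list(H1 = haps$H1[ri, ci, drop = FALSE],
                 H2 = haps$H2[ri, ci, drop = FALSE])
  genotype_matrix(g$dosage[ri, ci, drop = FALSE],
                  g$snps[ci, , drop = FALSE], haps)
}

#' Write PLINK text .ped/.map files
#'
#' White-space-delimited PLINK text format: six leading .ped columns
#' (FID IID PAT MAT SEX PHENO), then two allele letters per SNP
#' (missing = 0). Phased haplotypes, when present, determine the allele
#' order within a genotype.
#'
#' @param g a [genotype_matrix()].
#' @param pedigree pedigree data.frame covering every genotyped subject.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(g, pedigree, prefix) {
  ids <- rownames(g$dosage)
  pi <- match(ids, pedigree$individual_id)
  if (anyNA(pi)) stop_input("genotyped subject missing from pedigree")
  sex <- ifelse(pedigree$sex[pi] == "male", 1L, 2L)
  pat <- ifelse(is.na(pedigree$father_id[pi]), "0", pedigree$father_id[pi])
  mat <- ifelse(is.na(pedigree$mother_id[pi]), "0", pedigree$mother_id[pi])
  S <- ncol(g$dosage)
  allele_cols <- matrix("0", nrow(g$dosage), 2L * S)
  for (j in seq_len(S)) {
    mi <- g$snps$allele_minor[j]
    ma <- g$snps$allele_major[j]
    if (!is.null(g$haplotypes)) {
      a1 <- ifelse(g$haplotypes$H1[, j] == 1L, mi, ma)
      a2 <- ifelse(g$haplotypes$H2[, j] == 1L, mi, ma)
    } else {
      d <- g$dosage[, j]
      a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, mi, ma))
      a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, mi, ma))
    }
    miss <- is.na(g$dosage[, j])
    a1[miss] <- "0"; a2[miss] <- "0"
    allele_cols[, 2L * j - 1L] <- a1
    allele_cols[, 2L * j] <- a2
  }
  ped_out <- cbind(pedigree$family_id[pi], ids, pat, mat, sex, -9L,
                   allele_cols)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  ok <- tryCatch({
    utils::write.table(ped_out, ped_path, quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(
      data.frame(g$snps$chromosome, g$snps$snp_id, 0, g$snps$position),
      map_path, quote = FALSE, sep = " ",
      row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O failure writing ", prefix, ".ped/.map: ",
         conditionMessage(ok), call. = FALSE)
  invisible(c(ped_path, map_path))
}

#' Read PLINK text .ped/.map files
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @param snp_annotation optional data.frame (snp_id, allele_minor,
#'   allele_major, gene_label) fixing the minor-allele coding; otherwise the
#'   minor allele is the less frequent one (ties broken lexicographically).
#' @return list(genotypes = [genotype_matrix()], pedigree = data.frame).
#' @export
read_plink <- function(prefix, snp_annotation = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chromosome", "snp_id", "cm", "position")
  ped_raw <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                               colClasses = "character")
  S <- nrow(map)
  if (ncol(ped_raw) != 6L + 2L * S)
    stop_input(".ped column count does not match .map SNP count")
  n <- nrow(ped_raw)
  pedigree <- data.frame(
    family_id = ped_raw[[1]],
    individual_id = ped_raw[[2]],
    father_id = ifelse(ped_raw[[3]] == "0", NA, ped_raw[[3]]),
    mother_id = ifelse(ped_raw[[4]] == "0", NA, ped_raw[[4]]),
    sex = ifelse(ped_raw[[5]] == "1", "male", "female"),
    stringsAsFactors = FALSE
  )
  dosage <- matrix(NA_integer_, n, S)
  minor <- major <- character(S)
  for (j in seq_len(S)) {
    a1 <- ped_raw[[6L + 2L * j - 1L]]
    a2 <- ped_raw[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) > 2)
      stop_input("SNP ", map$snp_id[j], " has more than two alleles")
    if (!is.null(snp_annotation) &&
        map$snp_id[j] %in% snp_annotation$snp_id) {
      k <- match(map$snp_id[j], snp_annotation$snp_id)
      minor[j] <- snp_annotation$allele_minor[k]
      major[j] <- snp_annotation$allele_major[k]
    } else if (length(alleles) == 0) {
      minor[j] <- "N"; major[j] <- "M"  # all missing; flagged downstream
    } else {
      cnt <- table(factor(c(a1[!miss], a2[!miss]), levels = alleles))
      if (length(alleles) == 1) {
        major[j] <- alleles
        minor[j] <- setdiff(c("A", "C", "G", "T"), alleles)[1]
      } else {
        # less frequent allele is minor; tie broken lexicographically
        minor[j] <- if (cnt[1] < cnt[2] || (cnt[1] == cnt[2])) alleles[1]
                    else alleles[2]
        major[j] <- setdiff(alleles, minor[j])
      }
    }
    d <- (a1 == minor[j]) + (a2 == minor[j])
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  rownames(dosage) <- pedigree$individual_id
  gene <- if (!is.null(snp_annotation))
    snp_annotation$gene_label[match(map$snp_id, snp_annotation$snp_id)]
  else NA_character_
  snps <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                     position = map$position, allele_minor = minor,
                     allele_major = major, gene_label = gene,
                     stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage, snps), pedigree = pedigree)
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O failure writing ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Emits PLINK text `cohort.ped`/`cohort.map`, `metabolites.tsv` (subjects x
#' analytes), `metabolite_classes.tsv`, `covariates.tsv`,
#' `snp_annotation.tsv` and `truth.tsv` (the effect plan). The files
#' round-trip losslessly through [read_fixture()].
#'
#' @param cohort a cohort list from [simulate_cohort()].
#' @param outdir writable output directory (created if absent).
#' @return invisibly, the output directory.
#' @export
write_fixture <- function(cohort, outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  write_plink(cohort$genotypes, cohort$pedigree, file.path(outdir, "cohort"))
  met <- data.frame(individual_id = rownames(cohort$metabolites$values),
                    cohort$metabolites$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(met, file.path(outdir, "metabolites.tsv"))
  write_tsv(cohort$metabolites$annotation,
            file.path(outdir, "metabolite_classes.tsv"))
  write_tsv(cohort$covariates, file.path(outdir, "covariates.tsv"))
  write_tsv(cohort$genotypes$snps, file.path(outdir, "snp_annotation.tsv"))
  write_tsv(as.data.frame(cohort$plan), file.path(outdir, "truth.tsv"))
  invisible(outdir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return cohort list (pedigree, genotypes, covariates, metabolites,
#'   strata, plan).
#' @export
read_fixture <- function(dir) {
  ann <- read_tsv(file.path(dir, "snp_annotation.tsv"))
  pl <- read_plink(file.path(dir, "cohort"), snp_annotation = ann)
  met_tab <- read_tsv(file.path(dir, "metabolites.tsv"))
  V <- as.matrix(met_tab[, -1, drop = FALSE])
  rownames(V) <- met_tab$individual_id
  panel <- structure(
    list(values = V,
         annotation = read_tsv(file.path(dir, "metabolite_classes.tsv"))),
    class = "metabolite_panel")
  plan_df <- read_tsv(file.path(dir, "truth.tsv"))
  plan <- if (nrow(plan_df) == 0) effect_plan()
          else effect_plan(plan_df$snp_id, plan_df$metabolite_id,
                           plan_df$stratum, plan_df$beta_true)
  strata <- tryCatch(assign_apoe_groups(pl$genotypes),
                     error = function(e) NULL)
  list(pedigree = pl$pedigree, genotypes = pl$genotypes,
       covariates = read_tsv(file.path(dir, "covariates.tsv")),
       metabolites = panel, strata = strata, plan = plan)
}
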