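# Orchestration: simulate (or load) -> QC -> stratified scan -> contrasts /
# interactions / pooled re-analysis -> diagnostics -> enrichment, with a
# reproducibility manifest.

#' Run the full stratified analysis pipeline
#'
#' Executes every stage in order on a simulated cohort (or a fixture
#' directory written by [write_fixture()]): genotype QC at the standard
#' thresholds, APOE group assignment and effect-allele alignment, the
#' stage-one stratified mixed-model scan with BH discovery, stage-two
#' heterogeneity contrasts with interaction-model corroboration, the
#' pooled-sample re-analysis, diagnostics (VIF, metabolite summaries,
#' gene-by-stratum clustering, LD among discovered SNPs) and, when a GMT
#' library is supplied, pathway over-representation of the discovered
#' polar/lipid analytes. Any stage failure halts with a partial manifest.
#'
#' @param config a [sim_config()] (ignored when `fixture_dir` is given).
#' @param plan an [effect_plan()] of planted effects.
#' @param fixture_dir optional directory of fixture files to analyze
#'   instead of simulating.
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSVs and checksummed in the manifest.
#' @param gmt optional GMT path for the enrichment stage.
#' @param maf_min,hwe_min,miss_max,mendel_max QC thresholds.
#' @param fdr stage-one discovery threshold.
#' @param alpha stage-two family-wise level.
#' @param n_pcs genetic principal components used as covariates.
#' @param run_interactions fit the corroborating interaction model for each
#'   significant contrast (default TRUE).
#' @param fdr_family passed to [run_stratified_scan()].
#' @param on_error `"stop"` (default) propagates a stage failure;
#'   `"partial"` halts at the failing stage and returns the completed
#'   stages with a partial manifest recording the error.
#' @return list of class `pipeline_run`: cohort, qc_report, scan,
#'   contrasts, interactions, pooled, diagnostics, enrichment, manifest.
#' @export
run_pipeline <- function(config = sim_config(), plan = effect_plan(),
                         fixture_dir = NULL, outdir = NULL, gmt = NULL,
                         maf_min = 0.01, hwe_min = 1e-6, miss_max = 0.05,
                         mendel_max = 0.02, fdr = 0.05, alpha = 0.05,
                         n_pcs = 5, run_interactions = TRUE,
                         fdr_family = "stratum",
                         on_error = c("stop", "partial")) {
  on_error <- match.arg(on_error)
  if (is.null(fixture_dir) && !inherits(config, "sim_config"))
    stop_config("config must be a sim_config (or supply fixture_dir)")
  t0 <- proc.time()[["elapsed"]]
  stages <- character(0)
  timings <- numeric(0)
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    stages <<- c(stages, name)
    t0 <<- t1
  }
  manifest <- list(
    config = if (is.null(fixture_dir)) unclass(config) else NULL,
    fixture_dir = fixture_dir,
    seed = if (is.null(fixture_dir)) config$seed else NA_integer_,
    thresholds = list(maf_min = maf_min, hwe_min = hwe_min,
                      miss_max = miss_max, mendel_max = mendel_max,
                      fdr = fdr, alpha = alpha),
    version = as.character(utils::packageVersion("apoemqtl"))
  )

  cohort <- qc <- strata <- scan <- contrasts <- interactions <-
    pooled <- diagnostics <- enrichment <- NULL
  failed <- NULL

  stage_fns <- list(
    syndata = function() {
      cohort <<- if (is.null(fixture_dir)) simulate_cohort(config, plan)
                 else read_fixture(fixture_dir)
      if (is.null(cohort$metabolites))
        stop_input("metabolites missing from fixture")
    },
    gqc = function() {
      qc <<- apply_qc(cohort$genotypes, cohort$pedigree, maf_min = maf_min,
                      hwe_min = hwe_min, miss_max = miss_max,
                      mendel_max = mendel_max)
      strata <<- if (all(c("rs429358", "rs7412") %in%
                           qc$genotypes$snps$snp_id))
        assign_apoe_groups(qc$genotypes)
      else cohort$strata
      if (is.null(strata))
        stop_input("APOE SNPs absent and no precomputed strata available")
      cohort$genotypes <<- align_effect_alleles(qc$genotypes, strata)
      cohort$strata <<- strata
    },
    assoc = function() {
      scan <<- run_stratified_scan(cohort, strata = strata, fdr = fdr,
                                   n_pcs = n_pcs, fdr_family = fdr_family)
    },
    hetero = function() {
      contrasts <<- find_group_specific(scan, alpha = alpha)
      if (run_interactions && nrow(contrasts) > 0) {
        sig <- contrasts[contrasts$significant & !contrasts$untestable, ,
                         drop = FALSE]
        if (nrow(sig) > 0) {
          pcs <- if (n_pcs > 0) genotype_pcs(cohort$genotypes, k = n_pcs,
                                             pedigree = cohort$pedigree)
                 else NULL
          interactions <<- do.call(rbind,
            lapply(seq_len(nrow(sig)), function(i)
              interaction_test(cohort, strata,
                               pair = c(sig$group_a[i], sig$group_b[i]),
                               snp_id = sig$snp_id[i],
                               metabolite_id = sig$metabolite_id[i],
                               n_pcs = n_pcs, pcs = pcs)))
        }
      }
      pooled <<- pooled_scan(cohort, strata, discoveries = scan$discoveries,
                             group_specific = contrasts, fdr = fdr,
                             n_pcs = n_pcs, fdr_family = fdr_family)
    },
    diagnostics = function() {
      disc <- scan$discoveries
      diag_ld <- if (nrow(disc) > 0 && length(unique(disc$snp_id)) >= 2)
        ld_matrix(subset_genotypes(cohort$genotypes,
                                   snps = unique(disc$snp_id)),
                  pedigree = cohort$pedigree)
      else NULL
      diagnostics <<- list(
        vif = vif(cohort$genotypes, cohort$covariates),
        ld = diag_ld,
        summaries = if (nrow(disc) > 0)
          metabolite_summaries(cohort$metabolites, strata,
                               metabolite_ids = unique(disc$metabolite_id))
        else NULL,
        clustering = gene_group_clustering(disc, cohort$genotypes$snps,
                                           cohort$metabolites$annotation))
    },
    enrich = function() {
      if (!is.null(gmt)) {
        lib <- load_gmt(gmt)
        if (nrow(scan$discoveries) > 0)
          enrichment <<- enrich_table(unique(scan$discoveries$metabolite_id),
                                      lib)
      }
    })

  for (nm in names(stage_fns)) {
    ok <- tryCatch({ stage_fns[[nm]](); TRUE }, error = function(e) {
      if (on_error == "stop") stop(e)
      failed <<- list(stage = nm, message = conditionMessage(e))
      FALSE
    })
    if (!ok) break
    tick(nm)
  }

  manifest$timings <- timings
  manifest$stages <- stages
  manifest$failed <- failed
  if (!is.null(scan)) {
    disc <- scan$discoveries
    manifest$counts <- list(
      n_subjects = nrow(cohort$pedigree),
      n_snps_post_qc = ncol(cohort$genotypes$dosage),
      stratum_sizes = table(strata$stratum),
      discoveries_per_stratum = table(factor(disc$stratum,
                                             levels = c("E2", "E3", "E4"))),
      n_group_specific = if (!is.null(contrasts) && nrow(contrasts))
        length(unique(paste(contrasts$snp_id, contrasts$metabolite_id,
                            contrasts$group_a,
                            contrasts$group_b)[contrasts$significant]))
        else 0L,
      n_pooled_replicated = if (is.null(pooled)) NA_integer_
        else sum(pooled$overlap$replicated, na.rm = TRUE))
  }

  run <- list(cohort = cohort,
              qc_report = if (is.null(qc)) NULL else qc$report,
              scan = scan, contrasts = contrasts,
              interactions = interactions, pooled = pooled,
              diagnostics = diagnostics, enrichment = enrichment,
              manifest = manifest)
  class(run) <- "pipeline_run"
  if (!is.null(outdir) && is.null(failed)) write_run(run, outdir)
  run
}

# Write stage outputs as TSVs and add their checksums to the manifest.
write_run <- function(run, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- c(
    qc_report = "qc_report.tsv", associations = "associations.tsv",
    discoveries = "discoveries.tsv", contrasts = "contrasts.tsv",
    interactions = "interactions.tsv", pooled = "pooled.tsv",
    pooled_overlap = "pooled_overlap.tsv", vif = "vif.tsv")
  write_tsv(run$qc_report, file.path(outdir, files["qc_report"]))
  write_tsv(run$scan$results, file.path(outdir, files["associations"]))
  write_tsv(run$scan$discoveries, file.path(outdir, files["discoveries"]))
  write_tsv(as.data.frame(run$contrasts), file.path(outdir, files["contrasts"]))
  if (!is.null(run$interactions))
    write_tsv(run$interactions, file.path(outdir, files["interactions"]))
  write_tsv(run$pooled$results, file.path(outdir, files["pooled"]))
  write_tsv(run$pooled$overlap, file.path(outdir, files["pooled_overlap"]))
  write_tsv(run$diagnostics$vif, file.path(outdir, files["vif"]))
  if (!is.null(run$diagnostics$ld)) {
    ld <- run$diagnostics$ld
    write_tsv(data.frame(snp_id = rownames(ld), as.data.frame(unclass(ld)),
                         check.names = FALSE),
              file.path(outdir, "ld_matrix.tsv"))
  }
  if (!is.null(run$enrichment))
    write_tsv(as.data.frame(run$enrichment),
              file.path(outdir, "enrichment.tsv"))
  written <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  run$manifest$checksums <- tools::md5sum(written)
  saved <- run$manifest
  saved$timings <- NULL   # timings are not part of the reproducible state
  writeLines(utils::capture.output(utils::str(saved, vec.len = 100)),
             file.path(outdir, "manifest.txt"))
  invisible(run)
}

#' Summarize a pipeline run
#'
#' Prints per-stratum discovery counts, the number of significant
#' group-specific contrasts, interaction corroborations and pooled-sample
#' replications, mirroring the headline structure of a stratified
#' metabolite association study.
#'
#' @param run a `pipeline_run`.
#' @return invisibly, a data.frame of the printed counts.
#' @export
report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  cnt <- run$manifest$counts
  if (is.null(cnt)) {
    incomplete <- setdiff(c("syndata", "gqc", "assoc", "hetero",
                            "diagnostics", "enrich"), run$manifest$stages)
    cat(sprintf("stage '%s' failed: %s\n", run$manifest$failed$stage,
                run$manifest$failed$message),
        paste("not run:", paste(incomplete, collapse = ", ")), sep = "\n")
    return(invisible(NULL))
  }
  disc <- cnt$discoveries_per_stratum
  lines <- c(
    sprintf("subjects: %d (E2/E3/E4 = %s)", cnt$n_subjects,
            paste(cnt$stratum_sizes[c("E2", "E3", "E4")], collapse = "/")),
    sprintf("SNPs after QC: %d", cnt$n_snps_post_qc),
    sprintf("stage-one discoveries: %d (E2 %d, E3 %d, E4 %d)",
            sum(disc), disc[["E2"]], disc[["E3"]], disc[["E4"]]),
    sprintf("group-specific contrasts (Bonferroni): %d",
            cnt$n_group_specific),
    sprintf("interaction corroborations fitted: %d",
            if (is.null(run$interactions)) 0L else nrow(run$interactions)),
    sprintf("pooled-sample replications: %d", cnt$n_pooled_replicated))
  incomplete <- setdiff(c("syndata", "gqc", "assoc", "hetero",
                          "diagnostics", "enrich"), run$manifest$stages)
  if (length(incomplete))
    lines <- c(lines, paste("not run:", paste(incomplete, collapse = ", ")))
  cat(lines, sep = "\n")
  invisible(data.frame(
    metric = c("discoveries_total", "discoveries_E2", "discoveries_E3",
               "discoveries_E4", "group_specific", "pooled_replicated"),
    value = c(sum(disc), disc[["E2"]], disc[["E3"]], disc[["E4"]],
              cnt$n_group_specific, cnt$n_pooled_replicated)))
}
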