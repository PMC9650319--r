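# Bundled reference tables.

#' Published group-specific association estimates
#'
#' Reported stage-one effect estimates (beta, SE per APOE group) and
#' heterogeneity statistics for the 20 group-specific SNP-metabolite
#' associations from a published APOE-stratified analysis of plasma
#' metabolites in the Framingham Offspring cohort (19q13.3 region, hg38).
#' Used by the worked examples to recompute the cross-group chi-square
#' contrasts from reported inputs; `chi2_1`/`chi2_2` and `p_1`/`p_2` are
#' the printed statistics for the two reported contrasts (`contrast1`,
#' `contrast2`).
#'
#' @return data.frame with one row per reported association.
#' @export
published_group_specific <- function() {
  path <- system.file("extdata", "fhs_group_specific_estimates.tsv",
                      package = "apoemqtl", mustWork = TRUE)
  read_tsv(path)
}

#' Path to the bundled synthetic pathway library
#'
#' A small synthetic GMT file over the simulated metabolite identifiers,
#' for demonstrating the enrichment stage on simulated cohorts. Entirely
#' synthetic: the groupings carry no biochemical meaning.
#'
#' @return file path.
#' @export
synthetic_gmt <- function() {
  system.file("extdata", "synthetic_pathways.gmt", package = "apoemqtl",
              mustWork = TRUE)
}
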