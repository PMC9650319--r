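# Hypergeometric over-representation analysis of metabolite hit lists
# against a GMT pathway library.

norm_name <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Load a GMT pathway library
#'
#' Tab-delimited GMT: pathway name, description, then member identifiers.
#' Members are de-duplicated (case/whitespace-normalized); lines without a
#' name or members are skipped with a warning.
#'
#' @param path GMT file path.
#' @param background_size reference metabolome size; default the size of
#'   the union of all members.
#' @return list of class `pathway_library`: pathways (name -> member set),
#'   background_size.
#' @export
load_gmt <- function(path, background_size = NULL) {
  lines <- readLines(path, warn = FALSE)
  pathways <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    members <- unique(norm_name(parts[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(parts) < 3 || !nzchar(trimws(parts[1])) ||
        length(members) == 0) {
      warning("skipping GMT line without name or members")
      next
    }
    pathways[[trimws(parts[1])]] <- members
  }
  if (length(pathways) == 0) stop_input("no valid pathways in GMT file")
  union_size <- length(unique(unlist(pathways)))
  if (is.null(background_size)) background_size <- union_size
  if (background_size < union_size ||
      background_size < max(lengths(pathways)))
    stop_input("background_size smaller than the pathway universe")
  structure(list(pathways = pathways, background_size = background_size),
            class = "pathway_library")
}

#' Hypergeometric over-representation p-value
#'
#' P(X >= k) when drawing `n` metabolites from a background of `N` of which
#' `K` belong to the pathway.
#'
#' @param k observed hits in the pathway.
#' @param n input (hit list) size.
#' @param K pathway size.
#' @param N background metabolome size.
#' @return upper-tail probability.
#' @export
ora_hypergeom <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || K > N || n > N)
    stop_input("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway enrichment table
#'
#' One row per pathway with at least one hit: pathway size (Total), hits
#' among the input metabolites (Hits), hypergeometric upper-tail P and
#' Benjamini-Hochberg q over all tested pathways, sorted by P. Name
#' matching is exact after lower-casing and whitespace normalization;
#' unmapped inputs are reported in the `unmapped` attribute.
#'
#' @param hits character vector of metabolite identifiers.
#' @param library a `pathway_library` from [load_gmt()].
#' @return data.frame(pathway, total, hits, p, q) of class
#'   `enrichment_result`.
#' @export
enrich_table <- function(hits, library) {
  stopifnot(inherits(library, "pathway_library"))
  if (length(hits) == 0) {
    warning("empty hit list; empty enrichment table")
    out <- data.frame(pathway = character(0), total = integer(0),
                      hits = integer(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  hset <- unique(norm_name(hits))
  vocab <- unique(unlist(library$pathways))
  unmapped <- hset[!(hset %in% vocab)]
  n <- length(hset)
  N <- library$background_size
  rows <- lapply(names(library$pathways), function(nm) {
    members <- library$pathways[[nm]]
    k <- sum(hset %in% members)
    if (k == 0) return(NULL)
    data.frame(pathway = nm, total = length(members), hits = k,
               p = ora_hypergeom(k, n, length(members), N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(pathway = character(0), total = integer(0),
                      hits = integer(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$q <- bh_fdr(out$p)
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unmapped") <- unmapped
  class(out) <- c("enrichment_result", "data.frame")
  out
}
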