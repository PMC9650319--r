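#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)
stop_input <- function(...) stop("input error: ", ..., call. = FALSE)

# Topological order of a pedigree (parents before offspring).
# Errors on cycles (an individual that is its own ancestor).
pedigree_order <- function(ped) {
  n <- nrow(ped)
  id <- ped$individual_id
  idx <- stats::setNames(seq_len(n), id)
  fa <- idx[as.character(ped$father_id)]
  mo <- idx[as.character(ped$mother_id)]
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n)
    stop("structural error: pedigree contains a cycle or a parent reference ",
         "outside the pedigree", call. = FALSE)
  ord
}

is_founder <- function(ped) is.na(ped$father_id) & is.na(ped$mother_id)

#' Validate a pedigree table
#'
#' Checks the structural invariants of a pedigree: unique individual ids,
#' parent ids resolving to records in the same family, founders having both
#' parents missing or neither, and absence of ancestry cycles.
#'
#' @param ped data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (NA for founders) and `sex`
#'   (`"male"`/`"female"`).
#' @return `ped`, invisibly, after validation.
#' @export
validate_pedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  if (!all(need %in% names(ped)))
    stop_input("pedigree must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(ped$individual_id))
    stop_input("duplicate individual ids in pedigree")
  if (!all(ped$sex %in% c("male", "female")))
    stop_input("sex must be 'male' or 'female'")
  fam <- stats::setNames(ped$family_id, ped$individual_id)
  for (col in c("father_id", "mother_id")) {
    p <- ped[[col]]
    has <- !is.na(p)
    if (any(has & !(p %in% ped$individual_id)))
      stop_input(col, " refers to an individual not in the pedigree")
    if (any(has) &&
        any(fam[as.character(p[has])] != ped$family_id[has]))
      stop_input(col, " refers to an individual in a different family")
  }
  if (any(xor(is.na(ped$father_id), is.na(ped$mother_id))))
    stop("structural error: individuals must have both parents or neither",
         call. = FALSE)
  pedigree_order(ped)  # errors on cycles
  invisible(ped)
}
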