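#' Filter-cascade configuration
#'
#' Settings for the rarity / consequence / expression cascade applied to the
#' shared-candidate set. Defaults mirror a strict "novel or very rare,
#' protein-altering, brain-expressed" policy: remove anything present in the
#' in-house cohort database (presence-based, not frequency-based), remove
#' anything with population MAF at or above 1%, keep non-synonymous
#' consequences only, and require validated brain expression.
#'
#' @param maf_threshold variants with `pop_maf >= maf_threshold` are removed
#'   (strictly-below-threshold survives; default 0.01).
#' @param require_absent_from_cohort_db remove any candidate flagged present
#'   in the in-house cohort database (default TRUE).
#' @param cohort_db_size metadata only: number of exomes behind the cohort
#'   database (default 700); recorded in traces, never used in logic.
#' @param keep_consequences consequence classes retained (default
#'   `"non_synonymous"`).
#' @param require_brain_expression keep only candidates whose gene carries a
#'   validated brain-expression flag (default TRUE).
#' @return a `filter_config` list.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          require_absent_from_cohort_db = TRUE,
                          cohort_db_size = 700L,
                          keep_consequences = "non_synonymous",
                          require_brain_expression = TRUE) {
  if (!(maf_threshold > 0 && maf_threshold <= 1))
    stop_user("filter_config: maf_threshold must be in (0, 1]")
  if (!length(keep_consequences))
    stop_user("filter_config: keep_consequences must be non-empty")
  structure(list(maf_threshold = maf_threshold,
                 require_absent_from_cohort_db = isTRUE(require_absent_from_cohort_db),
                 cohort_db_size = as.integer(cohort_db_size),
                 keep_consequences = keep_consequences,
                 require_brain_expression = isTRUE(require_brain_expression)),
            class = "filter_config")
}

# look up one annotation column for a vector of keys; NA when the key has no
# annotation row (absent annotation = novel / unknown convention)
ann_col <- function(keys, annotations, col) {
  if (is.null(annotations) || is.null(annotations[[col]]))
    return(rep(NA, length(keys)))
  annotations[[col]][match(keys, annotations$key)]
}

filter_result <- function(candidates, keep, reason, notes = NULL) {
  removed <- data.frame(key = candidates[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(kept = candidates[keep], removed = removed,
       notes = notes %||% data.frame(key = character(0), note = character(0)))
}

#' Remove candidates present in the in-house cohort database
#'
#' Presence-based removal: any candidate flagged `in_cohort_db = TRUE` is
#' removed with reason `IN_COHORT_DB`, regardless of its frequency in that
#' database. Candidates with no cohort annotation are retained and noted
#' `NOVEL`.
#'
#' @param candidates character vector of variant keys.
#' @param annotations annotation data.frame (see [read_annotation_table()]).
#' @param cfg a [filter_config()].
#' @return list(kept, removed, notes); `removed` has columns key, reason.
#' @export
filter_cohort_db <- function(candidates, annotations, cfg = filter_config()) {
  if (!cfg$require_absent_from_cohort_db)
    return(filter_result(candidates, rep(TRUE, length(candidates)),
                         rep(NA_character_, length(candidates))))
  in_db <- as.logical(ann_col(candidates, annotations, "in_cohort_db"))
  keep <- is.na(in_db) | !in_db
  novel <- candidates[is.na(in_db)]
  notes <- data.frame(key = novel, note = rep("NOVEL", length(novel)),
                      stringsAsFactors = FALSE)
  filter_result(candidates, keep, rep("IN_COHORT_DB", length(candidates)), notes)
}

#' Remove candidates common in reference populations
#'
#' Removes candidates with `pop_maf >= maf_threshold` (reason `COMMON_MAF`);
#' candidates with no population frequency are treated as novel and
#' retained.
#'
#' @inheritParams filter_cohort_db
#' @return list(kept, removed, notes).
#' @export
filter_population_maf <- function(candidates, annotations, cfg = filter_config()) {
  maf <- as.numeric(ann_col(candidates, annotations, "pop_maf"))
  keep <- is.na(maf) | maf < cfg$maf_threshold
  filter_result(candidates, keep, rep("COMMON_MAF", length(candidates)))
}

#' Keep candidates with retained consequence classes
#'
#' Keeps candidates whose consequence is in `keep_consequences`. Candidates
#' with unknown or missing consequence are removed with reason
#' `UNKNOWN_CONSEQUENCE`; known-but-excluded classes get
#' `CONSEQUENCE_NOT_KEPT`.
#'
#' @inheritParams filter_cohort_db
#' @return list(kept, removed, notes).
#' @export
filter_consequence <- function(candidates, annotations, cfg = filter_config()) {
  csq <- as.character(ann_col(candidates, annotations, "consequence"))
  keep <- !is.na(csq) & csq %in% cfg$keep_consequences
  reason <- ifelse(is.na(csq) | csq == "unknown",
                   "UNKNOWN_CONSEQUENCE", "CONSEQUENCE_NOT_KEPT")
  filter_result(candidates, keep, reason)
}

#' Keep candidates in genes with validated brain expression
#'
#' Keeps candidates with `brain_expressed = TRUE` (the flag is a packaged
#' input, typically derived from a gene whitelist; its computation is
#' external). When expression is required, candidates with no annotation are
#' an error — the whitelist decision must be explicit.
#'
#' @inheritParams filter_cohort_db
#' @return list(kept, removed, notes).
#' @export
filter_expression <- function(candidates, annotations, cfg = filter_config()) {
  if (!cfg$require_brain_expression)
    return(filter_result(candidates, rep(TRUE, length(candidates)),
                         rep(NA_character_, length(candidates))))
  expr <- as.logical(ann_col(candidates, annotations, "brain_expressed"))
  if (anyNA(expr))
    stop_user("filter_expression: missing brain_expressed annotation for: ",
              paste(candidates[is.na(expr)], collapse = ", "))
  filter_result(candidates, expr, rep("NOT_BRAIN_EXPRESSED", length(candidates)))
}

#' Apply brain-expression whitelist to an annotation table
#'
#' Fills/overrides the `brain_expressed` column from a gene whitelist
#' (gene symbol in whitelist => TRUE, else FALSE).
#'
#' @param annotations annotation data.frame with a `gene` column.
#' @param whitelist character vector of gene symbols.
#' @return the annotation data.frame with `brain_expressed` set.
#' @export
apply_whitelist <- function(annotations, whitelist) {
  if (is.null(annotations$gene))
    stop_user("apply_whitelist: annotation table has no gene column")
  annotations$brain_expressed <- annotations$gene %in% whitelist
  annotations
}

#' Run the full annotation filter cascade
#'
#' Applies cohort-database, population-MAF, expression and consequence
#' filters in the fixed pipeline order. The filters have set-intersection
#' semantics (each is idempotent and order-independent); order affects only
#' which reason a doubly-failing variant is attributed to.
#'
#' @param candidates character vector of variant keys.
#' @param annotations annotation data.frame.
#' @param cfg a [filter_config()].
#' @return list with `kept` (keys), `removed` (data.frame key, reason),
#'   `stages` (data.frame stage, n_in, n_out), `notes`.
#' @export
run_filter_cascade <- function(candidates, annotations, cfg = filter_config()) {
  stages <- list(cohort_db = filter_cohort_db,
                 population_maf = filter_population_maf,
                 expression = filter_expression,
                 consequence = filter_consequence)
  kept <- candidates
  removed <- list(); notes <- list(); stage_rows <- list()
  for (nm in names(stages)) {
    res <- stages[[nm]](kept, annotations, cfg)
    stage_rows[[nm]] <- data.frame(stage = nm, n_in = length(kept),
                                   n_out = length(res$kept))
    stopifnot(length(res$kept) + nrow(res$removed) == length(kept))
    removed[[nm]] <- res$removed
    notes[[nm]] <- res$notes
    kept <- res$kept
  }
  list(kept = kept,
       removed = do.call(rbind, c(removed, list(make.row.names = FALSE))),
       stages = do.call(rbind, c(stage_rows, list(make.row.names = FALSE))),
       notes = do.call(rbind, c(notes, list(make.row.names = FALSE))))
}
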