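#' Inheritance model for co-segregation verdicts
#'
#' The dominant model under which per-variant verdicts are issued. "High
#' penetrance" is operationalized as a tolerated count of unaffected typed
#' carriers (`max_unaffected_carriers`); the default 0 encodes complete
#' penetrance among typed individuals, because a single unaffected carrier
#' is treated as disqualifying. `exception_ids` name carriers whose
#' transmission from a common ancestor must be separately confirmed (e.g.
#' an affected individual one of whose parents is untyped with unknown
#' phenotype, so the transmitting side is unclear).
#'
#' @param mode only `"autosomal_dominant"` is implemented.
#' @param max_unaffected_carriers tolerated unaffected typed carriers
#'   (default 0).
#' @param carrier_genotypes genotype(s) counting as carrying (default het).
#' @param exception_ids character vector of individual ids.
#' @param exception_notes optional named character vector of per-id notes.
#' @return an `inheritance_model` list.
#' @export
inheritance_model <- function(mode = "autosomal_dominant",
                              max_unaffected_carriers = 0L,
                              carrier_genotypes = "het",
                              exception_ids = character(0),
                              exception_notes = NULL) {
  mode <- match.arg(mode)
  if (max_unaffected_carriers < 0)
    stop_user("inheritance_model: max_unaffected_carriers must be >= 0")
  if (!length(carrier_genotypes) || !all(carrier_genotypes %in% c("het", "hom_alt")))
    stop_user("inheritance_model: carrier_genotypes must be a non-empty subset of {het, hom_alt}")
  structure(list(mode = mode,
                 max_unaffected_carriers = as.integer(max_unaffected_carriers),
                 carrier_genotypes = carrier_genotypes,
                 exception_ids = as.character(exception_ids),
                 exception_notes = exception_notes),
            class = "inheritance_model")
}

#' Override exome genotypes with validation genotypes
#'
#' Validation (Sanger-style) genotypes replace exome calls for the same
#' (variant, individual) pair and may add genotypes for individuals never
#' exome-sequenced (who thereby become typed for those variants only).
#' Override provenance is recorded (`source = "validation"`).
#'
#' @param table a genotype_table.
#' @param validation TSV path or data.frame with columns `variant_key`
#'   (`chrom:pos:ref:alt`), `individual_id`, `genotype` in
#'   `0/0`, `0/1`, `1/1`, `./.`.
#' @param ped optional pedigree; if given, validation individuals must exist
#'   in it.
#' @return a genotype_table.
#' @export
apply_validation <- function(table, validation, ped = NULL) {
  if (is.character(validation)) {
    if (!file.exists(validation))
      stop_user("apply_validation: file not found: ", validation)
    validation <- as.data.frame(data.table::fread(validation, sep = "\t",
                                                  header = TRUE,
                                                  colClasses = "character"))
  }
  validation <- as.data.frame(validation, stringsAsFactors = FALSE)
  if (!nrow(validation)) return(table)
  req <- c("variant_key", "individual_id", "genotype")
  miss <- setdiff(req, names(validation))
  if (length(miss))
    stop_user("apply_validation: missing column(s): ", paste(miss, collapse = ", "))
  gt_map <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
              "1/1" = "hom_alt", "./." = "missing")
  gt <- gt_map[validation$genotype]
  if (anyNA(gt))
    stop_user("apply_validation: invalid genotype string(s): ",
              paste(unique(validation$genotype[is.na(gt)]), collapse = ", "))
  pair <- paste(validation$variant_key, validation$individual_id)
  dup <- duplicated(pair) | duplicated(pair, fromLast = TRUE)
  if (any(dup)) {
    contradict <- tapply(gt[dup], pair[dup], function(g) length(unique(g)) > 1L)
    if (any(contradict))
      stop_user("apply_validation: contradictory duplicate validation rows for: ",
                paste(names(contradict)[contradict], collapse = ", "))
    keepu <- !duplicated(pair)
    validation <- validation[keepu, , drop = FALSE]
    gt <- gt[keepu]
  }
  bad_key <- setdiff(validation$variant_key, table$variants$key)
  if (length(bad_key))
    stop_user("apply_validation: variant key(s) not in table: ",
              paste(bad_key, collapse = ", "))
  if (!is.null(ped)) {
    bad_id <- setdiff(validation$individual_id, ped$id)
    if (length(bad_id))
      stop_user("apply_validation: individual(s) not in pedigree: ",
                paste(bad_id, collapse = ", "))
  }
  calls <- table$calls
  drop <- paste(calls$key, calls$sample) %in% pair
  calls <- calls[!drop, , drop = FALSE]
  calls <- rbind(calls, data.frame(key = validation$variant_key,
                                   sample = validation$individual_id,
                                   gt = unname(gt), alt_reads = NA_integer_,
                                   source = "validation",
                                   stringsAsFactors = FALSE))
  genotype_table(table$variants, table$samples, calls)
}

# typed ids for one variant: explicit non-missing call, or an exome sample
# under the no-call (hom_ref) policy unless its explicit call is missing
typed_genotypes <- function(table, key, ped) {
  ids <- union(ped$id, table$samples)
  g <- genotypes_of(table, key, ids)
  g[!is.na(g) & g != "missing"]
}

#' Per-variant co-segregation verdict
#'
#' Evaluates one variant against the pedigree under an
#' [inheritance_model()], using all individuals with non-missing genotypes
#' (exome calls after any validation override, plus validation-only typed
#' relatives). Checks in order: `FAIL_MONOMORPHIC` if no typed individual
#' carries the variant; `FAIL_MISSING_IN_AFFECTED` if any affected typed
#' individual is a non-carrier; `FAIL_UNAFFECTED_CARRIER` if unaffected
#' typed carriers exceed the tolerated count; `FAIL_ANCESTRY_UNCONFIRMED`
#' if an exception-id carrier's transmission from a common ancestor is
#' contradicted (see [confirm_transmission()]); otherwise
#' `PASS_COSEGREGATING`. Indeterminate transmission (all lineages through
#' untyped individuals) does not fail the variant; it passes with a caveat
#' note. Uncertain and untested individuals impose no constraint.
#'
#' @param variant variant key.
#' @param ped a pedigree.
#' @param table a genotype_table.
#' @param model an [inheritance_model()].
#' @return a `segregation_verdict`: list(key, status, offending_ids,
#'   narrative).
#' @export
cosegregation_test <- function(variant, ped, table,
                               model = inheritance_model()) {
  if (!variant %in% table$variants$key)
    stop_user("cosegregation_test: variant not in table: ", variant)
  typed <- typed_genotypes(table, variant, ped)
  carriers <- names(typed)[typed %in% model$carrier_genotypes]
  verdict <- function(status, ids = character(0), narrative) {
    structure(list(key = variant, status = status,
                   offending_ids = sort(ids), narrative = narrative),
              class = "segregation_verdict")
  }
  if (!length(carriers))
    return(verdict("FAIL_MONOMORPHIC", character(0),
                   "no typed individual carries the variant"))
  phe <- setNames(ped$phenotype, ped$id)[names(typed)]
  phe[is.na(phe)] <- "untested"
  aff_noncarrier <- names(typed)[phe == "affected" & !(typed %in% model$carrier_genotypes)]
  if (length(aff_noncarrier))
    return(verdict("FAIL_MISSING_IN_AFFECTED", aff_noncarrier,
                   paste("variant not carried by affected typed individual(s):",
                         paste(sort(aff_noncarrier), collapse = ", "))))
  una_carrier <- carriers[phe[carriers] == "unaffected"]
  if (length(una_carrier) > model$max_unaffected_carriers)
    return(verdict("FAIL_UNAFFECTED_CARRIER", una_carrier,
                   paste("carried by unaffected typed individual(s):",
                         paste(sort(una_carrier), collapse = ", "))))
  caveat <- character(0)
  for (e in intersect(model$exception_ids, carriers)) {
    ct <- confirm_transmission(variant, ped, table, e,
                               carrier_genotypes = model$carrier_genotypes)
    if (ct == "unconfirmed")
      return(verdict("FAIL_ANCESTRY_UNCONFIRMED", e,
                     paste0("transmission of the variant to ", e,
                            " from a common ancestor was not confirmed")))
    if (ct == "indeterminate")
      caveat <- c(caveat, paste0("transmission to ", e,
                                 " indeterminate (untyped lineage)"))
  }
  narrative <- if (length(caveat))
    paste("co-segregates with the trait;", paste(caveat, collapse = "; "))
  else "co-segregates with the trait in all typed individuals"
  verdict("PASS_COSEGREGATING", character(0), narrative)
}

#' @export
print.segregation_verdict <- function(x, ...) {
  cat(sprintf("<%s: %s%s>\n  %s\n", x$key, x$status,
              if (length(x$offending_ids))
                paste0(" [", paste(x$offending_ids, collapse = ", "), "]") else "",
              x$narrative))
  invisible(x)
}

#' Confirm transmission of a variant from a common ancestor
#'
#' For a carrier whose transmitting parent is unclear, searches for a
#' genealogical lineage (up through ancestors, then optionally down to a
#' relative) connecting the individual to another typed carrier such that
#' every typed individual along the lineage is a carrier. Returns
#' `"confirmed"` if such a lineage exists; `"unconfirmed"` if every lineage
#' to a typed carrier is contradicted by a typed non-carrier (e.g. typed
#' non-carrier mother plus unaffected non-carrier father); `"indeterminate"`
#' if no other typed carrier is reachable (all lineages run through untyped
#' individuals only).
#'
#' @param variant variant key.
#' @param ped a pedigree.
#' @param table a genotype_table.
#' @param individual_id the carrier whose ancestry is to be confirmed.
#' @param carrier_genotypes genotype(s) counting as carrying.
#' @return `"confirmed"`, `"unconfirmed"`, or `"indeterminate"`.
#' @export
confirm_transmission <- function(variant, ped, table, individual_id,
                                 carrier_genotypes = "het") {
  if (!individual_id %in% ped$id)
    stop_user("confirm_transmission: unknown individual: ", individual_id)
  typed <- typed_genotypes(table, variant, ped)
  typed <- typed[names(typed) %in% ped$id]
  if (!(individual_id %in% names(typed)) ||
      !(typed[[individual_id]] %in% carrier_genotypes))
    stop_user("confirm_transmission: ", individual_id,
              " does not carry the variant")
  is_carrier <- function(id) id %in% names(typed) && typed[[id]] %in% carrier_genotypes
  is_typed <- function(id) id %in% names(typed)
  targets <- setdiff(names(typed)[typed %in% carrier_genotypes], individual_id)
  if (!length(targets)) return("indeterminate")

  # all upward chains id -> ... -> ancestor (each step one parent), including
  # the trivial chain c(id)
  up_chains <- function(id) {
    out <- list(c(id))
    for (p in ped_parents(ped, id))
      for (ch in up_chains(p)) out <- c(out, list(c(id, ch)))
    out
  }
  # downward chains apex -> ... -> target (each step one child)
  down_chains_to <- function(apex, target, avoid) {
    if (apex == target) return(list(c(apex)))
    out <- list()
    for (ch in setdiff(ped_children(ped, apex), avoid))
      for (tail_chain in down_chains_to(ch, target, c(avoid, apex)))
        out <- c(out, list(c(apex, tail_chain)))
    out
  }

  # a lineage must leave the individual via a parent (carriers among the
  # individual's own descendants say nothing about where its allele came from)
  ups <- Filter(function(u) length(u) >= 2L, up_chains(individual_id))
  found_chain <- FALSE
  for (target in targets) {
    for (up in ups) {
      apex <- up[length(up)]
      downs <- down_chains_to(apex, target, avoid = up[-length(up)])
      for (down in downs) {
        chain <- c(up, down[-1])
        if (anyDuplicated(chain)) next
        if (!(target %in% chain)) next
        found_chain <- TRUE
        inner <- setdiff(chain, c(individual_id, target))
        contradicted <- any(vapply(inner, function(i)
          is_typed(i) && !is_carrier(i), logical(1)))
        if (!contradicted) return("confirmed")
      }
    }
  }
  if (found_chain) "unconfirmed" else "indeterminate"
}
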