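#' Scan configuration
#'
#' Settings for the shared-candidate scan. The carrier genotype defaults to
#' heterozygous only, matching the hypothesis of a heterozygous dominant
#' mutation; homozygous-alt carriers can be allowed for generality.
#' `exception_ids` name individuals whose carrier status is still required
#' at scan stage but whose transmission lineage is deferred to the
#' segregation stage (e.g. an affected individual with an untyped parent of
#' unknown phenotype).
#'
#' @param min_alt_reads minimum reads carrying the alternative allele for a
#'   non-reference exome call to be trusted (default 20).
#' @param carrier_genotypes genotype(s) counting as "carrying" the variant.
#' @param allow_hom_alt_carrier convenience flag adding `hom_alt` to
#'   `carrier_genotypes`.
#' @param exception_ids ids with deferred-transmission exception.
#' @param exception_missing_ok if TRUE, a `missing` genotype in an exception
#'   individual does not fail the "every affected carries" condition
#'   (documented leniency; default off).
#' @param support_mode `"per_call"` (default): the read-support threshold is
#'   applied to every non-reference exome call; `"any_sample"`: a variant is
#'   trusted if at least one of its non-reference calls reaches the
#'   threshold, otherwise all its non-reference calls are downgraded.
#' @return a `scan_config` list.
#' @export
scan_config <- function(min_alt_reads = 20L,
                        carrier_genotypes = "het",
                        allow_hom_alt_carrier = FALSE,
                        exception_ids = character(0),
                        exception_missing_ok = FALSE,
                        support_mode = c("per_call", "any_sample")) {
  support_mode <- match.arg(support_mode)
  if (allow_hom_alt_carrier) carrier_genotypes <- union(carrier_genotypes, "hom_alt")
  if (!length(carrier_genotypes) || !all(carrier_genotypes %in% c("het", "hom_alt")))
    stop_user("scan_config: carrier_genotypes must be a non-empty subset of {het, hom_alt}")
  if (min_alt_reads < 0) stop_user("scan_config: min_alt_reads must be >= 0")
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 carrier_genotypes = carrier_genotypes,
                 exception_ids = as.character(exception_ids),
                 exception_missing_ok = isTRUE(exception_missing_ok),
                 support_mode = support_mode),
            class = "scan_config")
}

#' Merge adjacent single-base substitutions into MNVs
#'
#' Per-sample discovery callers may represent a multi-nucleotide variant
#' (delins) as separate single-base substitution rows at consecutive
#' positions. Any run of single-base substitutions at consecutive positions
#' whose per-sample genotype vectors are identical (the only phase evidence
#' available without reads) is replaced by one multi-base substitution
#' record with position-ordered concatenated ref/alt. Runs containing a
#' position shared with another record are left untouched, as are indels.
#' The operation is idempotent.
#'
#' @param table a genotype_table sorted by (chrom, pos).
#' @return a genotype_table; merged records gain a `merged_from` note listing
#'   constituent keys, and per-sample `alt_reads` of a merged record is the
#'   minimum over constituents (the weakest supporting evidence).
#' @export
merge_adjacent_substitutions <- function(table) {
  table <- sort_variants(table)
  v <- table$variants
  if (is.null(v$merged_from)) v$merged_from <- NA_character_
  n <- nrow(v)
  if (n < 2L) return(table)
  is_snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  posid <- paste(v$chrom, v$pos)
  unique_pos <- !(duplicated(posid) | duplicated(posid, fromLast = TRUE))
  cand <- is_snv & unique_pos
  adj_next <- c(cand[-n] & cand[-1] & v$chrom[-n] == v$chrom[-1] &
                  v$pos[-1] == v$pos[-n] + 1L, FALSE)
  adj_prev <- c(FALSE, adj_next[-n])
  need <- adj_next | adj_prev
  if (!any(need)) return(table)

  # genotype-vector signature, computed only for adjacency candidates, from
  # explicit non-hom_ref calls (defaults normalize away under the no-call
  # policy); sorted by sample so equal signatures <=> equal vectors
  keys_need <- v$key[need]
  cc <- table$calls[table$calls$key %in% keys_need &
                      table$calls$sample %in% table$samples &
                      table$calls$gt != "hom_ref", , drop = FALSE]
  sig_map <- setNames(rep("", length(keys_need)), keys_need)
  nonref_map <- setNames(rep(FALSE, length(keys_need)), keys_need)
  if (nrow(cc)) {
    cc <- cc[order(cc$key, cc$sample), ]
    agg <- tapply(paste0(cc$sample, "=", cc$gt), cc$key, paste, collapse = "|")
    sig_map[names(agg)] <- unname(agg)
    nr <- tapply(cc$gt %in% c("het", "hom_alt"), cc$key, any)
    nonref_map[names(nr)] <- unname(nr)
  }
  sig <- rep(NA_character_, n)
  sig[need] <- sig_map[v$key[need]]
  has_nonref <- rep(FALSE, n)
  has_nonref[need] <- nonref_map[v$key[need]]

  mergeable <- need & has_nonref
  # group consecutive mergeable rows on the same chrom, adjacent positions,
  # identical genotype signature
  run_id <- integer(nrow(v))
  current <- 0L
  for (i in seq_len(nrow(v))) {
    if (!mergeable[i]) { run_id[i] <- 0L; next }
    if (i > 1L && mergeable[i - 1L] && v$chrom[i] == v$chrom[i - 1L] &&
        v$pos[i] == v$pos[i - 1L] + 1L && sig[i] == sig[i - 1L] &&
        run_id[i - 1L] != 0L) {
      run_id[i] <- run_id[i - 1L]
    } else {
      current <- current + 1L
      run_id[i] <- current
    }
  }

  keep_rows <- list()
  new_rows <- list()
  calls <- data.table::as.data.table(table$calls)
  drop_keys <- character(0)
  add_calls <- list()
  for (r in unique(run_id)) {
    idx <- which(run_id == r & r != 0L)
    if (r == 0L || length(idx) == 1L) next
    members <- v[idx, , drop = FALSE]
    merged <- data.frame(
      chrom = members$chrom[1], pos = members$pos[1],
      ref = paste(members$ref, collapse = ""),
      alt = paste(members$alt, collapse = ""),
      stringsAsFactors = FALSE)
    merged$key <- variant_key(merged$chrom, merged$pos, merged$ref, merged$alt)
    merged$merged_from <- paste(members$key, collapse = ";")
    # carry any extra variant columns from the first constituent
    extra <- setdiff(names(v), names(merged))
    for (col in extra) merged[[col]] <- members[[col]][1]
    new_rows[[length(new_rows) + 1L]] <- merged[, names(v)]
    drop_keys <- c(drop_keys, members$key)
    # merged per-sample calls: genotype identical by construction; alt_reads = min
    sub <- calls[calls$key %in% members$key]
    if (nrow(sub)) {
      agg <- sub[, list(
        gt = gt[1],
        alt_reads = if (all(!is.na(alt_reads))) min(alt_reads) else NA_integer_,
        source = source[1]), by = "sample"]
      agg$key <- merged$key
      add_calls[[length(add_calls) + 1L]] <-
        as.data.frame(agg[, c("key", "sample", "gt", "alt_reads", "source"), with = FALSE])
    }
  }
  if (!length(new_rows)) return(table)
  v_kept <- v[!(v$key %in% drop_keys), , drop = FALSE]
  v_new <- rbind(v_kept, do.call(rbind, new_rows))
  calls_kept <- table$calls[!(table$calls$key %in% drop_keys), , drop = FALSE]
  calls_new <- rbind(calls_kept, do.call(rbind, add_calls))
  sort_variants(genotype_table(v_new, table$samples, calls_new))
}

#' Downgrade weakly supported non-reference calls
#'
#' Non-reference exome calls supported by fewer than `min_alt_reads` reads
#' carrying the alternative allele are downgraded to `missing`
#' (unconstrained). Validation-source calls are never downgraded; calls with
#' unknown read support are left as-is. The number of downgrades is recorded
#' in attribute `n_downgraded`.
#'
#' @param table a genotype_table.
#' @param cfg a [scan_config()].
#' @return a genotype_table.
#' @export
support_filter <- function(table, cfg = scan_config()) {
  calls <- table$calls
  nonref_exome <- calls$source == "exome" & calls$gt %in% c("het", "hom_alt") &
    !is.na(calls$alt_reads)
  if (cfg$support_mode == "per_call") {
    downgrade <- nonref_exome & calls$alt_reads < cfg$min_alt_reads
  } else {
    # any_sample: variant trusted if any non-ref call reaches the threshold
    supported <- unique(calls$key[nonref_exome & calls$alt_reads >= cfg$min_alt_reads])
    assessable <- unique(calls$key[nonref_exome])
    unsupported <- setdiff(assessable, supported)
    downgrade <- calls$source == "exome" & calls$gt %in% c("het", "hom_alt") &
      calls$key %in% unsupported
  }
  calls$gt[downgrade] <- "missing"
  calls$alt_reads[downgrade] <- NA_integer_
  out <- genotype_table(table$variants, table$samples, calls)
  attr(out, "n_downgraded") <- sum(downgrade)
  out
}

#' Shared-candidate scan
#'
#' Returns exactly the variants for which every affected sequenced
#' individual has a carrier genotype and every unaffected sequenced
#' individual is `hom_ref` (under the no-call policy, a variant absent from
#' an unaffected sample's calls counts as `hom_ref`; an explicit `missing`
#' call is unconstrained). A `missing` genotype in an affected individual
#' fails the "every affected" condition unless that individual is an
#' exception id and `exception_missing_ok` is set.
#'
#' @param table a genotype_table.
#' @param ped a pedigree; the scan runs over its sequenced individuals.
#' @param cfg a [scan_config()].
#' @return character vector of variant keys, in variant order.
#' @export
shared_candidates <- function(table, ped, cfg = scan_config()) {
  seq_ids <- intersect(ped_sequenced_ids(ped), table$samples)
  groups <- phenotype_groups(ped, seq_ids)
  if (!length(groups$affected))
    stop_user("shared_candidates: no affected sequenced individuals; scan undefined")
  gm <- gt_matrix(table)
  aff <- gm[, groups$affected, drop = FALSE]
  carrier <- matrix(aff %in% cfg$carrier_genotypes, nrow = nrow(aff))
  ok_aff <- carrier
  if (cfg$exception_missing_ok && length(cfg$exception_ids)) {
    exc <- intersect(groups$affected, cfg$exception_ids)
    for (e in exc) {
      j <- match(e, groups$affected)
      ok_aff[, j] <- ok_aff[, j] | aff[, j] == "missing"
    }
  }
  pass_aff <- rowSums(ok_aff) == ncol(ok_aff)
  if (length(groups$unaffected)) {
    una <- gm[, groups$unaffected, drop = FALSE]
    pass_una <- rowSums(matrix(una %in% c("het", "hom_alt"), nrow = nrow(una))) == 0L
  } else pass_una <- rep(TRUE, nrow(gm))
  table$variants$key[pass_aff & pass_una]
}
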