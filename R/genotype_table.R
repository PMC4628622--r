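#' Construct a genotype table
#'
#' The central container: an ordered variant collection, an ordered list of
#' exome-sequenced sample ids, and a long-format call table. The no-call
#' policy follows per-sample discovery calling, which emits no reference
#' blocks: a variant absent from a sequenced sample's calls is interpreted as
#' `hom_ref` for that sample, whereas an explicit `missing` call (`./.`) is
#' unconstrained. Individuals outside `samples` (e.g. relatives typed only by
#' validation) are typed only where an explicit call exists.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (a `key` column `chrom:pos:ref:alt` is added if absent).
#' @param samples character vector of exome-sequenced sample ids.
#' @param calls data.frame with columns `key`, `sample`, `gt` (one of
#'   `hom_ref`, `het`, `hom_alt`, `missing`), `alt_reads` (integer or NA),
#'   `source` (`"exome"` or `"validation"`).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(variants, samples, calls) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop_user("genotype_table: variants missing column(s): ",
              paste(miss, collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop_user("genotype_table: pos must be >= 1")
  bad_allele <- !grepl("^[ACGTN]+$", variants$ref) | !grepl("^[ACGTN]+$", variants$alt)
  if (any(bad_allele))
    stop_user("genotype_table: ref/alt must be non-empty ACGTN strings")
  if (any(variants$ref == variants$alt))
    stop_user("genotype_table: ref == alt for some variant")
  if (is.null(variants$key))
    variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(variants$key))
    stop_user("genotype_table: duplicate variant key(s): ",
              paste(unique(variants$key[duplicated(variants$key)]), collapse = ", "))

  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls)) {
    creq <- c("key", "sample", "gt")
    cmiss <- setdiff(creq, names(calls))
    if (length(cmiss))
      stop_user("genotype_table: calls missing column(s): ",
                paste(cmiss, collapse = ", "))
    if (is.null(calls$alt_reads)) calls$alt_reads <- NA_integer_
    if (is.null(calls$source)) calls$source <- "exome"
    calls$alt_reads <- as.integer(calls$alt_reads)
    bad_key <- setdiff(calls$key, variants$key)
    if (length(bad_key))
      stop_user("genotype_table: call key(s) not in variants: ",
                paste(head(bad_key, 5), collapse = ", "))
    if (!all(calls$gt %in% GT_LEVELS))
      stop_user("genotype_table: invalid genotype value(s)")
    if (!all(calls$source %in% c("exome", "validation")))
      stop_user("genotype_table: invalid call source value(s)")
    # alt_reads only meaningful for non-missing exome calls
    calls$alt_reads[calls$gt == "missing" | calls$source == "validation"] <- NA_integer_
    if (anyDuplicated(calls[, c("key", "sample")]))
      stop_user("genotype_table: duplicate (variant, sample) call(s)")
  } else {
    calls <- data.frame(key = character(0), sample = character(0),
                        gt = character(0), alt_reads = integer(0),
                        source = character(0), stringsAsFactors = FALSE)
  }
  structure(list(variants = variants, samples = as.character(samples),
                 calls = calls[, c("key", "sample", "gt", "alt_reads", "source")]),
            class = "genotype_table")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table: %d variants x %d samples, %d explicit calls>\n",
              nrow(x$variants), length(x$samples), nrow(x$calls)))
  invisible(x)
}

#' Genotype of one individual at one variant
#'
#' Applies the no-call policy: explicit call if present; `"hom_ref"` for a
#' sequenced exome sample with no call; `NA` (untyped) for anyone else.
#'
#' @param table a genotype_table.
#' @param key variant key `chrom:pos:ref:alt`.
#' @param id individual id.
#' @return one of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`, or `NA`.
#' @export
genotype_at <- function(table, key, id) {
  hit <- table$calls$key == key & table$calls$sample == id
  if (any(hit)) return(table$calls$gt[which(hit)[1]])
  if (id %in% table$samples) return("hom_ref")
  NA_character_
}

# Genotypes of a variant across a set of individuals, vectorized.
# Returns named character vector; NA = untyped.
genotypes_of <- function(table, key, ids) {
  out <- ifelse(ids %in% table$samples, "hom_ref", NA_character_)
  names(out) <- ids
  sub <- table$calls[table$calls$key == key & table$calls$sample %in% ids, ]
  if (nrow(sub)) out[sub$sample] <- sub$gt
  out
}

# Full gt matrix (variants x samples) for the table's exome samples,
# default-expanded under the no-call policy. Character matrix.
gt_matrix <- function(table) {
  m <- matrix("hom_ref", nrow = nrow(table$variants), ncol = length(table$samples),
              dimnames = list(table$variants$key, table$samples))
  sub <- table$calls[table$calls$sample %in% table$samples, ]
  if (nrow(sub)) m[cbind(sub$key, sub$sample)] <- sub$gt
  m
}

# order variants by (chrom, pos, ref, alt); returns a new table
sort_variants <- function(table) {
  v <- table$variants
  o <- order(v$chrom, v$pos, v$ref, v$alt)
  table$variants <- v[o, , drop = FALSE]
  rownames(table$variants) <- NULL
  table
}
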