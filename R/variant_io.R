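#' Read per-sample variant calls into a genotype table
#'
#' Ingests one VCF per sample, or a single multi-sample VCF, via
#' `VariantAnnotation::readVcf()`. Multi-allelic records are split into
#' biallelic variant records sharing `chrom`/`pos`/`ref`; the per-sample
#' genotype is re-expressed against each split allele (0 copies = `hom_ref`,
#' 1 = `het`, 2 = `hom_alt`, any `.` = `missing`). Alt read depth is taken
#' from the per-sample `AD` field when present, else from `AO`.
#'
#' Only non-`hom_ref`-by-default information is stored: explicit calls are
#' kept as given; variants never mentioned for a sample fall under the
#' no-call policy of [genotype_table()].
#'
#' @param paths character vector of VCF paths. Length 1 with a multi-sample
#'   VCF, or one path per entry of `sample_ids`.
#' @param sample_ids sample ids. For per-sample files, pairs positionally
#'   with `paths`; for a multi-sample file, must match its sample columns.
#' @return a [genotype_table()].
#' @export
read_variant_calls <- function(paths, sample_ids) {
  for (p in paths) if (!file.exists(p))
    stop_user("read_variant_calls: file not found: ", p)
  if (length(paths) == 1L) {
    vcf <- read_one_vcf(paths[1])
    vcf_samples <- colnames(vcf)
    missing <- setdiff(sample_ids, vcf_samples)
    if (length(missing))
      stop_user("read_variant_calls: sample(s) missing from ", paths[1], ": ",
                paste(missing, collapse = ", "))
    parts <- list(vcf_calls(vcf, sample_ids, paths[1]))
  } else {
    if (length(paths) != length(sample_ids))
      stop_user("read_variant_calls: ", length(paths), " files but ",
                length(sample_ids), " sample ids")
    parts <- Map(function(p, s) {
      vcf <- read_one_vcf(p)
      if (ncol(vcf) != 1L)
        stop_user("read_variant_calls: expected single-sample VCF: ", p)
      colnames(vcf) <- s
      vcf_calls(vcf, s, p)
    }, paths, sample_ids)
  }
  variants <- unique(data.table::rbindlist(lapply(parts, `[[`, "variants")))
  calls <- data.table::rbindlist(lapply(parts, `[[`, "calls"))
  variants <- variants[order(variants$chrom, variants$pos, variants$ref, variants$alt), ]
  genotype_table(as.data.frame(variants), sample_ids, as.data.frame(calls))
}

read_one_vcf <- function(path) {
  tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "synthetic")),
    error = function(e)
      stop_user("read_variant_calls: failed to parse VCF ", path, ": ",
                conditionMessage(e)))
}

# expand a (possibly multi-allelic) VCF into biallelic variant rows and
# long-format calls for the requested samples
vcf_calls <- function(vcf, sample_ids, path) {
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt_flat <- as.character(unlist(alt_list, use.names = FALSE))
  row_of <- rep(seq_along(n_alt), n_alt)        # source VCF row per split record
  allele_idx <- unlist(lapply(n_alt, seq_len))  # which ALT allele (1-based)

  variants <- data.frame(chrom = chrom[row_of], pos = pos[row_of],
                         ref = ref[row_of], alt = alt_flat,
                         stringsAsFactors = FALSE)
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)

  gt_mat <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt_mat))
    stop_user("read_variant_calls: no GT field in ", path)
  ad <- VariantAnnotation::geno(vcf)$AD
  ao <- VariantAnnotation::geno(vcf)$AO

  calls_list <- vector("list", length(sample_ids))
  for (si in seq_along(sample_ids)) {
    s <- sample_ids[si]
    gt_raw <- gt_mat[row_of, s]
    alleles <- strsplit(gt_raw, "[/|]")
    gt <- vapply(seq_along(gt_raw), function(k) {
      a <- alleles[[k]]
      if (any(a == ".")) return("missing")
      n <- sum(a == as.character(allele_idx[k]))
      c("hom_ref", "het", "hom_alt")[n + 1L]
    }, character(1))
    reads <- rep(NA_integer_, length(gt_raw))
    if (!is.null(ad)) {
      reads <- vapply(seq_along(gt_raw), function(k) {
        v <- ad[[row_of[k], s]]
        if (length(v) >= allele_idx[k] + 1L) as.integer(v[allele_idx[k] + 1L])
        else NA_integer_
      }, integer(1))
    } else if (!is.null(ao)) {
      reads <- vapply(seq_along(gt_raw), function(k) {
        v <- ao[[row_of[k], s]]
        if (length(v) >= allele_idx[k]) as.integer(v[allele_idx[k]])
        else NA_integer_
      }, integer(1))
    }
    keep <- gt != "hom_ref" | length(sample_ids) > 1L  # keep explicit 0/0 in multi-sample files
    calls_list[[si]] <- data.frame(key = variants$key[keep], sample = s,
                                   gt = gt[keep], alt_reads = reads[keep],
                                   source = "exome", stringsAsFactors = FALSE)
  }
  list(variants = variants,
       calls = do.call(rbind, calls_list))
}

#' Read a variant annotation table (TSV)
#'
#' Required columns `chrom`, `pos`, `ref`, `alt`; recognised optional columns
#' `gene`, `consequence`, `pop_maf`, `in_cohort_db`, `brain_expressed`; any
#' further columns are carried through untouched as pass-through scores
#' (conservation/deleteriousness scores etc.). `pop_maf` accepts a fraction
#' or a percentage with `%` suffix (`"0.01%"` is stored as `1e-4`). Unknown
#' consequence strings map to `"unknown"` with a warning.
#'
#' @param path TSV path with a header row.
#' @return data.frame keyed by `key` (`chrom:pos:ref:alt`), one row per variant.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop_user("read_annotation_table: file not found: ", path)
  ann <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = list(character = "chrom")))
  for (col in c("chrom", "pos", "ref", "alt")) {
    if (!col %in% names(ann))
      stop_user("missing column: ", col)
  }
  ann$chrom <- as.character(ann$chrom)
  ann$key <- variant_key(ann$chrom, as.integer(ann$pos), ann$ref, ann$alt)
  if (anyDuplicated(ann$key))
    stop_user("read_annotation_table: duplicate key row(s): ",
              paste(unique(ann$key[duplicated(ann$key)]), collapse = ", "))
  if (!is.null(ann$pop_maf) && is.character(ann$pop_maf)) {
    pct <- grepl("%$", ann$pop_maf)
    val <- suppressWarnings(as.numeric(sub("%$", "", ann$pop_maf)))
    val[pct] <- val[pct] / 100
    ann$pop_maf <- val
  }
  if (!is.null(ann$consequence)) {
    unknown <- !is.na(ann$consequence) & !(ann$consequence %in% CONSEQUENCE_LEVELS)
    if (any(unknown)) {
      warning("read_annotation_table: unknown consequence string(s) mapped to 'unknown': ",
              paste(unique(ann$consequence[unknown]), collapse = ", "))
      ann$consequence[unknown] <- "unknown"
    }
  }
  for (col in c("in_cohort_db", "brain_expressed"))
    if (!is.null(ann[[col]])) ann[[col]] <- as.logical(ann[[col]])
  ann
}

#' Read a gene whitelist (one symbol per line, '#' comments)
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
read_gene_whitelist <- function(path) {
  if (!file.exists(path)) stop_user("read_gene_whitelist: file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a genotype table as a VCF 4.2 file
#'
#' Deterministic writer: variants sorted by (chrom, pos, ref, alt), fixed
#' header, genotypes as `GT:AO` (AO = reads carrying the alternative allele;
#' `.` when unknown). Annotations, when given, are emitted as INFO fields
#' `GENE`, `CSQ`, `MAF`, `COHORTDB`, `BRAINEXP`. Byte-identical for identical
#' input.
#'
#' @param table a genotype_table.
#' @param path output path.
#' @param annotations optional annotation data.frame (see
#'   [read_annotation_table()]).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, annotations = NULL) {
  table <- sort_variants(table)
  v <- table$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cosegr",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##INFO=<ID=COHORTDB,Number=1,Type=String,Description=\"Present in in-house cohort database\">",
    "##INFO=<ID=BRAINEXP,Number=1,Type=String,Description=\"Gene has validated brain expression\">",
    "##INFO=<ID=MERGED,Number=1,Type=String,Description=\"Keys of merged adjacent substitutions\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele read count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")

  # INFO: combine per-tag vectors, skipping absent values
  info_part <- function(tag, vals) {
    if (is.null(vals)) return(rep(NA_character_, nrow(v)))
    ifelse(is.na(vals), NA_character_, paste0(tag, "=", vals))
  }
  parts <- list()
  if (!is.null(annotations)) {
    idx <- match(v$key, annotations$key)
    logi <- function(x) if (is.null(x)) NULL else tolower(as.character(x[idx]))
    parts <- list(info_part("GENE", annotations$gene[idx]),
                  info_part("CSQ", annotations$consequence[idx]),
                  info_part("MAF", annotations$pop_maf[idx]),
                  info_part("COHORTDB", logi(annotations$in_cohort_db)),
                  info_part("BRAINEXP", logi(annotations$brain_expressed)))
  }
  if (!is.null(v$merged_from))
    parts <- c(parts, list(info_part(
      "MERGED", ifelse(is.na(v$merged_from) | v$merged_from == "", NA,
                       gsub(";", ",", v$merged_from)))))
  info <- Reduce(function(a, b) ifelse(is.na(b), a,
                                       ifelse(is.na(a), b, paste(a, b, sep = ";"))),
                 parts, rep(NA_character_, nrow(v)))
  info[is.na(info)] <- "."

  geno <- matrix("0/0:.", nrow = nrow(v), ncol = length(table$samples),
                 dimnames = list(v$key, table$samples))
  cc <- table$calls[table$calls$sample %in% table$samples, , drop = FALSE]
  if (nrow(cc))
    geno[cbind(cc$key, cc$sample)] <-
      paste0(gt_code[cc$gt], ":", ifelse(is.na(cc$alt_reads), ".", cc$alt_reads))
  rows <- if (nrow(v) == 0L) character(0) else
    do.call(paste, c(list(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                          info, "GT:AO"),
                     lapply(seq_along(table$samples), function(j) geno[, j]),
                     sep = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write pipeline outputs
#'
#' Emits (a) surviving variants as a VCF with annotations in INFO, (b) a TSV
#' report with one row per input variant and its terminal reason code, and
#' (c) the stage trace summary TSV. All outputs are deterministic in content
#' and ordering for a given input.
#'
#' @param table genotype_table restricted to (or containing) the surviving
#'   variants; survivors are the report rows whose reason is
#'   `PASS_COSEGREGATING`.
#' @param trace a `filter_trace` (see [run_pipeline()]).
#' @param out_dir output directory (created if needed).
#' @param annotations optional annotation data.frame.
#' @return named character vector of written paths, invisibly.
#' @export
write_outputs <- function(table, trace, out_dir, annotations = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- trace$report
  pass_keys <- report$key[report$reason == "PASS_COSEGREGATING"]
  surv <- subset_table(table, pass_keys)
  paths <- c(vcf = file.path(out_dir, "survivors.vcf"),
             report = file.path(out_dir, "report.tsv"),
             trace = file.path(out_dir, "trace.tsv"))
  write_vcf(surv, paths["vcf"], annotations)
  data.table::fwrite(report, paths["report"], sep = "\t")
  data.table::fwrite(trace$stages, paths["trace"], sep = "\t")
  invisible(paths)
}

# restrict a genotype_table to a set of variant keys
subset_table <- function(table, keys) {
  v <- table$variants[table$variants$key %in% keys, , drop = FALSE]
  rownames(v) <- NULL
  calls <- table$calls[table$calls$key %in% keys, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(variants = v, samples = table$samples, calls = calls),
            class = "genotype_table")
}
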