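# Packaged worked example: a multi-generation family segregating an
# autosomal-dominant trait, with ten exome-sequenced members (seven affected,
# three unaffected), five shared candidate variants, and validation genotypes
# that exclude four of them. The pedigree encodes only the published subtree
# plus minimal connecting relatives; invented connecting individuals and all
# coordinates except the CEP63 delins locus (chr3:134264558-9, build 37) are
# synthetic reconstructions, documented as such.

FIG1A_AFFECTED_SEQ <- c("IV:1", "IV:5", "IV:7", "IV:9", "V:6", "V:7", "V:8")
FIG1A_UNAFFECTED_SEQ <- c("III:2", "IV:6", "IV:11")
FIG1A_SEQ <- c(FIG1A_AFFECTED_SEQ, FIG1A_UNAFFECTED_SEQ)

#' The packaged worked-example pedigree
#'
#' Ten exome-sequenced individuals (seven affected, three unaffected), the
#' uncertain-status mother III:4 of exception individual IV:9, IV:9's
#' unaffected married-in father, and untyped connecting relatives up to a
#' shared founder couple. A synthetic reconstruction of the published
#' subtree: individuals not named in the source are invented connectors.
#'
#' @return a [pedigree()].
#' @export
fig1a_pedigree <- function() {
  rows <- list(
    #        id       father   mother   sex       phenotype     sequenced
    c("II:1",  NA,      NA,      "male",   "untested",   FALSE),
    c("II:2",  NA,      NA,      "female", "untested",   FALSE),
    c("III:1", "II:1",  "II:2",  "male",   "affected",   FALSE),
    c("III:2", NA,      NA,      "female", "unaffected", TRUE),
    c("III:4", "II:1",  "II:2",  "female", "uncertain",  FALSE),
    c("III:5", NA,      NA,      "male",   "unaffected", FALSE),
    c("III:7", "II:1",  "II:2",  "female", "affected",   FALSE),
    c("III:8", NA,      NA,      "male",   "untested",   FALSE),
    c("IV:1",  "III:1", "III:2", "male",   "affected",   TRUE),
    c("IV:5",  "III:1", "III:2", "female", "affected",   TRUE),
    c("IV:6",  "III:1", "III:2", "female", "unaffected", TRUE),
    c("IV:7",  "III:8", "III:7", "male",   "affected",   TRUE),
    c("IV:8",  NA,      NA,      "female", "untested",   FALSE),
    c("IV:9",  "III:5", "III:4", "male",   "affected",   TRUE),
    c("IV:11", "III:8", "III:7", "female", "unaffected", TRUE),
    c("V:6",   "IV:7",  "IV:8",  "male",   "affected",   TRUE),
    c("V:7",   "IV:7",  "IV:8",  "female", "affected",   TRUE),
    c("V:8",   "IV:7",  "IV:8",  "male",   "affected",   TRUE))
  df <- data.frame(
    family = "FAM_DD",
    id = vapply(rows, `[[`, "", 1), father = vapply(rows, `[[`, "", 2),
    mother = vapply(rows, `[[`, "", 3), sex = vapply(rows, `[[`, "", 4),
    phenotype = vapply(rows, `[[`, "", 5),
    sequenced = vapply(rows, function(r) as.logical(r[[6]]), NA),
    stringsAsFactors = FALSE)
  pedigree(df, name = "FAM_DD")
}

# the five candidate loci; the two-base CEP63 delins is represented in the
# exome calls as two adjacent single-base substitutions with identical
# genotype vectors (as a per-sample caller would emit it), merging to
# 3:134264558:GA:TT. Non-CEP63 coordinates are synthetic.
fig1a_variants <- function() {
  data.frame(
    chrom = c("3", "3", "7", "11", "18", "19"),
    pos = c(134264558L, 134264559L, 926250L, 61560000L, 59450000L, 32840000L),
    ref = c("G", "A", "T", "C", "G", "C"),
    alt = c("T", "T", "G", "T", "A", "G"),
    gene = c("CEP63", "CEP63", "GET4", "INTS5", "RNF152", "ZNF507"),
    base_reads = c(31L, 28L, 22L, 25L, 33L, 27L),
    stringsAsFactors = FALSE)
}

#' Build the packaged worked-example fixture
#'
#' Deterministic in-memory fixture: the pedigree, the exome genotype table
#' (five candidates, heterozygous in all seven affected and reference in all
#' three unaffected sequenced individuals, each supported by at least 20
#' alternative reads), the validation genotype table encoding the published
#' outcomes (GET4 monomorphic; INTS5 carried by IV:9 with both parents
#' typed reference; ZNF507 carried by unaffected III:2 and IV:11; RNF152
#' carried by unaffected IV:6; CEP63 carried by every affected typed
#' individual and by uncertain-status III:4, reference in every typed
#' unaffected), the annotation table, and the brain-expression gene
#' whitelist (the eight published genes plus decoys).
#'
#' @return list with elements `ped`, `table` (exome calls, pre-merge),
#'   `validation`, `annotations`, `whitelist`, `causal_key`, `model`,
#'   `scan`.
#' @export
make_fig1a_fixture <- function() {
  ped <- fig1a_pedigree()
  v <- fig1a_variants()
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)

  calls <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    rbind(
      data.frame(key = v$key[i], sample = FIG1A_AFFECTED_SEQ, gt = "het",
                 alt_reads = v$base_reads[i] + 2L * seq_along(FIG1A_AFFECTED_SEQ),
                 source = "exome", stringsAsFactors = FALSE),
      data.frame(key = v$key[i], sample = FIG1A_UNAFFECTED_SEQ, gt = "hom_ref",
                 alt_reads = NA_integer_, source = "exome",
                 stringsAsFactors = FALSE))
  }))
  table <- genotype_table(v[, c("chrom", "pos", "ref", "alt", "key")],
                          FIG1A_SEQ, calls)

  cep63_key <- "3:134264558:GA:TT"
  annotations <- data.frame(
    chrom = c("3", "7", "11", "18", "19"),
    pos = c(134264558L, 926250L, 61560000L, 59450000L, 32840000L),
    ref = c("GA", "T", "C", "G", "C"),
    alt = c("TT", "G", "T", "A", "G"),
    gene = c("CEP63", "GET4", "INTS5", "RNF152", "ZNF507"),
    consequence = "non_synonymous",
    pop_maf = c(1e-4, NA, NA, NA, NA),
    in_cohort_db = FALSE,
    brain_expressed = TRUE,
    gerp = c(5.53, NA, NA, NA, NA),
    polyphen2 = c(1, NA, NA, NA, NA),
    sift = c(0, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  annotations$key <- variant_key(annotations$chrom, annotations$pos,
                                 annotations$ref, annotations$alt)

  typed_all <- c("III:1", "III:2", "III:4", "III:5", "III:7", "IV:1", "IV:5",
                 "IV:6", "IV:7", "IV:8", "IV:9", "IV:11", "V:6", "V:7", "V:8")
  cep63_het <- c("III:1", "III:4", "III:7", FIG1A_AFFECTED_SEQ)
  validation <- rbind(
    data.frame(variant_key = cep63_key, individual_id = typed_all,
               genotype = ifelse(typed_all %in% cep63_het, "0/1", "0/0"),
               stringsAsFactors = FALSE),
    data.frame(variant_key = "7:926250:T:G", individual_id = typed_all,
               genotype = "0/0", stringsAsFactors = FALSE),
    data.frame(variant_key = "11:61560000:C:T",
               individual_id = c("IV:9", "III:4", "III:5"),
               genotype = c("0/1", "0/0", "0/0"), stringsAsFactors = FALSE),
    data.frame(variant_key = "19:32840000:C:G",
               individual_id = c("III:2", "IV:11"),
               genotype = c("0/1", "0/1"), stringsAsFactors = FALSE),
    data.frame(variant_key = "18:59450000:G:A", individual_id = "IV:6",
               genotype = "0/1", stringsAsFactors = FALSE))

  whitelist <- c("CEP63", "DNAJC11", "GET4", "INTS5", "PAQR9", "RNF152",
                 "TNRC18", "ZNF507",
                 paste0("DECOY", 1:8))  # synthetic decoys, not brain-expressed genes

  list(ped = ped, table = table, validation = validation,
       annotations = annotations, whitelist = whitelist,
       causal_key = cep63_key,
       scan = scan_config(exception_ids = "IV:9"),
       model = inheritance_model(exception_ids = "IV:9"))
}

#' Write the worked-example fixture to disk
#'
#' Emits the PED file, a multi-sample exome VCF, the annotation and
#' validation TSVs, the gene whitelist, and a ready-to-run pipeline config
#' (JSON) into `dir`. Deterministic, byte-identical across calls.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_fig1a_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_fig1a_fixture()
  paths <- c(ped = file.path(dir, "fig1a.ped"),
             vcf = file.path(dir, "fig1a_exome.vcf"),
             annotations = file.path(dir, "fig1a_annotations.tsv"),
             validation = file.path(dir, "fig1a_validation.tsv"),
             whitelist = file.path(dir, "brain_expressed_genes.txt"),
             config = file.path(dir, "fig1a_config.json"))
  write_ped(fx$ped, paths["ped"])
  write_vcf(fx$table, paths["vcf"])
  ann <- fx$annotations[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                            "pop_maf", "in_cohort_db", "brain_expressed",
                            "gerp", "polyphen2", "sift")]
  data.table::fwrite(ann, paths["annotations"], sep = "\t")
  data.table::fwrite(fx$validation, paths["validation"], sep = "\t")
  writeLines(c("# brain-expression gene whitelist (worked example; includes synthetic decoys)",
               fx$whitelist), paths["whitelist"])
  config <- list(
    ped = "fig1a.ped",
    vcf = "fig1a_exome.vcf",
    samples = FIG1A_SEQ,
    annotations = "fig1a_annotations.tsv",
    validation = "fig1a_validation.tsv",
    whitelist = "brain_expressed_genes.txt",
    out_dir = "out",
    scan = list(min_alt_reads = 20, exception_ids = "IV:9"),
    filters = list(maf_threshold = 0.01),
    model = list(max_unaffected_carriers = 0, exception_ids = "IV:9"))
  jsonlite::write_json(config, paths["config"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Synthetic analogue of the published 16-variant candidate table
#'
#' A deterministic annotation fixture mirroring the shape of the published
#' intermediate candidate set: 16 rare shared variants, 8 of them in the
#' eight named brain-expressed genes (5 non-synonymous, 3 synonymous) and 8
#' in synthetic decoy genes without validated brain expression. The row
#' contents other than the published gene symbols and consequence classes
#' are synthetic: the real supplementary table is not redistributable.
#'
#' @return annotation data.frame of 16 rows with a `key` column.
#' @export
make_results_fixture <- function() {
  genes8 <- c("CEP63", "GET4", "INTS5", "RNF152", "ZNF507",
              "DNAJC11", "PAQR9", "TNRC18")
  csq8 <- c(rep("non_synonymous", 5), rep("synonymous", 3))
  decoys <- paste0("DECOY", 1:8)
  csq_decoy <- rep(c("non_synonymous", "synonymous"), 4)
  ann <- data.frame(
    chrom = as.character(rep(1:8, 2)),
    pos = 1000000L + 137L * seq_len(16),
    ref = rep(c("A", "C", "G", "T"), 4),
    alt = rep(c("G", "T", "A", "C"), 4),
    gene = c(genes8, decoys),
    consequence = c(csq8, csq_decoy),
    pop_maf = rep(c(1e-4, NA), 8),
    in_cohort_db = FALSE,
    brain_expressed = c(rep(TRUE, 8), rep(FALSE, 8)),
    stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}
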