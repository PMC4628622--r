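write_test_vcf <- function(path, body, samples = "S1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>", "##contig=<ID=3>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

test_that("single-sample VCF with one het SNV is ingested with alt depth", {
  f <- write_test_vcf(withr::local_tempfile(),
                      "3\t134264558\t.\tG\tT\t.\tPASS\t.\tGT:AD\t0/1:30,25")
  tab <- read_variant_calls(f, "S1")
  expect_equal(nrow(tab$variants), 1)
  expect_equal(tab$calls$gt, "het")
  expect_equal(tab$calls$alt_reads, 25L)
  expect_equal(genotype_at(tab, "3:134264558:G:T", "S1"), "het")
})

test_that("multi-allelic records split into biallelic records sharing chrom/pos/ref", {
  f <- write_test_vcf(withr::local_tempfile(),
                      "1\t500\t.\tA\tT,C\t.\tPASS\t.\tGT:AD\t1/2:2,18,31")
  tab <- read_variant_calls(f, "S1")
  expect_equal(nrow(tab$variants), 2)
  expect_setequal(tab$variants$alt, c("T", "C"))
  expect_equal(unique(tab$variants$pos), 500L)
  expect_equal(unique(tab$variants$ref), "A")
  # 1/2 means one copy of each alt: het against both split records
  expect_setequal(tab$calls$gt, "het")
  expect_setequal(tab$calls$alt_reads, c(18L, 31L))
  # naive merge of the split alleles recovers the original allele set
  expect_setequal(tab$variants$alt[tab$variants$pos == 500],
                  c("T", "C"))
})

test_that("sample mismatch and unreadable input raise informative errors", {
  f <- write_test_vcf(withr::local_tempfile(),
                      "1\t500\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:5,9")
  expect_error(read_variant_calls(f, c("S1", "S9")), "S9")
  expect_error(read_variant_calls("/nonexistent.vcf", "S1"), "not found")
})

test_that("annotation table parsing normalizes units and validates columns", {
  f <- withr::local_tempfile(lines = c(
    "chrom\tpos\tref\talt\tgene\tconsequence\tpop_maf\tin_cohort_db\tbrain_expressed\tgerp",
    "3\t134264558\tG\tT\tCEP63\tnon_synonymous\t0.01%\tfalse\ttrue\t5.53",
    "1\t100\tA\tC\tXYZ\tweird_class\t0.2\ttrue\tfalse\t-1"))
  expect_warning(ann <- read_annotation_table(f), "weird_class")
  expect_equal(ann$pop_maf[1], 1e-4)  # '%' suffix divides by 100
  expect_equal(ann$gene[1], "CEP63")
  expect_equal(ann$consequence[2], "unknown")
  expect_equal(ann$gerp[1], 5.53)    # pass-through score column kept

  bad <- withr::local_tempfile(lines = c("chrom\tref\talt", "1\tA\tC"))
  expect_error(read_annotation_table(bad), "missing column: pos")

  dup <- withr::local_tempfile(lines = c(
    "chrom\tpos\tref\talt", "1\t5\tA\tC", "1\t5\tA\tC"))
  expect_error(read_annotation_table(dup), "duplicate")
})

test_that("VCF write -> read round-trip preserves variants and genotypes", {
  for (seed in 1:5) {
    tab <- rand_table(seed, samples = c("A1", "A2", "B1"), n_var = 6)
    f <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(tab, f)
    back <- read_variant_calls(f, c("A1", "A2", "B1"))
    expect_equal(back$variants[, c("chrom", "pos", "ref", "alt", "key")],
                 tab$variants[, c("chrom", "pos", "ref", "alt", "key")])
    for (k in tab$variants$key)
      for (s in tab$samples)
        expect_equal(genotype_at(back, k, s), genotype_at(tab, k, s))
    # alt reads survive via the AO field
    m <- merge(tab$calls, back$calls, by = c("key", "sample"))
    expect_equal(m$alt_reads.x, m$alt_reads.y)
  }
})

test_that("write_outputs emits report for all inputs even with empty PASS set", {
  tab <- rand_table(3, samples = c("A1", "B1"), n_var = 4)
  trace <- structure(list(
    stages = data.frame(stage = "ingest", n_in = 4, n_out = 4),
    report = data.frame(key = tab$variants$key,
                        reason = rep("NOT_SHARED", 4))), class = "filter_trace")
  d <- withr::local_tempdir()
  paths <- write_outputs(tab, trace, d)
  vcf_lines <- readLines(paths[["vcf"]])
  expect_false(any(!startsWith(vcf_lines, "#")))  # header-only VCF
  rep_tab <- read.delim(paths[["report"]])
  expect_equal(nrow(rep_tab), 4)
})

test_that("per-sample VCFs from the generator match the manifest counts", {
  cfg <- sim_config(seed = 42, n_background_mean = 800, n_background_sd = 150)
  d <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, out_dir = d)
  manifest <- jsonlite::read_json(file.path(d, "manifest.json"))
  for (s in sim$table$samples) {
    vcf_file <- file.path(d, paste0(gsub(":", "_", s), ".vcf"))
    n_rows <- sum(!startsWith(readLines(vcf_file), "#"))
    expect_equal(n_rows, manifest$per_sample_counts[[s]])
  }
})
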