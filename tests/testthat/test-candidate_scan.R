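two_adjacent_snvs <- function(gts_a, gts_b, samples) {
  variants <- data.frame(chrom = "3", pos = c(134264558L, 134264559L),
                         ref = c("G", "A"), alt = c("T", "T"),
                         stringsAsFactors = FALSE)
  calls <- rbind(
    data.frame(key = "3:134264558:G:T", sample = samples, gt = gts_a,
               alt_reads = 30L, source = "exome"),
    data.frame(key = "3:134264559:A:T", sample = samples, gt = gts_b,
               alt_reads = 28L, source = "exome"))
  calls <- calls[calls$gt != "hom_ref", ]
  calls$alt_reads[calls$gt == "missing"] <- NA_integer_
  genotype_table(variants, samples, calls)
}

test_that("adjacent substitutions with identical genotype vectors merge to an MNV", {
  samples <- c("A1", "A2", "U1")
  tab <- two_adjacent_snvs(c("het", "het", "hom_ref"),
                           c("het", "het", "hom_ref"), samples)
  merged <- merge_adjacent_substitutions(tab)
  expect_equal(nrow(merged$variants), 1)
  expect_equal(merged$variants$key, "3:134264558:GA:TT")
  expect_equal(merged$variants$ref, "GA")
  expect_match(merged$variants$merged_from, "3:134264558:G:T;3:134264559:A:T")
  # carrier status preserved; alt_reads is the weakest constituent support
  expect_equal(genotype_at(merged, "3:134264558:GA:TT", "A1"), "het")
  expect_equal(genotype_at(merged, "3:134264558:GA:TT", "U1"), "hom_ref")
  expect_equal(merged$calls$alt_reads[merged$calls$sample == "A1"], 28L)
})

test_that("adjacent substitutions with different carrier sets stay separate", {
  samples <- c("A1", "A2", "U1")
  tab <- two_adjacent_snvs(c("het", "het", "hom_ref"),
                           c("het", "hom_ref", "het"), samples)
  merged <- merge_adjacent_substitutions(tab)
  expect_equal(nrow(merged$variants), 2)
})

test_that("merging is idempotent and preserves per-sample carrier status", {
  samples <- c("S1", "S2", "S3", "S4")
  for (seed in 1:12) {
    tab <- rand_table(seed, samples, n_var = 10, clustered = TRUE)
    m1 <- merge_adjacent_substitutions(tab)
    m2 <- merge_adjacent_substitutions(m1)
    expect_equal(m2$variants$key, m1$variants$key)
    expect_equal(m2$calls[order(m2$calls$key, m2$calls$sample), ],
                 m1$calls[order(m1$calls$key, m1$calls$sample), ],
                 ignore_attr = TRUE)
    # every merged record carries each sample's original carrier status
    for (i in which(!is.na(m1$variants$merged_from))) {
      parts <- strsplit(m1$variants$merged_from[i], ";")[[1]]
      for (s in samples)
        expect_equal(genotype_at(m1, m1$variants$key[i], s),
                     genotype_at(tab, parts[1], s))
    }
  }
})

test_that("support filter boundary behavior matches the >= threshold rule", {
  samples <- c("A1", "U1")
  variants <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                         ref = "A", alt = "G")
  calls <- data.frame(key = paste("1", c(100, 200, 300), "A", "G", sep = ":"),
                      sample = "A1", gt = "het",
                      alt_reads = c(20L, 19L, NA), source = "exome")
  tab <- genotype_table(variants, samples, calls)
  out <- support_filter(tab, scan_config(min_alt_reads = 20))
  expect_equal(genotype_at(out, "1:100:A:G", "A1"), "het")      # exactly 20: retained
  expect_equal(genotype_at(out, "1:200:A:G", "A1"), "missing")  # 19: downgraded
  expect_equal(genotype_at(out, "1:300:A:G", "A1"), "het")      # unknown support: kept
  expect_equal(attr(out, "n_downgraded"), 1L)
  # disabled filter is the identity
  out0 <- support_filter(tab, scan_config(min_alt_reads = 0))
  expect_equal(out0$calls, tab$calls)
  # validation calls are never downgraded
  vtab <- apply_validation(tab, data.frame(variant_key = "1:200:A:G",
                                           individual_id = "U1",
                                           genotype = "0/1"))
  vout <- support_filter(vtab, scan_config(min_alt_reads = 20))
  expect_equal(genotype_at(vout, "1:200:A:G", "U1"), "het")
})

test_that("any-sample support mode rescues per-call failures", {
  samples <- c("A1", "A2")
  variants <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G")
  calls <- data.frame(key = "1:100:A:G", sample = samples, gt = "het",
                      alt_reads = c(40L, 8L), source = "exome")
  tab <- genotype_table(variants, samples, calls)
  per_call <- support_filter(tab, scan_config(min_alt_reads = 20))
  expect_equal(genotype_at(per_call, "1:100:A:G", "A2"), "missing")
  any_s <- support_filter(tab, scan_config(min_alt_reads = 20,
                                           support_mode = "any_sample"))
  expect_equal(genotype_at(any_s, "1:100:A:G", "A2"), "het")
})

test_that("shared_candidates matches the worked-example construction", {
  fx <- make_fig1a_fixture()
  keys <- shared_candidates(merge_adjacent_substitutions(fx$table),
                            fx$ped, fx$scan)
  expect_length(keys, 5)
  expect_true(fx$causal_key %in% keys)
  # a variant het in 6 of 7 affected is excluded
  tab <- fx$table
  drop <- tab$calls$key == fx$table$variants$key[3] & tab$calls$sample == "V:8"
  tab$calls$gt[drop] <- "hom_ref"
  keys2 <- shared_candidates(merge_adjacent_substitutions(tab), fx$ped, fx$scan)
  expect_length(keys2, 4)
})

test_that("shared_candidates agrees with the brute-force oracle", {
  for (seed in 1:20) {
    ped <- rand_ped(seed)
    samples <- ped$id[ped$sequenced]
    tab <- rand_table(seed + 100, samples, n_var = 8)
    cfg <- scan_config(exception_ids = if (seed %% 2) samples[1] else character(0),
                       exception_missing_ok = seed %% 3 == 0,
                       allow_hom_alt_carrier = seed %% 4 == 0)
    expect_equal(shared_candidates(tab, ped, cfg),
                 oracle_shared_candidates(tab, ped, cfg),
                 info = paste("seed", seed))
  }
})

test_that("scan errors without affected sequenced individuals", {
  ped <- pedigree(data.frame(id = c("A", "B"), father = NA, mother = NA,
                             sex = "male", phenotype = "unaffected",
                             sequenced = TRUE))
  tab <- rand_table(1, c("A", "B"), n_var = 3)
  expect_error(shared_candidates(tab, ped), "no affected")
})

test_that("shared set is anti-monotone in the affected set", {
  for (seed in 1:10) {
    ped <- rand_ped(seed)
    samples <- ped$id[ped$sequenced]
    tab <- rand_table(seed + 200, samples, n_var = 10)
    base <- shared_candidates(tab, ped)
    # promote one unconstrained sequenced individual to affected
    idx <- which(ped$sequenced & ped$phenotype %in% c("uncertain", "untested"))
    if (!length(idx)) next
    ped2 <- ped
    ped2$phenotype[idx[1]] <- "affected"
    expect_true(all(shared_candidates(tab, ped2) %in% base))
  }
})

test_that("support_filter then scan equals scan on a pre-downgraded table", {
  for (seed in 1:10) {
    ped <- rand_ped(seed)
    samples <- ped$id[ped$sequenced]
    tab <- rand_table(seed + 300, samples, n_var = 8)
    cfg <- scan_config(min_alt_reads = 25)
    # manual pre-downgrade per definition
    manual <- tab
    weak <- manual$calls$source == "exome" &
      manual$calls$gt %in% c("het", "hom_alt") &
      !is.na(manual$calls$alt_reads) & manual$calls$alt_reads < 25
    manual$calls$gt[weak] <- "missing"
    manual$calls$alt_reads[weak] <- NA_integer_
    manual <- genotype_table(manual$variants, manual$samples, manual$calls)
    expect_equal(shared_candidates(support_filter(tab, cfg), ped, cfg),
                 oracle_shared_candidates(manual, ped, cfg))
  }
})
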