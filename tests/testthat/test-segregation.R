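fx_merged <- function() {
  fx <- make_fig1a_fixture()
  fx$table <- merge_adjacent_substitutions(fx$table)
  fx
}

test_that("validation genotypes override exome calls and extend coverage", {
  fx <- fx_merged()
  tab <- apply_validation(fx$table, fx$validation, ped = fx$ped)
  # exome het overridden to hom_ref (the monomorphic artifact)
  expect_equal(genotype_at(fx$table, "7:926250:T:G", "IV:1"), "het")
  expect_equal(genotype_at(tab, "7:926250:T:G", "IV:1"), "hom_ref")
  # previously untyped relative gains a typed genotype
  expect_true(is.na(genotype_at(fx$table, "11:61560000:C:T", "III:4")))
  expect_equal(genotype_at(tab, "11:61560000:C:T", "III:4"), "hom_ref")
  expect_true(all(tab$calls$source[tab$calls$sample == "III:4"] == "validation"))
  # empty validation is the identity
  expect_equal(apply_validation(fx$table, data.frame()), fx$table)
  # contradictory duplicates are an error
  bad <- data.frame(variant_key = "7:926250:T:G",
                    individual_id = c("IV:1", "IV:1"),
                    genotype = c("0/1", "0/0"))
  expect_error(apply_validation(fx$table, bad), "contradictory")
  # unknown individual rejected when a pedigree is supplied
  ghost <- data.frame(variant_key = "7:926250:T:G", individual_id = "ZZ",
                      genotype = "0/0")
  expect_error(apply_validation(fx$table, ghost, ped = fx$ped), "ZZ")
})

test_that("the four exclusion narratives and the single PASS reproduce", {
  fx <- fx_merged()
  tab <- apply_validation(fx$table, fx$validation, ped = fx$ped)
  v <- function(key) cosegregation_test(key, fx$ped, tab, fx$model)

  znf <- v("19:32840000:C:G")
  expect_equal(znf$status, "FAIL_UNAFFECTED_CARRIER")
  expect_equal(znf$offending_ids, c("III:2", "IV:11"))

  rnf <- v("18:59450000:G:A")
  expect_equal(rnf$status, "FAIL_UNAFFECTED_CARRIER")
  expect_equal(rnf$offending_ids, "IV:6")

  get4 <- v("7:926250:T:G")
  expect_equal(get4$status, "FAIL_MONOMORPHIC")

  ints5 <- v("11:61560000:C:T")
  expect_equal(ints5$status, "FAIL_ANCESTRY_UNCONFIRMED")
  expect_equal(ints5$offending_ids, "IV:9")

  cep63 <- v("3:134264558:GA:TT")
  expect_equal(cep63$status, "PASS_COSEGREGATING")
})

test_that("confirm_transmission distinguishes confirmed/unconfirmed/indeterminate", {
  fx <- fx_merged()
  tab <- apply_validation(fx$table, fx$validation, ped = fx$ped)
  # CEP63: typed carrier mother III:4 gives an uncontradicted lineage
  expect_equal(confirm_transmission("3:134264558:GA:TT", fx$ped, tab, "IV:9"),
               "confirmed")
  # INTS5: both parents typed non-carriers block every lineage
  expect_equal(confirm_transmission("11:61560000:C:T", fx$ped, tab, "IV:9"),
               "unconfirmed")
  # carrier with untyped parents and no other typed carrier: indeterminate
  ped <- pedigree(data.frame(
    id = c("X", "P1", "P2"), father = c("P1", NA, NA),
    mother = c("P2", NA, NA), sex = c("male", "male", "female"),
    phenotype = c("affected", "untested", "untested"), sequenced = c(TRUE, FALSE, FALSE)))
  tab2 <- genotype_table(data.frame(chrom = "1", pos = 5L, ref = "A", alt = "G"),
                         "X", data.frame(key = "1:5:A:G", sample = "X",
                                         gt = "het", alt_reads = 30L,
                                         source = "exome"))
  expect_equal(confirm_transmission("1:5:A:G", ped, tab2, "X"), "indeterminate")
  expect_error(confirm_transmission("1:5:A:G", ped, tab2, "NOBODY"), "NOBODY")
})

test_that("verdicts match exhaustive enumeration on a nuclear pedigree", {
  parents <- c("F", "M"); kids <- c("C1", "C2", "C3")
  ids <- c(parents, kids)
  ped <- pedigree(data.frame(
    id = ids, father = c(NA, NA, "F", "F", "F"),
    mother = c(NA, NA, "M", "M", "M"),
    sex = c("male", "female", "male", "female", "male"),
    phenotype = c("untested", "uncertain", "affected", "unaffected", "affected"),
    sequenced = FALSE))
  variants <- data.frame(chrom = "1", pos = 10L, ref = "A", alt = "G")
  states <- c("hom_ref", "het", "missing")
  grid <- expand.grid(rep(list(states), 5), stringsAsFactors = FALSE)
  names(grid) <- ids
  models <- list(
    inheritance_model(),
    inheritance_model(exception_ids = "C1"),
    inheritance_model(max_unaffected_carriers = 1, exception_ids = "C3"))
  phenos <- setNames(ped$phenotype, ped$id)
  seen <- character(0)
  for (model in models) {
    for (i in seq_len(nrow(grid))) {
      gts <- unlist(grid[i, ])
      calls <- data.frame(key = "1:10:A:G", sample = ids, gt = unname(gts),
                          alt_reads = NA_integer_, source = "exome")
      tab <- genotype_table(variants, ids, calls)
      got <- cosegregation_test("1:10:A:G", ped, tab, model)$status
      want <- oracle_verdict_nuclear(gts, phenos, model)
      expect_equal(got, want, info = paste(paste(gts, collapse = ","),
                                           "exc:", paste(model$exception_ids)))
      seen <- union(seen, got)
    }
  }
  # the enumeration exercises every status code
  expect_setequal(seen, c("PASS_COSEGREGATING", "FAIL_MONOMORPHIC",
                          "FAIL_MISSING_IN_AFFECTED", "FAIL_UNAFFECTED_CARRIER",
                          "FAIL_ANCESTRY_UNCONFIRMED"))
})

test_that("verdicts are invariant to id relabeling and call order", {
  fx <- fx_merged()
  tab <- apply_validation(fx$table, fx$validation, ped = fx$ped)
  key <- "19:32840000:C:G"
  base <- cosegregation_test(key, fx$ped, tab, fx$model)
  # shuffle call rows
  tab2 <- tab
  set.seed(1)
  tab2$calls <- tab2$calls[sample(nrow(tab2$calls)), ]
  expect_equal(cosegregation_test(key, fx$ped, tab2, fx$model)$status,
               base$status)
  # relabel every id bijectively
  relabel <- function(x) paste0("id_", gsub(":", "_", x))
  ped3 <- as.data.frame(fx$ped)
  ped3$id <- relabel(ped3$id)
  ped3$father <- ifelse(is.na(ped3$father), NA, relabel(ped3$father))
  ped3$mother <- ifelse(is.na(ped3$mother), NA, relabel(ped3$mother))
  ped3 <- pedigree(ped3)
  tab3 <- tab
  tab3$calls$sample <- relabel(tab3$calls$sample)
  tab3 <- genotype_table(tab3$variants, relabel(tab$samples), tab3$calls)
  model3 <- inheritance_model(exception_ids = relabel(fx$model$exception_ids))
  v3 <- cosegregation_test(key, ped3, tab3, model3)
  expect_equal(v3$status, base$status)
  expect_equal(v3$offending_ids, relabel(base$offending_ids))
})

test_that("a passing variant also survives the scan on typed individuals", {
  # cross-stage consistency: with zero tolerated unaffected carriers and no
  # exceptions, PASS implies the variant is a shared candidate among the
  # typed sequenced subset
  for (seed in 1:10) {
    ped <- rand_ped(seed)
    samples <- ped$id[ped$sequenced]
    tab <- rand_table(seed + 400, samples, n_var = 8)
    if (!any(ped$phenotype[ped$sequenced] == "affected")) next
    carrier <- c("het", "hom_alt")  # aligned carrier sets across both stages
    shared <- shared_candidates(tab, ped,
                                scan_config(carrier_genotypes = carrier))
    for (k in tab$variants$key) {
      v <- cosegregation_test(k, ped, tab,
                              inheritance_model(carrier_genotypes = carrier))
      if (v$status == "PASS_COSEGREGATING") {
        aff <- samples[ped$phenotype[match(samples, ped$id)] == "affected"]
        typed_aff <- aff[vapply(aff, function(a)
          genotype_at(tab, k, a) != "missing", NA)]
        # restrict the claim to variants typed in every affected individual
        if (length(typed_aff) == length(aff))
          expect_true(k %in% shared, info = paste(seed, k))
      }
    }
  }
})
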