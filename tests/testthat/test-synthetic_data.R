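small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_background_mean = 1500, n_background_sd = 300,
             n_rare_per_founder = 60L, ...)
}

test_that("gene_drop is deterministic, contained, and Mendelian at 0.5", {
  ped <- fig1a_pedigree()
  set.seed(5); d1 <- gene_drop(ped, "II:1")
  set.seed(5); d2 <- gene_drop(ped, "II:1")
  expect_identical(d1, d2)
  # only descendants of the carrier founder can carry
  founders <- ped$id[is.na(ped$father) & is.na(ped$mother)]
  expect_true(all(d1[setdiff(founders, "II:1")] == 0L))
  expect_equal(d1[["II:1"]], 1L)
  expect_error(gene_drop(ped, "IV:9"), "has parents")
  expect_error(gene_drop(ped, "NOBODY"), "NOBODY")

  # transmission through one parent-child link: binomial around 1/2
  trio <- pedigree(data.frame(id = c("P", "S", "C"),
                              father = c(NA, NA, "P"), mother = c(NA, NA, "S"),
                              sex = c("male", "female", "male"),
                              phenotype = "untested"))
  set.seed(11)
  frac <- mean(vapply(1:10000, function(i) gene_drop(trio, "P")[["C"]], 0L))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("assign_phenotypes follows penetrance and phenocopy rates", {
  g_carrier <- setNames(rep(1L, 5), paste0("c", 1:5))
  g_non <- setNames(rep(0L, 10000), paste0("n", 1:10000))
  # degenerate cases
  set.seed(1)
  expect_true(all(assign_phenotypes(g_carrier, sim_config(penetrance = 1)) ==
                    "affected"))
  expect_true(all(assign_phenotypes(g_carrier, sim_config(penetrance = 0)) ==
                    "unaffected"))
  expect_true(all(assign_phenotypes(g_non, sim_config(phenocopy_rate = 0)) ==
                    "unaffected"))
  # phenocopy fraction within 3 SE of the configured rate
  set.seed(2)
  phe <- assign_phenotypes(g_non, sim_config(phenocopy_rate = 0.075))
  expect_lt(abs(mean(phe == "affected") - 0.075),
            3 * sqrt(0.075 * 0.925 / 10000))
})

test_that("background simulation is deterministic and Mendelian-consistent", {
  cfg <- small_cfg(21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim1 <- simulate_dataset(cfg, out_dir = d1)
  sim2 <- simulate_dataset(cfg, out_dir = d2)
  # byte-identical outputs under a fixed seed
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # Mendelian consistency of true genotypes: every child allele has a source
  ped <- sim1$ped
  truth <- sim1$truth
  for (id in ped$id) {
    i <- match(id, ped$id)
    if (is.na(ped$father[i])) next
    child <- truth[, id]
    # each inherited copy needs a parent who actually carries one
    max_inherit <- (truth[, ped$father[i]] > 0L) + (truth[, ped$mother[i]] > 0L)
    expect_true(all(child <= max_inherit), info = id)
  }
})

test_that("per-sample counts track the configured mean and causal calls are well supported", {
  cfg <- small_cfg(31)
  sim <- simulate_dataset(cfg)
  cnt <- unlist(sim$manifest$background_counts)
  expect_lt(abs(mean(cnt) - 1500), 3 * 300 / sqrt(length(cnt)) + 3 * sqrt(1500))
  causal_calls <- sim$table$calls[sim$table$calls$key == sim$causal_key, ]
  expect_true(all(causal_calls$alt_reads >= 20))
})

test_that("full cohort overlap drains every background variant", {
  cfg <- small_cfg(41, cohort_db_overlap = 1)
  sim <- simulate_dataset(cfg)
  bg_keys <- setdiff(sim$annotations$key, sim$causal_key)
  res <- filter_cohort_db(bg_keys, sim$annotations)
  expect_length(res$kept, 0)
})

test_that("inject_errors: identity at zero rates, bookkeeping otherwise", {
  cfg0 <- small_cfg(51, fp_call_rate = 0, fn_call_rate = 0)
  sim <- simulate_dataset(cfg0)
  out <- inject_errors(sim$table, cfg0, ped = sim$ped)
  expect_equal(out$calls[order(out$calls$key, out$calls$sample), ],
               sim$table$calls[order(sim$table$calls$key,
                                     sim$table$calls$sample), ],
               ignore_attr = TRUE)
  expect_equal(nrow(attr(out, "error_log")), 0)

  cfg1 <- small_cfg(52, fp_call_rate = 1e-3, fn_call_rate = 0.05)
  set.seed(1)
  out1 <- inject_errors(sim$table, cfg1, ped = sim$ped,
                        protect_keys = sim$causal_key)
  log <- attr(out1, "error_log")
  expect_gt(nrow(log), 0)
  # every logged flip is observable in the table, and counts reconcile
  fn <- log[log$kind == "fn", ]
  for (i in head(seq_len(nrow(fn)), 20))
    expect_equal(genotype_at(out1, fn$key[i], fn$sample[i]), "missing")
  fp <- log[log$kind == "fp", ]
  for (i in head(seq_len(nrow(fp)), 20))
    expect_equal(genotype_at(out1, fp$key[i], fp$sample[i]), "het")
  expect_false(sim$causal_key %in% log$key)
})

test_that("the worked-example fixture satisfies its construction contract", {
  fx <- make_fig1a_fixture()
  merged <- merge_adjacent_substitutions(fx$table)
  expect_length(shared_candidates(merged, fx$ped, fx$scan), 5)
  res <- run_pipeline_core(merged, fx$ped, fx$annotations,
                           validation = fx$validation, whitelist = fx$whitelist,
                           scan = fx$scan, model = fx$model)
  expect_equal(res$pass_keys, fx$causal_key)
  # packaged files are exactly what the builder emits (no drift)
  d <- withr::local_tempdir()
  paths <- write_fig1a_fixture(d)
  for (f in basename(paths))
    expect_identical(readLines(file.path(d, f)),
                     readLines(file.path(fig1a_dir(), f)), info = f)
})
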