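# Independent oracles and small generators used across the suite.
# The oracles re-evaluate definitions by direct loops/enumeration and stay
# independent of the vectorized implementation paths they check.

# literal re-evaluation of the shared-candidate rule, one variant and one
# individual at a time
oracle_shared_candidates <- function(table, ped, cfg = scan_config()) {
  seq_ids <- intersect(ped$id[ped$sequenced], table$samples)
  aff <- seq_ids[ped$phenotype[match(seq_ids, ped$id)] == "affected"]
  una <- seq_ids[ped$phenotype[match(seq_ids, ped$id)] == "unaffected"]
  keep <- character(0)
  for (k in table$variants$key) {
    ok <- TRUE
    for (a in aff) {
      g <- genotype_at(table, k, a)
      carrier <- g %in% cfg$carrier_genotypes
      lenient <- cfg$exception_missing_ok && a %in% cfg$exception_ids &&
        identical(g, "missing")
      if (!carrier && !lenient) { ok <- FALSE; break }
    }
    if (ok) for (u in una) {
      g <- genotype_at(table, k, u)
      if (g %in% c("het", "hom_alt")) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, k)
  }
  keep
}

# independent verdict evaluator for the two-parents + three-children
# pedigree used in the exhaustive enumeration; transmission logic is the
# closed form for that topology (parents reachable directly, siblings via
# one parent), derived by hand from the lineage rule
oracle_verdict_nuclear <- function(gts, phenos, model,
                                   parents = c("F", "M"),
                                   kids = c("C1", "C2", "C3")) {
  ids <- c(parents, kids)
  typed <- ids[gts[ids] != "missing"]
  carriers <- typed[gts[typed] %in% model$carrier_genotypes]
  if (!length(carriers)) return("FAIL_MONOMORPHIC")
  aff_typed <- typed[phenos[typed] == "affected"]
  if (any(!(gts[aff_typed] %in% model$carrier_genotypes)))
    return("FAIL_MISSING_IN_AFFECTED")
  una_carriers <- carriers[phenos[carriers] == "unaffected"]
  if (length(una_carriers) > model$max_unaffected_carriers)
    return("FAIL_UNAFFECTED_CARRIER")
  for (e in intersect(model$exception_ids, carriers)) {
    if (!(e %in% kids)) next  # closed form applies to children only
    others <- setdiff(carriers, e)
    if (!length(others)) next                     # indeterminate: passes with caveat
    open_parent <- function(p) !(p %in% typed) || gts[p] %in% model$carrier_genotypes
    confirmed <- any(vapply(intersect(others, parents), function(p)
      gts[p] %in% model$carrier_genotypes, NA)) ||
      (length(intersect(others, kids)) > 0 &&
         (open_parent(parents[1]) || open_parent(parents[2])))
    if (!confirmed) return("FAIL_ANCESTRY_UNCONFIRMED")
  }
  "PASS_COSEGREGATING"
}

# random small pedigree: founder couple, married-in spouses, two further
# generations; phenotypes and sequencing flags randomized
rand_ped <- function(seed) {
  set.seed(seed)
  rows <- list(
    list("F1", NA, NA, "male"), list("F2", NA, NA, "female"),
    list("S1", NA, NA, "female"), list("S2", NA, NA, "male"))
  n_kids <- sample(2:3, 1)
  for (i in seq_len(n_kids))
    rows <- c(rows, list(list(paste0("K", i), "F1", "F2",
                              sample(c("male", "female"), 1))))
  # grandchildren through K1 x S1 and (if present) K2 x S2
  for (i in seq_len(sample(1:3, 1)))
    rows <- c(rows, list(list(paste0("G", i), "S2", "K1", "female")))
  df <- data.frame(
    id = vapply(rows, function(r) r[[1]], ""),
    father = vapply(rows, function(r) if (is.na(r[[2]])) NA_character_ else r[[2]], ""),
    mother = vapply(rows, function(r) if (is.na(r[[3]])) NA_character_ else r[[3]], ""),
    sex = vapply(rows, function(r) r[[4]], ""),
    phenotype = sample(c("affected", "unaffected", "uncertain", "untested"),
                       length(rows), replace = TRUE),
    sequenced = sample(c(TRUE, FALSE), length(rows), replace = TRUE),
    stringsAsFactors = FALSE)
  # sex consistency with parent roles used above
  df$sex[df$id == "K1"] <- "female"
  if (!any(df$sequenced & df$phenotype == "affected"))
    df$phenotype[df$sequenced][1] <- "affected"
  if (!any(df$sequenced)) { df$sequenced[1] <- TRUE; df$phenotype[1] <- "affected" }
  pedigree(df, name = "RAND")
}

# random genotype table over given samples; positions drawn in a narrow
# window so adjacent runs occur, exercising the MNV merge
rand_table <- function(seed, samples, n_var = 8, clustered = FALSE) {
  set.seed(seed)
  pos <- if (clustered) sort(sample(1000:1020, n_var)) else
    sort(sample(seq(1000, 100000, by = 7), n_var))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  variants <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  variants$key <- paste("1", pos, ref, alt, sep = ":")
  calls <- do.call(rbind, lapply(variants$key, function(k) {
    gts <- sample(c("hom_ref", "het", "hom_alt", "missing"), length(samples),
                  TRUE, prob = c(0.45, 0.35, 0.1, 0.1))
    keep <- gts != "hom_ref"
    if (!any(keep)) return(NULL)
    data.frame(key = k, sample = samples[keep], gt = gts[keep],
               alt_reads = ifelse(gts[keep] == "missing", NA,
                                  sample(0:60, sum(keep), TRUE)),
               source = "exome", stringsAsFactors = FALSE)
  }))
  genotype_table(variants, samples, calls %||% data.frame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fig1a_dir <- function() system.file("extdata", "fig1a", package = "cosegr")
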