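#' Simulation configuration
#'
#' The stated world the generator emulates: a multi-generation pedigree in
#' which a heterozygous causal variant is dropped from a founder under
#' dominant inheritance with high or complete penetrance; a population
#' phenocopy prevalence of 5-10% (default 0.075, the middle of that range);
#' roughly 50,556 variant calls per sequenced sample with a between-sample
#' SD of 6,524 (modelled as a per-sample callable fraction — binomial noise
#' alone cannot produce a 13% CV); an in-house cohort database of 700
#' exomes that contains most background variants; rare founder-private
#' variants; and genotyping error producing occasional false-positive and
#' false-negative calls.
#'
#' @param seed integer master seed; identical configs give byte-identical
#'   outputs.
#' @param ped pedigree to simulate on (default: the packaged worked-example
#'   pedigree).
#' @param causal_founder_id founder carrying the causal variant (het).
#' @param penetrance P(affected | carrier), default 1.
#' @param phenocopy_rate P(affected | non-carrier), default 0.075.
#' @param n_background_mean target mean non-reference calls per sample.
#' @param n_background_sd target between-sample SD of that count.
#' @param maf_common_range uniform MAF range of the common background class.
#' @param rare_maf_range uniform MAF range of annotated rare variants.
#' @param p_rare_novel fraction of founder-private rare variants with no
#'   population-frequency annotation (novel).
#' @param n_rare_per_founder mean count of private rare het variants per
#'   founder (Poisson).
#' @param cohort_db_overlap fraction of background variants present in the
#'   simulated cohort database.
#' @param fp_call_rate per-(variant, sample) probability that an absent
#'   (hom_ref) background genotype is spuriously called het.
#' @param fn_call_rate probability that a true het exome call is dropped to
#'   missing.
#' @param n_universal_fp number of injected artifact variants called het in
#'   every affected sequenced sample (the monomorphic-at-validation error
#'   class); default 0.
#' @param validation_error_free if TRUE (default) validation genotypes are
#'   the simulation truth.
#' @param callable_margin mean callable fraction; the background pool is
#'   oversized by 1/callable_margin so per-sample targets up to +3 SD stay
#'   attainable by thinning.
#' @param consequence_props named proportions over consequence classes.
#' @param p_gene_brain_expressed fraction of background genes on the
#'   brain-expression whitelist.
#' @param n_genes size of the synthetic gene universe.
#' @param depth_mean mean sequencing depth at a called site (Poisson);
#'   het alt reads are Binomial(depth, 1/2).
#' @param fp_alt_read_mean mean alt reads of spurious calls (Poisson);
#'   deliberately low so the read-support filter has real work to do.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       ped = fig1a_pedigree(),
                       causal_founder_id = "II:1",
                       penetrance = 1.0,
                       phenocopy_rate = 0.075,
                       n_background_mean = 50556L,
                       n_background_sd = 6524L,
                       maf_common_range = c(0.05, 0.5),
                       rare_maf_range = c(1e-4, 0.01),
                       p_rare_novel = 0.5,
                       n_rare_per_founder = 700L,
                       cohort_db_overlap = 0.9,
                       fp_call_rate = 2e-5,
                       fn_call_rate = 0.03,
                       n_universal_fp = 0L,
                       validation_error_free = TRUE,
                       callable_margin = 0.70,
                       consequence_props = c(non_synonymous = 0.5,
                                             synonymous = 0.4, other = 0.1),
                       p_gene_brain_expressed = 0.5,
                       n_genes = 15000L,
                       depth_mean = 150,
                       fp_alt_read_mean = 12,
                       min_affected_sequenced = 2L) {
  rates <- c(penetrance = penetrance, phenocopy_rate = phenocopy_rate,
             cohort_db_overlap = cohort_db_overlap, fp_call_rate = fp_call_rate,
             fn_call_rate = fn_call_rate, p_rare_novel = p_rare_novel)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    stop_user("sim_config: rate(s) outside [0,1]: ",
              paste(names(rates)[bad], collapse = ", "))
  if (n_background_mean <= 0) stop_user("sim_config: n_background_mean must be > 0")
  structure(list(seed = as.integer(seed), ped = ped,
                 causal_founder_id = causal_founder_id,
                 penetrance = penetrance, phenocopy_rate = phenocopy_rate,
                 n_background_mean = as.integer(n_background_mean),
                 n_background_sd = as.integer(n_background_sd),
                 maf_common_range = maf_common_range,
                 rare_maf_range = rare_maf_range,
                 p_rare_novel = p_rare_novel,
                 n_rare_per_founder = as.integer(n_rare_per_founder),
                 cohort_db_overlap = cohort_db_overlap,
                 fp_call_rate = fp_call_rate, fn_call_rate = fn_call_rate,
                 n_universal_fp = as.integer(n_universal_fp),
                 validation_error_free = isTRUE(validation_error_free),
                 callable_margin = callable_margin,
                 consequence_props = consequence_props,
                 p_gene_brain_expressed = p_gene_brain_expressed,
                 n_genes = as.integer(n_genes),
                 depth_mean = depth_mean,
                 fp_alt_read_mean = fp_alt_read_mean,
                 min_affected_sequenced = as.integer(min_affected_sequenced)),
            class = "sim_config")
}

#' Drop a founder allele through the pedigree
#'
#' Mendelian gene dropping of a single heterozygous founder variant: each
#' child independently inherits the founder-derived allele from a carrier
#' parent with probability 1/2. Non-descendant founders are reference
#' unless listed in `extra_carrier_founders` (a married-in carrier).
#'
#' @param ped a pedigree.
#' @param causal_founder_id founder id; must have no parents in `ped`.
#' @param cfg a [sim_config()] (unused except for validation; kept for the
#'   module interface).
#' @param extra_carrier_founders optional ids of additional het founders.
#' @return named integer vector of allele dosages (0/1/2) over all
#'   individuals.
#' @export
gene_drop <- function(ped, causal_founder_id, cfg = NULL,
                      extra_carrier_founders = character(0)) {
  if (!causal_founder_id %in% ped$id)
    stop_user("gene_drop: unknown founder: ", causal_founder_id)
  if (!ped_is_founder(ped, causal_founder_id))
    stop_user("gene_drop: ", causal_founder_id, " has parents in the pedigree")
  order_ids <- topo_order(ped)
  dosage <- setNames(integer(nrow(ped)), ped$id)
  dosage[causal_founder_id] <- 1L
  dosage[intersect(extra_carrier_founders, ped$id)] <- 1L
  for (id in order_ids) {
    parents <- ped_parents(ped, id)
    if (!length(parents)) next
    d <- 0L
    for (p in parents) d <- d + stats::rbinom(1L, 1L, dosage[[p]] / 2)
    dosage[id] <- d
  }
  dosage
}

#' Assign phenotypes given causal genotypes
#'
#' Carriers are affected with probability `penetrance`; non-carriers with
#' probability `phenocopy_rate` (the background population prevalence),
#' independently across individuals given genotype.
#'
#' @param genotypes named dosage vector (from [gene_drop()]).
#' @param cfg a [sim_config()].
#' @return named character vector, `"affected"` / `"unaffected"`.
#' @export
assign_phenotypes <- function(genotypes, cfg = sim_config()) {
  carrier <- genotypes > 0L
  p <- ifelse(carrier, cfg$penetrance, cfg$phenocopy_rate)
  out <- ifelse(stats::runif(length(genotypes)) < p, "affected", "unaffected")
  setNames(out, names(genotypes))
}

# dosage matrix (variants x individuals) dropped through the pedigree from
# founder genotypes; founders drawn HWE from per-variant MAF unless given
drop_matrix <- function(ped, founder_dosage) {
  order_ids <- topo_order(ped)
  n <- nrow(founder_dosage)
  dos <- matrix(0L, nrow = n, ncol = nrow(ped), dimnames = list(NULL, ped$id))
  founders <- colnames(founder_dosage)
  dos[, founders] <- founder_dosage
  for (id in order_ids) {
    parents <- ped_parents(ped, id)
    if (!length(parents)) next
    d <- integer(n)
    for (p in parents) d <- d + stats::rbinom(n, 1L, dos[, p] / 2)
    dos[, id] <- d
  }
  dos
}

#' Simulate the background variant landscape of the family
#'
#' Draws a common background pool (HWE founder genotypes at MAFs from the
#' configured spectrum) and founder-private rare variants, drops every
#' variant through the pedigree, thins each sequenced sample's
#' non-reference calls to a per-sample target count drawn from
#' N(`n_background_mean`, `n_background_sd`) (the callable-fraction model of
#' between-sample variability), and assigns annotations (gene, consequence,
#' population MAF, cohort-database presence, brain expression) per the
#' configured proportions. Sequencing depths are Poisson(`depth_mean`) with
#' binomial alt reads for heterozygotes.
#'
#' Uses the current RNG state; [simulate_dataset()] seeds it from the config.
#'
#' @param ped a pedigree.
#' @param cfg a [sim_config()].
#' @return list: `table` (genotype_table of observed exome calls),
#'   `annotations`, `whitelist` (brain-expressed gene symbols), `truth`
#'   (dosage matrix of true genotypes, variants x individuals), `manifest`
#'   (list with per-sample observed counts and bookkeeping).
#' @export
simulate_background <- function(ped, cfg = sim_config()) {
  samples <- ped_sequenced_ids(ped)
  founders <- ped$id[vapply(ped$id, function(i) ped_is_founder(ped, i), NA)]

  a <- cfg$maf_common_range[1]; b <- cfg$maf_common_range[2]
  # E[1-(1-p)^2] for p ~ U(a, b), in closed form
  mean_nonref <- ((b^2 - a^2) - (b^3 - a^3) / 3) / (b - a)
  n_common <- max(1L, round(cfg$n_background_mean / cfg$callable_margin / mean_nonref))

  maf_common <- stats::runif(n_common, a, b)
  founder_common <- matrix(
    stats::rbinom(n_common * length(founders), 2L, rep(maf_common, length(founders))),
    nrow = n_common, dimnames = list(NULL, founders))

  n_rare <- stats::rpois(length(founders), cfg$n_rare_per_founder)
  founder_rare <- matrix(0L, nrow = sum(n_rare), ncol = length(founders),
                         dimnames = list(NULL, founders))
  row0 <- 0L
  for (fi in seq_along(founders)) {
    if (n_rare[fi] > 0L)
      founder_rare[row0 + seq_len(n_rare[fi]), fi] <- 1L
    row0 <- row0 + n_rare[fi]
  }
  founder_dosage <- rbind(founder_common, founder_rare)
  n_var <- nrow(founder_dosage)
  is_rare <- c(rep(FALSE, n_common), rep(TRUE, sum(n_rare)))

  truth <- drop_matrix(ped, founder_dosage)

  # variant identities: toy contigs, positions spaced by 10 so background
  # variants are never adjacent (MNV merging is exercised by fixtures)
  chrom <- sample(as.character(1:22), n_var, replace = TRUE)
  pos <- integer(n_var)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(24000000L, length(idx))) * 10L
  }
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, n_var, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3L, n_var, replace = TRUE)) %% 4L + 1L
  ref <- bases[ref_i]
  alt <- bases[alt_i]
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  variants$key <- variant_key(chrom, pos, ref, alt)

  # annotations
  maf_rare <- ifelse(stats::runif(sum(n_rare)) < cfg$p_rare_novel, NA_real_,
                     stats::runif(sum(n_rare), cfg$rare_maf_range[1],
                                  cfg$rare_maf_range[2]))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  gene_brain <- setNames(stats::runif(cfg$n_genes) < cfg$p_gene_brain_expressed,
                         gene_ids)
  gene <- sample(gene_ids, n_var, replace = TRUE)
  annotations <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, key = variants$key,
    gene = gene,
    consequence = sample(names(cfg$consequence_props), n_var, replace = TRUE,
                         prob = cfg$consequence_props),
    pop_maf = c(maf_common, maf_rare),
    in_cohort_db = stats::runif(n_var) < cfg$cohort_db_overlap,
    brain_expressed = unname(gene_brain[gene]),
    stringsAsFactors = FALSE)

  # observed calls: per-sample callable-fraction thinning of true non-ref calls
  truth_seq <- truth[, samples, drop = FALSE]
  true_counts <- colSums(truth_seq > 0L)
  targets <- stats::rnorm(length(samples), cfg$n_background_mean, cfg$n_background_sd)
  targets <- pmin(pmax(targets, cfg$n_background_mean - 3 * cfg$n_background_sd),
                  cfg$n_background_mean + 3 * cfg$n_background_sd)
  calls_list <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    nz <- which(truth_seq[, si] > 0L)
    d <- min(1, targets[si] / length(nz))
    keep <- nz[stats::runif(length(nz)) < d]
    depth <- stats::rpois(length(keep), cfg$depth_mean)
    dosage <- truth_seq[keep, si]
    alt_reads <- ifelse(dosage == 2L, depth,
                        stats::rbinom(length(keep), depth, 0.5))
    calls_list[[si]] <- data.frame(
      key = variants$key[keep], sample = samples[si],
      gt = ifelse(dosage == 2L, "hom_alt", "het"),
      alt_reads = as.integer(alt_reads), source = "exome",
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls_list)

  # per-sample exome calling emits only sites called in >= 1 sample
  seen <- unique(calls$key)
  variants_obs <- variants[variants$key %in% seen, , drop = FALSE]
  table <- sort_variants(genotype_table(variants_obs, samples, calls))

  manifest <- list(
    samples = samples,
    per_sample_counts = as.list(setNames(
      vapply(samples, function(s) sum(calls$sample == s), 1L), samples)),
    n_variants_pool = n_var, n_common = n_common,
    n_rare = sum(n_rare), true_counts = as.list(setNames(true_counts, samples)),
    is_rare = NULL)
  rownames(truth) <- variants$key

  list(table = table, annotations = annotations,
       whitelist = sort(gene_ids[gene_brain]),
       truth = truth, manifest = manifest, is_rare = is_rare)
}

#' Inject genotyping errors into a genotype table
#'
#' False positives: absent (hom_ref-by-policy) background genotypes of
#' sequenced samples flip to het with probability `fp_call_rate`, with low
#' simulated alt-read support. False negatives: existing het exome calls
#' drop to missing with probability `fn_call_rate`. Additionally,
#' `n_universal_fp` artifact variants are called het in every affected
#' sequenced sample with strong support — the error class that survives the
#' shared-candidate scan and dies at validation (monomorphic).
#' Validation-source calls are never touched when `validation_error_free`.
#'
#' @param table a genotype_table.
#' @param cfg a [sim_config()].
#' @param ped pedigree (needed to pick affected samples for universal FPs).
#' @param protect_keys variant keys never altered (e.g. the causal variant).
#' @return a genotype_table with attribute `error_log` (data.frame kind,
#'   key, sample).
#' @export
inject_errors <- function(table, cfg, ped = NULL, protect_keys = character(0)) {
  calls <- table$calls
  log <- list()

  if (cfg$fn_call_rate > 0) {
    het_idx <- which(calls$source == "exome" & calls$gt == "het" &
                     !(calls$key %in% protect_keys))
    drop <- het_idx[stats::runif(length(het_idx)) < cfg$fn_call_rate]
    if (length(drop)) {
      log[[length(log) + 1L]] <- data.frame(kind = "fn", key = calls$key[drop],
                                            sample = calls$sample[drop])
      calls$gt[drop] <- "missing"
      calls$alt_reads[drop] <- NA_integer_
    }
  }

  if (cfg$fp_call_rate > 0) {
    keys <- setdiff(table$variants$key, protect_keys)
    called <- paste(calls$key, calls$sample)
    fp_rows <- list()
    for (s in table$samples) {
      n_fp <- stats::rbinom(1L, length(keys), cfg$fp_call_rate)
      if (n_fp == 0L) next
      cand <- sample(keys, n_fp)
      cand <- cand[!(paste(cand, s) %in% called)]
      if (length(cand))
        fp_rows[[length(fp_rows) + 1L]] <- data.frame(
          key = cand, sample = s, gt = "het",
          alt_reads = stats::rpois(length(cand), cfg$fp_alt_read_mean),
          source = "exome", stringsAsFactors = FALSE)
    }
    if (length(fp_rows)) {
      fp <- do.call(rbind, fp_rows)
      calls <- rbind(calls, fp)
      log[[length(log) + 1L]] <- data.frame(kind = "fp", key = fp$key,
                                            sample = fp$sample)
    }
  }

  universal_keys <- character(0)
  variants <- table$variants
  if (cfg$n_universal_fp > 0L) {
    if (is.null(ped))
      stop_user("inject_errors: ped required for universal false positives")
    affected <- intersect(ped_sequenced_ids(ped),
                          ped$id[ped$phenotype == "affected"])
    # artifact variants are platform errors at loci nobody truly carries:
    # fresh records on a reserved position range, called het in every
    # affected sample with strong support (they survive the scan and the
    # read-support filter, and die at validation as monomorphic)
    for (i in seq_len(cfg$n_universal_fp)) {
      art <- data.frame(chrom = "9", pos = 77777701L + 7L * i, ref = "A",
                        alt = "G", stringsAsFactors = FALSE)
      art$key <- variant_key(art$chrom, art$pos, art$ref, art$alt)
      extra <- setdiff(names(variants), names(art))
      for (col in extra) art[[col]] <- NA
      variants <- rbind(variants, art[, names(variants)])
      rows <- data.frame(key = art$key, sample = affected, gt = "het",
                         alt_reads = 20L + stats::rpois(length(affected), 15),
                         source = "exome", stringsAsFactors = FALSE)
      calls <- rbind(calls, rows)
      universal_keys <- c(universal_keys, art$key)
      log[[length(log) + 1L]] <- data.frame(kind = "universal_fp",
                                            key = art$key, sample = affected)
    }
  }

  out <- sort_variants(genotype_table(variants, table$samples, calls))
  attr(out, "error_log") <- if (length(log))
    do.call(rbind, log)
  else data.frame(kind = character(0), key = character(0), sample = character(0))
  attr(out, "universal_fp_keys") <- universal_keys
  out
}

#' Simulate a complete dataset
#'
#' Orchestrates [gene_drop()], [assign_phenotypes()],
#' [simulate_background()] and [inject_errors()] under the config's seed,
#' injects the causal variant (heterozygous in carriers, Poisson depths,
#' never thinned: the causal locus is modelled as well covered in every
#' sample), and builds truth-based validation genotypes for the causal and
#' any injected artifact variants across all pedigree members (Sanger-style
#' follow-up of candidate loci). Optionally writes the dataset to disk as
#' PED, per-sample VCFs, annotation/validation TSVs, whitelist, and a JSON
#' manifest.
#'
#' Individuals whose pedigree phenotype is `uncertain` or `untested` keep
#' that status (no phenotype data exists for them); everyone else gets a
#' simulated phenotype.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory.
#' @return list: `ped` (phenotypes re-simulated), `table` (observed calls,
#'   errors injected), `annotations`, `validation`, `whitelist`, `truth`,
#'   `causal_key`, `manifest`, and `paths` when written.
#' @export
simulate_dataset <- function(cfg = sim_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  ped <- cfg$ped

  # ascertainment conditioning: a family study exists because the trait
  # visibly segregates, so redraw transmission/phenotypes until at least
  # min_affected_sequenced sequenced members are affected
  observable <- !(ped$phenotype %in% c("uncertain", "untested"))
  for (attempt in 1:1000) {
    causal <- gene_drop(ped, cfg$causal_founder_id, cfg)
    phe <- assign_phenotypes(causal, cfg)
    n_aff_seq <- sum(ped$sequenced & observable &
                       phe[ped$id] == "affected")
    if (n_aff_seq >= cfg$min_affected_sequenced) break
    if (attempt == 1000L)
      stop_user("simulate_dataset: could not satisfy ascertainment after 1000 draws")
  }
  ped$phenotype[observable] <- unname(phe[ped$id[observable]])

  bg <- simulate_background(ped, cfg)

  causal_variant <- data.frame(chrom = "3", pos = 134264558L, ref = "G",
                               alt = "T", stringsAsFactors = FALSE)
  causal_key <- variant_key("3", 134264558L, "G", "T")
  causal_variant$key <- causal_key
  samples <- ped_sequenced_ids(ped)
  carrier_samples <- samples[causal[samples] > 0L]
  causal_calls <- if (length(carrier_samples)) {
    depth <- stats::rpois(length(carrier_samples), cfg$depth_mean)
    data.frame(key = causal_key, sample = carrier_samples, gt = "het",
               alt_reads = as.integer(stats::rbinom(length(carrier_samples),
                                                    depth, 0.5)),
               source = "exome", stringsAsFactors = FALSE)
  } else NULL

  variants <- rbind(bg$table$variants[, c("chrom", "pos", "ref", "alt", "key")],
                    causal_variant)
  calls <- rbind(bg$table$calls, causal_calls)
  table <- sort_variants(genotype_table(variants, samples, calls))

  causal_gene <- "GCAUSL"  # synthetic symbol; whitelisted below
  annotations <- rbind(
    bg$annotations,
    data.frame(chrom = "3", pos = 134264558L, ref = "G", alt = "T",
               key = causal_key, gene = causal_gene,
               consequence = "non_synonymous", pop_maf = 1e-4,
               in_cohort_db = FALSE, brain_expressed = TRUE,
               stringsAsFactors = FALSE))
  whitelist <- sort(c(bg$whitelist, causal_gene))

  table <- inject_errors(table, cfg, ped = ped, protect_keys = causal_key)
  universal_fp <- attr(table, "universal_fp_keys")
  if (length(universal_fp)) {
    # artifact loci get benign-looking annotations so they reach validation,
    # mirroring how a convincing platform error passes every desk filter
    art_v <- table$variants[match(universal_fp, table$variants$key), ]
    annotations <- rbind(annotations, data.frame(
      chrom = art_v$chrom, pos = art_v$pos, ref = art_v$ref, alt = art_v$alt,
      key = art_v$key, gene = "GARTIF", consequence = "non_synonymous",
      pop_maf = NA_real_, in_cohort_db = FALSE, brain_expressed = TRUE,
      stringsAsFactors = FALSE))
    whitelist <- sort(c(whitelist, "GARTIF"))
  }

  validated_keys <- c(causal_key, universal_fp)
  truth_dosage <- rbind(bg$truth, matrix(causal[colnames(bg$truth)], nrow = 1,
                                         dimnames = list(causal_key)))
  validation <- do.call(rbind, lapply(validated_keys, function(k) {
    dos <- if (k %in% rownames(truth_dosage)) truth_dosage[k, ped$id]
           else setNames(rep(0L, nrow(ped)), ped$id)  # artifact: nobody carries it
    data.frame(variant_key = k, individual_id = ped$id,
               genotype = c("0/0", "0/1", "1/1")[dos + 1L],
               stringsAsFactors = FALSE)
  }))

  manifest <- bg$manifest
  manifest$background_counts <- manifest$per_sample_counts
  # final per-sample counts = rows of each emitted per-sample VCF
  manifest$per_sample_counts <- as.list(setNames(vapply(
    samples, function(s) sum(table$calls$sample == s & table$calls$gt != "hom_ref"),
    1L), samples))
  manifest$seed <- cfg$seed
  manifest$causal_key <- causal_key
  manifest$causal_carriers <- names(causal)[causal > 0L]
  manifest$universal_fp_keys <- as.list(universal_fp)
  manifest$n_errors <- nrow(attr(table, "error_log"))

  out <- list(ped = ped, table = table, annotations = annotations,
              validation = validation, whitelist = whitelist,
              truth = truth_dosage, causal_key = causal_key,
              manifest = manifest,
              error_log = attr(table, "error_log"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(ped = file.path(out_dir, "family.ped"),
               annotations = file.path(out_dir, "annotations.tsv"),
               validation = file.path(out_dir, "validation.tsv"),
               whitelist = file.path(out_dir, "whitelist.txt"),
               manifest = file.path(out_dir, "manifest.json"))
    write_ped(ped, paths["ped"])
    ann_out <- annotations[, c("chrom", "pos", "ref", "alt", "gene",
                               "consequence", "pop_maf", "in_cohort_db",
                               "brain_expressed")]
    data.table::fwrite(ann_out, paths["annotations"], sep = "\t")
    data.table::fwrite(validation, paths["validation"], sep = "\t")
    writeLines(whitelist, paths["whitelist"])
    vcfs <- setNames(file.path(out_dir, paste0(gsub(":", "_", samples), ".vcf")),
                     samples)
    for (s in samples) {
      sub <- table$calls[table$calls$sample == s & table$calls$gt != "hom_ref", ]
      st <- genotype_table(table$variants[table$variants$key %in% sub$key, ],
                           s, sub)
      write_vcf(st, vcfs[[s]])
    }
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         pretty = TRUE)
    out$paths <- c(paths, vcfs)
  }
  out
}
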