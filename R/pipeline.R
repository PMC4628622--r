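#' Run the co-segregation discovery pipeline
#'
#' Fixed stage order: ingest -> merge adjacent substitutions -> read-support
#' filter -> shared-candidate scan -> cohort-database filter -> population
#' MAF filter -> brain-expression filter -> consequence filter -> validation
#' override -> per-variant co-segregation verdicts. Because the annotation
#' filters have intersection semantics, stage order affects only the trace
#' attribution of doubly-failing variants, not the surviving set.
#'
#' The config is a JSON file or an R list with fields: `ped` (PED path),
#' `vcf` (one multi-sample VCF path or a vector of per-sample paths),
#' `samples` (sample ids), `annotations` (TSV path), optional `validation`
#' (TSV path), optional `whitelist` (gene list path; overrides the
#' `brain_expressed` annotation column), `out_dir`, and optional parameter
#' blocks `scan`, `filters`, `model` (arguments to [scan_config()],
#' [filter_config()], [inheritance_model()]). Unknown top-level or block
#' names are a schema error raised before any computation. Relative paths
#' resolve against the config file's directory.
#'
#' Every input (post-merge) variant appears exactly once in the report with
#' its terminal reason code; stage out-counts reconcile with the next
#' stage's in-count and with the reason tallies (enforced internally).
#'
#' @param config path to a JSON config, or an equivalent named list.
#' @return (invisibly) a `pipeline_result`: list with `trace` (stages +
#'   report), `verdicts`, `pass_keys`, `table` (post-validation), and
#'   `paths` of written outputs (when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  ped <- parse_ped(cfg$ped)
  table <- read_variant_calls(cfg$vcf, cfg$samples)
  annotations <- read_annotation_table(cfg$annotations)
  whitelist <- if (!is.null(cfg$whitelist)) read_gene_whitelist(cfg$whitelist)
  validation <- if (!is.null(cfg$validation)) cfg$validation
  res <- run_pipeline_core(table, ped, annotations,
                           validation = validation, whitelist = whitelist,
                           scan = cfg$scan_config, filters = cfg$filter_config,
                           model = cfg$model_config,
                           config_hash = cfg$config_hash, seed = cfg$seed)
  if (!is.null(cfg$out_dir))
    res$paths <- write_outputs(res$table, res$trace, cfg$out_dir, res$annotations)
  invisible(res)
}

load_pipeline_config <- function(config) {
  base_dir <- "."
  if (is.character(config)) {
    if (!file.exists(config))
      stop_user("run_pipeline: config file not found: ", config)
    base_dir <- dirname(config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_user("run_pipeline: config must be a list or JSON path")
  allowed <- c("ped", "vcf", "samples", "annotations", "validation",
               "whitelist", "out_dir", "scan", "filters", "model", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop_user("run_pipeline: unknown config field(s): ",
              paste(unknown, collapse = ", "))
  for (f in c("ped", "vcf", "samples", "annotations"))
    if (is.null(config[[f]]))
      stop_user("run_pipeline: missing config field: ", f)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  config$ped <- resolve(config$ped)
  config$vcf <- vapply(config$vcf, resolve, "")
  config$annotations <- resolve(config$annotations)
  if (!is.null(config$validation)) config$validation <- resolve(config$validation)
  if (!is.null(config$whitelist)) config$whitelist <- resolve(config$whitelist)
  if (!is.null(config$out_dir) && !startsWith(config$out_dir, "/"))
    config$out_dir <- file.path(base_dir, config$out_dir)
  for (f in c("ped", "vcf", "annotations", "validation", "whitelist"))
    for (p in config[[f]])
      if (!file.exists(p)) stop_user("run_pipeline: missing input file: ", p)
  config$scan_config <- do.call(scan_config, as.list(config$scan %||% list()))
  config$filter_config <- do.call(filter_config, as.list(config$filters %||% list()))
  config$model_config <- do.call(inheritance_model, as.list(config$model %||% list()))
  config$config_hash <- fnv1a(jsonlite::toJSON(
    config[intersect(allowed, names(config))], auto_unbox = TRUE))
  config
}

#' Run the pipeline stages on in-memory objects
#'
#' The object-level engine behind [run_pipeline()]; useful for simulation
#' experiments where file I/O would dominate.
#'
#' @param table genotype_table of exome calls.
#' @param ped pedigree.
#' @param annotations annotation data.frame.
#' @param validation optional validation data.frame or TSV path.
#' @param whitelist optional gene symbol vector (overrides `brain_expressed`).
#' @param scan a [scan_config()].
#' @param filters a [filter_config()].
#' @param model an [inheritance_model()].
#' @param config_hash,seed run metadata recorded in the trace.
#' @return a `pipeline_result` list (see [run_pipeline()]).
#' @export
run_pipeline_core <- function(table, ped, annotations, validation = NULL,
                              whitelist = NULL,
                              scan = scan_config(), filters = filter_config(),
                              model = inheritance_model(),
                              config_hash = NA_character_, seed = NA_integer_) {
  if (!is.null(whitelist)) annotations <- apply_whitelist(annotations, whitelist)

  stages <- list()
  reasons <- list()
  add_stage <- function(name, n_in, n_out)
    stages[[length(stages) + 1L]] <<- data.frame(stage = name, n_in = n_in,
                                                 n_out = n_out)
  add_reason <- function(keys, reason) {
    if (length(keys))
      reasons[[length(reasons) + 1L]] <<- data.frame(
        key = keys, reason = reason, stringsAsFactors = FALSE)
  }

  n0 <- nrow(table$variants)
  add_stage("ingest", n0, n0)

  table <- merge_adjacent_substitutions(table)
  add_stage("merge_mnv", n0, nrow(table$variants))
  all_keys <- table$variants$key

  table <- support_filter(table, scan)
  # support filter downgrades calls, not variants: counts stay equal and the
  # number of downgraded calls is recorded in the stage name column
  add_stage(sprintf("support_filter[%d calls downgraded]",
                    attr(table, "n_downgraded")),
            nrow(table$variants), nrow(table$variants))

  candidates <- shared_candidates(table, ped, scan)
  add_stage("shared_scan", nrow(table$variants), length(candidates))
  add_reason(setdiff(all_keys, candidates), "NOT_SHARED")

  cascade <- run_filter_cascade(candidates, annotations, filters)
  for (i in seq_len(nrow(cascade$stages)))
    add_stage(cascade$stages$stage[i], cascade$stages$n_in[i],
              cascade$stages$n_out[i])
  if (nrow(cascade$removed))
    add_reason(cascade$removed$key, cascade$removed$reason)

  if (!is.null(validation))
    table <- apply_validation(table, validation, ped = ped)

  verdicts <- lapply(cascade$kept, cosegregation_test, ped = ped,
                     table = table, model = model)
  names(verdicts) <- cascade$kept
  statuses <- vapply(verdicts, `[[`, "", "status")
  pass_keys <- cascade$kept[statuses == "PASS_COSEGREGATING"]
  add_stage("cosegregation", length(cascade$kept), length(pass_keys))
  add_reason(cascade$kept, unname(statuses))

  stages <- do.call(rbind, stages)
  # trace reconciliation invariants
  stopifnot(all(stages$n_out[-nrow(stages)] == stages$n_in[-1]))
  reasons <- do.call(rbind, reasons)
  report <- data.frame(key = all_keys,
                       reason = reasons$reason[match(all_keys, reasons$key)],
                       stringsAsFactors = FALSE)
  stopifnot(!anyNA(report$reason),
            sum(report$reason == "PASS_COSEGREGATING") == length(pass_keys))

  trace <- structure(list(stages = stages, report = report,
                          meta = list(config_hash = config_hash, seed = seed,
                                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
                     class = "filter_trace")
  structure(list(trace = trace, verdicts = verdicts, pass_keys = pass_keys,
                 table = table, annotations = annotations),
            class = "pipeline_result")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("<filter_trace>\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$trace)
  cat(sprintf("PASS_COSEGREGATING: %d variant(s)%s\n", length(x$pass_keys),
              if (length(x$pass_keys))
                paste0(" [", paste(x$pass_keys, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Causal-variant recovery experiment
#'
#' Runs simulate -> pipeline `n_reps` times with per-replicate seeds derived
#' deterministically from the config's master seed (`seed + rep`, kept below
#' 2^31), and summarises how often the implanted causal variant survives to
#' the PASS set and how large that set is.
#'
#' @param cfg a [sim_config()]; its `seed` is the master seed.
#' @param n_reps number of replicates (>= 1).
#' @param scan,filters,model pipeline parameter objects.
#' @return list: `recovery_rate`, `pass_size_quantiles`, `per_rep`
#'   (data.frame rep, seed, recovered, pass_size).
#' @export
recovery_experiment <- function(cfg, n_reps,
                                scan = scan_config(exception_ids = "IV:9"),
                                filters = filter_config(),
                                model = inheritance_model(exception_ids = "IV:9")) {
  if (n_reps < 1) stop_user("recovery_experiment: n_reps must be >= 1")
  per_rep <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rcfg <- cfg
    rcfg$seed <- (cfg$seed + r) %% 2147483647L
    sim <- simulate_dataset(rcfg)
    res <- run_pipeline_core(sim$table, sim$ped, sim$annotations,
                             validation = sim$validation,
                             whitelist = sim$whitelist,
                             scan = scan, filters = filters, model = model)
    per_rep[[r]] <- data.frame(rep = r, seed = rcfg$seed,
                               recovered = sim$causal_key %in% res$pass_keys,
                               pass_size = length(res$pass_keys))
  }
  per_rep <- do.call(rbind, per_rep)
  list(recovery_rate = mean(per_rep$recovered),
       pass_size_quantiles = stats::quantile(per_rep$pass_size,
                                             c(0, 0.25, 0.5, 0.75, 1)),
       per_rep = per_rep)
}
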