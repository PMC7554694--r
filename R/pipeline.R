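#' Pipeline configuration
#'
#' Assembles and validates the parameter record for the command-level
#' pipeline: input paths, group labels, tier-rule overrides, choice of
#' statistical test, enrichment options, output directory and seed. All
#' thresholds default to the tiered-caller defaults, so the standard
#' procedure is the zero-config behavior. A YAML file with these keys can be
#' loaded via `pipeline_config(yaml = path)`; explicit arguments override
#' file values.
#'
#' @param counts,design,gene_sets,directions,truth input file paths (some
#'   optional depending on the command).
#' @param test_group,ref_group group labels (distinct).
#' @param test statistical test: `"welch_log_nsaf"` or `"fisher_pooled"`.
#' @param tiers optional tier-rule override (data.frame or list of rows).
#' @param include_unique_in_z include unique proteins as observed signs.
#' @param detection_threshold detection floor on mean SpC.
#' @param out output directory.
#' @param seed integer seed for simulation.
#' @param sim named list of [sim_config()] overrides for `cmd_simulate`.
#' @param yaml optional path to a YAML file supplying any of these keys.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, design = NULL, gene_sets = NULL,
                            directions = NULL, truth = NULL,
                            test_group = "cancer", ref_group = "fertile",
                            test = "welch_log_nsaf", tiers = NULL,
                            include_unique_in_z = TRUE,
                            detection_threshold = 1.7,
                            out = ".", seed = 42L, sim = list(),
                            yaml = NULL) {
  cfg <- list(counts = counts, design = design, gene_sets = gene_sets,
              directions = directions, truth = truth,
              test_group = test_group, ref_group = ref_group,
              test = test, tiers = tiers,
              include_unique_in_z = include_unique_in_z,
              detection_threshold = detection_threshold,
              out = out, seed = as.integer(seed), sim = sim)
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) config_error(sprintf("config file not found: %s", yaml))
    fromfile <- yaml::read_yaml(yaml)
    bad <- setdiff(names(fromfile), names(cfg))
    if (length(bad))
      config_error(paste("unknown config key(s):", paste(bad, collapse = ", ")))
    # file values fill in only where the caller left the default
    defaults <- formals(pipeline_config)
    for (key in names(fromfile)) {
      supplied <- !identical(cfg[[key]], eval(defaults[[key]]))
      if (!supplied) cfg[[key]] <- fromfile[[key]]
    }
    cfg$seed <- as.integer(cfg$seed)
  }
  if (identical(cfg$test_group, cfg$ref_group))
    config_error("test_group and ref_group must differ")
  if (!cfg$test %in% c("welch_log_nsaf", "fisher_pooled"))
    config_error("test must be welch_log_nsaf or fisher_pooled")
  if (!is.null(cfg$tiers)) {
    tiers <- cfg$tiers
    if (!is.data.frame(tiers)) tiers <- do.call(rbind, lapply(tiers, as.data.frame))
    cfg$tiers <- tier_rules(tiers)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

ensure_outdir <- function(cfg) {
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  cfg$out
}

#' Simulate a dataset and write count, design and truth TSVs
#'
#' @param cfg a [pipeline_config()]; `cfg$sim` holds [sim_config()]
#'   overrides, `cfg$seed` the seed.
#' @return invisibly, named vector of the written paths.
#' @export
cmd_simulate <- function(cfg) {
  out <- ensure_outdir(cfg)
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  sim_args$test_group <- cfg$test_group
  sim_args$ref_group <- cfg$ref_group
  sim <- simulate_dataset(do.call(sim_config, sim_args))
  paths <- c(counts = file.path(out, "counts.tsv"),
             design = file.path(out, "design.tsv"),
             truth = file.path(out, "truth.tsv"))
  write_count_matrix(sim$matrix, paths["counts"], paths["design"])
  write_tsv(sim$truth, paths["truth"], digits = 10)
  message(sprintf("simulated %d proteins x %d runs -> %s",
                  nrow(sim$matrix$counts), ncol(sim$matrix$counts), out))
  invisible(paths)
}

#' Run the tiered differential caller and write its outputs
#'
#' Reads the count matrix and design, runs [run_dep_analysis()], and writes
#' `dep_records.tsv` plus `partition_summary.tsv` under the output directory.
#'
#' @param cfg a [pipeline_config()] with `counts` and `design` set.
#' @return invisibly, the `dep_analysis` object.
#' @export
cmd_call_deps <- function(cfg) {
  if (is.null(cfg$counts) || is.null(cfg$design))
    config_error("call-deps needs counts and design paths")
  out <- ensure_outdir(cfg)
  mat <- read_count_matrix(cfg$counts, cfg$design)
  rules <- if (is.null(cfg$tiers)) tier_rules() else cfg$tiers
  ana <- run_dep_analysis(mat, cfg$test_group, cfg$ref_group, rules = rules,
                          test = cfg$test,
                          detection_threshold = cfg$detection_threshold)
  write_results(ana$records, file.path(out, "dep_records.tsv"))
  write_results(as.data.frame(unclass(ana$summary)),
                file.path(out, "partition_summary.tsv"))
  tier_tab <- table(ana$records$tier)
  message("tier counts: ",
          paste(sprintf("%s=%d", names(tier_tab), tier_tab), collapse = ", "))
  invisible(ana)
}

#' Run enrichment and activation scoring and write its outputs
#'
#' Reads the DEP records written by [cmd_call_deps()] and the gene sets
#' (plus optional signed directions), runs [enrich_all()], and writes
#' `enrichment.tsv`.
#'
#' @param cfg a [pipeline_config()] with `gene_sets` set; DEP records are
#'   read from the output directory.
#' @return invisibly, the enrichment table.
#' @export
cmd_enrich <- function(cfg) {
  if (is.null(cfg$gene_sets)) config_error("enrich needs a gene_sets path")
  out <- ensure_outdir(cfg)
  rec_path <- file.path(out, "dep_records.tsv")
  if (!file.exists(rec_path))
    io_error("dep_records.tsv not found in output directory; run call-deps first")
  records <- read_results(rec_path)
  sets <- read_gmt(cfg$gene_sets)
  if (!is.null(cfg$directions)) sets <- read_directions(cfg$directions, sets)
  enr <- enrich_all(records, sets, include_unique = cfg$include_unique_in_z)
  write_results(enr, file.path(out, "enrichment.tsv"))
  invisible(enr)
}

#' Run the full pipeline: simulate (optional), call DEPs, enrich, evaluate
#'
#' When `cfg$counts` is `NULL` a dataset is simulated first. After the
#' differential and enrichment stages, a recovery report against ground
#' truth is written whenever a truth table is available.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, list with `analysis`, `enrichment` (or `NULL`) and
#'   `recovery` (or `NULL`).
#' @export
cmd_run_all <- function(cfg) {
  out <- ensure_outdir(cfg)
  if (is.null(cfg$counts)) {
    paths <- cmd_simulate(cfg)
    cfg$counts <- unname(paths["counts"])
    cfg$design <- unname(paths["design"])
    if (is.null(cfg$truth)) cfg$truth <- unname(paths["truth"])
  }
  ana <- cmd_call_deps(cfg)
  enr <- NULL
  if (!is.null(cfg$gene_sets)) enr <- cmd_enrich(cfg)
  recovery <- NULL
  if (!is.null(cfg$truth) && file.exists(cfg$truth)) {
    truth <- read_results(cfg$truth)
    recovery <- evaluate_recovery(ana$records, truth,
                                  cfg$detection_threshold)
    rep_tab <- data.frame(metric = c("sensitivity", "fdr", "unique_sensitivity"),
                          value = c(recovery$sensitivity, recovery$fdr,
                                    recovery$unique_sensitivity),
                          stringsAsFactors = FALSE)
    write_results(rep_tab, file.path(out, "recovery.tsv"))
  } else if (!is.null(cfg$truth)) {
    warning("truth file not found; recovery stage skipped", call. = FALSE)
  }
  invisible(list(analysis = ana, enrichment = enr, recovery = recovery))
}

# Exit-code contract for the command-line wrapper:
# 0 success, 2 usage/config, 3 data format, 4 internal contract violation.
exit_code_for <- function(cond) {
  if (inherits(cond, "nsafde_config_error")) 2L
  else if (inherits(cond, "nsafde_format_error") ||
           inherits(cond, "nsafde_design_error") ||
           inherits(cond, "nsafde_io_error")) 3L
  else 4L
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `call-deps`, `enrich` or `run-all` from a parsed
#' argument vector (as the installed `nsafde` Rscript wrapper does). Flags:
#' `--counts`, `--design`, `--gene-sets`, `--directions`, `--truth`,
#' `--test-group`, `--ref-group`, `--test`, `--out`, `--seed`, `--config`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit code (0 success, 2 config error, 3 data error,
#'   4 internal error).
#' @export
nsafde_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: nsafde <simulate|call-deps|enrich|run-all> [--counts F] [--design F]",
    "  [--gene-sets F] [--directions F] [--truth F] [--test-group L]",
    "  [--ref-group L] [--test welch_log_nsaf|fisher_pooled] [--out DIR]",
    "  [--seed N] [--config YAML]", sep = "\n")
  if (length(args) < 1) { message(usage); return(2L) }
  cmd <- args[1L]
  flags <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!startsWith(args[i], "--") || i + 1L > length(args)) {
      message("malformed flag: ", args[i]); return(2L)
    }
    flags[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  tryCatch({
    cfg_args <- list()
    for (nm in c("counts", "design", "truth", "directions", "out"))
      if (!is.null(flags[[nm]])) cfg_args[[nm]] <- flags[[nm]]
    if (!is.null(flags$gene_sets)) cfg_args$gene_sets <- flags$gene_sets
    if (!is.null(flags$test_group)) cfg_args$test_group <- flags$test_group
    if (!is.null(flags$ref_group)) cfg_args$ref_group <- flags$ref_group
    if (!is.null(flags$test)) cfg_args$test <- flags$test
    if (!is.null(flags$seed)) cfg_args$seed <- as.integer(flags$seed)
    if (!is.null(flags$config)) cfg_args$yaml <- flags$config
    cfg <- do.call(pipeline_config, cfg_args)
    switch(cmd,
           "simulate" = cmd_simulate(cfg),
           "call-deps" = cmd_call_deps(cfg),
           "enrich" = cmd_enrich(cfg),
           "run-all" = cmd_run_all(cfg),
           { message("unknown command: ", cmd); return(2L) })
    0L
  }, nsafde_error = function(e) {
    message("error: ", conditionMessage(e))
    exit_code_for(e)
  })
}
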