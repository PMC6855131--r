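# Configuration-driven orchestration of the full experiment: unimodal
# accuracies per map and family, redundancy matrices, the three multimodal
# strategies and a summary table, on a synthetic or user-supplied cohort.
# One global seed is expanded into per-component seeds through the
# deterministic derive_seed() scheme, and every output artifact carries the
# seed and a hash of the configuration.

#' Build and validate an experiment configuration
#'
#' @param cohort Either `list(type = "synthetic", ...)` with [cohort_spec()]
#'   arguments, or `list(type = "files", dir = <cohort directory>)`.
#' @param families Classifier families to run.
#' @param strategies Multimodal strategies among `"probability"`,
#'   `"twostep"`, `"cnn"` (empty vector runs unimodal only).
#' @param n_folds,stratified Fold settings.
#' @param n_boot Bootstrap resamples for accuracy intervals.
#' @param cnn [cnn_spec()] argument overrides (list).
#' @param classifier_args Per-family hyperparameter overrides, e.g.
#'   `list(random_forest = list(n_trees = 200))`.
#' @param output_dir Where [run_experiment()] writes the bundle.
#' @param seed Global seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cohort = list(type = "synthetic"),
                              families = c("ridge", "lasso", "random_forest",
                                           "gradient_boosting"),
                              strategies = c("probability", "twostep", "cnn"),
                              n_folds = 10, stratified = TRUE, n_boot = 1000,
                              cnn = list(), classifier_args = list(),
                              output_dir = "mmfuse_results", seed = 1L) {
  families <- match.arg(families, c("ridge", "lasso", "random_forest",
                                    "gradient_boosting"), several.ok = TRUE)
  if (length(strategies))
    strategies <- match.arg(strategies, c("probability", "twostep", "cnn"),
                            several.ok = TRUE)
  if (!is.list(cohort) || is.null(cohort$type) ||
      !cohort$type %in% c("synthetic", "files"))
    stop_mmfuse("cohort$type must be 'synthetic' or 'files'", "mmfuse_config_error")
  if (cohort$type == "files") {
    if (is.null(cohort$dir) || !dir.exists(cohort$dir))
      stop_mmfuse(paste0("cohort directory not found: ", cohort$dir %||% "<missing>"),
                  "mmfuse_config_error")
    if (!file.exists(file.path(cohort$dir, "subjects.csv")))
      stop_mmfuse("cohort directory lacks subjects.csv", "mmfuse_config_error")
  }
  structure(list(cohort = cohort, families = families, strategies = strategies,
                 n_folds = n_folds, stratified = stratified, n_boot = n_boot,
                 cnn = cnn, classifier_args = classifier_args,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#' @param path YAML file with [experiment_config()] fields.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path))
    stop_mmfuse(paste0("config file not found: ", path), "mmfuse_io_error")
  do.call(experiment_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  # identifies the scientific configuration; where results are written is
  # not part of it
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  sprintf("%08x", derive_seed(0L, yaml::as.yaml(cfg)))
}

load_config_cohort <- function(config) {
  if (config$cohort$type == "synthetic") {
    args <- config$cohort[setdiff(names(config$cohort), "type")]
    if (is.null(args$seed)) args$seed <- derive_seed(config$seed, "cohort")
    generate_cohort(do.call(cohort_spec, args))
  } else {
    read_cohort(config$cohort$dir)
  }
}

stage <- function(bundle, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) e)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (inherits(res, "error")) {
    message(sprintf("[mmfuse] stage %-28s FAILED after %.1fs: %s",
                    name, elapsed, conditionMessage(res)))
    bundle$failures <- rbind(bundle$failures,
                             data.frame(stage = name,
                                        error = conditionMessage(res),
                                        stringsAsFactors = FALSE))
  } else {
    message(sprintf("[mmfuse] stage %-28s ok (%.1fs)", name, elapsed))
    bundle$results[[name]] <- res
  }
  bundle
}

#' Run the full multimodal experiment
#'
#' Produces unimodal accuracy tables, per-family redundancy matrices,
#' fusion and two-step accuracy tables with selection-overlap statistics,
#' the CNN accuracies, and a best-per-strategy summary. Each enabled
#' (strategy x family) pair either yields results or an explicit row in
#' `failures.csv`; one failing stage never aborts the others. Deterministic
#' outputs are bit-identical across re-runs with the same config.
#'
#' @param config An [experiment_config()] (or path to its YAML file).
#' @return The result bundle (list), invisibly; side effect: CSV/JSON files
#'   under `config$output_dir`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  cohort <- load_config_cohort(config)
  foldplan <- make_folds(cohort$labels, config$n_folds,
                         seed = derive_seed(config$seed, "folds"),
                         stratified = config$stratified)
  bundle <- list(results = list(), failures = data.frame(),
                 seed = config$seed, config_hash = hash)

  make_spec <- function(family) {
    args <- c(list(family = family, seed = derive_seed(config$seed, family)),
              config$classifier_args[[family]] %||% list())
    do.call(classifier_spec, args)
  }

  for (family in config$families) {
    spec <- make_spec(family)
    for (mod in names(cohort$data))
      bundle <- stage(bundle, paste("unimodal", family, mod, sep = "."),
                      cross_validate_unimodal(cohort, mod, spec, foldplan))
    if ("probability" %in% config$strategies)
      bundle <- stage(bundle, paste0("fusion_probability.", family),
                      cross_validate_fusion(cohort, spec, foldplan))
    if ("twostep" %in% config$strategies)
      bundle <- stage(bundle, paste0("twostep.", family),
                      cross_validate_twostep(cohort, spec, foldplan))
  }
  if ("cnn" %in% config$strategies) {
    cnn <- do.call(cnn_spec, c(config$cnn,
                               list(seed = derive_seed(config$seed, "cnn"))))
    bundle <- stage(bundle, "cnn", cross_validate_cnn(cohort, cnn, foldplan))
  }

  # ---- assemble artifacts -------------------------------------------------
  res <- bundle$results
  is_table <- vapply(res, inherits, logical(1), "prediction_table")
  tables <- res[is_table]
  twostep_names <- grep("^twostep\\.", names(res), value = TRUE)
  tables <- c(tables, lapply(res[twostep_names], `[[`, "table"))
  all_pred <- if (length(tables)) do.call(bind_predictions, tables)

  provenance <- function(df) {
    df$seed <- config$seed
    df$config_hash <- hash
    df
  }
  if (!is.null(all_pred)) {
    write_prediction_table(all_pred, file.path(outdir, "predictions.csv"))
    acc <- provenance(accuracy_summary(all_pred, config$n_boot,
                                       seed = derive_seed(config$seed, "boot")))
    uni <- acc[acc$source %in% names(cohort$data), ]
    fus <- acc[!acc$source %in% names(cohort$data), ]
    utils::write.csv(uni, file.path(outdir, "unimodal_accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(fus, file.path(outdir, "fusion_accuracy.csv"),
                     row.names = FALSE)
    for (family in unique(all_pred$algorithm)) {
      sub <- all_pred[all_pred$algorithm == family &
                        all_pred$source %in% names(cohort$data), ]
      if (length(unique(sub$source)) >= 2) {
        rmat <- provenance(redundancy_matrix(sub, family))
        utils::write.csv(rmat, file.path(outdir, paste0("redundancy_", family, ".csv")),
                         row.names = FALSE)
      }
    }
    best <- do.call(rbind, lapply(split(acc, acc$source %in% names(cohort$data)),
                                  function(g) g[which.max(g$accuracy), ]))
    summary_tab <- acc[order(-acc$accuracy), ]
    utils::write.csv(summary_tab, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    bundle$accuracy <- acc
  }
  for (nm in twostep_names) {
    family <- sub("^twostep\\.", "", nm)
    ts <- res[[nm]]
    if (!is.null(ts$overlap)) {
      utils::write.csv(provenance(ts$overlap),
                       file.path(outdir, paste0("overlap_", family, ".csv")),
                       row.names = FALSE)
      utils::write.csv(provenance(summarize_overlap(ts$overlap)),
                       file.path(outdir, paste0("overlap_mean_", family, ".csv")),
                       row.names = FALSE)
    }
    write_selections(ts$selections,
                     file.path(outdir, paste0("selections_", family, ".json")))
  }
  if (nrow(bundle$failures))
    utils::write.csv(bundle$failures, file.path(outdir, "failures.csv"),
                     row.names = FALSE)
  cfg <- unclass(config)
  cfg$config_hash <- hash
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(bundle)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `unimodal`,
#' `redundancy`, `fuse`, `twostep`, `cnn` (run subsets of the pipeline),
#' `run-all` (everything), `report` (print the summary table of a finished
#' run). Typical use:
#' `Rscript -e 'mmfuse::cli_main()' run-all --config cfg.yaml --out results/`
#'
#' @param argv Command-line arguments (default: `commandArgs(TRUE)`).
#' @return Exit status 0, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0)
    stop_mmfuse("usage: <simulate|unimodal|redundancy|fuse|twostep|cnn|run-all|report> [--config F] [--out D] [--seed N]",
                "mmfuse_config_error")
  cmd <- argv[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL)))
  opts <- optparse::parse_args(parser, args = argv[-1])

  if (cmd == "report") {
    path <- file.path(opts$out %||% ".", "summary.csv")
    if (!file.exists(path)) stop_mmfuse(paste0("no summary at ", path), "mmfuse_io_error")
    print(utils::read.csv(path))
    return(invisible(0L))
  }
  config <- if (!is.null(opts$config)) read_experiment_config(opts$config)
            else experiment_config()
  if (!is.null(opts$seed)) config$seed <- opts$seed
  if (!is.null(opts$out)) config$output_dir <- opts$out

  if (cmd == "simulate") {
    cohort <- load_config_cohort(config)
    write_cohort(cohort, config$output_dir)
    message("[mmfuse] cohort written to ", config$output_dir)
    return(invisible(0L))
  }
  config$strategies <- switch(cmd,
    "run-all" = config$strategies,
    "unimodal" = ,
    "redundancy" = character(0),
    "fuse" = "probability",
    "twostep" = "twostep",
    "cnn" = "cnn",
    stop_mmfuse(paste0("unknown subcommand: ", cmd), "mmfuse_config_error"))
  if (cmd == "cnn") config$families <- character(0)
  run_experiment(config)
  invisible(0L)
}
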