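config_schema <- function() {
  list(
    paths = list(data_dir = "data", output_dir = "results"),
    tasks = "sepsis",
    modalities = "hsi",
    sites = "palm",
    tiers = "10h",
    seed = 1L,
    cohort = formals(cohort_config),
    training = formals(training_hyperparameters),
    evaluation = list(outer = 5L, inner = 5L, n_seeds = 3L, B = 1000L,
                      side = 16L, width_scale = 0.25,
                      outer_folds_to_run = NULL)
  )
}

check_unknown_keys <- function(given, allowed, path = "") {
  bad <- setdiff(names(given), names(allowed))
  if (length(bad) > 0L)
    stop("unknown configuration key: ", path, bad[1L])
  for (nm in names(given)) {
    if (is.list(allowed[[nm]]) && is.list(given[[nm]]) &&
        !is.null(names(allowed[[nm]])))
      check_unknown_keys(given[[nm]], allowed[[nm]],
                         paste0(path, nm, "."))
  }
  invisible(TRUE)
}

#' Validate and complete a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (naming the
#' offending key path), checks enumerated values, and fills documented
#' defaults for everything not given.
#'
#' @param file Path to a YAML file, or a list.
#' @return Object of class `run_config`.
#' @export
validate_config <- function(file) {
  raw <- if (is.character(file)) yaml::read_yaml(file) else file
  if (is.null(raw)) raw <- list()
  schema <- config_schema()
  check_unknown_keys(raw, schema)
  cfg <- utils::modifyList(
    list(paths = schema$paths, tasks = schema$tasks,
         modalities = schema$modalities, sites = schema$sites,
         tiers = schema$tiers, seed = schema$seed,
         cohort = list(), training = list(), evaluation = schema$evaluation),
    raw)
  bad_tier <- setdiff(cfg$tiers, c("1h", "10h"))
  if (length(bad_tier) > 0L)
    stop("invalid tier \"", bad_tier[1L], "\"; allowed values: {1h, 10h}")
  bad_task <- setdiff(cfg$tasks, c("sepsis", "mortality"))
  if (length(bad_task) > 0L)
    stop("invalid task \"", bad_task[1L],
         "\"; allowed values: {sepsis, mortality}")
  bad_mod <- setdiff(cfg$modalities,
                     c("hsi", "tpi", "rgb", "hsi_stacked", "clinical",
                       "hsi+clinical"))
  if (length(bad_mod) > 0L)
    stop("invalid modality \"", bad_mod[1L], "\"")
  bad_site <- setdiff(cfg$sites, c("palm", "finger"))
  if (length(bad_site) > 0L)
    stop("invalid site \"", bad_site[1L], "\"; allowed: {palm, finger}")
  cfg$cohort$seed <- cfg$cohort$seed %||% cfg$seed
  cfg$cohort_config <- do.call(cohort_config, cfg$cohort)
  cfg$training$seed <- cfg$training$seed %||% cfg$seed
  cfg$hp <- do.call(training_hyperparameters, cfg$training)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from a configuration
#'
#' Generates the synthetic cohort, then runs one experiment per
#' requested (task, modality, site, tier) combination plus the tissue
#' index group statistics, writing machine-readable reports (JSON and
#' CSV) under the configured output directory.
#'
#' @param config A `run_config` (see [validate_config()]).
#' @param dry_run Print the execution plan and return it without
#'   running or writing anything.
#' @return List of evaluation reports (invisibly unless `dry_run`).
#' @export
run_all <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  plan <- expand.grid(task = config$tasks, modality = config$modalities,
                      site = config$sites, tier = config$tiers,
                      stringsAsFactors = FALSE)
  if (dry_run) {
    message("cohort: n = ", config$cohort_config$n_patients,
            ", seed = ", config$seed)
    for (i in seq_len(nrow(plan)))
      message("experiment: ", paste(unlist(plan[i, ]), collapse = " / "))
    return(plan)
  }
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config$cohort_config)
  ev <- config$evaluation
  reports <- list()
  for (i in seq_len(nrow(plan))) {
    rep <- run_experiment(cohort, task = plan$task[i],
                          modality = plan$modality[i], site = plan$site[i],
                          tier = plan$tier[i], side = ev$side,
                          width_scale = ev$width_scale, hp = config$hp,
                          outer = ev$outer, inner = ev$inner,
                          n_seeds = ev$n_seeds,
                          outer_folds_to_run = ev$outer_folds_to_run,
                          B = ev$B, seed = config$seed)
    tag <- paste(plan$task[i], gsub("[+]", "_", plan$modality[i]),
                 plan$site[i], plan$tier[i], sep = "_")
    jsonlite::write_json(
      rep[c("task", "modality", "site", "tier", "auroc", "seed")],
      file.path(out_dir, paste0(tag, ".json")), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(rep$roc, file.path(out_dir, paste0(tag, "_roc.csv")),
                     row.names = FALSE)
    reports[[tag]] <- rep
  }
  ## tissue-index group statistics for the sepsis task
  sel <- select_task_cohort(cohort, "sepsis")
  summ <- patient_index_summaries(cohort)
  stats <- group_statistics(summ[sel$index, ], sel$labels)
  utils::write.csv(stats, file.path(out_dir, "group_statistics.csv"),
                   row.names = FALSE)
  invisible(reports)
}
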