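# End-to-end orchestration: simulate -> select -> fit -> compare ->
# export -> monitor, with a YAML config file and plain-text/JSON reports.
#
# The four pipeline commands are ordinary R functions; inst/cli/spoilwarn.R
# wraps them in a thin Rscript front end.  All randomness flows from the
# seeds recorded in the config, so every command is reproducible.

#' Assemble a pipeline configuration
#'
#' @param sim A [warehouse_sim_config()].
#' @param cv A [cv_config()].
#' @param selectors Named list of the four selector configs
#'   (`ga`, `sa`, `aco`, `cars`).
#' @param split_ratio Calibration fraction (default 2/3).
#' @param split_seed Seed for the calibration/prediction split.
#' @param out_dir Output directory for pipeline artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = warehouse_sim_config(),
                            cv = cv_config(),
                            selectors = list(ga = ga_config(),
                                             sa = sa_config(),
                                             aco = aco_config(),
                                             cars = cars_config()),
                            split_ratio = 2 / 3,
                            split_seed = 1L,
                            out_dir = ".") {
  stopifnot(inherits(sim, "warehouse_sim_config"), inherits(cv, "cv_config"),
            all(c("ga", "sa", "aco", "cars") %in% names(selectors)))
  structure(list(sim = sim, cv = cv, selectors = selectors,
                 split_ratio = split_ratio,
                 split_seed = as.integer(split_seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any omitted field falls back to the package default; recognised
#' top-level sections are `sim`, `cv`, `ga`, `sa`, `aco`, `cars`,
#' `split_ratio`, `split_seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  pipeline_config(
    sim = build(warehouse_sim_config, raw$sim),
    cv = build(cv_config, raw$cv),
    selectors = list(ga = build(ga_config, raw$ga),
                     sa = build(sa_config, raw$sa),
                     aco = build(aco_config, raw$aco),
                     cars = build(cars_config, raw$cars)),
    split_ratio = raw$split_ratio %||% (2 / 3),
    split_seed = raw$split_seed %||% 1L,
    out_dir = raw$out_dir %||% "."
  )
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Pipeline command: simulate a warehouse dataset
#'
#' Writes `dataset.csv` (sample-by-feature table) and
#' `ground_truth.json` to the configured output directory.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the simulated `dataset`, `ground_truth`
#'   and output `paths`.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config$sim)
  paths <- list(
    dataset = file.path(config$out_dir, "dataset.csv"),
    ground_truth = file.path(config$out_dir, "ground_truth.json")
  )
  write_dataset_csv(sim$dataset, paths$dataset)
  write_ground_truth_json(sim$ground_truth, paths$ground_truth)
  pipeline_log("simulated ", nrow(sim$dataset$features), " samples x ",
               ncol(sim$dataset$features), " features (seed ",
               config$sim$seed, ") -> ", paths$dataset)
  invisible(list(dataset = sim$dataset, ground_truth = sim$ground_truth,
                 paths = paths))
}

#' Pipeline command: train and compare the four selector-PLS models
#'
#' Splits the dataset (stratified by day), runs GA/SA/ACO/CARS on the
#' calibration rows, refits a sparse PLS warning model per selection, and
#' evaluates Rc/RMSEC/Rp/RMSEP on the split.  Writes
#' `comparison_table.csv` (one row per algorithm), a per-algorithm model
#' JSON, and `warning_model.json` for the best model (highest Rp, then
#' lowest RMSEP, then fewest variables).
#'
#' @param config A [pipeline_config()].
#' @param dataset A [sensor_dataset()], or a path to one written by
#'   [write_dataset_csv()].
#' @return Invisibly, a list with `comparison` (data.frame), `models`,
#'   `best` (algorithm name), and `paths`.
#' @export
cmd_train <- function(config, dataset) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(dataset)) dataset <- read_dataset_csv(dataset)
  stopifnot(inherits(dataset, "sensor_dataset"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- split_calibration_prediction(dataset, config$split_ratio,
                                          config$split_seed)
  cal <- dataset$split == "calibration"
  x_cal <- dataset$features[cal, , drop = FALSE]
  y_cal <- dataset$label[cal]
  pipeline_log("training on ", sum(cal), " calibration / ", sum(!cal),
               " prediction samples")
  selections <- run_all_selectors(x_cal, y_cal, config$selectors,
                                  config$cv)
  rows <- list()
  models <- list()
  for (alg in names(selections)) {
    sel <- selections[[alg]]
    if (inherits(sel, "error")) {
      pipeline_log(alg, " failed: ", conditionMessage(sel))
      rows[[alg]] <- data.frame(model = paste0(alg, "-PLS"),
                                n_variables = NA_integer_,
                                Rc = NA_real_, RMSEC = NA_real_,
                                Rp = NA_real_, RMSEP = NA_real_,
                                error = conditionMessage(sel))
      next
    }
    wm <- build_warning_model(dataset, sel, config$cv)
    ev <- evaluate_model(wm, dataset)
    models[[alg]] <- wm
    rows[[alg]] <- data.frame(model = paste0(alg, "-PLS"),
                              n_variables = length(sel$selected_indices),
                              Rc = ev$r_calibration,
                              RMSEC = ev$rmse_calibration,
                              Rp = ev$r_prediction,
                              RMSEP = ev$rmse_prediction,
                              error = NA_character_)
    export_model(wm, file.path(config$out_dir,
                               paste0("model_", tolower(alg), ".json")))
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  utils::write.csv(comparison,
                   file.path(config$out_dir, "comparison_table.csv"),
                   row.names = FALSE, na = "")
  ok <- comparison[!is.na(comparison$Rp), , drop = FALSE]
  if (nrow(ok) == 0L) stop("every selector failed; no model to export")
  ok <- ok[order(-ok$Rp, ok$RMSEP, ok$n_variables), , drop = FALSE]
  best <- sub("-PLS$", "", ok$model[1L])
  export_model(models[[best]],
               file.path(config$out_dir, "warning_model.json"))
  pipeline_log("best model: ", ok$model[1L], " (Rp = ",
               sprintf("%.3f", ok$Rp[1L]), ", RMSEP = ",
               sprintf("%.3f", ok$RMSEP[1L]), ")")
  invisible(list(comparison = comparison, models = models, best = best,
                 selections = selections,
                 paths = list(
                   comparison = file.path(config$out_dir,
                                          "comparison_table.csv"),
                   warning_model = file.path(config$out_dir,
                                             "warning_model.json"))))
}

#' Pipeline command: score acquisitions with a warning model
#'
#' Loads a model, flattens each acquisition file, scores and grades it,
#' and writes `monitoring_report.json` plus a plain-text table.
#'
#' @param model_path Path to a model JSON ([export_model()]).
#' @param acquisition_paths Character vector of acquisition CSV paths.
#' @param out_dir Output directory (default: directory of `model_path`).
#' @return Invisibly, a list with `report` (data.frame: one row per
#'   acquisition with warehouse, day, score, grade, in_range and channel
#'   means) and `any_severe` (logical; a shell wrapper can map it onto a
#'   distinct exit code).
#' @export
cmd_monitor <- function(model_path, acquisition_paths,
                        out_dir = dirname(model_path)) {
  model <- import_model(model_path)
  entries <- lapply(acquisition_paths, function(pth) {
    rec <- read_acquisition_csv(pth)
    x <- flatten_record(rec)
    y <- score_sample(model, x)
    g <- grade_score(model, y)
    means <- colMeans(rec$values)
    cbind(data.frame(file = basename(pth),
                     warehouse = rec$warehouse_id, day = rec$day,
                     score = y, grade = g$grade, in_range = g$in_range,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(round(means, 4))))
  })
  report <- do.call(rbind, entries)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report,
                       file.path(out_dir, "monitoring_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(
    report[c("file", "warehouse", "day", "score", "grade", "in_range")],
    row.names = FALSE))
  writeLines(txt, file.path(out_dir, "monitoring_report.txt"))
  any_severe <- any(report$grade == "severe spoilage")
  if (any_severe) pipeline_log("severe spoilage detected")
  invisible(list(report = report, any_severe = any_severe))
}

#' Pipeline command: summarise a run directory
#'
#' Aggregates the comparison table, the selected variables of the exported
#' warning model with their channel attribution, and the model equation
#' into one plain-text document (`report.txt`).
#'
#' @param run_directory Directory holding the artifacts written by
#'   [cmd_train()].
#' @return Invisibly, the report lines.
#' @export
cmd_report <- function(run_directory) {
  need <- c("comparison_table.csv", "warning_model.json")
  paths <- file.path(run_directory, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("run directory ", run_directory, " is missing: ",
         paste(missing, collapse = ", "))
  }
  comparison <- utils::read.csv(paths[1L])
  model <- import_model(paths[2L])
  attribution <- index_to_channel(model$variable_indices)
  by_ch <- split(attribution$index, attribution$channel)
  lines <- c(
    "== Model comparison (calibration | prediction) ==",
    utils::capture.output(print(comparison, row.names = FALSE)),
    "",
    "== Warning model ==",
    paste0("provenance: ", model$provenance),
    render_model_equation(model),
    "",
    "== Selected variables by channel ==",
    vapply(names(by_ch), function(ch) {
      paste0(ch, ": ", paste(by_ch[[ch]], collapse = ", "))
    }, character(1))
  )
  writeLines(lines, file.path(run_directory, "report.txt"))
  invisible(lines)
}
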