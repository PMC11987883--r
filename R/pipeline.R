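#' Assemble a full pipeline run configuration
#'
#' Bundles every stage's settings — cohort simulation, series preprocessing,
#' windowing, subject-level split, model training and interval evaluation —
#' into one serializable list that round-trips losslessly through YAML.
#'
#' @param sim Named list of [sim_config()] arguments.
#' @param preprocess Named list: `smooth_window` (odd points; 1 disables) and
#'   `normalize` (`"cohort"`, `"per_sow"`, or `"none"`) for min-max scaling
#'   of the activity series to `[0, 100]`. In `"cohort"` mode (default) the
#'   reference range is computed from the training sows only and frozen, so
#'   activity levels stay comparable across sows and no information flows
#'   from held-out subjects; out-of-range values clip to `[0, 100]`.
#'   `"per_sow"` rescales each sow by its own range instead.
#' @param windowing Named list: `w`, `step` for dataset construction;
#'   `train_step`, the stride with which training/validation windows are
#'   subsampled; and `train_max_label_min`, the training label horizon in
#'   minutes (windows further from onset than this carry no ramp signal and
#'   are excluded from fitting; test windows always keep `step` and the
#'   full horizon).
#' @param split Named list: `n_train`, `n_val`, `n_test`, `n_folds`.
#' @param model Named list of [claptnet_config()] arguments (its `seq_len`
#'   and `seed` are filled from `windowing$w` and `seed`).
#' @param analysis Named list: `breaks_hours` for [interval_report()] and
#'   `eval_max_label_min`, the label ceiling (minutes) for the headline
#'   test-set comparison against the predict-the-mean baseline.
#' @param seed Master seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = list(),
                       preprocess = list(smooth_window = 5L, normalize = "cohort"),
                       windowing = list(w = 72L, step = 1L, train_step = 2L,
                                        train_max_label_min = 1440),
                       split = list(n_train = 12L, n_val = 4L, n_test = 4L,
                                    n_folds = 4L),
                       model = list(),
                       analysis = list(breaks_hours = c(30, 24, 18, 12, 6, 0),
                                       eval_max_label_min = 1080),
                       seed = 1L) {
  check_count(seed, "seed", min = 0L)
  defaults <- list(
    preprocess = list(smooth_window = 5L, normalize = "cohort"),
    windowing = list(w = 72L, step = 1L, train_step = 2L,
                     train_max_label_min = 1440),
    split = list(n_train = 12L, n_val = 4L, n_test = 4L, n_folds = 4L),
    analysis = list(breaks_hours = c(30, 24, 18, 12, 6, 0),
                    eval_max_label_min = 1080)
  )
  cfg <- list(
    sim = sim,
    preprocess = modifyList(defaults$preprocess, preprocess),
    windowing = modifyList(defaults$windowing, windowing),
    split = modifyList(defaults$split, split),
    model = model,
    analysis = modifyList(defaults$analysis, analysis),
    seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) fc_abort(sprintf("config file '%s' does not exist.", path))
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

# smoothing then min-max normalization; in cohort mode the reference range
# comes from `ref_sows` (training subjects) and is applied frozen to all
preprocess_cohort <- function(cohort, smooth_window, normalize,
                              ref_sows = NULL) {
  if (smooth_window > 1L) {
    cohort <- cohort |>
      dplyr::group_by(.data$sow_id) |>
      dplyr::mutate(activity = smooth_series(.data$activity, smooth_window)) |>
      dplyr::ungroup()
  }
  if (normalize == "per_sow") {
    cohort <- cohort |>
      dplyr::group_by(.data$sow_id) |>
      dplyr::mutate(activity = normalize_series(.data$activity,
                                                allow_constant = TRUE)) |>
      dplyr::ungroup()
  } else if (normalize == "cohort") {
    ref <- if (is.null(ref_sows)) cohort$activity else
      cohort$activity[cohort$sow_id %in% ref_sows]
    cohort$activity <- normalize_series(cohort$activity,
                                        ref_min = min(ref), ref_max = max(ref),
                                        allow_constant = TRUE)
  } else if (normalize != "none") {
    fc_abort(sprintf("unknown normalization mode '%s'.", normalize))
  }
  cohort
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fc_abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
             class = "farrowcast_stage_error")
  })
}

#' Run the full synthetic farrowing-prediction pipeline
#'
#' Executes simulate -> preprocess -> window -> split -> train -> predict ->
#' report on one seeded configuration. All artifacts (activity CSV, split
#' JSON, model checkpoint, test-set predictions, interval report, metrics
#' JSON and the configuration with its hash) are written under `out_dir`
#' when given; the same objects are returned invisibly.
#'
#' The headline metric compares the trained model's test-set MAE, on
#' windows whose remaining-time label does not exceed
#' `analysis$eval_max_label_min` (default 18 h), against a
#' predict-the-mean baseline that always answers the mean training label
#' of that same range.
#'
#' @param config A [run_config()] or path to its YAML serialization.
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param verbose Print stage progress.
#' @return (Invisibly) a list: `cohort`, `split`, `model`, `predictions`,
#'   `interval_report`, `metrics` (tibble with model vs baseline), and
#'   `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  sim_args <- modifyList(list(seed = config$seed), config$sim)
  scfg <- pipeline_stage("simulate", do.call(sim_config, sim_args))
  cohort_raw <- pipeline_stage("simulate", simulate_cohort(scfg))
  say("simulated %d sows x %d points", scfg$n_sows, scfg$horizon_points)

  split <- pipeline_stage("split", make_split(
    unique(cohort_raw$sow_id),
    n_train = config$split$n_train, n_val = config$split$n_val,
    n_test = config$split$n_test, n_folds = config$split$n_folds,
    seed = config$seed))

  cohort <- pipeline_stage("preprocess", preprocess_cohort(
    cohort_raw, config$preprocess$smooth_window, config$preprocess$normalize,
    ref_sows = split$train))

  w <- config$windowing$w
  step <- config$windowing$step
  train_step <- config$windowing$train_step %||% step
  windows <- pipeline_stage("window", make_windows(cohort, w = w, step = step))
  say("built %d windows (w = %d, step = %d)", nrow(windows), w, step)

  stride <- function(df, k) df[seq(1L, nrow(df), by = k), , drop = FALSE]
  horizon <- config$windowing$train_max_label_min %||% Inf
  fit_pool <- windows[windows$label <= horizon, , drop = FALSE]
  train_windows <- stride(fit_pool[fit_pool$sow_id %in% split$train, ], train_step)
  val_windows <- stride(fit_pool[fit_pool$sow_id %in% split$val, ], train_step)
  test_windows <- windows[windows$sow_id %in% split$test, ]

  model_args <- modifyList(list(seq_len = w, seed = config$seed), config$model)
  mcfg <- pipeline_stage("train", do.call(claptnet_config, model_args))
  model <- pipeline_stage("train", {
    m <- claptnet_init(mcfg)
    claptnet_fit(m, train_windows, val_windows, verbose = verbose)
  })
  say("trained %d epochs", nrow(model$history))

  predictions <- pipeline_stage("predict", predict(model, test_windows))

  report <- pipeline_stage("report",
                           interval_report(predictions,
                                           config$analysis$breaks_hours))
  max_lab <- config$analysis$eval_max_label_min
  eval_sub <- predictions[predictions$label <= max_lab, , drop = FALSE]
  train_eval_labels <- train_windows$label[train_windows$label <= max_lab]
  baseline_pred <- rep(mean(train_eval_labels), nrow(eval_sub))
  model_metrics <- regression_metrics(eval_sub$prediction, eval_sub$label)
  baseline_metrics <- regression_metrics(baseline_pred, eval_sub$label)
  metrics <- dplyr::bind_rows(
    dplyr::mutate(model_metrics, method = "claptnet", .before = 1),
    dplyr::mutate(baseline_metrics, method = "mean_baseline", .before = 1)
  )
  metrics$mae_reduction_pct <- c(
    100 * (1 - model_metrics$mae / baseline_metrics$mae), NA_real_)

  config_hash <- NA_character_
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.yaml")
    write_run_config(config, cfg_path)
    config_hash <- unname(tools::md5sum(cfg_path))
    write_activity_csv(cohort, file.path(out_dir, "activity.csv"))
    write_split_json(split, file.path(out_dir, "split.json"))
    save_claptnet(model, file.path(out_dir, "model.rds"))
    utils::write.csv(predictions[setdiff(names(predictions), "window")],
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "interval_report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = config_hash,
           metrics = metrics),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    say("artifacts written to %s (config %s)", out_dir, config_hash)
  }

  invisible(list(cohort = cohort, windows = windows, split = split,
                 model = model, predictions = predictions,
                 interval_report = report, metrics = metrics,
                 config_hash = config_hash))
}
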