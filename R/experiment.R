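# Per-patient experiment orchestration: preprocess -> features -> label ->
# leave-one-seizure-out -> grid-searched RBF-SVM -> firing-power candidates
# -> normalized-FPR Euclidean-distance selection -> pooled evaluation.

#' Experiment configuration
#'
#' Bundles every stage's parameters with explicit seeds so that two runs of
#' [run_patient()] with the same configuration are identical.
#'
#' @param entropy An [entropy_config()].
#' @param split A [split_spec()] (labelling horizon, post-ictal margin,
#'   balancing seed).
#' @param preprocess A [preprocess_config()], or `NULL` to skip
#'   preprocessing (e.g. for synthetic recordings that need none).
#' @param C_grid,g_grid SVM grid-search candidates.
#' @param folds Cross-validation folds for the grid search (default 6).
#' @param p_grid Two-step short-window thresholds to search (default
#'   `1:12`).
#' @param k_grid Two-step k-of-3 values to search (default `1:3`).
#' @param one_step_thresholds One-step window thresholds to search
#'   (default `seq(3, 36, 3)`, the two-step `p` range scaled to the 3x
#'   longer window).
#' @param modes Post-processing modes to run (`"two_step"`, `"one_step"`).
#' @param refractory_min Alarm refractory period, minutes (default = the
#'   labelling horizon).
#' @param selection `"validation"`: score firing-power candidates on a
#'   held-out training seizure's continuous record (an inner model trained
#'   without it supplies the labels); `"test"`: score candidates on the
#'   test seizure itself (in-sample selection).
#' @param seed Master seed for fold assignment and undersampling.
#' @return An object of class `ExperimentConfig`.
#' @export
experiment_config <- function(entropy = entropy_config(),
                              split = split_spec(),
                              preprocess = NULL,
                              C_grid = 2^seq(-1, 5, 2),
                              g_grid = 2^seq(-7, -1, 2),
                              folds = 6L,
                              p_grid = 1:12, k_grid = 1:3,
                              one_step_thresholds = seq(3L, 36L, 3L),
                              modes = c("two_step", "one_step"),
                              refractory_min = split$preictal_horizon_min,
                              selection = c("validation", "test"),
                              seed = 1L) {
  selection <- match.arg(selection)
  modes <- match.arg(modes, c("two_step", "one_step"), several.ok = TRUE)
  structure(list(entropy = entropy, split = split, preprocess = preprocess,
                 C_grid = C_grid, g_grid = g_grid, folds = as.integer(folds),
                 p_grid = as.integer(p_grid), k_grid = as.integer(k_grid),
                 one_step_thresholds = as.integer(one_step_thresholds),
                 modes = modes, refractory_min = refractory_min,
                 selection = selection, seed = as.integer(seed)),
            class = "ExperimentConfig")
}

#' Read an experiment configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of
#' [experiment_config()], with `entropy`, `split` and `preprocess` given as
#' nested maps of the respective constructor arguments.
#'
#' @param path YAML file path.
#' @return An `ExperimentConfig`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$entropy)) args$entropy <- do.call(entropy_config, raw$entropy)
  if (!is.null(raw$split)) args$split <- do.call(split_spec, raw$split)
  if (!is.null(raw$preprocess))
    args$preprocess <- do.call(preprocess_config, raw$preprocess)
  do.call(experiment_config, args)
}

# Candidate firing-power grid for one mode, enumerated conservative-first
# (largest thresholds first): candidates indistinguishable on selection
# data then resolve to the one demanding the most evidence per alarm,
# which risks a shorter prediction horizon instead of false alarms.
.candidate_grid <- function(cfg, mode) {
  if (mode == "two_step")
    expand.grid(p = rev(sort(cfg$p_grid)), k = rev(sort(cfg$k_grid)))
  else data.frame(threshold = rev(sort(cfg$one_step_thresholds)))
}

# alarms for candidate i of the grid on one label sequence
.candidate_alarms <- function(tg, grid, i, cfg, mode) {
  if (mode == "two_step")
    firing_power_alarms(tg,
      fp_config("two_step", p = grid$p[i], k = grid$k[i],
                refractory_min = cfg$refractory_min))
  else
    one_step_alarms(tg, threshold = grid$threshold[i],
                    refractory_min = cfg$refractory_min)
}

# score every candidate of a grid on (possibly several) labelled records:
# each element of streams is list(tg, annotations, hours)
.score_candidates <- function(streams, grid, cfg, mode, horizon_min) {
  ss <- fpr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    reps <- lapply(streams, function(s) {
      al <- .candidate_alarms(s$tg, grid, i, cfg, mode)
      score_alarms(al, s$annotations, horizon_min, s$hours)
    })
    pooled <- pool_reports(reps)
    ss[i] <- pooled$SS
    fpr[i] <- pooled$FPR
  }
  cbind(grid, model_scores(ss, fpr))
}

#' Run the full per-patient experiment
#'
#' For every seizure in turn: hold out its recording, build the training
#' set from the remaining seizures' preictal windows plus the interictal
#' pool, balance by undersampling, grid-search the SVM by stratified CV,
#' train, and predict the test recording's label stream. Firing-power
#' candidates (`p x k` for two-step, thresholds for one-step) are scored on
#' selection data (see `selection` in [experiment_config()]) and the
#' minimum-Euclidean-distance candidate is applied to the test recording.
#' Per-fold reports are pooled into one patient-level result per mode.
#'
#' @param records Named list of [recording()]s; recordings with annotations
#'   are seizure records (one held-out fold per seizure), the rest form the
#'   interictal pool.
#' @param cfg An [experiment_config()].
#' @return Object of class `PatientResult`: list with per-mode entries,
#'   each holding `folds` (per-fold details: selected candidate, candidate
#'   score table, test report) and `pooled` (pooled `EvaluationReport`),
#'   plus `summary` (data frame: mode, SS, FPR, mean SPH, mean selected
#'   test distance).
#' @export
run_patient <- function(records, cfg = experiment_config()) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    names(records) <- paste0("rec", seq_along(records))
  if (!is.null(cfg$preprocess))
    records <- lapply(records, preprocess_recording, cfg = cfg$preprocess)

  features <- lapply(records, sliding_feature_matrix, cfg = cfg$entropy)
  labeled <- mapply(function(f, r, id)
    label_windows(f, r$annotations, cfg$split, recording_id = id),
    features, records, names(records), SIMPLIFY = FALSE)

  has_sz <- vapply(records, function(r) nrow(r$annotations) > 0L, TRUE)
  seizure_ids <- names(records)[has_sz]
  if (length(seizure_ids) < 3L)
    .stopf("need at least 3 seizure recordings, got %d", length(seizure_ids))
  pool <- if (any(!has_sz))
    rbind_datasets(lapply(labeled[!has_sz], function(ds)
      subset_dataset(ds, ds$labels == 0L)))
  else labeled_dataset(matrix(numeric(0), 0, ncol(labeled[[1]]$features)),
                       integer(0), numeric(0),
                       data.frame(recording_id = character(0),
                                  seizure_id = numeric(0)))
  horizon <- cfg$split$preictal_horizon_min

  test_ids <- cfg$split$test_seizure_ids
  if (is.null(test_ids)) test_ids <- seizure_ids

  result <- list()
  for (mode in cfg$modes) {
    grid <- .candidate_grid(cfg, mode)
    folds <- list()
    for (test_id in test_ids) {
      split <- leave_one_seizure_split(labeled[seizure_ids], pool, test_id)
      train_bal <- balance_undersample(split$train, cfg$split$balance_seed)
      spec <- grid_search_cv(train_bal, cfg$C_grid, cfg$g_grid,
                             folds = cfg$folds, seed = cfg$seed)
      model <- train_classifier(spec, train_bal)

      sel_streams <- .selection_streams(mode, cfg, spec, labeled, features,
                                        records, pool, seizure_ids, test_id,
                                        model)
      sel_scores <- .score_candidates(sel_streams, grid, cfg, mode, horizon)
      best <- select_best_model(sel_scores)

      # firing power runs on the full continuous record so alarm indices
      # map to true time (exclusion-filtered datasets are training-only)
      tg_test <- predict_labels(model, features[[test_id]])
      test_stream <- list(tg = tg_test,
                          annotations = records[[test_id]]$annotations,
                          hours = rec_duration(records[[test_id]]) / 3600)
      test_scores <- .score_candidates(list(test_stream), grid, cfg, mode,
                                       horizon)
      al <- .candidate_alarms(tg_test, grid, best, cfg, mode)
      report <- score_alarms(al, records[[test_id]]$annotations, horizon,
                             test_stream$hours)
      folds[[test_id]] <- list(test_id = test_id, model_spec = spec,
                               selected = grid[best, , drop = FALSE],
                               selection_scores = sel_scores,
                               test_scores = test_scores,
                               selected_test_ed = test_scores$ed[best],
                               report = report)
    }
    pooled <- pool_reports(lapply(folds, `[[`, "report"))
    result[[mode]] <- list(folds = folds, pooled = pooled)
  }

  summary <- do.call(rbind, lapply(names(result), function(mode) {
    pooled <- result[[mode]]$pooled
    data.frame(mode = mode, SS = pooled$SS, FPR = pooled$FPR,
               mean_SPH_min = pooled$mean_SPH_min,
               mean_selected_ed = mean(vapply(result[[mode]]$folds,
                                              `[[`, 1, "selected_test_ed")))
  }))
  structure(c(result, list(summary = summary, config = cfg)),
            class = "PatientResult")
}

# label streams used for firing-power candidate selection. The classifier
# labels come from the trained model on the test record (selection =
# "test"), or from an inner model applied to one held-out training
# seizure's record (selection = "validation"); the inner model reuses the
# grid-searched (C, g) but is trained without the validation seizure.
.selection_streams <- function(mode, cfg, spec, labeled, features, records,
                               pool, seizure_ids, test_id, model) {
  if (cfg$selection == "test") {
    tg <- predict_labels(model, features[[test_id]])
    return(list(list(tg = tg, annotations = records[[test_id]]$annotations,
                     hours = rec_duration(records[[test_id]]) / 3600)))
  }
  train_ids <- setdiff(seizure_ids, test_id)
  val_id <- train_ids[length(train_ids)]
  inner_train <- rbind_datasets(c(
    lapply(labeled[setdiff(train_ids, val_id)], function(ds)
      subset_dataset(ds, ds$labels == 1L)),
    list(subset_dataset(pool,
      !pool$provenance$recording_id %in% c(val_id, test_id)))))
  inner_bal <- balance_undersample(inner_train, cfg$split$balance_seed)
  inner_model <- train_classifier(spec, inner_bal)
  tg <- predict_labels(inner_model, features[[val_id]])
  list(list(tg = tg, annotations = records[[val_id]]$annotations,
            hours = rec_duration(records[[val_id]]) / 3600))
}

#' @export
print.PatientResult <- function(x, ...) {
  cat("PatientResult\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
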