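# Turning feature series + seizure annotations into labeled train/test sets.
#
# Window labels: a window [t, t+w) is
#   - excluded   if it intersects an ictal interval [onset, offset) or the
#                post-ictal exclusion margin [offset, offset + margin);
#   - preictal   if it intersects any [onset - horizon, onset);
#   - interictal otherwise.
# Exclusion takes precedence over preictal.

#' Train/test split and labelling specification
#'
#' @param test_seizure_ids Seizure ids held out for testing (used by
#'   [run_patient()]); `NULL` means rotate over all seizures.
#' @param preictal_horizon_min Length of the preictal labelling horizon
#'   before each onset, minutes. Default 50.
#' @param exclusion_margin_min Post-ictal margin excluded from the dataset,
#'   minutes. Default 30.
#' @param balance_seed Seed for [balance_undersample()].
#' @return An object of class `SplitSpec`.
#' @export
split_spec <- function(test_seizure_ids = NULL, preictal_horizon_min = 50,
                       exclusion_margin_min = 30, balance_seed = 1L) {
  .check_scalar_num(preictal_horizon_min, "preictal_horizon_min",
                    lower = .Machine$double.eps)
  .check_scalar_num(exclusion_margin_min, "exclusion_margin_min", lower = 0)
  structure(list(test_seizure_ids = test_seizure_ids,
                 preictal_horizon_min = preictal_horizon_min,
                 exclusion_margin_min = exclusion_margin_min,
                 balance_seed = as.integer(balance_seed)),
            class = "SplitSpec")
}

.intersects <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1

#' Label feature windows as preictal / interictal
#'
#' Applies the horizon-based labelling rule to every window of a feature
#' series; windows inside an ictal interval or the post-ictal exclusion
#' margin are dropped. A window counts as preictal when its half-open
#' interval intersects `[onset - horizon, onset)`.
#'
#' @param fs A `FeatureSeries` (see [sliding_feature_matrix()]).
#' @param annotations Data frame of seizures with `onset`/`offset` columns
#'   (seconds); may be empty for a purely interictal recording. Optional
#'   `seizure_id` column; defaults to the row number.
#' @param spec A [split_spec()].
#' @param recording_id Provenance tag stored with every window.
#' @return Object of class `LabeledDataset`: list with `features`
#'   (`n_windows x n_channels` matrix), `labels` (integer, preictal = 1,
#'   interictal = 0), `window_times` (window start, seconds) and
#'   `provenance` (data frame: `recording_id`, `seizure_id`).
#' @export
label_windows <- function(fs, annotations, spec = split_spec(),
                          recording_id = "rec1") {
  ann <- as.data.frame(annotations)
  if (NROW(ann) > 0L) {
    if (!all(c("onset", "offset") %in% names(ann)))
      .stopf("annotations need 'onset' and 'offset' columns")
    ann <- ann[order(ann$onset), , drop = FALSE]
    if (NROW(ann) > 1L &&
        any(ann$onset[-1] < ann$offset[-NROW(ann)]))
      .stopf("overlapping seizure annotations")
    if (is.null(ann$seizure_id)) ann$seizure_id <- seq_len(NROW(ann))
  }
  wlen <- fs$config$window_len
  w0 <- fs$window_starts
  w1 <- w0 + wlen
  n <- length(w0)
  horizon_s <- spec$preictal_horizon_min * 60
  margin_s <- spec$exclusion_margin_min * 60

  status <- rep("interictal", n)
  sz_of <- rep(NA, n)
  for (i in seq_len(NROW(ann))) {
    pre <- .intersects(w0, w1, ann$onset[i] - horizon_s, ann$onset[i])
    status[pre & status == "interictal"] <- "preictal"
    sz_of[pre & is.na(sz_of)] <- ann$seizure_id[i]
  }
  for (i in seq_len(NROW(ann))) {
    excl <- .intersects(w0, w1, ann$onset[i], ann$offset[i] + margin_s)
    status[excl] <- "excluded"
  }
  keep <- status != "excluded"
  labeled_dataset(
    features = t(fs$values)[keep, , drop = FALSE],
    labels = as.integer(status[keep] == "preictal"),
    window_times = w0[keep],
    provenance = data.frame(recording_id = recording_id,
                            seizure_id = ifelse(status[keep] == "preictal",
                                                sz_of[keep], NA)))
}

#' Assemble a labeled dataset
#'
#' Low-level constructor used by [label_windows()]; exposed for tests and
#' for building datasets from externally computed features.
#'
#' @param features Numeric matrix, one row per window.
#' @param labels Integer vector in `{0, 1}` (1 = preictal).
#' @param window_times Window start times, seconds.
#' @param provenance Data frame with `recording_id` and `seizure_id`
#'   aligned with the rows.
#' @return Object of class `LabeledDataset`.
#' @export
labeled_dataset <- function(features, labels, window_times, provenance) {
  features <- as.matrix(features)
  if (!all(labels %in% c(0L, 1L))) .stopf("labels must be 0 or 1")
  if (NROW(provenance) == 1L && nrow(features) > 1L)
    provenance <- provenance[rep(1L, nrow(features)), , drop = FALSE]
  if (nrow(features) != length(labels) ||
      nrow(features) != length(window_times) ||
      nrow(features) != NROW(provenance))
    .stopf("features, labels, window_times and provenance must align")
  structure(list(features = features, labels = as.integer(labels),
                 window_times = as.numeric(window_times),
                 provenance = as.data.frame(provenance)),
            class = "LabeledDataset")
}

#' @export
print.LabeledDataset <- function(x, ...) {
  cat(sprintf("LabeledDataset: %d windows x %d features (%d preictal, %d interictal)\n",
              nrow(x$features), ncol(x$features), sum(x$labels == 1L),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Number of windows in a labeled dataset
#' @param ds A `LabeledDataset`.
#' @return Integer row count.
#' @export
n_samples <- function(ds) nrow(ds$features)

#' Row-subset a labeled dataset
#' @param ds A `LabeledDataset`.
#' @param idx Row indices (or logical mask).
#' @return The subset `LabeledDataset`.
#' @export
subset_dataset <- function(ds, idx) {
  labeled_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                  ds$window_times[idx], ds$provenance[idx, , drop = FALSE])
}

#' Concatenate labeled datasets
#' @param ... `LabeledDataset` objects.
#' @return The row-bound `LabeledDataset`.
#' @export
rbind_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && is.list(dss[[1]]) &&
      !inherits(dss[[1]], "LabeledDataset")) dss <- dss[[1]]
  labeled_dataset(do.call(rbind, lapply(dss, `[[`, "features")),
                  unlist(lapply(dss, `[[`, "labels")),
                  unlist(lapply(dss, `[[`, "window_times")),
                  do.call(rbind, lapply(dss, `[[`, "provenance")))
}

#' Leave-one-seizure-out split
#'
#' Holds out one seizure's full continuous segment (preictal plus
#' surrounding interictal windows of its recording) for testing; training
#' data are the remaining seizures' preictal windows plus the interictal
#' pool, with any pool windows recorded alongside the test seizure removed.
#' Requires at least three seizures, so at least two remain for training.
#'
#' @param seizure_datasets Named list of `LabeledDataset`, one per seizure
#'   (the full labelled recording containing that seizure); names are
#'   seizure ids.
#' @param interictal_pool `LabeledDataset` of interictal windows from
#'   seizure-free recordings (may have zero rows).
#' @param test_id Name of the seizure to hold out.
#' @return List with elements `train` and `test` (`LabeledDataset`s).
#' @export
leave_one_seizure_split <- function(seizure_datasets, interictal_pool,
                                    test_id) {
  if (length(seizure_datasets) < 3L)
    .stopf("need at least 3 seizures (got %d): patients with fewer are not analysed",
           length(seizure_datasets))
  if (!test_id %in% names(seizure_datasets))
    .stopf("unknown test seizure id '%s'", test_id)
  test <- seizure_datasets[[test_id]]
  train_parts <- lapply(seizure_datasets[names(seizure_datasets) != test_id],
                        function(ds) subset_dataset(ds, ds$labels == 1L))
  if (n_samples(interictal_pool) > 0L) {
    keep <- !interictal_pool$provenance$recording_id %in%
      unique(test$provenance$recording_id)
    train_parts <- c(train_parts, list(subset_dataset(interictal_pool, keep)))
  }
  train <- rbind_datasets(train_parts)
  list(train = train, test = test)
}

#' Balance classes by random undersampling
#'
#' Randomly subsamples the majority class without replacement down to the
#' minority-class count. All minority rows are kept; the selection is
#' deterministic for a given seed.
#'
#' @param train A `LabeledDataset` containing both classes.
#' @param seed Integer seed for the random selection.
#' @return The balanced `LabeledDataset` (original row order preserved).
#' @export
balance_undersample <- function(train, seed = 1L) {
  n1 <- sum(train$labels == 1L)
  n0 <- sum(train$labels == 0L)
  if (n1 == 0L || n0 == 0L)
    .stopf("both classes must be present (preictal %d, interictal %d)", n1, n0)
  if (n1 == n0) return(train)
  maj <- if (n0 > n1) 0L else 1L
  maj_idx <- which(train$labels == maj)
  keep_maj <- withr::with_seed(seed,
    sample(maj_idx, min(n0, n1), replace = FALSE))
  subset_dataset(train, sort(c(which(train$labels != maj), keep_maj)))
}
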