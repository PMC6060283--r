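# Binary preictal/interictal classification behind a small contract:
# a ModelSpec names the hyperparameters, train_classifier() fits, and
# predict_labels() emits one 0/1 label per 5-s window. The default engine
# is an RBF-kernel SVM (e1071/libsvm).

#' SVM hyperparameter specification
#'
#' @param C Cost parameter (margin/violation trade-off), `> 0`.
#' @param g RBF kernel width parameter `gamma`, `> 0`.
#' @return An object of class `ModelSpec` (kernel fixed to RBF).
#' @export
model_spec <- function(C, g) {
  .check_scalar_num(C, "C", lower = .Machine$double.eps)
  .check_scalar_num(g, "g", lower = .Machine$double.eps)
  structure(list(C = C, g = g, kernel = "RBF"), class = "ModelSpec")
}

#' @export
print.ModelSpec <- function(x, ...) {
  cat(sprintf("ModelSpec: RBF SVM, C = %g, g = %g\n", x$C, x$g))
  invisible(x)
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so folds are balanced and deterministic given the seed.
.stratified_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < folds)
        .stopf("class %s has %d samples, fewer than %d folds",
               cl, length(idx), folds)
      idx <- sample(idx)
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

.svm_fit <- function(features, labels, spec) {
  e1071::svm(x = features, y = factor(labels, levels = c(0L, 1L)),
             kernel = "radial", cost = spec$C, gamma = spec$g, scale = TRUE)
}

#' Grid search with stratified cross-validation
#'
#' Evaluates every `(C, g)` pair by mean held-out accuracy over
#' label-stratified folds (default 6) and returns the best specification.
#' Ties are broken towards smaller `C`, then smaller `g`.
#'
#' @param train A balanced `LabeledDataset` with both classes present.
#' @param C_grid,g_grid Candidate values; defaults are the standard
#'   exponential grids `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`.
#' @param folds Number of CV folds (default 6).
#' @param seed Seed for the fold assignment.
#' @return The winning [model_spec()], with the full CV table attached as
#'   attribute `"cv_table"`.
#' @export
grid_search_cv <- function(train, C_grid = 2^seq(-5, 15, 2),
                           g_grid = 2^seq(-15, 3, 2), folds = 6L,
                           seed = 1L) {
  if (folds < 2L) .stopf("need at least 2 folds")
  if (length(unique(train$labels)) < 2L)
    .stopf("training data must contain both classes")
  fold_of <- .stratified_folds(train$labels, folds, seed)
  grid <- expand.grid(g = g_grid, C = C_grid)[, c("C", "g")]
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    spec <- model_spec(grid$C[i], grid$g[i])
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- fold_of != f
      fit <- .svm_fit(train$features[tr, , drop = FALSE],
                      train$labels[tr], spec)
      pred <- predict(fit, train$features[!tr, , drop = FALSE])
      mean(as.integer(as.character(pred)) == train$labels[!tr])
    }, 1)
    mean(fold_acc)
  }, 1)
  best <- order(-acc, grid$C, grid$g)[1]
  out <- model_spec(grid$C[best], grid$g[best])
  attr(out, "cv_table") <- cbind(grid, cv_accuracy = acc)
  out
}

#' Fit the preictal/interictal classifier
#'
#' @param spec A [model_spec()].
#' @param train A `LabeledDataset` containing both classes.
#' @return Object of class `TrainedModel` wrapping the fitted decision
#'   function plus the feature dimensionality it expects.
#' @export
train_classifier <- function(spec, train) {
  if (length(unique(train$labels)) < 2L)
    .stopf("training data must contain both classes")
  fit <- .svm_fit(train$features, train$labels, spec)
  structure(list(spec = spec, fit = fit,
                 n_features = ncol(train$features),
                 n_train = n_samples(train)),
            class = "TrainedModel")
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel: RBF SVM (C = %g, g = %g), %d features, %d training windows\n",
              x$spec$C, x$spec$g, x$n_features, x$n_train))
  invisible(x)
}

#' Predict per-window binary labels
#'
#' @param model A [train_classifier()] result.
#' @param newdata A `FeatureSeries`, a `LabeledDataset`, or a numeric
#'   matrix with one row per window; the feature dimensionality must match
#'   the training data.
#' @return Integer vector of labels (1 = preictal, 0 = interictal), one per
#'   window.
#' @export
predict_labels <- function(model, newdata) {
  feats <- if (inherits(newdata, "FeatureSeries")) t(newdata$values)
           else if (inherits(newdata, "LabeledDataset")) newdata$features
           else as.matrix(newdata)
  if (ncol(feats) != model$n_features)
    .stopf("feature dimensionality mismatch: model expects %d, got %d",
           model$n_features, ncol(feats))
  as.integer(as.character(predict(model$fit, feats)))
}
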