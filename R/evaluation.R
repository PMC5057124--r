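#' Confusion counts from truth and prediction
#'
#' @param truth,predicted Vectors of +1/-1 labels of equal length.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- check_labels(truth, length(truth))
  predicted <- check_labels(predicted, length(truth))
  new_confusion(TP = sum(truth == 1L & predicted == 1L),
                FP = sum(truth == -1L & predicted == 1L),
                TN = sum(truth == -1L & predicted == -1L),
                FN = sum(truth == 1L & predicted == -1L))
}

new_confusion <- function(TP, FP, TN, FN) {
  structure(list(TP = as.numeric(TP), FP = as.numeric(FP),
                 TN = as.numeric(TN), FN = as.numeric(FN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%g FP=%g TN=%g FN=%g\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Threshold classification metrics
#'
#' Computes sensitivity `Sn = TP / (TP + FN)`, specificity
#' `Sp = TN / (TN + FP)`, accuracy `Acc = (TP + TN) / n` (all reported as
#' percentages) and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#'
#' Conventions for degenerate inputs: `Sn` or `Sp` is `NaN` (with a
#' warning) when its denominator is zero; `MCC` is reported as 0 when any
#' marginal is zero.
#'
#' @param counts A `confusion_counts`, or the `TP` count if the four counts
#'   are given separately.
#' @param FP,TN,FN Remaining counts when not passing a `confusion_counts`.
#' @return An object of class `metrics_report` with fields `Sn`, `Sp`,
#'   `Acc` (percent) and `MCC`, plus the input `counts`.
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, -1), c(1, -1, -1)))
#' @export
classification_metrics <- function(counts, FP = NULL, TN = NULL, FN = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    if (is.null(FP) || is.null(TN) || is.null(FN))
      stop("supply a confusion_counts object or all four counts")
    counts <- new_confusion(counts, FP, TN, FN)
  }
  with(counts, {
    if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be non-negative")
    n <- TP + FP + TN + FN
    if (n == 0) stop("all-zero confusion counts")
    if (TP + FN == 0) warning("no positive samples: Sn undefined")
    if (TN + FP == 0) warning("no negative samples: Sp undefined")
    sn <- TP / (TP + FN)
    sp <- TN / (TN + FP)
    acc <- (TP + TN) / n
    denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    mcc <- if (denom2 == 0) 0 else (TP * TN - FP * FN) / sqrt(denom2)
    structure(list(Sn = 100 * sn, Sp = 100 * sp, Acc = 100 * acc, MCC = mcc,
                   counts = new_confusion(TP, FP, TN, FN)),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn = %.2f%%  Sp = %.2f%%  Acc = %.2f%%  MCC = %.2f\n",
              x$Sn, x$Sp, x$Acc, x$MCC))
  invisible(x)
}

#' Format a metrics report as key-value text
#' @param report A `metrics_report`.
#' @return Character vector of `key<TAB>value` lines.
#' @export
format_metrics <- function(report) {
  c(sprintf("Sn\t%.2f", report$Sn), sprintf("Sp\t%.2f", report$Sp),
    sprintf("Acc\t%.2f", report$Acc), sprintf("MCC\t%.2f", report$MCC),
    sprintf("TP\t%g", report$counts$TP), sprintf("FP\t%g", report$counts$FP),
    sprintf("TN\t%g", report$counts$TN), sprintf("FN\t%g", report$counts$FN))
}

# Shared engine for k-fold CV and jackknife: encode once, then train/predict
# per fold and pool the confusion counts across folds (per-fold metrics are
# ill-defined for single-sample folds, so pooling is the only convention
# that covers the jackknife).
cv_engine <- function(features, labels, fold_id, C, gamma, config, table) {
  predicted <- integer(length(labels))
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    fit <- svm_train(features[!test, , drop = FALSE], labels[!test],
                     C = C, gamma = gamma, config = config, table = table)
    predicted[test] <- predict(fit, features[test, , drop = FALSE])
  }
  classification_metrics(confusion_counts(labels, predicted))
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Encodes the windows with [psednc()], then for each of `k` stratified
#' folds trains an RBF SVM on the remaining folds and predicts the held-out
#' fold. Confusion counts are pooled over folds before computing metrics.
#' Deterministic given `seed`.
#'
#' @param windows List (or character vector) of windows.
#' @param labels +1/-1 vector, one per window.
#' @param config A [psednc_config()].
#' @param C,gamma SVM hyperparameters, held fixed across folds.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param table Property table used for encoding.
#' @return A `metrics_report`.
#' @export
kfold_cv <- function(windows, labels, config = psednc_config(),
                     C = 1, gamma = NULL, k = 5L, seed = 1L,
                     table = builtin_property_table()) {
  labels <- check_labels(labels, length(windows))
  k <- as.integer(k)
  if (k > min(table(labels)) && k != length(labels))
    stop("`k` exceeds the smaller class size (", min(table(labels)),
         "); folds could not all contain both classes")
  features <- psednc(windows, config = config, table = table)
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  fold_id <- stratified_folds(labels, k, seed)
  cv_engine(features, labels, fold_id, C, gamma, config, table)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each sample is predicted by a model trained on all remaining samples;
#' the n rounds' confusion counts are pooled into one report. Fully
#' deterministic — no fold randomization is involved. Equivalent to
#' [kfold_cv()] with `k = n`.
#'
#' @inheritParams kfold_cv
#' @return A `metrics_report`.
#' @export
jackknife <- function(windows, labels, config = psednc_config(),
                      C = 1, gamma = NULL,
                      table = builtin_property_table()) {
  labels <- check_labels(labels, length(windows))
  if (length(labels) < 2L) stop("jackknife requires at least 2 samples")
  features <- psednc(windows, config = config, table = table)
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  cv_engine(features, labels, seq_along(labels), C, gamma, config, table)
}

#' Sweep the (w, lambda) encoding parameters
#'
#' Evaluates stratified k-fold cross-validated accuracy of the pipeline at
#' every point of a `w` x `lambda` grid (default: `w` from 0 to 1 in steps
#' of 0.1 and `lambda` from 1 to 10, i.e. 110 cells) and returns the full
#' grid with the maximizing cell. Ties are broken toward smaller `lambda`,
#' then smaller `w`. The same seed, hence the same fold assignment, is used
#' for every cell so cells are comparable.
#'
#' @inheritParams kfold_cv
#' @param w_values,lambda_values Grid axes.
#' @param counting_mode Passed to [psednc_config()].
#' @return List of class `sweep_result`: `grid` (data frame with columns
#'   `w`, `lambda`, `accuracy` in percent), `best_w`, `best_lambda`,
#'   `best_accuracy`.
#' @export
parameter_sweep <- function(windows, labels,
                            w_values = seq(0, 1, by = 0.1),
                            lambda_values = 1:10,
                            C = 1, gamma = NULL, k = 5L, seed = 1L,
                            counting_mode = "overlapping",
                            table = builtin_property_table()) {
  if (length(w_values) == 0L || length(lambda_values) == 0L)
    stop("sweep ranges must be non-empty")
  grid <- expand.grid(w = w_values, lambda = as.integer(lambda_values),
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- psednc_config(w = grid$w[i], lambda = grid$lambda[i],
                         counting_mode = counting_mode)
    rep_i <- kfold_cv(windows, labels, config = cfg, C = C, gamma = gamma,
                      k = k, seed = seed, table = table)
    grid$accuracy[i] <- rep_i$Acc
  }
  ord <- order(grid$lambda, grid$w)
  best <- ord[which.max(grid$accuracy[ord])]
  structure(list(grid = grid, best_w = grid$w[best],
                 best_lambda = grid$lambda[best],
                 best_accuracy = grid$accuracy[best]),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells; peak Acc = %.2f%% at w = %g, lambda = %d\n",
              nrow(x$grid), x$best_accuracy, x$best_w, x$best_lambda))
  invisible(x)
}
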