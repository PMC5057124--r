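#' Train an RBF-kernel SVM on PseDNC features
#'
#' Fits a C-classification support vector machine with radial basis
#' function kernel (via the libsvm solver) on encoded windows. Labels use
#' the convention +1 = editing site, -1 = non-site. Features are not
#' rescaled: PseDNC components already lie in `[0, 1]` and sum to 1
#' (`scale_features = TRUE` enables standardization for experimentation).
#'
#' @param features Numeric matrix, one row per sample (from [psednc()]).
#' @param labels Vector of +1/-1, one per row; both classes must be present.
#' @param C Regularization parameter (> 0).
#' @param gamma RBF kernel width (> 0); default `1 / ncol(features)`.
#' @param config The [psednc_config()] used for encoding; stored so that
#'   prediction can verify dimension compatibility.
#' @param table The `property_table` used for encoding; its fingerprint is
#'   stored for compatibility checks.
#' @param scale_features Standardize feature columns before fitting
#'   (default `FALSE`).
#' @return An object of class `adared_model`.
#' @export
svm_train <- function(features, labels, C = 1, gamma = 1 / ncol(features),
                      config = psednc_config(),
                      table = builtin_property_table(),
                      scale_features = FALSE) {
  features <- as.matrix(features)
  labels <- check_labels(labels, nrow(features))
  if (length(unique(labels)) < 2L)
    stop("training requires samples from both classes")
  if (C <= 0 || gamma <= 0) stop("`C` and `gamma` must be positive")
  if (!inherits(config, "psednc_config")) stop("`config` must be a psednc_config")
  if (ncol(features) != 16L + config$lambda)
    stop("feature dimension ", ncol(features), " does not match config dimension ",
         16L + config$lambda)
  fit <- e1071::svm(x = features, y = factor(labels, levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = scale_features)
  structure(list(svm_state = fit, C = C, gamma = gamma,
                 encoding_config = config,
                 table_fingerprint = property_fingerprint(validate_property_table(table)),
                 dim = ncol(features),
                 label_convention = c(positive = 1, negative = -1),
                 version = 1L),
            class = "adared_model")
}

check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("number of labels (", length(labels), ") does not match number of samples (", n, ")")
  if (!all(labels %in% c(-1L, 1L)))
    stop("labels must be +1 (editing site) or -1 (non-site)")
  labels
}

#' @export
print.adared_model <- function(x, ...) {
  cat(sprintf(
    "<adared_model> RBF SVM, C = %g, gamma = %g, %d features (w = %g, lambda = %d)\n",
    x$C, x$gamma, x$dim, x$encoding_config$w, x$encoding_config$lambda))
  invisible(x)
}

#' Predict editing-site labels
#'
#' @param object A trained `adared_model`.
#' @param features Numeric matrix of PseDNC vectors with the dimension the
#'   model was trained on.
#' @param decision_values Also return the signed distance to the separating
#'   hyperplane as attribute `"decision_values"`.
#' @param ... Unused.
#' @return Integer vector of +1/-1, one per row, in input order.
#' @export
predict.adared_model <- function(object, features, decision_values = FALSE, ...) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) return(integer(0))
  if (ncol(features) != object$dim)
    stop("feature dimension mismatch: model expects ", object$dim,
         ", received ", ncol(features))
  p <- stats::predict(object$svm_state, features, decision.values = decision_values)
  out <- as.integer(as.character(p))
  if (decision_values) {
    dv <- drop(attr(p, "decision.values"))
    # libsvm orients the decision value by the first class seen (-1 here);
    # flip so positive scores mean "editing site".
    if (colnames(attr(p, "decision.values"))[1L] == "-1/1") dv <- -dv
    attr(out, "decision_values") <- unname(dv)
  }
  out
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds so that class proportions are as
#' even as possible across folds: within each class, the (seed-shuffled)
#' samples are dealt cyclically onto folds, with the starting fold advanced
#' between classes so fold sizes stay balanced. With `k = n` every fold
#' holds exactly one sample, making k-fold identical to the jackknife.
#'
#' @param labels +1/-1 vector.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("`k` must be between 2 and the number of samples")
  folds <- integer(n)
  set.seed(as.integer(seed))
  offset <- 0L
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds
}

#' Grid search for SVM hyperparameters
#'
#' Exhaustively evaluates every `(C, gamma)` pair by stratified k-fold
#' cross-validated accuracy (fold assignment derived from `seed`, identical
#' for every pair) and returns the maximizing pair. Ties are broken toward
#' smaller `C`, then smaller `gamma`, so the result does not depend on the
#' ordering (or duplication) of the supplied grids. The default grid is the
#' standard libsvm-guide lattice `C = 2^(-5), 2^(-3), ..., 2^15`,
#' `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#'
#' @param features,labels As in [svm_train()].
#' @param C_values,gamma_values Numeric vectors of candidate values.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for fold assignment.
#' @param config,table Passed through to [svm_train()].
#' @return List with `C`, `gamma`, `cv_accuracy` (fraction), and `grid`
#'   (data frame of all evaluated cells).
#' @export
grid_search <- function(features, labels,
                        C_values = 2^seq(-5, 15, by = 2),
                        gamma_values = 2^seq(-15, 3, by = 2),
                        folds = 5L, seed = 1L,
                        config = psednc_config(),
                        table = builtin_property_table()) {
  features <- as.matrix(features)
  labels <- check_labels(labels, nrow(features))
  if (length(C_values) == 0L || length(gamma_values) == 0L)
    stop("grid value lists must be non-empty")
  C_values <- sort(unique(C_values))
  gamma_values <- sort(unique(gamma_values))
  fold_id <- stratified_folds(labels, folds, seed)
  grid <- expand.grid(C = C_values, gamma = gamma_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(max(fold_id))) {
      test <- fold_id == f
      fit <- svm_train(features[!test, , drop = FALSE], labels[!test],
                       C = grid$C[i], gamma = grid$gamma[i],
                       config = config, table = table)
      correct <- correct + sum(predict(fit, features[test, , drop = FALSE]) ==
                                 labels[test])
    }
    grid$accuracy[i] <- correct / length(labels)
  }
  # reorder so that which.max's first-hit rule realizes the documented
  # smaller-C-then-smaller-gamma tie-break
  byC <- order(grid$C, grid$gamma)
  best <- byC[which.max(grid$accuracy[byC])]
  list(C = grid$C[best], gamma = grid$gamma[best],
       cv_accuracy = grid$accuracy[best], grid = grid)
}

#' Save / load a trained model
#'
#' The model file is a single versioned container bundling the fitted SVM,
#' its hyperparameters, the encoding configuration and the property-table
#' fingerprint. [load_model()] validates the version and structure;
#' prediction after loading is bitwise-identical to before saving.
#'
#' @param model An `adared_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `adared_model`.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "adared_model")) stop("`model` must be an adared_model")
  saveRDS(list(container = "adared_model", container_version = 1L,
               payload = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt model file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (!is.list(obj) || !identical(obj$container, "adared_model"))
    stop("not an adared model file: ", path)
  if (!identical(obj$container_version, 1L))
    stop("unsupported model container version: ", obj$container_version)
  model <- obj$payload
  if (!inherits(model, "adared_model")) stop("corrupt model payload in ", path)
  model
}

#' Check a model against the property table in use
#'
#' Emits a warning when the fingerprint of `table` differs from the one the
#' model was trained with (predictions would then be made on incompatibly
#' encoded features).
#'
#' @param model An `adared_model`.
#' @param table A `property_table`.
#' @return `TRUE` (match) or `FALSE` (mismatch, with warning), invisibly.
#' @export
check_model_table <- function(model, table = builtin_property_table()) {
  ok <- identical(model$table_fingerprint,
                  property_fingerprint(validate_property_table(table)))
  if (!ok)
    warning("property-table fingerprint differs from the one used at training time")
  invisible(ok)
}
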