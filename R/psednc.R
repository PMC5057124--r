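#' PseDNC encoding configuration
#'
#' Bundles the pseudo dinucleotide composition parameters: the weight factor
#' `w` balancing composition against pseudo components, the number of
#' correlation tiers `lambda`, and the dinucleotide counting convention.
#' Defaults `w = 0.3`, `lambda = 4` are the values selected by 5-fold
#' cross-validated accuracy on the editing-site benchmark.
#'
#' `counting_mode` controls how the 16 dinucleotide frequencies are counted:
#' `"overlapping"` (default) counts all `L - 1` adjacent dinucleotides;
#' `"non_overlapping"` counts the `floor(L / 2)` dinucleotides at positions
#' 1-2, 3-4, ... Tier correlation factors always run over the overlapping
#' dinucleotide sequence, whichever mode is chosen.
#'
#' @param w Weight factor in `[0, 1]`.
#' @param lambda Number of correlation tiers (positive integer); the feature
#'   dimension is `16 + lambda`.
#' @param counting_mode `"overlapping"` or `"non_overlapping"`.
#' @return An object of class `psednc_config`.
#' @export
psednc_config <- function(w = 0.3, lambda = 4L,
                          counting_mode = c("overlapping", "non_overlapping")) {
  counting_mode <- match.arg(counting_mode)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("`w` must be a single number in [0, 1]")
  lambda <- as.integer(lambda)
  if (length(lambda) != 1L || is.na(lambda) || lambda < 1L)
    stop("`lambda` must be a positive integer")
  structure(list(w = as.numeric(w), lambda = lambda, k = 2L,
                 counting_mode = counting_mode),
            class = "psednc_config")
}

#' @export
print.psednc_config <- function(x, ...) {
  cat(sprintf("<psednc_config> w = %g, lambda = %d, counting = %s (dim %d)\n",
              x$w, x$lambda, x$counting_mode, 16L + x$lambda))
  invisible(x)
}

# Integer codes (1..16) of the overlapping dinucleotides of a residue string,
# in the fixed lexicographic order of DINUCLEOTIDES.
dinucleotide_codes <- function(residues) {
  base <- match(strsplit(residues, "", fixed = TRUE)[[1L]], c("A", "C", "G", "U"))
  L <- length(base)
  (base[-L] - 1L) * 4L + base[-1L]
}

#' Dinucleotide frequency vector
#'
#' Computes the 16 normalized dinucleotide occurrence frequencies of a
#' window, in fixed lexicographic order (AA, AC, ..., UU). In overlapping
#' mode all `L - 1` adjacent dinucleotides are counted and divided by
#' `L - 1`; in non-overlapping mode the dinucleotides at positions 1-2,
#' 3-4, ... are counted and divided by `floor(L / 2)`. Either way the
#' frequencies sum to 1.
#'
#' @param window A `site_window` or residue string of length >= 2.
#' @param mode Counting convention; see [psednc_config()].
#' @return Named numeric vector of length 16 summing to 1.
#' @export
dinucleotide_frequencies <- function(window,
                                     mode = c("overlapping", "non_overlapping")) {
  mode <- match.arg(mode)
  codes <- dinucleotide_codes(window_residues(window))
  if (mode == "non_overlapping")
    codes <- codes[seq(1L, length(codes), by = 2L)]
  f <- tabulate(codes, nbins = 16L) / length(codes)
  names(f) <- DINUCLEOTIDES
  f
}

#' Structural correlation between two dinucleotides
#'
#' The mean squared difference of the six standardized structural parameter
#' values of two dinucleotide steps: `(1/v) * sum_u (P_u(d1) - P_u(d2))^2`
#' with `v` the number of properties (6 for the built-in table). Zero for
#' identical property rows, strictly positive otherwise.
#'
#' @param d1,d2 Dinucleotide strings, e.g. `"AA"`.
#' @param table A standardized `property_table`.
#' @return Non-negative scalar.
#' @export
correlation_theta <- function(d1, d2, table = standardized_table_cached()) {
  if (!is_standardized(table)) stop("`table` must be standardized; see standardize_properties()")
  if (!d1 %in% rownames(table) || !d2 %in% rownames(table))
    stop("unknown dinucleotide: ", d1, " / ", d2)
  mean((table[d1, ] - table[d2, ])^2)
}

# 16 x 16 matrix of pairwise correlation values Theta(d_i, d_j); encoding
# works off this cache so each window costs O(L * lambda) lookups.
theta_matrix <- function(table) {
  if (!is_standardized(table)) stop("`table` must be standardized; see standardize_properties()")
  m <- unclass(table)
  v <- ncol(m)
  g <- tcrossprod(m)
  sq <- diag(g)
  (outer(sq, sq, "+") - 2 * g) / v
}

#' Tier correlation factor of a window
#'
#' The j-th tier correlation factor: the average structural correlation
#' between all pairs of overlapping dinucleotides separated by `j`
#' positions, `theta_j = mean_i Theta(T_i, T_(i+j))` over the
#' `L - 1 - j` available pairs.
#'
#' @param window A `site_window` or residue string.
#' @param j Tier, `1 <= j <= L - 2`.
#' @param table A standardized `property_table`.
#' @return Non-negative scalar.
#' @export
tier_correlation <- function(window, j, table = standardized_table_cached()) {
  codes <- dinucleotide_codes(window_residues(window))
  n <- length(codes)
  j <- as.integer(j)
  if (j < 1L || j > n - 1L)
    stop("tier j = ", j, " out of range [1, ", n - 1L, "] for window length ", n + 1L)
  tm <- theta_matrix(table)
  idx <- seq_len(n - j)
  mean(tm[cbind(codes[idx], codes[idx + j])])
}

#' Encode windows as pseudo dinucleotide composition vectors
#'
#' The PseDNC feature vector of a window has `16 + lambda` components:
#' the first 16 are the (down-weighted) dinucleotide frequencies
#' `d_u = f_u / (sum_i f_i + w * sum_j theta_j)` and the remaining `lambda`
#' are the pseudo components `d_(16+j) = w * theta_j / (same denominator)`.
#' All components are non-negative and sum to 1.
#'
#' @param windows A single `site_window`/residue string, or a list/character
#'   vector of them (all lengths must satisfy `lambda <= L - 2`).
#' @param config A [psednc_config()].
#' @param table A `property_table`; a raw table is standardized
#'   automatically (population SD).
#' @return A numeric matrix with one row per window and `16 + lambda` named
#'   columns (`AA` ... `UU`, `theta1` ... `theta<lambda>`).
#' @examples
#' psednc(site_window(strrep("A", 51)))  # d_AA = 1, all else 0
#' @export
psednc <- function(windows, config = psednc_config(),
                   table = builtin_property_table()) {
  if (!inherits(config, "psednc_config")) stop("`config` must be a psednc_config")
  if (!is_standardized(table)) table <- standardize_properties(table)
  if (inherits(windows, "site_window") || is.character(windows) && length(windows) == 1L)
    windows <- list(windows)
  tm <- theta_matrix(table)
  lam <- config$lambda
  w <- config$w
  ids <- names(windows)
  if (is.null(ids) && length(windows) > 0L && inherits(windows[[1L]], "site_window"))
    ids <- vapply(windows, function(x) x$source_id, character(1))
  out <- matrix(0, nrow = length(windows), ncol = 16L + lam,
                dimnames = list(ids,
                                c(DINUCLEOTIDES, paste0("theta", seq_len(lam)))))
  for (r in seq_along(windows)) {
    res <- window_residues(windows[[r]])
    codes <- dinucleotide_codes(res)
    n <- length(codes)
    if (lam > n - 1L)
      stop("lambda = ", lam, " too large for window length ", n + 1L,
           " (need lambda <= L - 2)")
    f <- if (config$counting_mode == "non_overlapping")
      tabulate(codes[seq(1L, n, by = 2L)], 16L) / length(seq(1L, n, by = 2L))
    else
      tabulate(codes, 16L) / n
    theta <- vapply(seq_len(lam), function(j) {
      idx <- seq_len(n - j)
      mean(tm[cbind(codes[idx], codes[idx + j])])
    }, numeric(1))
    denom <- sum(f) + w * sum(theta)
    out[r, ] <- c(f, w * theta) / denom
  }
  out
}

# Standardized built-in table, computed once per session.
standardized_table_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- standardize_properties(builtin_property_table())
    cache
  }
})

#' Write a feature table to delimited text
#'
#' Batch output of [psednc()]: one row per window with identifier, optional
#' label, and the `16 + lambda` feature columns, tab-separated. With
#' `format = "libsvm"` writes the sparse `label idx:val ...` format used by
#' SVM command-line tools.
#'
#' @param features Matrix from [psednc()].
#' @param path Output path.
#' @param labels Optional vector of +1/-1 labels.
#' @param format `"tsv"` (default) or `"libsvm"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, labels = NULL,
                                format = c("tsv", "libsvm")) {
  format <- match.arg(format)
  ids <- rownames(features)
  if (is.null(ids)) ids <- paste0("window", seq_len(nrow(features)))
  if (!is.null(labels) && length(labels) != nrow(features))
    stop("`labels` length must match the number of rows")
  if (format == "tsv") {
    df <- data.frame(id = ids, stringsAsFactors = FALSE)
    if (!is.null(labels)) df$label <- labels
    df <- cbind(df, as.data.frame(features))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lab <- if (is.null(labels)) rep(0, nrow(features)) else labels
    lines <- vapply(seq_len(nrow(features)), function(i) {
      nz <- which(features[i, ] != 0)
      paste(lab[i], paste0(nz, ":", format(features[i, nz], digits = 12,
                                           trim = TRUE, scientific = FALSE),
                           collapse = " "))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
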