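#' Specification of a synthetic editing-site benchmark
#'
#' Describes a two-class dataset of fixed-length windows with a central
#' adenosine, sized like the fly editing-site benchmark (125 positive /
#' 119 negative 51-nt windows). Windows are drawn from a first-order Markov
#' chain over `{A, C, G, U}` whose transition weights are tilted by a
#' per-class dinucleotide bias map, so that dinucleotide composition — the
#' quantity PseDNC measures — is the controlled signal. `separation`
#' scales the contrast: at 0 both classes sample the same (uniform) chain,
#' at 1 the full bias applies. Default bias maps favor CG/GC in positives
#' and AU/UA in negatives with weight 8.
#'
#' @param n_pos,n_neg Class sizes (defaults 125 and 119).
#' @param window_length Odd window length (default 51).
#' @param separation Real in `[0, 1]` scaling the class contrast
#'   (default 0.5).
#' @param pos_bias,neg_bias Named numeric vectors mapping dinucleotides to
#'   positive weight multipliers (unnamed dinucleotides default to 1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 125L, n_neg = 119L, window_length = 51L,
                           separation = 0.5,
                           pos_bias = c(CG = 8, GC = 8),
                           neg_bias = c(AU = 8, UA = 8),
                           seed = 1L) {
  window_length <- as.integer(window_length)
  if (window_length %% 2L == 0L) stop("`window_length` must be odd")
  if (window_length < 3L) stop("`window_length` must be at least 3")
  if (separation < 0 || separation > 1) stop("`separation` must be in [0, 1]")
  for (b in list(pos_bias, neg_bias)) {
    if (length(b) && (is.null(names(b)) || !all(names(b) %in% DINUCLEOTIDES)))
      stop("bias maps must be named by RNA dinucleotides")
    if (any(b <= 0)) stop("bias weights must be positive")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window_length = window_length, separation = separation,
                 pos_bias = pos_bias, neg_bias = neg_bias,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# 4x4 transition matrix (rows = current base, cols = next base) from a bias
# map: weight(X -> Y) = bias(XY)^separation over a uniform base chain.
transition_matrix <- function(bias, separation) {
  w <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
  for (dn in names(bias))
    w[substr(dn, 1, 1), substr(dn, 2, 2)] <- bias[[dn]]^separation
  sweep(w, 1, rowSums(w), "/")
}

#' Generate a labeled synthetic window dataset
#'
#' Draws `n_pos + n_neg` windows from the class-specific Markov chains of a
#' [synthetic_spec()] and overwrites the central position with `A` (the
#' slight composition distortion this causes is accepted; see the package
#' vignette). Reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `windows` (list of `site_window`, positives first) and
#'   `labels` (+1/-1 vector).
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "U")
  draw <- function(n, trans, prefix) {
    lapply(seq_len(n), function(i) {
      b <- integer(spec$window_length)
      b[1L] <- sample.int(4L, 1L)
      for (p in 2L:spec$window_length)
        b[p] <- sample.int(4L, 1L, prob = trans[b[p - 1L], ])
      b[(spec$window_length + 1L) %/% 2L] <- 1L  # force central A
      site_window(paste(bases[b], collapse = ""),
                  source_id = sprintf("%s%03d", prefix, i))
    })
  }
  pos <- draw(spec$n_pos, transition_matrix(spec$pos_bias, spec$separation), "pos")
  neg <- draw(spec$n_neg, transition_matrix(spec$neg_bias, spec$separation), "neg")
  list(windows = c(pos, neg),
       labels = c(rep(1L, spec$n_pos), rep(-1L, spec$n_neg)))
}

#' Materialize a synthetic benchmark as FASTA files
#'
#' Writes the generated dataset in the shape editing-site benchmarks are
#' distributed: one FASTA of positive (editing-site) windows and one of
#' negative windows.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths (positive, negative), invisibly.
#' @export
write_benchmark_like <- function(spec, dir) {
  ds <- generate_dataset(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- vapply(ds$windows, function(w) w$residues, character(1))
  ids <- vapply(ds$windows, function(w) w$source_id, character(1))
  pos_path <- file.path(dir, "positive.fasta")
  neg_path <- file.path(dir, "negative.fasta")
  write_fasta(stats::setNames(res[ds$labels == 1L], ids[ds$labels == 1L]), pos_path)
  write_fasta(stats::setNames(res[ds$labels == -1L], ids[ds$labels == -1L]), neg_path)
  invisible(c(positive = pos_path, negative = neg_path))
}
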