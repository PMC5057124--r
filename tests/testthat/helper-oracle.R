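# Brute-force transcription of the PseDNC definition, kept deliberately
# separate from the production encoder: plain loops, string lookups, its own
# standardization. Used as the independent oracle in equivalence tests.

oracle_standardize <- function(raw) {
  out <- raw
  for (col in colnames(raw)) {
    x <- raw[, col]
    mu <- sum(x) / length(x)
    sdev <- sqrt(sum((x - mu)^2) / length(x))
    out[, col] <- (x - mu) / sdev
  }
  out
}

oracle_theta_fun <- function(d1, d2, ztab) {
  total <- 0
  for (u in seq_len(ncol(ztab)))
    total <- total + (ztab[d1, u] - ztab[d2, u])^2
  total / ncol(ztab)
}

oracle_psednc <- function(residues, w, lam, mode = "overlapping") {
  ztab <- oracle_standardize(unclass(builtin_property_table()))
  L <- nchar(residues)
  dinucs <- character(L - 1)
  for (i in seq_len(L - 1)) dinucs[i] <- substr(residues, i, i + 1)

  all16 <- paste0(rep(c("A", "C", "G", "U"), each = 4), c("A", "C", "G", "U"))
  counted <- if (mode == "overlapping") dinucs
             else dinucs[seq(1, L - 1, by = 2)]
  f <- numeric(16)
  names(f) <- all16
  for (d in counted) f[d] <- f[d] + 1 / length(counted)

  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    s <- 0
    for (i in seq_len(L - 1 - j))
      s <- s + oracle_theta_fun(dinucs[i], dinucs[i + j], ztab)
    theta[j] <- s / (L - 1 - j)
  }

  denom <- sum(f) + w * sum(theta)
  c(f, w * theta) / denom
}

# Random residue string of given length, drawn under the current RNG state.
random_residues <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Random 51-nt window string with the central A forced.
random_window51 <- function() {
  r <- strsplit(random_residues(51), "")[[1]]
  r[26] <- "A"
  paste(r, collapse = "")
}
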