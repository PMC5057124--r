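# Fixed lexicographic dinucleotide order used throughout the package.
DINUCLEOTIDES <- paste0(rep(c("A", "C", "G", "U"), each = 4L),
                        c("A", "C", "G", "U"))
PROPERTY_NAMES <- c("Shift", "Slide", "Rise", "Tilt", "Roll", "Twist")

# 16 dinucleotide steps x 6 local structural parameters.
# Shift/Slide/Rise in nm; Tilt/Roll/Twist in degrees.
RAW_PROPERTY_VALUES <- matrix(c(
  # Shift  Slide  Rise  Tilt   Roll  Twist
  -0.08, -1.27, 3.18, -0.80,  7.00, 31.00,  # AA
   0.23, -1.43, 3.24,  0.80,  4.80, 32.00,  # AC
  -0.04, -1.50, 3.30,  0.50,  8.50, 30.00,  # AG
  -0.06, -1.36, 3.24,  1.10,  7.10, 33.00,  # AU
   0.11, -1.46, 3.09,  1.00,  9.90, 31.00,  # CA
  -0.01, -1.78, 3.32,  0.30,  8.70, 32.00,  # CC
   0.30, -1.89, 3.30, -0.10, 12.10, 27.00,  # CG
  -0.04, -1.50, 3.30,  0.50,  8.50, 30.00,  # CU
   0.07, -1.70, 3.38,  1.30,  9.40, 32.00,  # GA
   0.07, -1.39, 3.22,  0.00,  6.10, 35.00,  # GC
  -0.01, -1.78, 3.32,  0.30, 12.10, 32.00,  # GG
   0.23, -1.43, 3.24,  0.80,  4.80, 32.00,  # GU
  -0.02, -1.45, 3.26, -0.20, 10.70, 32.00,  # UA
   0.07, -1.70, 3.38,  1.30,  9.40, 32.00,  # UC
   0.11, -1.46, 3.09,  1.00,  9.90, 31.00,  # UG
  -0.08, -1.27, 3.18, -0.80,  7.00, 31.00   # UU
), nrow = 16, ncol = 6, byrow = TRUE,
  dimnames = list(NULL, NULL))

#' Built-in RNA dinucleotide structure parameters
#'
#' Returns the raw (unstandardized) table of six local structural parameters
#' for the 16 RNA dinucleotide steps: the translational parameters Shift,
#' Slide and Rise (nm) and the angular parameters Tilt, Roll and Twist
#' (degrees). Rows are in fixed lexicographic order (AA, AC, ..., UU).
#'
#' @return A `property_table`: a 16 x 6 numeric matrix with dinucleotide row
#'   names, property column names, and attribute `standardized = FALSE`.
#' @examples
#' tab <- builtin_property_table()
#' tab["AA", "Shift"]  # -0.08
#' @export
builtin_property_table <- function() {
  m <- RAW_PROPERTY_VALUES
  dimnames(m) <- list(DINUCLEOTIDES, PROPERTY_NAMES)
  new_property_table(m, standardized = FALSE)
}

new_property_table <- function(values, standardized) {
  structure(values, standardized = standardized,
            class = c("property_table", class(values)))
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> 16 dinucleotides x %d properties (%s)\n",
              ncol(x), if (isTRUE(attr(x, "standardized")))
                "standardized" else "raw"))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Test whether a property table is standardized
#' @param table A `property_table`.
#' @return Logical scalar.
#' @export
is_standardized <- function(table) isTRUE(attr(table, "standardized"))

#' Standardize a property table
#'
#' Converts each property column to z-scores over the 16 dinucleotides:
#' `(P - mean(P)) / SD(P)`. After conversion every column has zero mean.
#' By default SD is the population standard deviation (divisor 16): the 16
#' dinucleotides are the entire population, and this matches canonical
#' pseudo-nucleotide-composition implementations. The sample convention
#' (divisor 15) is available for sensitivity analysis.
#'
#' @param table A raw `property_table`.
#' @param sd Either `"population"` (default) or `"sample"`.
#' @return A standardized `property_table`.
#' @export
standardize_properties <- function(table, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  table <- validate_property_table(table)
  m <- unclass(table)
  n <- nrow(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j])
    dev <- m[, j] - mu
    s <- if (sd == "population") sqrt(sum(dev^2) / n) else sqrt(sum(dev^2) / (n - 1))
    if (s == 0)
      stop("property column '", colnames(m)[j],
           "' is constant and cannot be standardized")
    out[, j] <- dev / s
  }
  new_property_table(out, standardized = TRUE)
}

#' Read a user-supplied property table
#'
#' Accepts a tab- or comma-separated file with a header row naming the
#' properties and a first column listing the 16 RNA dinucleotides (T is
#' accepted for U). The loader validates completeness: exactly the 16
#' dinucleotides, at least one numeric property column, no missing cells.
#'
#' @param path Path to the delimited text file.
#' @return A raw `property_table` with rows reordered to the fixed
#'   lexicographic dinucleotide order.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("property table needs a dinucleotide column plus >= 1 property column")
  dn <- chartr("tT", "uU", toupper(df[[1L]]))
  dn <- chartr("T", "U", dn)
  if (anyDuplicated(dn)) stop("duplicated dinucleotide rows in ", path)
  missing <- setdiff(DINUCLEOTIDES, dn)
  extra <- setdiff(dn, DINUCLEOTIDES)
  if (length(missing) || length(extra))
    stop("property table must cover exactly the 16 RNA dinucleotides",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("property values must be numeric with no missing cells")
  rownames(m) <- dn
  m <- m[DINUCLEOTIDES, , drop = FALSE]
  new_property_table(m, standardized = FALSE)
}

validate_property_table <- function(table) {
  if (!inherits(table, "property_table")) {
    if (!is.matrix(table) || !is.numeric(table))
      stop("`table` must be a property_table or a numeric matrix")
    if (is.null(rownames(table)) || !setequal(rownames(table), DINUCLEOTIDES))
      stop("property matrix must have the 16 RNA dinucleotides as row names")
    table <- new_property_table(table[DINUCLEOTIDES, , drop = FALSE],
                                standardized = FALSE)
  }
  if (nrow(table) != 16L) stop("property table must have 16 rows")
  if (anyNA(table)) stop("property table contains missing cells")
  table
}

# Stable fingerprint of a property table (polynomial rolling hash over the
# formatted values); used to detect encode/predict mismatches between a
# saved model and the table supplied at prediction time.
property_fingerprint <- function(table) {
  txt <- paste(rownames(table),
               apply(format(unclass(table), digits = 15), 1L, paste, collapse = ","),
               collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
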