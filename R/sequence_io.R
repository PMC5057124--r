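#' Normalize a raw sequence to the RNA alphabet
#'
#' Uppercases the input and converts thymidine (T) to uridine (U) so that
#' DNA-style input (e.g. sequences taken from genomic coordinates) can be
#' used directly. Any character outside `A`, `C`, `G`, `T`, `U` (either
#' case) is rejected; ambiguity codes such as `N` are not resolved because
#' the dinucleotide property lookup is undefined for them.
#'
#' @param raw A single non-empty character string.
#' @return The normalized string over the alphabet `{A, C, G, U}`.
#' @examples
#' normalize_rna("acgt")  # "ACGU"
#' @export
normalize_rna <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop("`raw` must be a single non-empty character string")
  up <- chartr("acgtu", "ACGTU", raw)
  bad <- regexpr("[^ACGTU]", up)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d (allowed: A, C, G, T, U)",
                 substr(raw, bad, bad), bad))
  chartr("T", "U", up)
}

#' Read sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file and normalizes
#' every record to the RNA alphabet via [normalize_rna()]. Record order is
#' preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of normalized residue strings; names are
#'   the FASTA identifiers (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found in ", path)
  ids <- sub("\\s.*$", "", names(set))
  res <- character(length(set))
  for (i in seq_along(set)) {
    res[i] <- tryCatch(normalize_rna(as.character(set[[i]])),
                       error = function(e)
                         stop(sprintf("record '%s': %s", ids[i], conditionMessage(e)),
                              call. = FALSE))
  }
  names(res) <- ids
  res
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of residue strings (as returned
#'   by [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (length(sequences) == 0L) warning("writing an empty FASTA file: ", path)
  set <- Biostrings::BStringSet(unname(as.character(sequences)))
  names(set) <- if (is.null(names(sequences)))
    paste0("seq", seq_along(sequences)) else names(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a site window
#'
#' A site window is the unit of prediction: an odd-length RNA window whose
#' central residue is the candidate adenosine. The default length is 51 nt,
#' placing the candidate A at 1-based position 26.
#'
#' @param residues Residue string over `{A, C, G, U}` (normalized if needed),
#'   of odd length with `A` at the central position.
#' @param source_id Identifier of the source sequence.
#' @param center_position_1based 1-based position of the candidate A in the
#'   source sequence (defaults to the window's own center).
#' @return An object of class `site_window`.
#' @export
site_window <- function(residues, source_id = "window",
                        center_position_1based = NULL) {
  residues <- normalize_rna(residues)
  len <- nchar(residues)
  if (len %% 2L == 0L) stop("window length must be odd, got ", len)
  if (len < 3L) stop("window must contain at least one flanking dinucleotide")
  mid <- (len + 1L) %/% 2L
  if (substr(residues, mid, mid) != "A")
    stop("center is not adenosine (position ", mid, " is '",
         substr(residues, mid, mid), "')")
  if (is.null(center_position_1based)) center_position_1based <- mid
  structure(list(source_id = as.character(source_id),
                 center_position_1based = as.integer(center_position_1based),
                 residues = residues,
                 window_length = len),
            class = "site_window")
}

#' @export
print.site_window <- function(x, ...) {
  cat(sprintf("<site_window> %s @ %d (%d nt)\n  %s\n",
              x$source_id, x$center_position_1based, x$window_length,
              x$residues))
  invisible(x)
}

#' Extract a fixed-length window around a candidate adenosine
#'
#' Returns the inclusive 1-based substring `[center - flank, center + flank]`
#' of the source sequence as a [site_window()]. No padding is performed: a
#' window extending past either end of the sequence is an error.
#'
#' @param sequence Residue string (normalized if needed).
#' @param center_1based 1-based position of the candidate adenosine.
#' @param flank Number of residues on each side of the center (default 25,
#'   giving the standard 51-nt window with the A at position 26).
#' @param source_id Identifier carried into the window.
#' @return A `site_window` of length `2 * flank + 1`.
#' @export
extract_window <- function(sequence, center_1based, flank = 25L,
                           source_id = "seq") {
  sequence <- normalize_rna(sequence)
  len <- nchar(sequence)
  center_1based <- as.integer(center_1based)
  flank <- as.integer(flank)
  if (flank < 1L) stop("`flank` must be >= 1")
  if (center_1based < 1L || center_1based > len)
    stop("center position ", center_1based, " outside sequence of length ", len)
  if (substr(sequence, center_1based, center_1based) != "A")
    stop("center is not adenosine")
  if (center_1based - flank < 1L || center_1based + flank > len)
    stop(sprintf("window [%d, %d] exceeds sequence bounds [1, %d]",
                 center_1based - flank, center_1based + flank, len))
  site_window(substr(sequence, center_1based - flank, center_1based + flank),
              source_id = source_id,
              center_position_1based = center_1based)
}

# Residue string of a window or plain character input, validated length >= 2.
window_residues <- function(x) {
  r <- if (inherits(x, "site_window")) x$residues else normalize_rna(x)
  if (nchar(r) < 2L) stop("sequence must contain at least one dinucleotide")
  r
}
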