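# IUPAC degenerate nucleotide alphabet: code tables, degeneracy, expansion,
# matching, reverse complement, and consensus construction.

# Base sets for the 15 IUPAC nucleotide codes.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Reverse lookup: sorted concatenated base set -> code.
IUPAC_CODE_FOR_SET <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(IUPAC_SETS), keys)
})

iupac_chars <- function(pattern, name = "pattern") {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop_validation(sprintf("`%s` must be a single string", name))
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, names(IUPAC_SETS))
  if (length(bad))
    stop_validation(sprintf("invalid IUPAC code(s) in `%s`: %s",
                            name, paste(unique(bad), collapse = ", ")))
  ch
}

#' Number of concrete sequences matching an IUPAC pattern
#'
#' The degeneracy of a pattern is the product over positions of the size of
#' each code's base set; e.g. an 11-mer of all `N` covers 4^11 = 4,194,304
#' sequences.
#'
#' @param pattern A string over the 15-letter IUPAC nucleotide alphabet.
#' @return A positive number (double, to accommodate large spaces).
#' @examples
#' degeneracy("GACRNANNACG")
#' degeneracy(strrep("N", 11))
#' @export
degeneracy <- function(pattern) {
  ch <- iupac_chars(pattern)
  if (!length(ch)) stop_validation("`pattern` must have length >= 1")
  prod(lengths(IUPAC_SETS[ch]))
}

#' Enumerate all concrete sequences matching an IUPAC pattern
#'
#' Intended for small patterns (used for consensus checks and as a
#' brute-force oracle); refuses expansions above `max_size`.
#'
#' @param pattern IUPAC pattern string.
#' @param max_size Refuse to enumerate more than this many sequences.
#' @return Character vector of distinct ACGT sequences, lexicographic order.
#' @export
iupac_expand <- function(pattern, max_size = 1e6) {
  ch <- iupac_chars(pattern)
  d <- prod(lengths(IUPAC_SETS[ch]))
  if (d > max_size)
    stop_validation(sprintf("expansion of %.0f sequences exceeds max_size", d))
  grid <- expand.grid(rev(IUPAC_SETS[ch]), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  sort(do.call(paste0, rev(grid)))
}

#' Test concrete sequences against an IUPAC pattern
#'
#' Case-insensitive, position-wise containment: `TRUE` iff every base of a
#' sequence lies in the corresponding code's base set. Pattern and sequences
#' must have equal length.
#'
#' @param pattern IUPAC pattern string.
#' @param sequences Character vector of ACGT sequences, same length as the
#'   pattern.
#' @return Logical vector, one element per sequence.
#' @examples
#' iupac_match("GACRNANNACG", "GACGTACAACG")
#' @export
iupac_match <- function(pattern, sequences) {
  ch <- iupac_chars(pattern)
  if (!is.character(sequences) || anyNA(sequences))
    stop_validation("`sequences` must be a character vector without NA")
  if (!length(sequences)) return(logical(0))
  if (any(nchar(sequences) != length(ch)))
    stop_validation("`sequences` must have the same length as `pattern`")
  mat <- toupper(seq_matrix(sequences))
  if (any(!mat %in% c("A", "C", "G", "T")))
    stop_validation("`sequences` must contain only A/C/G/T")
  ok <- rep(TRUE, length(sequences))
  for (p in seq_along(ch)) {
    ok <- ok & mat[, p] %in% IUPAC_SETS[[ch[p]]]
  }
  ok
}

#' Reverse complement with IUPAC-aware complementation
#'
#' Complements all 15 IUPAC codes (e.g. `R` <-> `Y`, `B` <-> `V`) and
#' preserves case, so patterns whose case marks critical bases keep their
#' annotation. Vectorised; an empty string maps to itself.
#'
#' @param x Character vector of sequences or IUPAC patterns.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ggaaacccttagag") # the reverse-orientation site
#' @export
revcomp <- function(x) {
  if (!is.character(x) || anyNA(x))
    stop_validation("`x` must be a character vector without NA")
  if (any(grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", x)))
    stop_validation("invalid nucleotide/IUPAC character in `x`")
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Build an IUPAC consensus from aligned sites
#'
#' For each column of an ungapped alignment, takes the set of bases whose
#' column frequency is at least `inclusion_frequency` and writes the minimal
#' IUPAC code covering that set; a column where no base reaches the
#' threshold becomes `N`.
#'
#' @param aligned_sites Character vector (>= 2) of equal-length ACGT sites.
#' @param inclusion_frequency Fraction in (0, 1]; a base must occur in at
#'   least this fraction of sites to enter the column's code.
#' @return A single IUPAC pattern string.
#' @examples
#' consensus_from_alignment(c("ACG", "ACG", "GCG", "GCT"), 0.25)
#' @export
consensus_from_alignment <- function(aligned_sites, inclusion_frequency) {
  if (!is.character(aligned_sites) || length(aligned_sites) < 2L)
    stop_validation("`aligned_sites` must be >= 2 sequences")
  assert_scalar_number(inclusion_frequency, "inclusion_frequency")
  if (inclusion_frequency <= 0 || inclusion_frequency > 1)
    stop_validation("`inclusion_frequency` must be in (0, 1]")
  if (length(unique(nchar(aligned_sites))) != 1L)
    stop_validation("`aligned_sites` must have equal lengths")
  assert_dna(aligned_sites, "aligned_sites")
  mat <- toupper(seq_matrix(aligned_sites))
  n <- nrow(mat)
  codes <- vapply(seq_len(ncol(mat)), function(j) {
    freq <- table(mat[, j]) / n
    keep <- sort(names(freq)[as.numeric(freq) >= inclusion_frequency - 1e-12])
    if (!length(keep)) return("N")
    IUPAC_CODE_FOR_SET[[paste(keep, collapse = "")]]
  }, "")
  paste(codes, collapse = "")
}
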