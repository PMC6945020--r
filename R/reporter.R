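# Reporter-assay analysis: fold induction of starved over replete
# fluorescence, localisation of the activating-sequence boundary from a
# truncation series, scanning-mutagenesis design, and classification of
# critical positions by case annotation.

sample_values <- function(x, name) {
  if (inherits(x, "fluorescence_sample")) return(x)
  if (is.numeric(x) && length(x) >= 1L)
    return(structure(list(condition = NA_character_, values = x,
                          background_mean = 0),
                     class = "fluorescence_sample"))
  stop_validation(sprintf("`%s` must be a fluorescence_sample or numeric vector",
                          name))
}

#' Fold induction of a reporter under starvation
#'
#' Ratio of the mean per-cell fluorescence under starvation to the mean
#' under nutrient-replete growth. With `subtract_background`, each
#' sample's own background mean is subtracted first; the numerator is
#' floored at a small positive epsilon, and a non-positive denominator is
#' an undefined-induction error.
#'
#' @param sample_starved,sample_replete `fluorescence_sample` objects (or
#'   bare numeric vectors of per-cell values, background 0).
#' @param subtract_background Subtract each sample's `background_mean`
#'   (default `FALSE`; assays are reported in raw arbitrary units with
#'   per-experiment controls).
#' @param epsilon Floor for the background-subtracted numerator.
#' @return Fold induction (real, >= 0).
#' @export
fold_induction <- function(sample_starved, sample_replete,
                           subtract_background = FALSE, epsilon = 1e-6) {
  st <- sample_values(sample_starved, "sample_starved")
  re <- sample_values(sample_replete, "sample_replete")
  num <- mean(st$values)
  den <- mean(re$values)
  if (subtract_background) {
    num <- max(num - st$background_mean, epsilon)
    den <- den - re$background_mean
  }
  if (den <= 0)
    selseq_error("undefined_induction",
                 "replete mean is non-positive after background subtraction")
  num / den
}

#' Localise the activating-sequence boundary in a truncation series
#'
#' Given inductions of progressively shorter promoters (sorted by
#' decreasing length; the first entry is the full-length reference), finds
#' the first adjacent pair where induction falls from at least
#' `(1 - drop_fraction)` of the reference to below it — a greater-than-90%
#' drop at the default. The element's 5' edge then lies between the two
#' truncation endpoints.
#'
#' @param series data.frame with columns `promoter_length` (strictly
#'   decreasing) and `induction` (>= 0).
#' @param drop_fraction Fractional decrease defining the cliff
#'   (default 0.9).
#' @return List of class `truncation_boundary`: `found`, and when found,
#'   `length_high` and `length_low`, the truncation endpoints bracketing
#'   the element's 5' edge.
#' @examples
#' s <- data.frame(promoter_length = c(1000, 260, 240), induction = c(50, 48, 2))
#' truncation_boundary(s, 0.9)
#' @export
truncation_boundary <- function(series, drop_fraction = 0.9) {
  if (!is.data.frame(series) ||
      !all(c("promoter_length", "induction") %in% names(series)))
    stop_validation("`series` needs columns promoter_length and induction")
  if (nrow(series) < 2L) stop_validation("`series` needs >= 2 entries")
  if (any(diff(series$promoter_length) >= 0))
    stop_validation("`series` must be sorted by strictly decreasing length")
  if (any(series$induction < 0)) stop_validation("inductions must be >= 0")
  assert_scalar_number(drop_fraction, "drop_fraction")
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop_validation("`drop_fraction` must be in (0, 1)")
  threshold <- (1 - drop_fraction) * series$induction[1L]
  above <- series$induction >= threshold
  for (i in seq_len(nrow(series) - 1L)) {
    if (above[i] && !above[i + 1L]) {
      return(structure(list(found = TRUE,
                            length_high = series$promoter_length[i],
                            length_low = series$promoter_length[i + 1L]),
                       class = "truncation_boundary"))
    }
  }
  structure(list(found = FALSE, length_high = NA_real_, length_low = NA_real_),
            class = "truncation_boundary")
}

#' Design a scanning-mutagenesis series
#'
#' Scheme `"TG"` makes two mutants per position: the native base is
#' replaced by T and by G, except that a native T becomes A (instead of T)
#' and a native G becomes C (instead of G). Scheme `"A"` makes one mutant
#' per position: to A, or to C where the native base is already A. No
#' mutant ever retains the native base at its position.
#'
#' @param region ACGT sequence to scan (case-insensitive).
#' @param scheme `"TG"` or `"A"`.
#' @return data.frame with columns `position` (1-based within the region),
#'   `original`, `replacement`, and `mutant_sequence`.
#' @examples
#' scanning_mutants("GACGTACAACG", "TG")
#' @export
scanning_mutants <- function(region, scheme = c("TG", "A")) {
  scheme <- match.arg(scheme)
  assert_dna(region, "region")
  if (length(region) != 1L || !nzchar(region))
    stop_validation("`region` must be a single non-empty sequence")
  bases <- strsplit(toupper(region), "", fixed = TRUE)[[1L]]
  rows <- list()
  for (p in seq_along(bases)) {
    repl <- if (scheme == "TG") {
      c(if (bases[p] == "T") "A" else "T",
        if (bases[p] == "G") "C" else "G")
    } else {
      if (bases[p] == "A") "C" else "A"
    }
    for (r in repl) {
      mut <- bases; mut[p] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, original = bases[p], replacement = r,
        mutant_sequence = paste(mut, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify critical positions from scanning-mutagenesis inductions
#'
#' A position is critical when every tested replacement there drops
#' induction below `critical_cutoff` times the reference; the region is
#' returned with critical positions in uppercase and the rest lowercase
#' (e.g. `"gACGTacaacG"`). Positions with no measurements are lowercase.
#'
#' @param region The scanned ACGT region.
#' @param reference_induction Fold induction of the unmutated construct
#'   (> 0).
#' @param mutant_inductions data.frame with columns `position`,
#'   `replacement`, `induction`.
#' @param critical_cutoff Fraction of the reference below which a mutant
#'   counts as defective (default 0.2).
#' @return Case-annotated region string.
#' @export
classify_critical <- function(region, reference_induction, mutant_inductions,
                              critical_cutoff = 0.2) {
  assert_dna(region, "region")
  assert_scalar_number(reference_induction, "reference_induction")
  if (reference_induction <= 0)
    stop_validation("`reference_induction` must be > 0")
  if (!is.data.frame(mutant_inductions) ||
      !all(c("position", "induction") %in% names(mutant_inductions)))
    stop_validation("`mutant_inductions` needs columns position and induction")
  assert_scalar_number(critical_cutoff, "critical_cutoff")
  if (critical_cutoff <= 0 || critical_cutoff >= 1)
    stop_validation("`critical_cutoff` must be in (0, 1)")
  n <- nchar(region)
  if (any(mutant_inductions$position < 1 | mutant_inductions$position > n))
    stop_validation("mutant positions outside the region")
  cutoff <- critical_cutoff * reference_induction
  bases <- strsplit(tolower(region), "", fixed = TRUE)[[1L]]
  for (p in unique(mutant_inductions$position)) {
    ind <- mutant_inductions$induction[mutant_inductions$position == p]
    if (all(ind < cutoff)) bases[p] <- toupper(bases[p])
  }
  paste(bases, collapse = "")
}
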