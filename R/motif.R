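# Promoter scanning with degenerate patterns and ungapped best-match
# alignment of candidate elements.
#
# Coordinate convention: promoter sequences are written 5'->3' and end
# immediately before the start codon, so positions are reported as negative
# offsets upstream of the ATG (-260 = the base 260 bp upstream). Internally
# 1-based string indices are used and converted at the reporting boundary.

# Offsets (1-based, within `chars`) where `pattern_chars` matches under
# IUPAC containment.
iupac_offsets <- function(pattern_chars, chars) {
  L <- length(pattern_chars)
  n_off <- length(chars) - L + 1L
  if (n_off < 1L) return(integer(0))
  ok <- rep(TRUE, n_off)
  for (p in seq_len(L)) {
    ok <- ok & chars[seq_len(n_off) + p - 1L] %in% IUPAC_SETS[[pattern_chars[p]]]
  }
  which(ok)
}

#' Scan promoters for an IUPAC consensus pattern
#'
#' Scans the `window` 3'-most bases of each promoter (the stretch nearest
#' the start codon, as in a 1-kb-upstream search) for exact IUPAC matches of
#' `pattern`, optionally on both strands. Promoters shorter than the pattern
#' are skipped with a warning.
#'
#' @param pattern IUPAC pattern string.
#' @param promoters Named character vector of promoter sequences (names are
#'   gene identifiers), or a `Biostrings::DNAStringSet`.
#' @param window Number of 3'-most bases to scan (default 1000); promoters
#'   shorter than the window are scanned in full.
#' @param both_strands Also scan the reverse strand (default `FALSE`;
#'   consensus patterns here are directional).
#' @return A list with `matches` — a data.frame with columns `target_name`,
#'   `start` (negative offset of the match's 5'-most promoter base upstream
#'   of the start codon), `strand`, `matched_subsequence` (plus-strand
#'   text), `identities`, `pattern_length` — and `n_promoters_with_match`,
#'   the number of promoters with at least one hit.
#' @export
scan_promoters <- function(pattern, promoters, window = 1000,
                           both_strands = FALSE) {
  pat <- iupac_chars(pattern)
  L <- length(pat)
  assert_scalar_number(window, "window")
  if (window < L) stop_validation("`window` must be >= pattern length")
  promoters <- as_named_sequences(promoters, "promoters")
  pat_rc <- if (both_strands) iupac_chars(revcomp(paste(pat, collapse = "")))
            else NULL

  rows <- list()
  hit_promoters <- character(0)
  for (nm in names(promoters)) {
    s <- toupper(promoters[[nm]])
    n <- nchar(s)
    if (n < L) {
      warning(sprintf("promoter '%s' (%d bp) is shorter than the pattern; skipped",
                      nm, n), call. = FALSE)
      next
    }
    w <- as.integer(min(window, n))
    win_start <- n - w + 1L
    chars <- strsplit(substr(s, win_start, n), "", fixed = TRUE)[[1L]]
    strands <- list(`+` = pat)
    if (both_strands) strands[["-"]] <- pat_rc
    for (st in names(strands)) {
      off <- iupac_offsets(strands[[st]], chars)
      if (!length(off)) next
      i <- win_start + off - 1L            # 1-based index in full promoter
      rows[[length(rows) + 1L]] <- data.frame(
        target_name = nm,
        start = -(n - i + 1L),
        strand = st,
        matched_subsequence = substring(s, i, i + L - 1L),
        identities = L,
        pattern_length = L,
        stringsAsFactors = FALSE
      )
      hit_promoters <- union(hit_promoters, nm)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_name = character(0), start = integer(0),
               strand = character(0), matched_subsequence = character(0),
               identities = integer(0), pattern_length = integer(0),
               stringsAsFactors = FALSE)
  matches <- matches[order(matches$target_name, matches$start,
                           matches$strand), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches, n_promoters_with_match = length(hit_promoters))
}

#' Best ungapped match of a query sequence in a target
#'
#' Slides the query over every offset of the target (and, optionally, the
#' reverse strand), counts positional base identities, and returns the
#' maximum. Ties are broken by smallest offset, then the plus strand, for
#' deterministic reports. This is the comparison used to relate enriched
#' selection winners to native promoter elements (e.g. a 10/11 bp match).
#'
#' @param query ACGT query sequence (case-insensitive).
#' @param target ACGT target sequence, at least as long as the query.
#' @param both_strands Also try the reverse complement of the query.
#' @param target_name Optional identifier recorded in the result.
#' @return One-row data.frame with `target_name`, `start` (1-based offset in
#'   the target), `upstream_start` (negative offset of that base from the
#'   target 3' end), `strand`, `matched_subsequence` (plus-strand target
#'   text), `identities`, `pattern_length`.
#' @export
best_ungapped_match <- function(query, target, both_strands = FALSE,
                                target_name = NA_character_) {
  assert_dna(query, "query"); assert_dna(target, "target")
  if (length(query) != 1L || length(target) != 1L)
    stop_validation("`query` and `target` must be single sequences")
  m <- nchar(query); n <- nchar(target)
  if (m < 1L) stop_validation("`query` must be non-empty")
  if (m > n) stop_validation("`query` is longer than `target`")
  tchars <- strsplit(toupper(target), "", fixed = TRUE)[[1L]]
  queries <- list(`+` = strsplit(toupper(query), "", fixed = TRUE)[[1L]])
  if (both_strands)
    queries[["-"]] <- strsplit(toupper(revcomp(query)), "", fixed = TRUE)[[1L]]

  best <- list(identities = -1L, start = NA_integer_, strand = NA_character_)
  n_off <- n - m + 1L
  for (st in names(queries)) {
    q <- queries[[st]]
    ids <- integer(n_off)
    for (p in seq_len(m)) {
      ids <- ids + (tchars[seq_len(n_off) + p - 1L] == q[p])
    }
    o <- which.max(ids)  # earliest offset among ties
    if (ids[o] > best$identities) {
      best <- list(identities = as.integer(ids[o]), start = as.integer(o),
                   strand = st)
    }
  }
  data.frame(
    target_name = target_name,
    start = best$start,
    upstream_start = -(n - best$start + 1L),
    strand = best$strand,
    matched_subsequence = substring(target, best$start, best$start + m - 1L),
    identities = best$identities,
    pattern_length = m,
    stringsAsFactors = FALSE
  )
}

# Coerce promoter input to a named character vector.
as_named_sequences <- function(x, name) {
  if (methods_is_dnastringset(x)) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop_validation(sprintf("`%s` must be a named character vector or DNAStringSet", name))
  as.list(x)
}

methods_is_dnastringset <- function(x) {
  inherits(x, "XStringSet")
}
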