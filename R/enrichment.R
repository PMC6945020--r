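# Read counting and fold-enrichment scoring: variable-region extraction
# between constant flanks, unique-sequence counting, top-k abundance
# summaries, pseudocount-regularised fold enrichment against the time-zero
# sample, and the pathway-dependence filter against the deletion-strain
# control selection.

REJECTION_LEVELS <- c("ok", "flank-not-found", "wrong-length", "ambiguous-base")

# Best offset (1-based) in `chars` at/after `from` where `flank` matches
# with at most `max_mm` substitutions: fewest mismatches wins, leftmost on
# ties (so an approximate hit never shadows an exact flank one base away).
# NA when nothing qualifies.
best_approx_match <- function(chars, flank, max_mm, from = 1L) {
  m <- length(flank)
  last <- length(chars) - m + 1L
  if (last < from) return(NA_integer_)
  best_o <- NA_integer_
  best_mm <- max_mm + 1L
  for (o in from:last) {
    mm <- sum(chars[o:(o + m - 1L)] != flank)
    if (mm < best_mm) {
      best_mm <- mm
      best_o <- o
      if (mm == 0L) break
    }
  }
  if (best_mm <= max_mm) best_o else NA_integer_
}

#' Extract variable regions between constant flanks
#'
#' For each read, locates the 5' flank and then the 3' flank (each
#' allowing up to `max_flank_mismatch` substitutions; the fewest-mismatch
#' position wins, leftmost on ties) and returns the intervening sequence
#' if it has the expected
#' length and contains only A/C/G/T. Failures are typed rejections, not
#' errors: `flank-not-found`, `wrong-length`, or `ambiguous-base`.
#'
#' @param reads Character vector of reads (case-insensitive).
#' @param flank5,flank3 Constant flanking sequences.
#' @param region_length Expected variable-region length.
#' @param max_flank_mismatch Substitutions tolerated per flank (default 1).
#' @return A data.frame with columns `region` (NA on rejection) and
#'   `status` (one of ok / flank-not-found / wrong-length /
#'   ambiguous-base).
#' @export
extract_variable_region <- function(reads, flank5, flank3, region_length,
                                    max_flank_mismatch = 1) {
  assert_dna(flank5, "flank5"); assert_dna(flank3, "flank3")
  if (!nzchar(flank5) || !nzchar(flank3))
    stop_validation("flanks must be non-empty")
  assert_scalar_number(region_length, "region_length")
  if (region_length < 1) stop_validation("`region_length` must be >= 1")
  if (max_flank_mismatch < 0)
    stop_validation("`max_flank_mismatch` must be >= 0")
  if (!is.character(reads)) stop_validation("`reads` must be character")
  f5 <- strsplit(toupper(flank5), "", fixed = TRUE)[[1L]]
  f3 <- strsplit(toupper(flank3), "", fixed = TRUE)[[1L]]

  region <- rep(NA_character_, length(reads))
  status <- rep("flank-not-found", length(reads))
  for (i in seq_along(reads)) {
    chars <- strsplit(toupper(reads[i]), "", fixed = TRUE)[[1L]]
    o5 <- best_approx_match(chars, f5, max_flank_mismatch)
    if (is.na(o5)) next
    o3 <- best_approx_match(chars, f3, max_flank_mismatch,
                            from = o5 + length(f5))
    if (is.na(o3)) next
    mid <- chars[seq.int(o5 + length(f5), length.out = o3 - o5 - length(f5))]
    if (length(mid) != region_length) {
      status[i] <- "wrong-length"
    } else if (any(!mid %in% c("A", "C", "G", "T"))) {
      status[i] <- "ambiguous-base"
    } else {
      region[i] <- paste(mid, collapse = "")
      status[i] <- "ok"
    }
  }
  data.frame(region = region,
             status = factor(status, levels = REJECTION_LEVELS),
             stringsAsFactors = FALSE)
}

#' Count unique variable-region sequences
#'
#' Exact multiset count of extracted regions, with sample metadata and the
#' accounting invariant `sum(counts) + rejected_reads = total_reads`.
#'
#' @param regions Character vector of accepted region sequences.
#' @param rejected_reads Number of reads rejected upstream (default 0).
#' @param sample_id,strain,time,replicate Optional sample metadata.
#' @return List of class `count_table` with `counts` (named numeric,
#'   decreasing then lexicographic), `n_unique`, `total_reads`,
#'   `rejected_reads` and the metadata fields.
#' @export
count_unique <- function(regions, rejected_reads = 0, sample_id = NA_character_,
                         strain = NA_character_, time = NA_character_,
                         replicate = NA_integer_) {
  if (!is.character(regions)) stop_validation("`regions` must be character")
  if (anyNA(regions)) stop_validation("`regions` must not contain NA")
  tab <- table(regions)
  counts <- stats::setNames(as.double(tab), names(tab))
  ord <- order(-counts, names(counts))
  structure(list(sample_id = sample_id, strain = strain, time = time,
                 replicate = replicate, counts = counts[ord],
                 n_unique = length(counts),
                 total_reads = length(regions) + rejected_reads,
                 rejected_reads = rejected_reads),
            class = "count_table")
}

#' Extract and count in one step
#'
#' Convenience wrapper: [extract_variable_region()] followed by
#' [count_unique()], with rejections recorded in the table.
#'
#' @inheritParams extract_variable_region
#' @inheritParams count_unique
#' @return A `count_table`.
#' @export
count_reads <- function(reads, flank5, flank3, region_length,
                        max_flank_mismatch = 1, sample_id = NA_character_,
                        strain = NA_character_, time = NA_character_,
                        replicate = NA_integer_) {
  ex <- extract_variable_region(reads, flank5, flank3, region_length,
                                max_flank_mismatch)
  count_unique(ex$region[ex$status == "ok"],
               rejected_reads = sum(ex$status != "ok"),
               sample_id = sample_id, strain = strain, time = time,
               replicate = replicate)
}

as_counts <- function(x, name) {
  if (inherits(x, "count_table")) return(x$counts)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop_validation(sprintf("`%s` must be a count_table or named numeric vector",
                          name))
}

#' Fraction of counted reads in the k most abundant sequences
#'
#' Ties are broken lexicographically for reproducible reports; `k` beyond
#' the number of unique sequences returns 1.
#'
#' @param table A `count_table` or named numeric count vector.
#' @param k Number of top sequences (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
top_k_fraction <- function(table, k) {
  counts <- as_counts(table, "table")
  assert_scalar_number(k, "k")
  if (k < 1) stop_validation("`k` must be >= 1")
  if (!length(counts) || sum(counts) <= 0)
    selseq_error("empty_table", "no counted reads")
  ord <- order(-counts, names(counts))
  sum(counts[ord][seq_len(min(k, length(counts)))]) / sum(counts)
}

#' Pseudocount-regularised fold enrichment
#'
#' For every sequence in the union of the two tables, the ratio of
#' post-selection to pre-selection relative frequency, each regularised by
#' adding `pseudocount` reads per sequence (and `pseudocount * U` to the
#' totals, `U` the union size). With `pseudocount > 0`, sequences unseen
#' before selection get finite folds instead of infinities.
#'
#' @param pre,post `count_table`s or named numeric count vectors with
#'   positive totals.
#' @param pseudocount Non-negative regularising count (default 1 read).
#' @return Named numeric vector of folds over the union of sequences,
#'   lexicographic order.
#' @export
fold_enrichment <- function(pre, post, pseudocount = 1) {
  pre_c <- as_counts(pre, "pre"); post_c <- as_counts(post, "post")
  if (pseudocount < 0) stop_validation("`pseudocount` must be >= 0")
  if (sum(pre_c) <= 0 && sum(post_c) <= 0)
    selseq_error("empty_table", "both tables have zero totals")
  if (sum(pre_c) <= 0 || sum(post_c) <= 0)
    stop_validation("`pre` and `post` totals must both be > 0")
  seqs <- sort(union(names(pre_c), names(post_c)))
  u <- length(seqs)
  a <- ifelse(is.na(pre_c[seqs]), 0, pre_c[seqs])
  b <- ifelse(is.na(post_c[seqs]), 0, post_c[seqs])
  post_freq <- (b + pseudocount) / (sum(post_c) + pseudocount * u)
  pre_freq <- (a + pseudocount) / (sum(pre_c) + pseudocount * u)
  stats::setNames(as.double(post_freq / pre_freq), seqs)
}

#' Pathway-dependent enriched set
#'
#' A sequence is called pathway-dependent when its wild-type fold
#' enrichment exceeds `wt_threshold` — in every replicate if
#' `require_all_replicates`, otherwise by the replicate mean — while its
#' fold in the pathway-deletion control stays below `control_ceiling`.
#' Sequences enriched in both strains express independently of the pathway
#' (constitutive) and are excluded.
#'
#' @param wt_folds A named numeric fold vector (one replicate) or a list of
#'   them (one per independently grown wild-type culture).
#' @param control_folds Named numeric fold vector for the deletion-strain
#'   control; sequences absent from it are treated as not control-enriched.
#' @param wt_threshold Wild-type fold threshold (default 90).
#' @param control_ceiling Control fold ceiling (default 10).
#' @param require_all_replicates Demand the threshold in every replicate
#'   rather than on the mean (default `FALSE`).
#' @return A data.frame of the passing records — columns `sequence`,
#'   per-replicate `fold_wt_<r>`, `mean_fold_wt`, `mean_fold_control`,
#'   `pathway_dependent` (all `TRUE`) — ordered by decreasing mean fold.
#'   The full record table (all sequences, with the flag) is in attribute
#'   `all_records`.
#' @export
pathway_dependent_set <- function(wt_folds, control_folds, wt_threshold = 90,
                                  control_ceiling = 10,
                                  require_all_replicates = FALSE) {
  if (!is.list(wt_folds)) wt_folds <- list(wt_folds)
  if (!length(wt_folds)) stop_validation("need >= 1 wild-type replicate")
  wt_folds <- lapply(wt_folds, as_counts, name = "wt_folds")
  control_folds <- as_counts(control_folds, "control_folds")
  if (wt_threshold <= 0 || control_ceiling <= 0)
    stop_validation("thresholds must be > 0")
  seqs <- sort(Reduce(union, lapply(wt_folds, names)))
  mat <- vapply(wt_folds, function(f) as.double(f[seqs]), numeric(length(seqs)))
  mat <- matrix(mat, nrow = length(seqs),
                dimnames = list(seqs, paste0("fold_wt_", seq_along(wt_folds))))
  mean_wt <- rowMeans(mat, na.rm = TRUE)
  pass_wt <- if (require_all_replicates) {
    apply(mat, 1L, function(r) all(r[!is.na(r)] > wt_threshold) && any(!is.na(r)))
  } else {
    mean_wt > wt_threshold
  }
  ctrl <- as.double(control_folds[seqs])
  pass_ctrl <- is.na(ctrl) | ctrl < control_ceiling
  records <- data.frame(sequence = seqs, mat, mean_fold_wt = mean_wt,
                        mean_fold_control = ctrl,
                        pathway_dependent = pass_wt & pass_ctrl,
                        stringsAsFactors = FALSE, row.names = NULL)
  records <- records[order(-records$mean_fold_wt, records$sequence), ,
                     drop = FALSE]
  rownames(records) <- NULL
  out <- records[records$pathway_dependent, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_records") <- records
  out
}
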