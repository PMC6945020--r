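# Extraction, counting, fold enrichment and the pathway-dependence filter.

test_that("variable regions are extracted between exact flanks", {
  ex <- extract_variable_region(c("GGAAATT", "GGAATT", "GGAANTT"),
                                "GG", "TT", 3, max_flank_mismatch = 0)
  expect_identical(ex$region, c("AAA", NA, NA))
  expect_identical(as.character(ex$status),
                   c("ok", "wrong-length", "ambiguous-base"))
})

test_that("flank matching tolerates the stated number of mismatches", {
  # One substitution anywhere in a flank must still extract; verified
  # exhaustively over every single-mismatch corruption of both flanks.
  # Corruptions that happen to create an exact copy of the flank at a
  # shifted position make the read genuinely ambiguous (the exact copy
  # rightly wins) and are excluded from the expectation.
  f5 <- "GGACG"; f3 <- "TTGCA"; region <- "ACGTACGTACG"
  bases <- c("A", "C", "G", "T")
  for (which_flank in c(5L, 3L)) {
    flank <- if (which_flank == 5L) f5 else f3
    intended_start <- if (which_flank == 5L) 1L else nchar(f5) + nchar(region) + 1L
    for (p in seq_len(nchar(flank))) {
      for (b in setdiff(bases, substr(flank, p, p))) {
        corrupted <- flank
        substr(corrupted, p, p) <- b
        read <- if (which_flank == 5L) paste0(corrupted, region, f3)
                else paste0(f5, region, corrupted)
        exact_at <- as.integer(gregexpr(flank, read, fixed = TRUE)[[1]])
        if (any(exact_at > 0 & exact_at != intended_start)) next
        ex1 <- extract_variable_region(read, f5, f3, 11, max_flank_mismatch = 1)
        ex0 <- extract_variable_region(read, f5, f3, 11, max_flank_mismatch = 0)
        expect_identical(ex1$region, region)
        expect_false(identical(ex0$region, region))
      }
    }
  }
})

test_that("reads without flanks are typed rejections, and accounting balances", {
  reads <- c("GGAAATT", "CCCCCCC", "GGAAAT")
  tab <- count_reads(reads, "GG", "TT", 3, max_flank_mismatch = 0)
  expect_identical(tab$counts, c(AAA = 1))
  expect_identical(tab$rejected_reads, 2L)
  expect_identical(sum(tab$counts) + tab$rejected_reads, 3)
})

test_that("unique counting is an exact multiset count", {
  tab <- count_unique(c("A", "A", "B"))
  expect_identical(tab$counts, c(A = 2, B = 1))
  expect_identical(tab$n_unique, 2L)
  # Pigeonhole at screen depth.
  lib <- gen_library(5000, 11, seed = 23)
  reads <- gen_reads(stats::setNames(lib$initial_frequency * 1e6, lib$sequence),
                     depth = 3500, error_rate = 0, seed = 24)
  tab2 <- count_unique(attr(reads, "true_region"))
  expect_lte(tab2$n_unique, 3500L)
  expect_true(all(names(tab2$counts) %in% lib$sequence))
})

test_that("top-k abundance fractions follow the definition", {
  tab <- c(A = 5, B = 3, C = 2)
  expect_equal(top_k_fraction(tab, 2), 0.8)
  expect_equal(top_k_fraction(tab, 3), 1)
  expect_equal(top_k_fraction(tab, 10), 1)
  # Non-decreasing in k, bounded by [0, 1].
  set.seed(41)
  counts <- stats::setNames(rpois(30, 20) + 1, random_dna(30, 6))
  fr <- vapply(1:30, top_k_fraction, 0, table = counts)
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(top_k_fraction(numeric(0), 1), class = "selseq_error_validation")
})

test_that("ties in top-k are broken lexicographically", {
  # All equal counts: any k selects the k lexicographically smallest, and
  # the fraction is k/n regardless - check determinism of the selection.
  tab <- c(TT = 2, AA = 2, GG = 2, CC = 2)
  expect_equal(top_k_fraction(tab, 2), 0.5)
})

test_that("fold enrichment reproduces hand-computed values exactly", {
  # pre {A:10, B:990}, post {A:500, B:500}, no pseudocount -> fold(A) = 50.
  folds <- fold_enrichment(c(A = 10, B = 990), c(A = 500, B = 500),
                           pseudocount = 0)
  expect_equal(unname(folds["A"]), 50, tolerance = 1e-12)
  expect_equal(unname(folds["B"]), (500 / 1000) / (990 / 1000), tolerance = 1e-12)
  # Hand-computed pseudocount case on a 3-sequence union.
  pre <- c(A = 8, B = 2); post <- c(A = 1, C = 9); pc <- 1
  u <- 3
  expected_a <- ((1 + pc) / (10 + pc * u)) / ((8 + pc) / (10 + pc * u))
  expected_c <- ((9 + pc) / (10 + pc * u)) / ((0 + pc) / (10 + pc * u))
  folds2 <- fold_enrichment(pre, post, pc)
  expect_equal(unname(folds2["A"]), expected_a, tolerance = 1e-12)
  expect_equal(unname(folds2["C"]), expected_c, tolerance = 1e-12)
})

test_that("identical pre and post tables give fold 1 for any pseudocount", {
  set.seed(43)
  tab <- stats::setNames(rpois(20, 30) + 1, random_dna(20, 11))
  for (pc in c(0, 0.5, 1, 5)) {
    expect_equal(unname(fold_enrichment(tab, tab, pc)),
                 rep(1, 20), tolerance = 1e-12)
  }
})

test_that("sequences unseen before selection get finite folds above 1", {
  folds <- fold_enrichment(c(A = 100), c(A = 50, B = 50), pseudocount = 1)
  expect_true(is.finite(folds[["B"]]))
  expect_gt(folds[["B"]], 1)
})

test_that("the control filter removes constitutively enriched sequences", {
  wt <- list(c(SEQCONST = 200, SEQFUN = 150, OTHER = 1),
             c(SEQCONST = 210, SEQFUN = 120, OTHER = 0.9))
  ctrl <- c(SEQCONST = 180, SEQFUN = 1.5, OTHER = 1.1)
  pd <- pathway_dependent_set(wt, ctrl)
  expect_identical(pd$sequence, "SEQFUN")
  expect_true(all(pd$pathway_dependent))
})

test_that("threshold semantics: mean rule, all-replicate rule, ceiling", {
  wt <- list(c(X = 100), c(X = 120), c(X = 95))
  expect_identical(pathway_dependent_set(wt, c(X = 1.2))$sequence, "X")
  # One replicate below threshold still passes by mean, fails the strict rule.
  wt2 <- list(c(X = 100), c(X = 80), c(X = 120))
  expect_identical(pathway_dependent_set(wt2, c(X = 1))$sequence, "X")
  expect_identical(nrow(pathway_dependent_set(wt2, c(X = 1),
                                              require_all_replicates = TRUE)),
                   0L)
  # Control at the ceiling excludes.
  expect_identical(nrow(pathway_dependent_set(wt, c(X = 50))), 0L)
  # Absent from the control map counts as not control-enriched.
  expect_identical(pathway_dependent_set(wt, c(OTHER = 1))$sequence, "X")
})

test_that("planted functional variants are recovered end to end", {
  # library -> selection -> reads -> counts -> folds -> filter, with the
  # deletion-strain control removing the constitutive plants.
  run <- run_pipeline(pipeline_config(seed = 7))
  truth <- run$library$sequence[run$library$is_functional]
  expect_setequal(run$pathway_dependent$sequence, truth)
  expect_identical(run$summary$precision_vs_planted, 1)
  expect_identical(run$summary$recall_vs_planted, 1)
})
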