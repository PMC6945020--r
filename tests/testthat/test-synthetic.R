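# Synthetic-data generators: library bias structure, sequencing sampling,
# fluorescence distribution, and seeded reproducibility.

test_that("the near-uniform limit yields four equal 1-mers", {
  lib <- gen_library(4, length = 1, bias_concentration = 1e9, seed = 1)
  expect_setequal(lib$sequence, c("A", "C", "G", "T"))
  expect_equal(sum(lib$initial_frequency), 1, tolerance = 1e-9)
  expect_true(all(abs(lib$initial_frequency - 0.25) < 0.01))
})

test_that("a 90,000-variant 11-mer library is distinct, normalised and biased", {
  lib <- gen_library(90000, length = 11, seed = 5)
  expect_identical(nrow(lib), 90000L)
  expect_identical(anyDuplicated(lib$sequence), 0L)
  expect_equal(sum(lib$initial_frequency), 1, tolerance = 1e-9)
  expect_true(all(nchar(lib$sequence) == 11))
  # Default concentration puts the top-20 share at the ~10% scale, far above
  # the uniform 20/90000.
  top20 <- top_k_fraction(stats::setNames(lib$initial_frequency, lib$sequence), 20)
  expect_gt(top20, 0.03)
  expect_lt(top20, 0.3)
})

test_that("smaller bias concentration concentrates the library more", {
  skewed <- gen_library(100, 11, bias_concentration = 0.05,
                        n_functional = 5, n_constitutive = 2, seed = 7)
  flat <- gen_library(100, 11, bias_concentration = 100,
                      n_functional = 5, n_constitutive = 2, seed = 7)
  f <- function(lib) top_k_fraction(
    stats::setNames(lib$initial_frequency, lib$sequence), 20)
  expect_gt(f(skewed), f(flat))
})

test_that("functional variants carry the core motif and others never do", {
  lib <- gen_library(300, 11, n_functional = 8, n_constitutive = 3, seed = 9)
  core <- attr(lib, "functional_core")
  expect_identical(core, "NACGTNNNNNG")
  expect_true(all(iupac_match(core, lib$sequence[lib$is_functional])))
  expect_false(any(iupac_match(core, lib$sequence[!lib$is_functional])))
  expect_false(any(lib$is_functional & lib$is_constitutive))
  expect_identical(sum(lib$is_functional), 8L)
  expect_identical(sum(lib$is_constitutive), 3L)
})

test_that("library generation is deterministic and validates its space", {
  expect_identical(gen_library(50, 5, seed = 3), gen_library(50, 5, seed = 3))
  expect_error(gen_library(5, length = 1),
               class = "selseq_error_infeasible_library")
  expect_error(gen_library(10, 11, n_functional = 11),
               class = "selseq_error_validation")
})

test_that("a single error-free variant yields identical flanked reads", {
  r <- gen_reads(c(AAA = 1), depth = 5, flank5 = "GG", flank3 = "TT",
                 error_rate = 0, seed = 0)
  expect_identical(as.character(r), rep("GGAAATT", 5))
})

test_that("read sampling follows the multinomial and the requested depth", {
  r <- gen_reads(c(A = 900, C = 100), depth = 10000, flank5 = "GG",
                 flank3 = "TT", error_rate = 0, seed = 3)
  expect_length(r, 10000)
  frac_a <- mean(attr(r, "true_region") == "A")
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(frac_a - 0.9), 3 * se)
  # The per-sample depth used in the screen.
  r2 <- gen_reads(c(AAAAAAAAAAA = 3), depth = 3500, error_rate = 0, seed = 1)
  expect_length(r2, 3500)
})

test_that("error-free reads contain only input variable regions", {
  counts <- stats::setNames(c(5, 3, 2), c("ACGTACGTACG", "TTTTTTTTTTT",
                                          "GACGTACAACG"))
  r <- gen_reads(counts, depth = 200, error_rate = 0, seed = 4)
  tab <- count_reads(r, attr(r, "flank5"), attr(r, "flank3"), 11,
                     max_flank_mismatch = 0)
  expect_true(all(names(tab$counts) %in% names(counts)))
  expect_identical(sum(tab$counts), 200)
})

test_that("read generation is byte-identical under one seed and errs on empty input", {
  counts <- c(ACG = 2, TGA = 1)
  expect_identical(gen_reads(counts, 50, seed = 8), gen_reads(counts, 50, seed = 8))
  expect_error(gen_reads(c(ACG = 0), 10), class = "selseq_error_empty_population")
  expect_error(gen_reads(c(ACG = 1), 10, error_rate = 0.7),
               class = "selseq_error_validation")
})

test_that("per-base errors appear at roughly the requested rate", {
  counts <- c(ACGTACGTACG = 1)
  r <- gen_reads(counts, depth = 2000, error_rate = 0.01, seed = 12)
  expected <- paste0(attr(r, "flank5"), "ACGTACGTACG", attr(r, "flank3"))
  n_bases <- 2000 * nchar(expected)
  mm <- sum(vapply(as.character(r), function(x)
    sum(strsplit(x, "")[[1]] != strsplit(expected, "")[[1]]), 0))
  se <- sqrt(0.01 * 0.99 * n_bases)
  expect_lt(abs(mm - 0.01 * n_bases), 4 * se)
})

test_that("fluorescence samples hit the requested mean and stay reproducible", {
  s <- gen_fluorescence(mean = 50000, cv = 0.3, n_cells = 100000,
                        background_mean = 10000, seed = 1)
  expect_true(all(s$values >= 0))
  expect_lt(abs(mean(s$values) - 60000) / 60000, 0.01)
  s2 <- gen_fluorescence(50000, 0.3, 10, seed = 1)
  s3 <- gen_fluorescence(50000, 0.3, 10, seed = 1)
  expect_identical(s2$values, s3$values)
  expect_error(gen_fluorescence(0, 0.3, 10), class = "selseq_error_validation")
})

test_that("planted promoter elements sit verbatim at their recorded offsets", {
  element <- "GACGTACAACG"
  proms <- gen_promoters(4, length = 300, element = element,
                         planted_in = c(1, 3), offsets = c(120, 60),
                         strand = c("+", "-"), seed = 21)
  planted <- attr(proms, "planted")
  for (k in seq_len(nrow(planted))) {
    s <- proms[[planted$name[k]]]
    start <- nchar(s) + planted$offset[k] + 1 # offset is negative upstream
    found <- substr(s, start, start + nchar(element) - 1)
    expected <- if (planted$strand[k] == "-") revcomp(element) else element
    expect_identical(found, expected)
  }
})
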