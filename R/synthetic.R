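# Seeded synthetic-data generators: biased degenerate libraries, sequencing
# reads, per-cell fluorescence, and promoters with planted elements.
#
# These generators emulate the statistical structure of a growth-selection
# sequencing screen: a degenerate 11-mer library whose abundance
# distribution is skewed by PCR/primer-synthesis bias (a few abundant
# sequences plus a long tail), rare planted functional/constitutive
# variants, multinomial sequencing with low per-base substitution error,
# and right-skewed cytometry-like fluorescence.

DEFAULT_FUNCTIONAL_CORE <- "NACGTNNNNNG" # ACGT at 2-5 and G at 11 fixed

# Map 1-based indices of the 4^L sequence space to ACGT strings.
index_to_sequence <- function(idx, len) {
  idx0 <- as.double(idx) - 1
  cols <- vector("list", len)
  for (p in len:1) {
    cols[[p]] <- c("A", "C", "G", "T")[(idx0 %% 4) + 1]
    idx0 <- idx0 %/% 4
  }
  do.call(paste0, cols)
}

#' Generate a biased degenerate variant library
#'
#' Draws `n_variants` distinct fixed-length sequences with initial
#' frequencies from a symmetric Dirichlet distribution whose concentration
#' `bias_concentration` controls the synthesis-bias skew (smaller = a few
#' sequences dominate; very large = near-uniform). Exactly `n_functional`
#' variants are flagged functional — each drawn from the expansion of
#' `functional_core`, so they carry the pathway-responsive element — and
#' `n_constitutive` are flagged constitutive (expression independent of the
#' pathway); no variant is both, and no unflagged variant matches the core.
#'
#' Flagged variants are planted rare: their combined initial masses default
#' to `functional_mass` = 2.5e-4 and `constitutive_mass` = 1e-4 of the
#' library (about 5e-5 per planted variant at the default counts), split
#' with mild within-class variability, while the abundance spikes live in
#' the non-functional background. This mirrors a screen in which the
#' eventual winners start from frequencies of order 1e-5 to 1e-4 — below
#' one read at typical sampling depth — and the most abundant
#' pre-selection sequences are synthesis artifacts.
#'
#' @param n_variants Number of distinct variants (must be <= 4^length).
#' @param length Variable-region length in bp (default 11).
#' @param bias_concentration Symmetric Dirichlet concentration for the
#'   background abundance distribution (default 0.0075, which gives a
#'   90,000-variant library a top-20 abundance share of about 10%).
#' @param n_functional,n_constitutive Numbers of flagged variants.
#' @param seed Integer seed; output is byte-identical for equal arguments.
#' @param functional_core IUPAC pattern every functional variant must match
#'   (same length as the region). Default for 11-mers fixes ACGT at
#'   positions 2-5 and G at position 11.
#' @param functional_mass,constitutive_mass Combined initial frequency of
#'   each flagged class (ignored when the class is empty).
#' @return A data.frame of class `selseq_library` with columns `sequence`,
#'   `initial_frequency`, `is_functional`, `is_constitutive`; frequencies
#'   sum to 1.
#' @export
gen_library <- function(n_variants, length = 11, bias_concentration = 0.0075,
                        n_functional = 0, n_constitutive = 0, seed = 1,
                        functional_core = NULL,
                        functional_mass = 0.00025, constitutive_mass = 0.0001) {
  assert_scalar_number(n_variants, "n_variants")
  assert_scalar_number(length, "length")
  assert_scalar_number(bias_concentration, "bias_concentration")
  if (length < 1) stop_validation("`length` must be >= 1")
  if (n_variants < 1) stop_validation("`n_variants` must be >= 1")
  if (bias_concentration <= 0)
    stop_validation("`bias_concentration` must be > 0")
  space <- 4^length
  if (n_variants > space)
    selseq_error("infeasible_library",
                 sprintf("n_variants (%g) exceeds 4^%d = %g distinct sequences",
                         n_variants, length, space))
  if (n_functional < 0 || n_constitutive < 0 ||
      n_functional + n_constitutive > n_variants)
    stop_validation("flagged counts must be >= 0 and sum to <= n_variants")
  if (n_functional > 0) {
    if (is.null(functional_core)) {
      if (length == 11) functional_core <- DEFAULT_FUNCTIONAL_CORE
      else stop_validation("supply `functional_core` for region lengths != 11")
    }
    if (nchar(functional_core) != length)
      stop_validation("`functional_core` must have the region length")
    if (n_functional > degeneracy(functional_core))
      selseq_error("infeasible_library",
                   "n_functional exceeds the degeneracy of `functional_core`")
  }

  with_seed(seed, {
    # Functional variants: distinct draws from the core expansion.
    functional <- character(0)
    if (n_functional > 0) {
      d <- degeneracy(functional_core)
      if (d <= 2e5) {
        functional <- sample(iupac_expand(functional_core), n_functional)
      } else {
        functional <- character(0)
        ch <- iupac_chars(functional_core)
        while (base::length(functional) < n_functional) {
          draw <- vapply(seq_len(n_functional), function(i)
            paste(vapply(IUPAC_SETS[ch],
                         function(s) s[sample.int(base::length(s), 1L)], ""),
                  collapse = ""), "")
          functional <- unique(c(functional, draw))
        }
        functional <- functional[seq_len(n_functional)]
      }
    }
    # Remaining variants: distinct draws from the full space, excluding the
    # functional core so non-functional variants never carry the element.
    n_rest <- n_variants - n_functional
    rest <- character(0)
    while (base::length(rest) < n_rest) {
      need <- n_rest - base::length(rest)
      idx <- sample(space, min(space, ceiling(need * 1.1) + 10L))
      cand <- index_to_sequence(idx, length)
      cand <- setdiff(cand, c(functional, rest))
      if (n_functional > 0)
        cand <- cand[!iupac_match(functional_core, cand)]
      rest <- c(rest, cand)
    }
    rest <- rest[seq_len(n_rest)]
    constitutive <- if (n_constitutive > 0) rest[seq_len(n_constitutive)]
                    else character(0)
    background <- if (n_rest > n_constitutive)
      rest[(n_constitutive + 1):n_rest] else character(0)

    # Class masses; empty classes contribute nothing and the remainder is
    # renormalised over the classes present.
    fm <- if (n_functional > 0) functional_mass else 0
    cm <- if (n_constitutive > 0) constitutive_mass else 0
    bm <- if (base::length(background) > 0) 1 - fm - cm else 0
    if (bm < 0) stop_validation("flagged class masses must sum to < 1")
    masses <- c(bm, fm, cm) / sum(c(bm, fm, cm))

    dirichlet <- function(n, alpha) {
      if (n == 0L) return(numeric(0))
      g <- stats::rgamma(n, shape = alpha)
      if (sum(g) == 0) g <- rep(1, n) # guard against total underflow
      g / sum(g)
    }
    # Within-class concentration 4: planted variants are spike-ins at
    # comparable (not identical) abundances.
    freq <- c(dirichlet(base::length(background), bias_concentration) * masses[1],
              dirichlet(base::length(functional), 4) * masses[2],
              dirichlet(base::length(constitutive), 4) * masses[3])

    lib <- data.frame(
      sequence = c(background, functional, constitutive),
      initial_frequency = freq,
      is_functional = rep(c(FALSE, TRUE, FALSE),
                          c(base::length(background), base::length(functional),
                            base::length(constitutive))),
      is_constitutive = rep(c(FALSE, FALSE, TRUE),
                            c(base::length(background), base::length(functional),
                              base::length(constitutive))),
      stringsAsFactors = FALSE
    )
    lib <- lib[order(lib$sequence), , drop = FALSE]
    rownames(lib) <- NULL
    structure(lib, class = c("selseq_library", "data.frame"),
              region_length = as.integer(length),
              functional_core = if (n_functional > 0) functional_core else NA_character_,
              seed = seed)
  })
}

#' Simulate sequencing reads from variant counts
#'
#' Draws `depth` variable regions multinomially with probabilities
#' proportional to `variant_counts`, wraps each in the constant flanks, and
#' applies independent per-base substitution errors at `error_rate`.
#'
#' @param variant_counts Named non-negative numeric vector (names are
#'   variable-region sequences); at least one count must be positive.
#' @param depth Number of reads to generate.
#' @param flank5,flank3 Constant flanking sequences (amplicon context).
#' @param error_rate Per-base substitution probability in `[0, 0.5)`
#'   (default 0.001, i.e. Q30-scale).
#' @param seed Integer seed.
#' @return Character vector of reads with attributes `flank5`, `flank3`,
#'   `region_length`, and `true_region` (the error-free region per read).
#' @export
gen_reads <- function(variant_counts, depth,
                      flank5 = "ACGCTTGCAT", flank3 = "GATCCGTTAC",
                      error_rate = 0.001, seed = 1) {
  if (is.null(names(variant_counts)) || !is.numeric(variant_counts))
    stop_validation("`variant_counts` must be a named numeric vector")
  if (any(variant_counts < 0)) stop_validation("counts must be non-negative")
  if (sum(variant_counts) <= 0)
    selseq_error("empty_population", "all variant counts are zero")
  assert_scalar_number(depth, "depth")
  if (depth < 1) stop_validation("`depth` must be >= 1")
  assert_scalar_number(error_rate, "error_rate")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_validation("`error_rate` must be in [0, 0.5)")
  assert_dna(flank5, "flank5"); assert_dna(flank3, "flank3")
  region_length <- unique(nchar(names(variant_counts)))
  if (length(region_length) != 1L)
    stop_validation("all variant sequences must share one length")

  with_seed(seed, {
    pos <- variant_counts[variant_counts > 0]
    idx <- sample.int(length(pos), size = depth, replace = TRUE,
                      prob = as.double(pos))
    regions <- names(pos)[idx]
    reads <- paste0(toupper(flank5), regions, toupper(flank3))
    L <- nchar(reads[1L])
    if (error_rate > 0) {
      err <- which(stats::runif(depth * L) < error_rate)
      if (length(err)) {
        r <- ((err - 1L) %/% L) + 1L
        p <- ((err - 1L) %% L) + 1L
        bases <- c("A", "C", "G", "T")
        for (k in seq_along(err)) {
          cur <- substr(reads[r[k]], p[k], p[k])
          sub <- sample(setdiff(bases, cur), 1L)
          substr(reads[r[k]], p[k], p[k]) <- sub
        }
      }
    }
    structure(reads, flank5 = toupper(flank5), flank3 = toupper(flank3),
              region_length = region_length, true_region = regions)
  })
}

#' Simulate per-cell reporter fluorescence
#'
#' Per-cell values are log-normal with the requested mean and coefficient
#' of variation, shifted by a constant background, emulating the
#' right-skewed positive fluorescence of cytometry in arbitrary units. The
#' sample mean converges to `mean + background_mean`.
#'
#' @param mean Target mean of the signal component (a.u., > 0).
#' @param cv Coefficient of variation of the signal component (> 0).
#' @param n_cells Number of cells (>= 1).
#' @param background_mean Constant background fluorescence (a.u., >= 0).
#' @param seed Integer seed.
#' @param condition Optional label, e.g. `"starved"` or `"replete"`.
#' @return List of class `fluorescence_sample` with elements `condition`,
#'   `values` (non-negative per-cell a.u.) and `background_mean`.
#' @export
gen_fluorescence <- function(mean, cv, n_cells, background_mean = 0,
                             seed = 1, condition = NA_character_) {
  assert_scalar_number(mean, "mean"); assert_scalar_number(cv, "cv")
  assert_scalar_number(n_cells, "n_cells")
  if (mean <= 0) stop_validation("`mean` must be > 0")
  if (cv <= 0) stop_validation("`cv` must be > 0")
  if (n_cells < 1) stop_validation("`n_cells` must be >= 1")
  if (background_mean < 0) stop_validation("`background_mean` must be >= 0")
  with_seed(seed, {
    sdlog <- sqrt(log1p(cv^2))
    meanlog <- log(mean) - sdlog^2 / 2
    values <- stats::rlnorm(n_cells, meanlog, sdlog) + background_mean
    structure(list(condition = condition, values = values,
                   background_mean = background_mean),
              class = "fluorescence_sample")
  })
}

#' Generate synthetic promoters with planted elements
#'
#' Random uniform ACGT promoters into which concrete element instances are
#' planted at stated offsets upstream of the 3' end (the position of the
#' element's 5'-most base, as a positive distance in bp); strand `"-"`
#' plants the reverse complement.
#'
#' @param n_promoters Number of promoters.
#' @param length Promoter length in bp (default 1000, a 1-kb upstream
#'   region).
#' @param element Element sequence to plant, or `NULL` for none.
#' @param planted_in Integer indices of promoters receiving the element.
#' @param offsets Upstream offsets of the element's 5' base, one per
#'   planted promoter (each must be in `[element length, length]`).
#' @param strand `"+"` or `"-"`, recycled over planted promoters.
#' @param seed Integer seed.
#' @return Named character vector of sequences (names `promoter_001`, ...)
#'   with attribute `planted`, a data.frame of (name, element, offset,
#'   strand).
#' @export
gen_promoters <- function(n_promoters, length = 1000, element = NULL,
                          planted_in = integer(0), offsets = NULL,
                          strand = "+", seed = 1) {
  assert_scalar_number(n_promoters, "n_promoters")
  assert_scalar_number(length, "length")
  if (n_promoters < 1 || length < 1)
    stop_validation("`n_promoters` and `length` must be >= 1")
  if (base::length(planted_in)) {
    assert_dna(element, "element")
    if (is.null(offsets) || base::length(offsets) != base::length(planted_in))
      stop_validation("`offsets` must match `planted_in` in length")
    m <- nchar(element)
    if (any(offsets < m | offsets > length))
      stop_validation("offsets must lie in [element length, promoter length]")
    if (any(planted_in < 1 | planted_in > n_promoters))
      stop_validation("`planted_in` indices out of range")
    strand <- rep_len(strand, base::length(planted_in))
  }
  with_seed(seed, {
    seqs <- vapply(seq_len(n_promoters), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- sprintf("promoter_%03d", seq_len(n_promoters))
    planted <- data.frame(name = character(0), element = character(0),
                          offset = integer(0), strand = character(0),
                          stringsAsFactors = FALSE)
    for (k in seq_along(planted_in)) {
      i <- planted_in[k]
      ins <- if (strand[k] == "-") revcomp(element) else toupper(element)
      start <- length - offsets[k] + 1L # 1-based index of the 5' base
      substr(seqs[i], start, start + nchar(ins) - 1L) <- ins
      planted <- rbind(planted, data.frame(
        name = names(seqs)[i], element = toupper(element),
        offset = -offsets[k], strand = strand[k], stringsAsFactors = FALSE))
    }
    structure(seqs, planted = planted)
  })
}
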