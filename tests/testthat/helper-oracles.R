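# Independent brute-force oracles and small generators used across tests.
# These deliberately take a different route from the package code (regex
# filtering over full enumerations, character-by-character loops) so they
# can serve as cross-checks.

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

# All 4^L ACGT strings, lexicographic.
all_kmers <- function(L) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), L),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sort(do.call(paste0, rev(grid)))
}

# Regex-based IUPAC membership test.
bf_iupac_match <- function(pattern, sequences) {
  ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  grepl(paste0("^", paste(IUPAC_REGEX[ch], collapse = ""), "$"),
        toupper(sequences))
}

# Enumerate-and-filter expansion of a pattern.
bf_iupac_expand <- function(pattern) {
  k <- all_kmers(nchar(pattern))
  k[bf_iupac_match(pattern, k)]
}

# Exhaustive best ungapped match: max identities over offsets and strands,
# ties -> smallest offset, then plus strand.
bf_best_match <- function(query, target, both_strands = FALSE) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(toupper(s), "")[[1L]]]), collapse = "")
  }
  t_ch <- strsplit(toupper(target), "")[[1L]]
  best <- list(identities = -1, start = NA, strand = NA)
  strands <- c("+", if (both_strands) "-")
  for (st in strands) {
    q <- if (st == "-") rc(query) else toupper(query)
    q_ch <- strsplit(q, "")[[1L]]
    for (o in seq_len(length(t_ch) - length(q_ch) + 1L)) {
      ids <- 0
      for (p in seq_along(q_ch)) {
        if (t_ch[o + p - 1L] == q_ch[p]) ids <- ids + 1
      }
      if (ids > best$identities) best <- list(identities = ids, start = o,
                                              strand = st)
    }
  }
  best
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

random_iupac_pattern <- function(len) {
  paste(sample(names(IUPAC_REGEX), len, replace = TRUE), collapse = "")
}

# Library for the takeover scenario: a given total functional frequency.
takeover_library <- function(functional_mass = 0.06, seed = 1) {
  gen_library(n_variants = 50, length = 11, bias_concentration = 0.0075,
              n_functional = 3, n_constitutive = 0, seed = seed,
              functional_mass = functional_mass)
}
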