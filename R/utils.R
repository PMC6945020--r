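# Internal helpers: seeded evaluation, typed errors, small validators.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators do not perturb the global random stream. A `NULL` seed
#' evaluates `code` with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic integer mixing so that each pipeline stage (and each
#' replicate within a stage) draws from an independent, reproducible stream.
#' Results stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param stage Non-negative integer stage index.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (abs(as.double(seed)) %% m)
  as.integer(((s * 48271) %% m + (as.double(stage) * 1299709) %% m) %% m)
}

# Typed condition constructor; `type` becomes class selseq_error_<type>.
selseq_error <- function(type, msg, call = sys.call(-1)) {
  stop(errorCondition(
    msg,
    class = c(paste0("selseq_error_", gsub("-", "_", type)), "selseq_error")
  ))
}

stop_validation <- function(msg) selseq_error("validation", msg)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

assert_dna <- function(x, name = deparse(substitute(x))) {
  if (!is.character(x) || anyNA(x))
    stop_validation(sprintf("`%s` must be a character vector without NA", name))
  if (any(grepl("[^ACGTacgt]", x)))
    stop_validation(sprintf("`%s` must contain only A/C/G/T", name))
  invisible(x)
}

# Split sequences into a character matrix (rows = sequences). All inputs
# must share one length.
seq_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) != 1L)
    stop_validation("sequences must have equal lengths")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}
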