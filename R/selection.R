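# Prototrophy-based growth selection under serial dilution: a variant whose
# reporter expression exceeds the growth threshold rescues thiamine
# prototrophy and doubles through the regrowth phase; non-expressing cells
# arrest (thiamine auxotrophy) but do not die. A pathway-deletion control
# strain (pdc2_delta) abolishes pathway-dependent expression, so only
# constitutive variants grow there.

#' Selection regime for serial-dilution passaging
#'
#' @param dilution_factor Dilution applied at each passage (> 1; default
#'   1000, a 1:1000 daily dilution).
#' @param n_passages Number of dilute-regrow cycles (default 3, i.e. three
#'   successive days).
#' @param doublings_per_regrowth Doublings a growing cell completes per
#'   regrowth phase; defaults to `log2(dilution_factor)`, the number needed
#'   to regrow to the pre-dilution density.
#' @param population_size_at_saturation Cells in the saturated founding
#'   culture (default 1e9).
#' @return List of class `selection_regime`.
#' @export
selection_regime <- function(dilution_factor = 1000, n_passages = 3,
                             doublings_per_regrowth = log2(dilution_factor),
                             population_size_at_saturation = 1e9) {
  assert_scalar_number(dilution_factor, "dilution_factor")
  if (dilution_factor <= 1) stop_validation("`dilution_factor` must be > 1")
  assert_scalar_number(n_passages, "n_passages")
  if (n_passages < 0) stop_validation("`n_passages` must be >= 0")
  assert_scalar_number(doublings_per_regrowth, "doublings_per_regrowth")
  if (doublings_per_regrowth <= 0)
    stop_validation("`doublings_per_regrowth` must be > 0")
  assert_scalar_number(population_size_at_saturation,
                       "population_size_at_saturation")
  if (population_size_at_saturation < 1 ||
      population_size_at_saturation >= 2^31)
    stop_validation("`population_size_at_saturation` must be in [1, 2^31)")
  structure(list(dilution_factor = dilution_factor,
                 n_passages = as.integer(n_passages),
                 doublings_per_regrowth = doublings_per_regrowth,
                 population_size_at_saturation = population_size_at_saturation),
            class = "selection_regime")
}

#' Generations elapsed over serial-dilution regrowth cycles
#'
#' Each 1:d dilution requires `log2(d)` doublings to regrow to the
#' pre-dilution density, so `n` cycles allow `n * log2(d)` generations;
#' two 1:1000 cycles give 19.93, the conventional "about 20 generations".
#'
#' @param dilution_factor Dilution factor (> 1).
#' @param n_regrowth_cycles Number of regrowth cycles (>= 0).
#' @return Doublings elapsed (real).
#' @examples
#' generations_elapsed(1000, 2)
#' @export
generations_elapsed <- function(dilution_factor, n_regrowth_cycles) {
  assert_scalar_number(dilution_factor, "dilution_factor")
  if (dilution_factor <= 1) stop_validation("`dilution_factor` must be > 1")
  assert_scalar_number(n_regrowth_cycles, "n_regrowth_cycles")
  if (n_regrowth_cycles < 0)
    stop_validation("`n_regrowth_cycles` must be >= 0")
  n_regrowth_cycles * log2(dilution_factor)
}

#' Fitness model: who expresses, and how much growth expression confers
#'
#' Expression is 1 for functional variants in the wild-type strain (the
#' pathway drives the reporter), 1 for constitutive variants in either
#' strain, and 0 otherwise; a cell divides through the regrowth phase iff
#' its expression exceeds `growth_threshold`.
#'
#' @param functional Character vector of functional variant sequences.
#' @param constitutive Character vector of constitutive variant sequences
#'   (disjoint from `functional`).
#' @param growth_threshold Expression level above which a cell grows
#'   (default 0.5); set above 1 to disable selection entirely.
#' @param doublings_if_growing Doublings completed by a growing cell per
#'   regrowth (default `log2(1000)`).
#' @return List of class `fitness_model`.
#' @export
fitness_model <- function(functional = character(0),
                          constitutive = character(0),
                          growth_threshold = 0.5,
                          doublings_if_growing = log2(1000)) {
  if (length(intersect(functional, constitutive)))
    stop_validation("a variant cannot be both functional and constitutive")
  assert_scalar_number(growth_threshold, "growth_threshold")
  assert_scalar_number(doublings_if_growing, "doublings_if_growing")
  if (doublings_if_growing <= 0)
    stop_validation("`doublings_if_growing` must be > 0")
  structure(list(functional = unique(functional),
                 constitutive = unique(constitutive),
                 growth_threshold = growth_threshold,
                 doublings_if_growing = doublings_if_growing),
            class = "fitness_model")
}

#' Fitness model from a synthetic library's flags
#'
#' @param library A `selseq_library` (from [gen_library()]).
#' @inheritParams fitness_model
#' @return List of class `fitness_model`.
#' @export
as_fitness_model <- function(library, growth_threshold = 0.5,
                             doublings_if_growing = log2(1000)) {
  if (!inherits(library, "selseq_library"))
    stop_validation("`library` must be a selseq_library")
  fitness_model(functional = library$sequence[library$is_functional],
                constitutive = library$sequence[library$is_constitutive],
                growth_threshold = growth_threshold,
                doublings_if_growing = doublings_if_growing)
}

#' Expression level of variants in a strain
#'
#' @param model A `fitness_model`.
#' @param sequences Character vector of variant sequences.
#' @param strain `"wild_type"` or `"pdc2_delta"`.
#' @return Numeric vector of expression levels in `[0, 1]`.
#' @export
expression_of <- function(model, sequences, strain = c("wild_type", "pdc2_delta")) {
  strain <- match.arg(strain)
  expr <- numeric(length(sequences))
  expr[sequences %in% model$constitutive] <- 1
  if (strain == "wild_type") expr[sequences %in% model$functional] <- 1
  expr
}

#' Construct a population of variant-carrying cells
#'
#' @param counts Named non-negative numeric vector of cell counts per
#'   variant sequence.
#' @param strain `"wild_type"` or `"pdc2_delta"`.
#' @return List of class `population` with elements `counts` and `strain`.
#' @export
population <- function(counts, strain = c("wild_type", "pdc2_delta")) {
  strain <- match.arg(strain)
  if (!is.numeric(counts) || is.null(names(counts)) || any(counts < 0) ||
      anyNA(counts))
    stop_validation("`counts` must be a named non-negative numeric vector")
  structure(list(counts = counts, strain = strain), class = "population")
}

#' One regrowth phase under starvation selection
#'
#' Variants whose expression (in the population's strain) exceeds the
#' model's growth threshold multiply by `2^doublings_if_growing`; the rest
#' arrest with unchanged counts (starvation arrest, not death). Grown
#' counts are rounded to the nearest integer with a floor of 1 for any
#' variant that entered with a positive count.
#'
#' @param pop A `population`.
#' @param model A `fitness_model`.
#' @return The grown `population`.
#' @export
grow <- function(pop, model) {
  if (!inherits(pop, "population")) stop_validation("`pop` must be a population")
  if (!inherits(model, "fitness_model"))
    stop_validation("`model` must be a fitness_model")
  if (sum(pop$counts) <= 0)
    selseq_error("empty_population", "population has no cells")
  counts <- pop$counts
  expr <- expression_of(model, names(counts), pop$strain)
  growing <- expr > model$growth_threshold
  grown <- round(counts[growing] * 2^model$doublings_if_growing)
  counts[growing] <- pmax(grown, ifelse(pop$counts[growing] > 0, 1, 0))
  population(counts, pop$strain)
}

#' Serial-dilution bottleneck
#'
#' Multinomially samples `floor(total / dilution_factor)` cells with
#' probabilities proportional to current counts.
#'
#' @param pop A `population` with total count >= `dilution_factor`.
#' @param dilution_factor Dilution factor (> 1).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return The diluted `population`.
#' @export
dilute <- function(pop, dilution_factor, seed = NULL) {
  if (!inherits(pop, "population")) stop_validation("`pop` must be a population")
  assert_scalar_number(dilution_factor, "dilution_factor")
  if (dilution_factor <= 1) stop_validation("`dilution_factor` must be > 1")
  total <- sum(pop$counts)
  if (total < dilution_factor)
    selseq_error("bottleneck_extinction",
                 sprintf("total count %g is below the dilution factor %g",
                         total, dilution_factor))
  n_keep <- floor(total / dilution_factor)
  if (n_keep >= 2^31)
    stop_validation("post-dilution population too large for multinomial sampling")
  with_seed(seed, {
    kept <- stats::rmultinom(1L, size = n_keep,
                             prob = as.double(pop$counts))[, 1L]
    population(stats::setNames(as.double(kept), names(pop$counts)),
               pop$strain)
  })
}

#' Run a full growth selection
#'
#' Founds a saturated population from the library's initial frequencies
#' (multinomial of `population_size_at_saturation` cells), then applies
#' `n_passages` dilute-then-regrow cycles. All randomness derives from
#' `seed` via per-stage seeds, so trajectories are reproducible.
#'
#' @param library A `selseq_library`.
#' @param regime A `selection_regime`.
#' @param model A `fitness_model`.
#' @param strain `"wild_type"` or `"pdc2_delta"`.
#' @param seed Integer seed.
#' @param initial_population Optional `population` to use as the founding
#'   time point (e.g. to run both strains from one transformant pool); its
#'   strain field is overridden by `strain`.
#' @return List of class `selection_trajectory`: `n_passages + 1`
#'   `population` objects, time 0 first.
#' @export
run_selection <- function(library, regime, model,
                          strain = c("wild_type", "pdc2_delta"), seed = 1,
                          initial_population = NULL) {
  strain <- match.arg(strain)
  if (!inherits(library, "selseq_library"))
    stop_validation("`library` must be a selseq_library")
  if (!inherits(regime, "selection_regime"))
    stop_validation("`regime` must be a selection_regime")
  if (!nrow(library)) stop_validation("`library` is empty")
  pop <- if (is.null(initial_population)) {
    with_seed(stage_seed(seed, 0L), {
      cells <- stats::rmultinom(1L, size = regime$population_size_at_saturation,
                                prob = library$initial_frequency)[, 1L]
      population(stats::setNames(as.double(cells), library$sequence), strain)
    })
  } else {
    population(initial_population$counts, strain)
  }
  trajectory <- vector("list", regime$n_passages + 1L)
  trajectory[[1L]] <- pop
  for (p in seq_len(regime$n_passages)) {
    pop <- dilute(pop, regime$dilution_factor, seed = stage_seed(seed, p))
    pop <- grow(pop, model)
    trajectory[[p + 1L]] <- pop
  }
  structure(trajectory, class = "selection_trajectory", strain = strain,
            seed = seed)
}

#' Fraction of cells carrying listed variants
#'
#' @param pop A `population`.
#' @param sequences Variant sequences of interest (e.g. the functional set).
#' @return Fraction of the population's cells carrying any of `sequences`.
#' @export
variant_fraction <- function(pop, sequences) {
  if (!inherits(pop, "population")) stop_validation("`pop` must be a population")
  total <- sum(pop$counts)
  if (total <= 0) selseq_error("empty_population", "population has no cells")
  sum(pop$counts[names(pop$counts) %in% sequences]) / total
}
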