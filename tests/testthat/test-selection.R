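# Growth-selection simulator: generation bookkeeping, threshold-gated
# growth, multinomial bottlenecks, and the neutral/control symmetries.

test_that("generation bookkeeping follows n * log2(dilution)", {
  expect_equal(generations_elapsed(2, 1), 1)
  expect_equal(generations_elapsed(1000, 2), 19.93, tolerance = 1e-3)
  expect_identical(round(generations_elapsed(1000, 2)), 20)
  # Three cycles would be ~30 doublings - the other reading of the regime.
  expect_equal(generations_elapsed(1000, 3), 29.90, tolerance = 1e-3)
  expect_error(generations_elapsed(1, 2), class = "selseq_error_validation")
})

test_that("non-expressing variants arrest and expressing ones double fully", {
  model <- fitness_model(functional = "FUNVARIANT",
                         doublings_if_growing = 10)
  arrested <- grow(population(c(NONFUNCTIONAL = 100)), model)
  expect_identical(arrested$counts, c(NONFUNCTIONAL = 100))

  pop <- population(c(FUNVARIANT = 6, NONFUNCTIONAL = 94))
  grown <- grow(pop, model)
  expect_identical(unname(grown$counts["FUNVARIANT"]), 6 * 1024)
  expect_identical(unname(grown$counts["NONFUNCTIONAL"]), 94)
  frac <- grown$counts["FUNVARIANT"] / sum(grown$counts)
  expect_gt(frac, 0.98)
})

test_that("functional variants do not grow in the pathway-deletion strain", {
  model <- fitness_model(functional = "FUNVARIANT", doublings_if_growing = 10)
  pop <- population(c(FUNVARIANT = 6, NONFUNCTIONAL = 94), "pdc2_delta")
  expect_identical(grow(pop, model)$counts, pop$counts)
  # Constitutive variants grow in either strain.
  model2 <- fitness_model(constitutive = "CONSTVARIANT",
                          doublings_if_growing = 10)
  pop2 <- population(c(CONSTVARIANT = 5, NONFUNCTIONAL = 95), "pdc2_delta")
  expect_identical(unname(grow(pop2, model2)$counts["CONSTVARIANT"]), 5 * 1024)
})

test_that("growth rounding never extinguishes a present variant", {
  model <- fitness_model(functional = "F", doublings_if_growing = 0.1)
  # 1 cell x 2^0.1 rounds to 1, floor keeps it alive.
  grown <- grow(population(c(F = 1, O = 5)), model)
  expect_gte(unname(grown$counts["F"]), 1)
})

test_that("dilution conserves a single variant and errs below the bottleneck", {
  d <- dilute(population(c(A = 1000)), 1000, seed = 1)
  expect_identical(d$counts, c(A = 1))
  expect_error(dilute(population(c(A = 999)), 1000),
               class = "selseq_error_bottleneck_extinction")
})

test_that("dilution is an unbiased multinomial bottleneck", {
  pop <- population(c(A = 500000, B = 500000))
  fracs <- vapply(1:100, function(s) {
    d <- dilute(pop, 1000, seed = s)
    d$counts["A"] / sum(d$counts)
  }, 0)
  se_mean <- sqrt(0.25 / 1000) / sqrt(100)
  expect_lt(abs(mean(fracs) - 0.5), 3 * se_mean)
  # Per-draw spread is binomial-like, not degenerate.
  expect_gt(stats::sd(fracs), 0.5 * sqrt(0.25 / 1000))
})

test_that("a one-variant library survives any trajectory unchanged in composition", {
  lib <- gen_library(1, 11, seed = 2)
  regime <- selection_regime(n_passages = 2,
                             population_size_at_saturation = 1e7)
  traj <- run_selection(lib, regime, as_fitness_model(lib), seed = 4)
  expect_length(traj, 3)
  for (pop in traj) {
    expect_identical(names(pop$counts)[pop$counts > 0], lib$sequence)
  }
})

test_that("6% functional cells take over in a single regrowth cycle", {
  lib <- takeover_library(functional_mass = 0.06, seed = 1)
  fun <- lib$sequence[lib$is_functional]
  regime <- selection_regime(dilution_factor = 1000, n_passages = 1,
                             doublings_per_regrowth = 10,
                             population_size_at_saturation = 1e6)
  model <- as_fitness_model(lib, doublings_if_growing = 10)
  traj <- run_selection(lib, regime, model, strain = "wild_type", seed = 42)
  start <- variant_fraction(traj[[1]], fun)
  final <- variant_fraction(traj[[length(traj)]], fun)
  expect_equal(start, 0.06, tolerance = 0.01)
  expect_gte(final, 0.90)
})

test_that("selection trajectories are reproducible from their seed", {
  lib <- gen_library(40, 11, n_functional = 2, seed = 6)
  regime <- selection_regime(n_passages = 2,
                             population_size_at_saturation = 1e7)
  model <- as_fitness_model(lib)
  t1 <- run_selection(lib, regime, model, seed = 99)
  t2 <- run_selection(lib, regime, model, seed = 99)
  expect_identical(lapply(t1, `[[`, "counts"), lapply(t2, `[[`, "counts"))
})

test_that("neutral passaging conserves expected frequencies", {
  # Nobody grows: expected variant frequencies are invariant under dilution.
  pop <- population(c(A = 300000, B = 600000, C = 100000))
  p0 <- pop$counts / sum(pop$counts)
  model <- fitness_model(functional = "A", growth_threshold = 2)
  means <- rowMeans(vapply(1:100, function(s) {
    d <- grow(dilute(pop, 1000, seed = s), model)
    d$counts / sum(d$counts)
  }, numeric(3)))
  n_kept <- 1000
  for (v in names(p0)) {
    se <- sqrt(p0[[v]] * (1 - p0[[v]]) / n_kept) / sqrt(100)
    expect_lt(abs(means[[v]] - p0[[v]]), 3 * se)
  }
})

test_that("functional frequency is non-decreasing across wild-type passages", {
  lib <- gen_library(60, 11, n_functional = 3, seed = 13,
                     functional_mass = 0.01)
  fun <- lib$sequence[lib$is_functional]
  regime <- selection_regime(n_passages = 3,
                             population_size_at_saturation = 1e8)
  model <- as_fitness_model(lib)
  traj <- run_selection(lib, regime, model, strain = "wild_type", seed = 31)
  fracs <- vapply(traj, variant_fraction, 0, sequences = fun)
  expect_true(all(diff(fracs) >= -1e-12))
})

test_that("the control strain enriches constitutive but not functional variants", {
  lib <- gen_library(60, 11, n_functional = 3, n_constitutive = 2, seed = 17,
                     functional_mass = 0.001, constitutive_mass = 0.001)
  fun <- lib$sequence[lib$is_functional]
  const <- lib$sequence[lib$is_constitutive]
  regime <- selection_regime(n_passages = 2,
                             population_size_at_saturation = 1e9)
  model <- as_fitness_model(lib)
  traj <- run_selection(lib, regime, model, strain = "pdc2_delta", seed = 51)
  first <- traj[[1]]; last <- traj[[length(traj)]]
  expect_gt(variant_fraction(last, const), 100 * variant_fraction(first, const))
  # Functional-only variants stay at the neutral scale in the control.
  expect_lt(variant_fraction(last, fun), 10 * variant_fraction(first, fun))
})
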