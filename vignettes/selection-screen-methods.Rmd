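---
title: "Simulating and analysing growth-selection screens of degenerate promoter elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing growth-selection screens of degenerate promoter elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selseq)
```

## The experiment being modelled

A degenerate upstream activating sequence (UAS) library screen works as
follows. An 11-bp element in a starvation-responsive yeast promoter is
replaced by fully degenerate sequence (4^11 = 4,194,304 possibilities), and
the promoter is fused to a biosynthetic gene whose expression rescues
growth of an otherwise auxotrophic strain on starvation medium. Cells
carrying a variant that drives strong expression divide; the rest arrest.
Serial 1:1000 dilutions with daily regrowth amplify the difference over
~10 doublings per cycle, and deep sequencing of the element before and
after selection identifies the winners by fold enrichment. A parallel
selection in a strain deleted for the pathway's DNA-binding regulator
(*pdc2*Δ) separates variants that act through the starvation pathway from
variants that simply drive constitutive expression: a sequence enriched in
both strains is pathway independent and is discarded.

`selseq` implements every computational stage of such a screen — and a
seeded synthetic-data generator that stands in for the wet-lab inputs —
so the whole analysis runs at desk scale and every stage is testable
against planted ground truth. It also implements the companion
reporter-assay analyses used to map the element in the first place:
fold induction from per-cell fluorescence, truncation-boundary
localisation, and scanning mutagenesis.

## The synthetic library

`gen_library()` draws `n_variants` distinct fixed-length sequences and
assigns initial frequencies in three blocks:

* **Background** (non-functional) variants receive a symmetric Dirichlet
  distribution with concentration `bias_concentration`. Small
  concentrations concentrate the library into a few abundant sequences
  with a long tail — the signature of PCR and primer-synthesis bias. The
  default, 0.0075, was calibrated by simulation so that a 90,000-variant
  library puts roughly 10% of its mass into its 20 most abundant
  sequences, the concentration observed in real pre-selection libraries
  of this design.
* **Functional** variants are drawn from the expansion of a functional
  core pattern (default `NACGTNNNNNG`: ACGT fixed at positions 2–5 and G
  at position 11, the critical bases of the element in its case-annotated
  form `gACGTacaacG`). Background and constitutive variants are rejected
  if they match the core, so planted truth is unambiguous and the motif
  matcher can verify both directions.
* **Constitutive** variants express independently of the pathway and are
  the adversarial class the control selection must remove.

Flagged variants are planted rare: combined masses default to 2.5×10⁻⁴
(functional) and 1×10⁻⁴ (constitutive), split with mild within-class
variability (Dirichlet with concentration 4 — spike-ins at comparable but
not identical abundances). The scale follows from the screen's own
arithmetic: winners that end up >90-fold enriched with post-selection
shares of several percent must have started at frequencies of order
10⁻⁵–10⁻⁴, below one read at the 3,500-read sampling depth. Planting them
higher would not be more realistic — it would put them where the fold
statistic cannot reach the 90-fold bar at all.

## The selection model

Growth is threshold-gated rather than rate-based, because prototrophy
selection is nearly binary: a cell either makes enough of the rescue
enzyme to divide or it arrests. `fitness_model()` assigns expression 1 to
functional variants in the wild type, 1 to constitutive variants in
either strain, and 0 otherwise; `grow()` multiplies the count of every
variant whose expression exceeds `growth_threshold` (default 0.5) by
`2^doublings_if_growing` and leaves the rest unchanged — starvation
arrest, not death, since non-enriched sequences are still recovered after
selection. Grown counts are rounded to the nearest integer with a floor
of 1 for any variant that entered with a positive count, so rounding
never extinguishes a lineage that growth should preserve.

`dilute()` is a seeded multinomial bottleneck keeping
`floor(total / dilution_factor)` cells, and `run_selection()` founds a
saturated population from the library frequencies and alternates
dilute→grow for `n_passages` cycles. Defaults: 1:1000 dilution, 3
passages, `doublings_per_regrowth = log2(1000) ≈ 9.97` (regrow exactly to
saturation), saturation 10⁹ cells. The saturation size matters more than
it looks: the 1:1000 bottleneck keeps `N/1000` cells, and with planted
variants at ~5×10⁻⁵ frequency a 10⁸-cell culture would push them through
the bottleneck as a handful of cells each, causing stochastic extinctions
that a real 10⁹–10¹⁰-cell culture does not suffer. The founding
transformant count of such screens (~10⁵) is the library's *diversity*,
not the culture size, and enters the model through `n_variants` instead.

On generation bookkeeping: `generations_elapsed(d, n) = n · log2(d)`.
Two 1:1000 regrowth cycles give 19.93 ≈ 20 doublings; three give 29.90.
Descriptions of three-day regimes as "~20 generations" are consistent
with counting regrowths after the first day's outgrowth; the simulator
exposes `n_passages` and lets the user adopt either reading rather than
deciding it for them.

## Sequencing, extraction and enrichment

`gen_reads()` draws variable regions multinomially from cell counts,
wraps them in constant flanks, and applies independent per-base
substitution errors (default 0.001, the Q30 scale; FASTQ output carries a
constant Q30 placeholder because the analysis never consumes qualities).
The default depth of 3,500 reads per sample mirrors a screen that
analysed at least 2×1,750 sequences per sample.

`extract_variable_region()` finds each flank allowing up to
`max_flank_mismatch` substitutions (default 1). Within the tolerance the
*fewest-mismatch* position wins, leftmost on ties — leftmost-first
matching would let an approximate hit one base early shadow an exact
flank and truncate the region. Failures are typed rejections
(`flank-not-found`, `wrong-length`, `ambiguous-base`) that are data, not
errors, and the accounting invariant `counts + rejections = reads` is
enforced by construction.

Fold enrichment of sequence *i* between time-zero and post-selection
tables is the pseudocount-regularised frequency ratio

$$F_i = \frac{(c^{post}_i + p)/(T^{post} + pU)}{(c^{pre}_i + p)/(T^{pre} + pU)},$$

with pseudocount *p* = 1 read and *U* the union of sequences in both
tables. The regularisation gives finite folds to winners unseen at time
zero — the typical case, since winners start below one expected read.
`pathway_dependent_set()` then keeps sequences whose wild-type fold
exceeds `wt_threshold` (default 90, the screen's reported bound) while
their control fold stays below `control_ceiling` (default 10). Replicates
are combined by the mean (`require_all_replicates = FALSE`); the strict
every-replicate rule is available but needlessly fragile at this depth,
where a single unlucky replicate draw can drop a true winner. Sequences
absent from the control comparison are treated as not control-enriched.

## Motif operations

The IUPAC utilities (`degeneracy()`, `iupac_expand()`, `iupac_match()`,
`revcomp()`, `consensus_from_alignment()`) implement the 15-letter
degenerate alphabet with case preserved through reverse complement, since
case annotation (`gACGTacaacG`) carries the critical-base information.
`scan_promoters()` scans the `window` 3′-most bases of each promoter (the
1-kb stretch nearest the start codon) and reports matches at negative
offsets upstream of the start codon (−260 = 260 bp upstream); internal
coordinates are 1-based string indices converted only at the reporting
boundary. Scanning defaults to the given strand because these consensus
patterns are directional; `both_strands = TRUE` is available since *cis*
elements may act in either orientation. `best_ungapped_match()` slides a
query over every target offset (optionally both strands) and maximises
positional identities, with deterministic tie-breaking (smallest offset,
then plus strand). `consensus_from_alignment()` writes, per column, the
minimal IUPAC code covering all bases at or above an inclusion frequency,
falling back to `N` — a deliberate simplification standing in for motif
discovery, which is out of scope.

## Reporter analysis

`fold_induction()` is the ratio of mean per-cell fluorescence, starved
over replete, matching a mean-based cytometer readout; medians are not
used. Background subtraction is off by default (assays report raw
arbitrary units with per-experiment controls); when enabled it uses each
sample's own background mean, floors the numerator at a small epsilon,
and treats a non-positive denominator as an undefined-induction error.
`truncation_boundary()` implements the drop rule: walking a series of
progressively shorter promoters, it returns the first adjacent pair where
induction falls from at least `(1 − drop_fraction)` of the full-length
reference to below it (default drop 0.9, a >90% decrease); the element's
5′ edge lies between the two endpoints. `scanning_mutants()` generates
the two substitution schemes — T/G everywhere with native T→A and native
G→C, or A everywhere with native A→C — and never emits a synonymous
"mutant". `classify_critical()` calls a position critical only when
*every* tested replacement there drops induction below `critical_cutoff`
× reference (default 0.2). The cutoff is an artifact decision — published
critical-base calls of this kind are visual — so the synthetic
reproduction plants effects far from the boundary (defective mutants at
~4% of reference, tolerated ones at ~90%) and no conclusion depends on
the default's exact value.

## Fluorescence generator

`gen_fluorescence()` draws per-cell values from a log-normal with the
requested mean and coefficient of variation (`sdlog² = log(1+cv²)`,
`meanlog = log(mean) − sdlog²/2`), shifted by a constant background —
right-skewed positive values on the arbitrary-unit scale of cytometry,
with backgrounds around 10⁴ a.u. It does not model gating, compensation,
autofluorescence spread, or instrument binning; it exists so the reporter
statistics have distributionally sensible input with known truth.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis relies
on: skewed abundances, rare winners, binary selection, multinomial
sampling, low substitution error, log-normal fluorescence. It omits PCR
chimeras and indels, paired-end read structure, quality-score variation,
expression heterogeneity between cells carrying the same variant,
mutation during selection, fitness costs of expression, and cell death.
Planted-truth recovery therefore demonstrates that the pipeline's
statistics are correct and well-calibrated for data with this structure —
not that a real screen is free of the artifacts the generator omits.

Stochastic honesty matters here: with planted variants at ~5×10⁻⁵
frequency, a variant occasionally draws a far-below-average frequency,
passes the bottleneck as a few cells, and drifts or goes extinct — as in
a real screen. Recovery is therefore perfect for the pinned demonstration
seed and for the large majority of seeds, not a theorem.

## Problem sizes and reproducibility

Every random draw flows from explicit integer seeds (`with_seed()`
restores the caller's RNG state; `stage_seed()` derives independent
per-stage streams below 2³¹, so re-running one stage is stable when
another's parameters change). Identical seeds give byte-identical
outputs, including written artifacts.

The analysis scripts run the screen at study scale (90,000 variants, 10⁹
cells, 3,500 reads per sample, seven sequenced samples) in seconds; the
test suite uses the 100-variant demonstration configuration plus
module-level fixtures and completes in well under a minute. These sizes
are the package's chosen desk-scale defaults; all of them are ordinary
function arguments.

## Known limitations

* Growth is all-or-none; partial expression levels between the threshold
  and zero are not modelled, so the screen cannot rank weak winners.
* The fold statistic has no significance test attached — the screens it
  models report none — so the thresholds are decision rules, not
  inference.
* Consensus construction from aligned sites is not motif discovery; it
  requires the sites to be pre-aligned and equal-length.
* Genome-scale scans depend on the assembly used and are validated here
  only on synthetic promoter panels with planted elements.
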