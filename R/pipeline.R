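# End-to-end orchestration: library generation, wild-type and
# pathway-deletion selections from one transformant pool, sequencing,
# counting, fold enrichment, the pathway-dependence filter, and best-match
# alignment of the surviving sequences against promoters.

#' Configuration for a full synthetic selection screen
#'
#' Collects every stage's parameters with validated defaults; a single
#' master seed deterministically derives per-stage seeds, so a config plus
#' seed fully reproduces a run.
#'
#' @param seed Master seed.
#' @param n_variants,region_length,bias_concentration,n_functional,n_constitutive,functional_mass,constitutive_mass,functional_core
#'   Library parameters, see [gen_library()].
#' @param dilution_factor,n_passages,doublings_per_regrowth,population_size_at_saturation
#'   Selection regime, see [selection_regime()].
#' @param growth_threshold Expression level required for growth; set above
#'   1 to disable selection (neutral passaging).
#' @param depth,flank5,flank3,error_rate Sequencing parameters, see
#'   [gen_reads()]; depth defaults to 3500 reads per sample.
#' @param max_flank_mismatch,pseudocount Extraction / fold parameters.
#' @param wt_threshold,control_ceiling,require_all_replicates Pathway-
#'   dependence filter, see [pathway_dependent_set()].
#' @param n_wt_replicates,n_control_replicates Independently grown
#'   selection cultures per strain (default 3 each).
#' @param consensus_pattern IUPAC pattern reported against the promoter
#'   set (default the 11-bp element consensus `GACRNANNACG`).
#' @param scan_window 3'-most bases of each promoter to scan.
#' @param outdir Optional directory for stage artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42,
                            n_variants = 100, region_length = 11,
                            bias_concentration = 0.0075,
                            n_functional = 5, n_constitutive = 2,
                            functional_mass = 0.00025,
                            constitutive_mass = 0.0001,
                            functional_core = NULL,
                            dilution_factor = 1000, n_passages = 3,
                            doublings_per_regrowth = log2(dilution_factor),
                            population_size_at_saturation = 1e9,
                            growth_threshold = 0.5,
                            depth = 3500,
                            flank5 = "ACGCTTGCAT", flank3 = "GATCCGTTAC",
                            error_rate = 0.001, max_flank_mismatch = 1,
                            pseudocount = 1,
                            wt_threshold = 90, control_ceiling = 10,
                            require_all_replicates = FALSE,
                            n_wt_replicates = 3, n_control_replicates = 3,
                            consensus_pattern = "GACRNANNACG",
                            scan_window = 1000,
                            outdir = NULL) {
  cfg <- as.list(environment())
  # Validate through the stage constructors; errors carry stage identity.
  selection_regime(dilution_factor, n_passages, doublings_per_regrowth,
                   population_size_at_saturation)
  if (n_wt_replicates < 1) stop_validation("need >= 1 wild-type replicate")
  if (n_control_replicates < 1) stop_validation("need >= 1 control replicate")
  iupac_chars(consensus_pattern, "consensus_pattern")
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic selection screen
#'
#' Executes, for one master seed: library generation; founding of a single
#' transformant pool; wild-type and pathway-deletion (`pdc2_delta`)
#' selections from that pool, each with independently seeded replicate
#' cultures; sequencing of the time-zero pool and each post-selection
#' culture; extraction and counting; fold enrichment of every post sample
#' against time zero; the pathway-dependence filter; and, when promoters
#' are supplied, best ungapped matches of each surviving sequence against
#' them.
#'
#' @param config A `pipeline_config`.
#' @param promoters Optional named character vector (or FASTA path) of
#'   promoter sequences for the best-match report.
#' @return List of class `selseq_run` with elements `library`, `pre_table`,
#'   `wt_tables`, `control_tables`, `wt_folds`, `control_folds`,
#'   `pathway_dependent`, `matches` (or NULL), and `summary` (unique
#'   counts, top-20 fractions pre/post, precision/recall against the
#'   planted truth).
#' @export
run_pipeline <- function(config, promoters = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_validation("`config` must be a pipeline_config")
  cfg <- config
  if (is.character(promoters) && length(promoters) == 1L &&
      file.exists(promoters)) {
    promoters <- read_promoters(promoters)
  }
  if (!is.null(promoters)) promoters <- as_named_sequences(promoters, "promoters")

  run_stage <- function(stage, expr) {
    tryCatch(expr, selseq_error = function(e) {
      stop(errorCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                          class = class(e)))
    })
  }

  lib <- run_stage("library", gen_library(
    n_variants = cfg$n_variants, length = cfg$region_length,
    bias_concentration = cfg$bias_concentration,
    n_functional = cfg$n_functional, n_constitutive = cfg$n_constitutive,
    seed = stage_seed(cfg$seed, 1L), functional_core = cfg$functional_core,
    functional_mass = cfg$functional_mass,
    constitutive_mass = cfg$constitutive_mass))
  regime <- selection_regime(cfg$dilution_factor, cfg$n_passages,
                             cfg$doublings_per_regrowth,
                             cfg$population_size_at_saturation)
  model <- as_fitness_model(lib, growth_threshold = cfg$growth_threshold,
                            doublings_if_growing = cfg$doublings_per_regrowth)

  # One transformant pool founds every culture, as when a pooled library is
  # split across strains and replicates.
  pool <- run_stage("founding", with_seed(stage_seed(cfg$seed, 2L), {
    cells <- stats::rmultinom(1L, size = regime$population_size_at_saturation,
                              prob = lib$initial_frequency)[, 1L]
    population(stats::setNames(as.double(cells), lib$sequence), "wild_type")
  }))

  select_one <- function(strain, replicate, seed_offset) {
    run_stage(sprintf("selection_%s_%d", strain, replicate),
              run_selection(lib, regime, model, strain = strain,
                            seed = stage_seed(cfg$seed, seed_offset),
                            initial_population = pool))
  }
  wt_traj <- lapply(seq_len(cfg$n_wt_replicates), function(r)
    select_one("wild_type", r, 10L + r))
  ctrl_traj <- lapply(seq_len(cfg$n_control_replicates), function(r)
    select_one("pdc2_delta", r, 30L + r))

  sequence_sample <- function(pop, sample_id, strain, time, replicate,
                              seed_offset) {
    reads <- run_stage(paste0("sequencing_", sample_id), gen_reads(
      pop$counts, depth = cfg$depth, flank5 = cfg$flank5, flank3 = cfg$flank3,
      error_rate = cfg$error_rate, seed = stage_seed(cfg$seed, seed_offset)))
    run_stage(paste0("counting_", sample_id), count_reads(
      reads, cfg$flank5, cfg$flank3, cfg$region_length,
      cfg$max_flank_mismatch, sample_id = sample_id, strain = strain,
      time = time, replicate = replicate))
  }

  pre_table <- sequence_sample(pool, "t0", "wild_type", "pre", 0L, 50L)
  wt_tables <- lapply(seq_along(wt_traj), function(r)
    sequence_sample(wt_traj[[r]][[length(wt_traj[[r]])]],
                    sprintf("wt_rep%d", r), "wild_type", "post", r, 60L + r))
  ctrl_tables <- lapply(seq_along(ctrl_traj), function(r)
    sequence_sample(ctrl_traj[[r]][[length(ctrl_traj[[r]])]],
                    sprintf("pdc2d_rep%d", r), "pdc2_delta", "post", r,
                    80L + r))

  wt_folds <- lapply(wt_tables, function(tab)
    fold_enrichment(pre_table, tab, pseudocount = cfg$pseudocount))
  ctrl_fold_list <- lapply(ctrl_tables, function(tab)
    fold_enrichment(pre_table, tab, pseudocount = cfg$pseudocount))
  # Mean control fold over replicates, on the union of their sequences.
  ctrl_seqs <- sort(Reduce(union, lapply(ctrl_fold_list, names)))
  ctrl_mat <- vapply(ctrl_fold_list, function(f) as.double(f[ctrl_seqs]),
                     numeric(length(ctrl_seqs)))
  ctrl_mat <- matrix(ctrl_mat, nrow = length(ctrl_seqs))
  control_folds <- stats::setNames(rowMeans(ctrl_mat, na.rm = TRUE), ctrl_seqs)

  pd <- pathway_dependent_set(wt_folds, control_folds,
                              wt_threshold = cfg$wt_threshold,
                              control_ceiling = cfg$control_ceiling,
                              require_all_replicates = cfg$require_all_replicates)

  matches <- NULL
  if (!is.null(promoters) && nrow(pd)) {
    matches <- do.call(rbind, lapply(pd$sequence, function(s) {
      per_target <- do.call(rbind, lapply(names(promoters), function(nm)
        cbind(query = s,
              best_ungapped_match(s, promoters[[nm]], both_strands = TRUE,
                                  target_name = nm))))
      best <- per_target[order(-per_target$identities, per_target$target_name), ,
                         drop = FALSE][1L, , drop = FALSE]
      best
    }))
    rownames(matches) <- NULL
  }

  truth <- lib$sequence[lib$is_functional]
  called <- pd$sequence
  precision <- if (length(called)) mean(called %in% truth) else NA_real_
  recall <- if (length(truth)) mean(truth %in% called) else NA_real_

  summary <- list(
    n_unique_pre = pre_table$n_unique,
    n_unique_post_wt = vapply(wt_tables, function(t) t$n_unique, 0L),
    top20_pre = top_k_fraction(pre_table, 20),
    top20_post_wt = vapply(wt_tables, top_k_fraction, 0, k = 20),
    top20_post_wt_mean = mean(vapply(wt_tables, top_k_fraction, 0, k = 20)),
    n_pathway_dependent = nrow(pd),
    precision_vs_planted = precision,
    recall_vs_planted = recall
  )

  run <- structure(list(config = cfg, library = lib, pre_table = pre_table,
                        wt_tables = wt_tables, control_tables = ctrl_tables,
                        wt_folds = wt_folds, control_folds = control_folds,
                        pathway_dependent = pd, matches = matches,
                        summary = summary),
                   class = "selseq_run")
  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  run
}

#' Write a pipeline run's artifacts to a directory
#'
#' @param run A `selseq_run`.
#' @param outdir Directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_library(run$library, file.path(outdir, "library.tsv"))
  write_count_table(run$pre_table, file.path(outdir, "counts_t0.tsv"))
  for (r in seq_along(run$wt_tables))
    write_count_table(run$wt_tables[[r]],
                      file.path(outdir, sprintf("counts_wt_rep%d.tsv", r)))
  for (r in seq_along(run$control_tables))
    write_count_table(run$control_tables[[r]],
                      file.path(outdir, sprintf("counts_pdc2d_rep%d.tsv", r)))
  pd <- run$pathway_dependent
  write_tsv(attr(pd, "all_records"), file.path(outdir, "enrichment.tsv"))
  if (!is.null(run$matches))
    write_tsv(run$matches, file.path(outdir, "matches.tsv"))
  s <- run$summary
  write_tsv(data.frame(statistic = c("n_unique_pre", "top20_pre",
                                     "top20_post_wt_mean",
                                     "n_pathway_dependent",
                                     "precision_vs_planted",
                                     "recall_vs_planted"),
                       value = c(s$n_unique_pre, s$top20_pre,
                                 s$top20_post_wt_mean, s$n_pathway_dependent,
                                 s$precision_vs_planted, s$recall_vs_planted),
                       stringsAsFactors = FALSE),
            file.path(outdir, "summary.tsv"))
  invisible(outdir)
}

#' @export
print.selseq_run <- function(x, ...) {
  s <- x$summary
  cat("Synthetic selection screen (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  library: %d variants (%d functional, %d constitutive)\n",
              nrow(x$library), sum(x$library$is_functional),
              sum(x$library$is_constitutive)))
  cat(sprintf("  unique sequences: %d pre; top-20 share %.1f%% pre, %.1f%% post (wt mean)\n",
              s$n_unique_pre, 100 * s$top20_pre, 100 * s$top20_post_wt_mean))
  cat(sprintf("  pathway-dependent set: %d sequences (precision %.2f, recall %.2f vs planted)\n",
              s$n_pathway_dependent, s$precision_vs_planted, s$recall_vs_planted))
  invisible(x)
}
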