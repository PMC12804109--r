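# End-to-end pipeline: simulate -> filter/normalize -> fit -> compare.
# These functions are the orchestration layer; each step is an exported
# module function, so a YAML config plus this file reproduces a whole run.

#' Build or load a run configuration
#'
#' A run is described by one YAML-serializable list: a `design` section
#' (see [sim_design()]), a `genotypes` section with `wt` and `mutant`
#' entries (`name`, `doubling_time`, and for the mutant `synthesis_factor`,
#' `decay_factor`, `jitter_sdlog`), an optional `fit` section (see
#' [fit_config()]), and a mandatory top-level `seed`. Defaults encode the
#' reference experiment: 90 min WT doubling time (growth rate 0.0077
#' min^-1), ~150.7 min for the slow-growing mutant (0.0046 min^-1), and
#' global mutant shifts of 1/3.7 in synthesis and 1/3.2 in decay.
#'
#' @param config A list, or a path to a YAML file containing one.
#' @return A validated list of class `run_config` with `design`
#'   ([sim_design()]), `genotypes` (list of two [genotype_spec()]s),
#'   `jitter_sdlog`, `fit` ([fit_config()]) and `seed`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path")
  assert_that(!is.null(config$seed), "config must declare a seed")
  design_args <- config$design %||% list()
  design_args$seed <- config$seed
  design <- do.call(sim_design, design_args)
  g <- config$genotypes %||% list()
  wt <- g$wt %||% list(name = "WT", doubling_time = 90)
  mut <- g$mutant %||% list(name = "mutant", doubling_time = log(2) / 0.0046,
                            synthesis_factor = 1 / 3.7,
                            decay_factor = 1 / 3.2)
  jitter <- mut$jitter_sdlog %||% 0
  mut$jitter_sdlog <- NULL
  fit <- do.call(fit_config, config$fit %||% list())
  structure(list(design = design,
                 genotypes = list(wt = do.call(genotype_spec, wt),
                                  mutant = do.call(genotype_spec, mut)),
                 jitter_sdlog = jitter,
                 fit = fit,
                 seed = as.integer(config$seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a two-genotype labeling experiment and write fixture files
#'
#' Draws ground-truth parameters, derives the mutant truth by the
#' configured global shifts, and simulates one joint labeling table and
#' one joint steady-state table covering both genotypes (shared
#' transcriptome and spike-in genes, so they can be normalized together).
#' Writes TSVs under `outdir`: `labeling_{counts,samples,genes}.tsv`,
#' `steady_{counts,samples,genes}.tsv`, `truth_<genotype>.tsv`, plus a
#' `config_echo.yaml` that reproduces the run.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @param outdir Output directory (created).
#' @return Invisibly, a list with the in-memory `labeling` and `steady`
#'   tables and both truth tibbles.
#' @export
pipeline_simulate <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  design <- cfg$design
  wt <- cfg$genotypes$wt; mut <- cfg$genotypes$mutant
  truth_wt <- draw_transcript_params(design)
  truth_mut <- apply_genotype_shift(truth_wt, mut,
                                    jitter_sdlog = cfg$jitter_sdlog,
                                    seed = design$seed + 1L)
  labeling <- ct_cbind(simulate_labeling_counts(truth_wt, wt, design),
                       simulate_labeling_counts(truth_mut, mut, design))
  steady <- ct_cbind(simulate_steady_counts(truth_wt, wt, design),
                     simulate_steady_counts(truth_mut, mut, design))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_count_table(labeling, outdir, "labeling")
  write_count_table(steady, outdir, "steady")
  write_truth(truth_wt, file.path(outdir, paste0("truth_", wt$name, ".tsv")))
  write_truth(truth_mut, file.path(outdir, paste0("truth_", mut$name, ".tsv")))
  yaml::write_yaml(run_config_as_list(cfg),
                   file.path(outdir, "config_echo.yaml"))
  invisible(list(labeling = labeling, steady = steady,
                 truth_wt = truth_wt, truth_mut = truth_mut))
}

run_config_as_list <- function(cfg) {
  list(
    seed = cfg$seed,
    design = cfg$design[setdiff(names(cfg$design), "seed")],
    genotypes = list(
      wt = cfg$genotypes$wt[c("name", "doubling_time", "synthesis_factor",
                              "decay_factor")],
      mutant = c(cfg$genotypes$mutant[c("name", "doubling_time",
                                        "synthesis_factor", "decay_factor")],
                 list(jitter_sdlog = cfg$jitter_sdlog))
    ),
    fit = unclass(cfg$fit)
  )
}

#' Filter, normalize and fit both genotypes of an experiment
#'
#' Applies the low-count filter (raw counts summed across *all* samples,
#' both genotypes), computes spike-in size factors jointly across each
#' experiment's samples, normalizes, anchors the abundance calibration on
#' the reference (WT) genotype, and runs [batch_fit()] per genotype.
#'
#' @param labeling,steady Raw `count_table`s covering both genotypes (as
#'   written by [pipeline_simulate()], or loaded with
#'   [read_count_table()]).
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, writes
#'   `rates_<genotype>.tsv` per genotype.
#' @return List of `rate_fit`s, one per genotype (names from the config),
#'   with attribute `stage_counts` recording genes surviving each stage.
#' @export
pipeline_fit <- function(labeling, steady, config, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  n0 <- sum(labeling$genes$species == "host")
  lab_f <- filter_low_counts(labeling, 15)
  ss_f <- filter_low_counts(steady, 15)
  lab_n <- normalize_counts(lab_f, spike_size_factors(lab_f))
  ss_n <- normalize_counts(ss_f, spike_size_factors(ss_f))
  mpu <- molecules_per_unit(ss_n, cfg$genotypes$wt$name, cfg$fit)
  fits <- lapply(cfg$genotypes, function(g)
    batch_fit(lab_n, ss_n, g, cfg$fit, mpu = mpu))
  names(fits) <- vapply(cfg$genotypes, `[[`, "", "name")
  attr(fits, "stage_counts") <- c(
    host_genes = n0,
    after_filter = sum(lab_f$genes$species == "host"),
    converged = vapply(fits, function(f) nrow(f$estimates), integer(1))
  )
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    for (nm in names(fits))
      write_rate_estimates(fits[[nm]], file.path(outdir,
                                                 paste0("rates_", nm, ".tsv")))
  }
  fits
}

#' Compare genotype rate estimates and summarize buffering
#'
#' Computes per-transcript fold changes on the shared converged genes,
#' median WT/mutant ratios with Wilcoxon rank-sum p-values for synthesis,
#' decay and half-life, the Spearman buffering correlation, and the top
#' 20th-percentile gene sets for synthesis and decay change.
#'
#' @param wt,mut Estimate tibbles (e.g. `fits$WT$estimates`).
#' @param outdir Optional directory; writes `comparison.tsv` and
#'   `summary.json` when given.
#' @param top_pct Percentile for the top gene sets.
#' @return List with `comparison` (fold-change tibble) and `summary`.
#' @export
pipeline_compare <- function(wt, mut, outdir = NULL, top_pct = 20) {
  cmp <- rate_fold_changes(wt, mut)
  shared <- cmp$gene_id
  wt_s <- wt[match(shared, wt$gene_id), ]
  mut_s <- mut[match(shared, mut$gene_id), ]
  syn <- compare_rate_distributions(wt_s$synthesis, mut_s$synthesis)
  dec <- compare_rate_distributions(wt_s$alpha, mut_s$alpha)
  hl <- compare_rate_distributions(wt_s$half_life_min, mut_s$half_life_min)
  rho <- buffering_correlation(cmp)
  tops <- list(synthesis = top_percentile(cmp, "synthesis", top_pct),
               decay = top_percentile(cmp, "decay", top_pct))
  summary <- list(
    n_shared = length(shared),
    synthesis = syn, decay = dec, half_life = hl,
    buffering = rho,
    top_sets = lapply(tops, function(s)
      list(name = s$name, size = length(s$members)))
  )
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    readr::write_tsv(cmp, file.path(outdir, "comparison.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(comparison = cmp, summary = summary, top_sets = tops)
}
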