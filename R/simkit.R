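# Synthetic-data generator: labeling time courses, steady-state libraries
# and reporter shutoff curves with known kinetic ground truth.

#' Genotype description for the kinetic model
#'
#' Carries a strain's growth-rate constant (`alpha_growth = ln2 /
#' doubling_time`, the dilution term the labeling model subtracts from the
#' observed exponent) together with the global synthesis and decay
#' multipliers the simulator applies when generating that genotype.
#' The wild-type and slow-growing mutant of the reference design have
#' `alpha_growth` 0.0077 and 0.0046 min^-1 (doubling times 90 and
#' ~150.7 min).
#'
#' @param name Strain label, e.g. `"WT"`.
#' @param doubling_time Doubling time in minutes (> 0).
#' @param synthesis_factor,decay_factor Global multipliers (> 0) applied by
#'   [apply_genotype_shift()]; 1 means unchanged.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(name, doubling_time, synthesis_factor = 1,
                          decay_factor = 1) {
  assert_that(is.character(name) && nzchar(name), "name must be a string")
  assert_that(is.numeric(doubling_time) && doubling_time > 0,
              "doubling_time must be > 0")
  assert_that(synthesis_factor > 0 && decay_factor > 0,
              "genotype factors must be > 0")
  structure(
    list(name = name, doubling_time = doubling_time,
         alpha_growth = log(2) / doubling_time,
         synthesis_factor = synthesis_factor, decay_factor = decay_factor),
    class = "genotype_spec"
  )
}

#' Simulation design for a labeling experiment
#'
#' Collects the experimental design knobs of the generator. Defaults encode
#' the reference experiment: labeling durations 6, 9, 12, 24 and 90 min,
#' two biological replicates, a 14:1 host:spike cell ratio, and negative
#' binomial counting noise (dispersion 0 degenerates to Poisson).
#'
#' @param n_transcripts Number of host transcripts to simulate (>= 1).
#' @param labeling_times Strictly increasing positive labeling durations, min.
#' @param n_replicates Replicates per time point (>= 1).
#' @param spike_ratio Host cells per spike-in cell (> 0); default 14.
#' @param n_spike_genes Number of spike-in genes carried in the table.
#' @param library_size Expected reads in a fully-labeled sample.
#' @param nb_dispersion Negative binomial dispersion shared across genes;
#'   0 means Poisson noise.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_transcripts = 2000,
                       labeling_times = c(6, 9, 12, 24, 90),
                       n_replicates = 2,
                       spike_ratio = 14,
                       n_spike_genes = 2000,
                       library_size = 5e6,
                       nb_dispersion = 0.05,
                       seed) {
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1,
              "an integer seed is mandatory")
  assert_that(n_transcripts >= 1, "n_transcripts must be >= 1")
  assert_that(length(labeling_times) >= 1 && all(labeling_times > 0) &&
                all(diff(labeling_times) > 0),
              "labeling_times must be positive and strictly increasing")
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  assert_that(spike_ratio > 0, "spike_ratio must be > 0")
  assert_that(n_spike_genes >= 1, "n_spike_genes must be >= 1")
  assert_that(library_size > 0, "library_size must be > 0")
  assert_that(nb_dispersion >= 0, "nb_dispersion must be >= 0")
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         labeling_times = as.numeric(labeling_times),
         n_replicates = as.integer(n_replicates),
         spike_ratio = spike_ratio,
         n_spike_genes = as.integer(n_spike_genes),
         library_size = library_size,
         nb_dispersion = nb_dispersion,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Draw ground-truth kinetic parameters for a simulated transcriptome
#'
#' Decay rate constants `alpha` (min^-1, the fitted exponent after the
#' growth-rate correction) are lognormal; by default their median is the
#' reference wild-type median decay rate 0.259 min^-1. Synthesis rates
#' `k_syn` are lognormal too; equilibrium abundances follow as
#' `m_eq = k_syn / alpha` and both are rescaled by a common factor so the
#' simulated cell totals `total_mrna_per_cell` mRNA molecules, preserving
#' `m_eq * alpha = k_syn` exactly.
#'
#' @param design A [sim_design()]; `design$seed` drives the draw.
#' @param alpha_meanlog,alpha_sdlog Lognormal location/scale for alpha;
#'   `alpha_sdlog = 0` makes every alpha equal `exp(alpha_meanlog)`.
#' @param ksyn_meanlog,ksyn_sdlog Lognormal location/scale for the raw
#'   synthesis draw (location is immaterial after rescaling).
#' @param total_mrna_per_cell Total mRNA molecules per cell the simulated
#'   transcriptome is rescaled to; `NULL` skips rescaling.
#' @return Tibble with columns `gene_id`, `k_syn`, `alpha`, `m_eq`.
#' @export
draw_transcript_params <- function(design,
                                   alpha_meanlog = log(0.259),
                                   alpha_sdlog = 0.8,
                                   ksyn_meanlog = log(8),
                                   ksyn_sdlog = 1,
                                   total_mrna_per_cell = 60000) {
  stopifnot(inherits(design, "sim_design"))
  assert_that(alpha_sdlog >= 0 && ksyn_sdlog >= 0,
              "lognormal scale parameters must be >= 0")
  n <- design$n_transcripts
  draws <- with_seed(design$seed, {
    list(alpha = rlnorm(n, alpha_meanlog, alpha_sdlog),
         k_syn = rlnorm(n, ksyn_meanlog, ksyn_sdlog))
  })
  m_eq <- draws$k_syn / draws$alpha
  k_syn <- draws$k_syn
  if (!is.null(total_mrna_per_cell)) {
    f <- total_mrna_per_cell / sum(m_eq)
    m_eq <- m_eq * f
    k_syn <- k_syn * f
  }
  tibble::tibble(
    gene_id = sprintf("gene_%05d", seq_len(n)),
    k_syn = k_syn, alpha = draws$alpha, m_eq = m_eq
  )
}

#' Labeled abundance under the approach-to-equilibrium model
#'
#' `Y(t) = Yeq * (1 - exp(-alpha * t))`: during a pulse-only labeling
#' experiment the labeled pool of a transcript rises from 0 toward its
#' steady-state abundance `Yeq` with rate constant `alpha` (the observed
#' decay constant, growth-corrected). Vectorized over all arguments.
#'
#' @param t Labeling time, minutes (>= 0).
#' @param yeq Equilibrium (steady-state) abundance (> 0).
#' @param alpha Decay rate constant, min^-1 (> 0).
#' @return Labeled abundance, same units as `yeq`.
#' @export
labeled_abundance <- function(t, yeq, alpha) {
  assert_that(all(t >= 0), "labeling time must be >= 0")
  assert_that(all(yeq > 0), "yeq must be > 0")
  assert_that(all(alpha > 0), "alpha must be > 0")
  yeq * (1 - exp(-alpha * t))
}

#' Apply a global genotype shift to ground-truth parameters
#'
#' Multiplies every transcript's synthesis rate by the genotype's
#' `synthesis_factor` and its decay constant by `decay_factor`, optionally
#' times independent per-gene lognormal jitter with median 1 (so the global
#' factors are exactly the median fold changes); `m_eq` is recomputed so
#' `m_eq * alpha = k_syn` still holds for every gene.
#'
#' @param truth Tibble from [draw_transcript_params()].
#' @param spec A [genotype_spec()] supplying the factors.
#' @param jitter_sdlog Lognormal sdlog of the per-gene jitter (>= 0;
#'   0 = deterministic shift).
#' @param seed Seed for the jitter draw (required when `jitter_sdlog > 0`).
#' @return Tibble with the same genes and columns as `truth`.
#' @export
apply_genotype_shift <- function(truth, spec, jitter_sdlog = 0, seed = NULL) {
  stopifnot(inherits(spec, "genotype_spec"))
  assert_that(jitter_sdlog >= 0, "jitter_sdlog must be >= 0")
  n <- nrow(truth)
  if (jitter_sdlog > 0) {
    assert_that(!is.null(seed), "a seed is required when jitter_sdlog > 0")
    jit <- with_seed(seed, list(s = rlnorm(n, 0, jitter_sdlog),
                                d = rlnorm(n, 0, jitter_sdlog)))
  } else {
    jit <- list(s = rep(1, n), d = rep(1, n))
  }
  k_syn <- truth$k_syn * spec$synthesis_factor * jit$s
  alpha <- truth$alpha * spec$decay_factor * jit$d
  tibble::tibble(gene_id = truth$gene_id, k_syn = k_syn, alpha = alpha,
                 m_eq = k_syn / alpha)
}

# Fixed relative abundance profile for the spike-in genes (deterministic,
# lognormal quantiles) summing to the spike RNA content per host cell.
spike_weights <- function(design, spike_mrna_per_cell = 60000) {
  w <- stats::qlnorm(stats::ppoints(design$n_spike_genes), 0, 1)
  w / sum(w) * spike_mrna_per_cell / design$spike_ratio
}

spike_gene_sheet <- function(design) {
  tibble::tibble(gene_id = sprintf("spike_%03d", seq_len(design$n_spike_genes)),
                 species = "spike")
}

# Expected read matrix for a set of samples. `host_weight` is a
# genes x samples matrix of per-cell labeled abundances; spike genes are at
# equilibrium so their per-cell content is constant across samples. One
# read-per-molecule scale per genotype converts molecules to expected
# reads, anchored so a fully-labeled sample totals `library_size`.
expected_counts_matrix <- function(host_weight, truth, design,
                                   spike_mrna_per_cell = 60000) {
  sw <- spike_weights(design, spike_mrna_per_cell)
  scale <- design$library_size /
    (sum(truth$m_eq) + sum(sw))
  spike_block <- matrix(rep(sw, ncol(host_weight)), nrow = length(sw),
                        dimnames = list(NULL, colnames(host_weight)))
  rbind(host_weight, spike_block) * scale
}

labeling_sample_sheet <- function(genotype, design) {
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      time_min = design$labeling_times)
  tibble::tibble(
    sample_id = paste0(genotype$name, "_t", grid$time_min, "_r",
                       grid$replicate),
    genotype = genotype$name,
    time_min = grid$time_min,
    replicate = as.integer(grid$replicate)
  )
}

#' Expected (noise-free) labeling counts
#'
#' Returns the expected read matrix of [simulate_labeling_counts()] as a
#' real-valued `count_table` (flagged normalized so non-integers are
#' allowed). Host genes follow [labeled_abundance()] across the labeling
#' times; spike genes are constant, the spike cells being pre-labeled to
#' equilibrium before mixing.
#'
#' @inheritParams simulate_labeling_counts
#' @return A `count_table` of expected reads.
#' @export
expected_labeling_counts <- function(truth, genotype, design,
                                     spike_mrna_per_cell = 60000) {
  stopifnot(inherits(genotype, "genotype_spec"), inherits(design, "sim_design"))
  assert_that(nrow(truth) >= 1, "truth must be non-empty")
  samples <- labeling_sample_sheet(genotype, design)
  host <- vapply(samples$time_min, function(t)
    labeled_abundance(t, truth$m_eq, truth$alpha), numeric(nrow(truth)))
  host <- matrix(host, nrow = nrow(truth),
                 dimnames = list(NULL, samples$sample_id))
  mu <- expected_counts_matrix(host, truth, design, spike_mrna_per_cell)
  genes <- dplyr::bind_rows(
    tibble::tibble(gene_id = truth$gene_id, species = "host"),
    spike_gene_sheet(design)
  )
  count_table(mu, genes, samples, normalized = TRUE)
}

# Draw counts around an expected matrix with the design's noise model.
draw_counts <- function(mu, design, seed) {
  with_seed(seed, {
    k <- length(mu)
    cnt <- if (design$nb_dispersion == 0) {
      rpois(k, lambda = mu)
    } else {
      rnbinom(k, mu = mu, size = 1 / design$nb_dispersion)
    }
    matrix(cnt, nrow = nrow(mu), dimnames = dimnames(mu))
  })
}

#' Simulate a 4tU labeling count time course
#'
#' Forward model for the sequencing readout of a pulse-only labeling
#' experiment: expected host-gene reads are proportional to the labeled
#' abundance `m_eq * (1 - exp(-alpha t))` at each labeling duration,
#' spike-in genes contribute constant expected reads set by the host:spike
#' cell ratio (the spike cells are pre-labeled, already at equilibrium),
#' and counts are drawn with negative binomial (or Poisson) noise.
#' Deterministic given the seed.
#'
#' @param truth Ground-truth tibble (`gene_id`, `k_syn`, `alpha`, `m_eq`).
#' @param genotype A [genotype_spec()] naming the samples.
#' @param design A [sim_design()].
#' @param spike_mrna_per_cell Labeled RNA content of one spike cell, in the
#'   same molecule units as `m_eq` (a fixed property of the spike species).
#' @param seed Seed for the count draw; defaults to `design$seed` offset by
#'   the genotype name so two genotypes simulated from one design receive
#'   independent noise.
#' @return A raw `count_table` (host + spike genes, one column per
#'   time x replicate sample).
#' @export
simulate_labeling_counts <- function(truth, genotype, design,
                                     spike_mrna_per_cell = 60000,
                                     seed = NULL) {
  expected <- expected_labeling_counts(truth, genotype, design,
                                       spike_mrna_per_cell)
  if (is.null(seed)) seed <- design$seed + seed_offset(genotype$name)
  counts <- draw_counts(expected$counts, design, seed)
  count_table(counts, expected$genes, expected$samples)
}

#' Simulate steady-state (total RNA) counts
#'
#' Expected host-gene reads are proportional to the equilibrium abundance
#' `m_eq`; spike genes behave as in [simulate_labeling_counts()]. Used for
#' the abundance arm of the rate pipeline.
#'
#' @inheritParams simulate_labeling_counts
#' @param n_replicates Number of steady-state libraries (defaults to the
#'   design's replicate count).
#' @return A raw `count_table` with `time_min = NA` samples.
#' @export
simulate_steady_counts <- function(truth, genotype, design,
                                   n_replicates = design$n_replicates,
                                   spike_mrna_per_cell = 60000,
                                   seed = NULL) {
  stopifnot(inherits(genotype, "genotype_spec"), inherits(design, "sim_design"))
  assert_that(nrow(truth) >= 1, "truth must be non-empty")
  samples <- tibble::tibble(
    sample_id = sprintf("%s_ss_r%d", genotype$name, seq_len(n_replicates)),
    genotype = genotype$name,
    time_min = NA_real_,
    replicate = seq_len(n_replicates)
  )
  host <- matrix(rep(truth$m_eq, n_replicates), nrow = nrow(truth),
                 dimnames = list(NULL, samples$sample_id))
  mu <- expected_counts_matrix(host, truth, design, spike_mrna_per_cell)
  if (is.null(seed)) seed <- design$seed + seed_offset(genotype$name) + 7919L
  counts <- draw_counts(mu, design, seed)
  genes <- dplyr::bind_rows(
    tibble::tibble(gene_id = truth$gene_id, species = "host"),
    spike_gene_sheet(design)
  )
  count_table(counts, genes, samples)
}

#' Simulate a transcription-shutoff reporter decay series
#'
#' After the promoter is shut off the reporter signal decays as
#' `S0 * 2^(-t / half_life)`, measured against a constant loading control;
#' both are perturbed multiplicatively with coefficient of variation
#' `noise_cv` (`0` gives the exact exponential).
#'
#' @param half_life Reporter mRNA half-life, minutes (> 0).
#' @param times Sampling times since shutoff, minutes (>= 0).
#' @param noise_cv Multiplicative noise CV (>= 0).
#' @param seed Seed (required when `noise_cv > 0`).
#' @param s0 Signal at t = 0; `loading` the control band intensity.
#' @param condition Label carried into the output.
#' @return Tibble with columns `condition`, `time_min`, `signal`, `loading`.
#' @export
simulate_shutoff_series <- function(half_life, times = c(0, 2, 4, 8, 12, 20),
                                    noise_cv = 0, seed = NULL,
                                    s0 = 100, loading = 50,
                                    condition = "reporter") {
  assert_that(half_life > 0, "half_life must be > 0")
  assert_that(all(times >= 0), "times must be >= 0")
  assert_that(noise_cv >= 0, "noise_cv must be >= 0")
  n <- length(times)
  eps <- if (noise_cv > 0) {
    assert_that(!is.null(seed), "a seed is required when noise_cv > 0")
    with_seed(seed, list(s = rnorm(n, 0, noise_cv), l = rnorm(n, 0, noise_cv)))
  } else {
    list(s = rep(0, n), l = rep(0, n))
  }
  tibble::tibble(
    condition = condition,
    time_min = as.numeric(times),
    signal = {
      raw <- s0 * 2^(-times / half_life) * (1 + eps$s)
      ifelse(raw > 0, raw, s0 * 1e-12)   # guard against negative noise draws
    },
    loading = {
      raw <- loading * (1 + eps$l)
      ifelse(raw > 0, raw, loading * 1e-12)
    }
  )
}

#' Write / read a ground-truth parameter table as TSV
#'
#' @param truth Tibble (`gene_id`, `k_syn`, `alpha`, `m_eq`).
#' @param path File path.
#' @return `read_truth` returns the tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth[, c("gene_id", "k_syn", "alpha", "m_eq")], path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene_id = "c", k_syn = "d",
                                          alpha = "d", m_eq = "d"))
}
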