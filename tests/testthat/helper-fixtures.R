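# Small fixtures built in code for the unit tests.

toy_count_table <- function(counts, species, genotype = "WT",
                            time_min = NULL, normalized = FALSE) {
  counts <- as.matrix(counts)
  n_s <- ncol(counts)
  if (is.null(time_min)) time_min <- rep(NA_real_, n_s)
  count_table(
    counts,
    genes = tibble::tibble(
      gene_id = if (!is.null(rownames(counts))) rownames(counts) else
        sprintf("g%02d", seq_len(nrow(counts))),
      species = species),
    samples = tibble::tibble(
      sample_id = if (!is.null(colnames(counts))) colnames(counts) else
        sprintf("s%02d", seq_len(n_s)),
      genotype = rep_len(genotype, n_s),
      time_min = rep_len(time_min, n_s),
      replicate = seq_len(n_s)),
    normalized = normalized
  )
}

wt_spec <- function() genotype_spec("WT", 90)

mutant_spec <- function(synthesis_factor = 1 / 3.7, decay_factor = 1 / 3.2) {
  genotype_spec("mutant", log(2) / 0.0046,
                synthesis_factor = synthesis_factor,
                decay_factor = decay_factor)
}

# Noise-free normalized labeling + steady tables for a set of
# (alpha, yeq) ground truths on the default time grid.
exact_experiment <- function(alpha, yeq, genotype = wt_spec(),
                             times = c(6, 9, 12, 24, 90), n_rep = 2) {
  truth <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_along(alpha)),
    k_syn = alpha * yeq, alpha = alpha, m_eq = yeq)
  grid <- expand.grid(rep = seq_len(n_rep), t = times)
  lab_counts <- vapply(grid$t, function(t)
    yeq * (1 - exp(-alpha * t)), numeric(length(alpha)))
  lab_counts <- matrix(lab_counts, nrow = length(alpha))
  colnames(lab_counts) <- paste0(genotype$name, "_t", grid$t, "_r", grid$rep)
  lab <- count_table(
    rbind(lab_counts, spike = rep(1000, ncol(lab_counts))),
    genes = tibble::tibble(gene_id = c(truth$gene_id, "spike01"),
                           species = c(rep("host", length(alpha)), "spike")),
    samples = tibble::tibble(sample_id = colnames(lab_counts),
                             genotype = genotype$name,
                             time_min = grid$t,
                             replicate = as.integer(grid$rep)),
    normalized = TRUE)
  steady <- count_table(
    cbind(r1 = c(yeq, 1000), r2 = c(yeq, 1000)),
    genes = lab$genes,
    samples = tibble::tibble(sample_id = c("ss1", "ss2"),
                             genotype = genotype$name,
                             time_min = NA_real_, replicate = 1:2),
    normalized = TRUE)
  list(truth = truth, labeling = lab, steady = steady)
}
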