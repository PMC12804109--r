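# Approach-to-equilibrium kinetic fitting and derived rate quantities.
#
# Model: Y(t) = Yeq * (1 - exp(-alpha * t)), where alpha is the RNA decay
# rate constant after the growth-rate correction (alpha = alpha_RNA -
# alpha_growth, with alpha_growth = ln2 / doubling time). Half-life and
# synthesis rate derive from alpha: half-life = ln2 / alpha, synthesis =
# alpha * [mRNA].

#' Growth-rate constant from a doubling time
#'
#' `ln2 / doubling_time`, the dilution term that slow growth contributes to
#' the observed labeling exponent (0.0077 min^-1 for a 90 min doubling
#' time, 0.0046 min^-1 at ~150.7 min).
#'
#' @param doubling_time Doubling time, minutes (> 0).
#' @return Growth rate, min^-1.
#' @export
growth_rate <- function(doubling_time) {
  assert_that(all(doubling_time > 0), "doubling_time must be > 0")
  log(2) / doubling_time
}

#' mRNA half-life from a decay rate constant
#'
#' @param alpha Decay rate constant, min^-1 (> 0).
#' @return Half-life in minutes, `ln2 / alpha`.
#' @export
half_life <- function(alpha) {
  assert_that(all(alpha > 0), "alpha must be > 0")
  log(2) / alpha
}

#' Per-cell mRNA abundance from steady-state read counts
#'
#' Converts a gene's share of steady-state host reads into molecules per
#' cell, assuming the transcriptome totals `total_mrna_per_cell` molecules
#' (default 60,000).
#'
#' @param gene_counts Steady-state reads for the gene(s).
#' @param total_counts Total steady-state host reads (> 0).
#' @param total_mrna_per_cell Total mRNA molecules assumed per cell.
#' @return Abundance, molecules per cell.
#' @export
abundance_from_counts <- function(gene_counts, total_counts,
                                  total_mrna_per_cell = 60000) {
  assert_that(length(total_counts) == 1 && total_counts > 0,
              "total_counts must be a single positive number")
  assert_that(all(gene_counts >= 0) && all(gene_counts <= total_counts),
              "gene_counts must lie in [0, total_counts]")
  gene_counts / total_counts * total_mrna_per_cell
}

#' Synthesis rate from decay constant and abundance
#'
#' At steady state production balances turnover, so the synthesis rate is
#' `alpha * [mRNA]` molecules per minute per cell.
#'
#' @param alpha Decay rate constant, min^-1 (> 0).
#' @param m_eq Abundance, molecules per cell (>= 0).
#' @return Synthesis rate, molecules min^-1 cell^-1.
#' @export
synthesis_rate <- function(alpha, m_eq) {
  assert_that(all(alpha > 0), "alpha must be > 0")
  assert_that(all(m_eq >= 0), "m_eq must be >= 0")
  alpha * m_eq
}

#' Configuration for the kinetic fit
#'
#' @param alpha_lower,alpha_upper Bounds for the decay constant, min^-1.
#'   A transcript with `alpha` at the default ceiling of 1.5 min^-1 is
#'   99.99% labeled by the first (6 min) time point, so faster rates are
#'   indistinguishable from one another (and a 28 s half-life is already
#'   below the fastest known yeast mRNAs). Estimates at the lower bound
#'   are flagged non-converged; estimates at the ceiling are *kept*,
#'   pinned to the ceiling and flagged `saturated = TRUE` ("at least this
#'   fast") so population summaries are not truncated toward slow
#'   transcripts.
#' @param yeq_upper_mult Upper bound on `Yeq` as a multiple of the largest
#'   observed value.
#' @param min_points Minimum number of distinct time points (two free
#'   parameters need at least three).
#' @param rel_tol Optimizer tolerance on log(alpha).
#' @param grid_points Size of the coarse log-spaced alpha grid used to
#'   bracket the minimum before 1-D refinement.
#' @param loss Residual scale for the least-squares objective. `"log"`
#'   (default) minimizes squared residuals of `log(y)`, matching the
#'   roughly constant coefficient of variation of overdispersed count
#'   noise; `"linear"` minimizes plain squared residuals of `y`, which
#'   lets the (noisy) plateau dominate and skews decay constants of
#'   fast-saturating transcripts downward. Both recover noise-free data
#'   exactly.
#' @param total_mrna_per_cell Molecules of mRNA assumed per cell for the
#'   abundance calibration (default 60,000).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(alpha_lower = 1e-4, alpha_upper = 1.5,
                       yeq_upper_mult = 10, min_points = 3,
                       rel_tol = 1e-10, grid_points = 60,
                       loss = c("log", "linear"),
                       total_mrna_per_cell = 60000) {
  assert_that(alpha_lower > 0 && alpha_upper > alpha_lower,
              "alpha bounds must satisfy 0 < lower < upper")
  assert_that(yeq_upper_mult > 1, "yeq_upper_mult must be > 1")
  assert_that(min_points >= 3, "min_points must be >= 3")
  structure(
    list(alpha_lower = alpha_lower, alpha_upper = alpha_upper,
         yeq_upper_mult = yeq_upper_mult, min_points = as.integer(min_points),
         rel_tol = rel_tol, grid_points = as.integer(grid_points),
         loss = match.arg(loss),
         total_mrna_per_cell = total_mrna_per_cell),
    class = "fit_config"
  )
}

# Least-squares Yeq for a fixed alpha (variable projection): with
# f = 1 - exp(-alpha t), the optimal Yeq is <y, f> / <f, f> on the linear
# scale, and log(Yeq) = mean(log y - log f) on the log scale.
profile_rss_linear <- function(log_alpha, t, y) {
  f <- 1 - exp(-exp(log_alpha) * t)
  ff <- sum(f * f)
  if (ff == 0) return(sum(y * y))
  yeq <- sum(y * f) / ff
  sum((y - yeq * f)^2)
}

profile_rss_log <- function(log_alpha, t, ly) {
  lf <- log(-expm1(-exp(log_alpha) * t))   # log(1 - e^(-alpha t)), stable
  r <- ly - lf
  sum((r - mean(r))^2)
}

#' Fit the approach-to-equilibrium model to one labeling time course
#'
#' Least-squares estimation of `(Yeq, alpha)` in
#' `y = Yeq (1 - exp(-alpha t))`, on the residual scale set by
#' `cfg$loss` (variance-stabilized log residuals by default). `Yeq` is
#' profiled out in closed form given `alpha` (variable projection), and
#' the one-dimensional residual surface is minimized deterministically
#' over `log(alpha)`: a coarse log-spaced grid brackets the optimum,
#' which golden-section/parabolic refinement then localizes. Replicate
#' measurements enter as separate residuals. The fit never throws on
#' pathological data: failures and estimates at the lower bound come back
#' with `converged = FALSE` and a reason, while fits at the upper bound
#' are kept, pinned to the ceiling, and flagged `saturated`. The reported
#' `rss` is on the fitting scale.
#'
#' @param t Labeling times, minutes (replicates repeat a time).
#' @param y Observed normalized labeled abundances (>= 0), same length.
#' @param cfg A [fit_config()].
#' @param alpha_growth Growth-rate constant of the strain, min^-1; only
#'   used to report `alpha_rna = alpha + alpha_growth`.
#' @param gene_id Optional label carried into the result.
#' @return One-row tibble: `gene_id`, `yeq`, `alpha`, `alpha_rna`,
#'   `half_life_min`, `converged`, `saturated`, `reason`, `rss`,
#'   `n_points`.
#' @export
fit_approach_to_equilibrium <- function(t, y, cfg = fit_config(),
                                        alpha_growth = 0,
                                        gene_id = NA_character_) {
  stopifnot(inherits(cfg, "fit_config"))
  assert_that(length(t) == length(y), "t and y must have equal length")
  assert_that(all(t >= 0), "times must be >= 0")
  assert_that(all(y >= 0), "labeled abundances must be >= 0")
  fail <- function(reason) tibble::tibble(
    gene_id = gene_id, yeq = NA_real_, alpha = NA_real_,
    alpha_rna = NA_real_, half_life_min = NA_real_,
    converged = FALSE, saturated = FALSE, reason = reason, rss = NA_real_,
    n_points = length(t)
  )
  if (length(unique(t)) < cfg$min_points) return(fail("too few distinct time points"))
  if (all(y == 0)) return(fail("all-zero trajectory"))

  if (cfg$loss == "log") {
    # the model passes through 0 at t = 0, so those points carry no
    # information on the log scale; zeros are clamped scale-invariantly
    keep <- t > 0
    tt <- t[keep]
    if (length(unique(tt)) < cfg$min_points)
      return(fail("too few distinct positive time points"))
    eps <- min(y[y > 0]) / 2
    ly <- log(pmax(y[keep], eps))
    objective <- function(la) profile_rss_log(la, tt, ly)
  } else {
    tt <- t
    objective <- function(la) profile_rss_linear(la, tt, y)
  }

  lo <- log(cfg$alpha_lower); hi <- log(cfg$alpha_upper)
  grid <- seq(lo, hi, length.out = cfg$grid_points)
  rss_grid <- vapply(grid, objective, numeric(1))
  i <- which.min(rss_grid)
  lower <- grid[max(1, i - 1)]
  upper <- grid[min(length(grid), i + 1)]
  opt <- optimize(objective, c(lower, upper), tol = cfg$rel_tol)
  log_alpha <- opt$minimum
  # refinement can't beat an interior grid point it never explored
  if (rss_grid[i] < opt$objective) log_alpha <- grid[i]
  alpha <- exp(log_alpha)
  if (cfg$loss == "log") {
    lf <- log(-expm1(-alpha * tt))
    yeq <- exp(mean(ly - lf))
    rss <- sum((ly - lf - log(yeq))^2)
  } else {
    f <- 1 - exp(-alpha * tt)
    yeq <- sum(y * f) / sum(f * f)
    rss <- sum((y - yeq * f)^2)
  }

  saturated <- alpha >= cfg$alpha_upper * (1 - 1e-6)
  if (saturated) alpha <- cfg$alpha_upper
  at_lower <- alpha <= cfg$alpha_lower * (1 + 1e-6)
  bad_yeq <- !is.finite(yeq) || yeq <= 0 || yeq > cfg$yeq_upper_mult * max(y)
  if (at_lower || bad_yeq) {
    out <- fail(if (at_lower) "alpha at lower bound (no decay signal)" else
      "Yeq outside bounds")
    out$yeq <- yeq; out$alpha <- alpha; out$rss <- rss
    return(out)
  }
  tibble::tibble(
    gene_id = gene_id, yeq = yeq, alpha = alpha,
    alpha_rna = alpha + alpha_growth,
    half_life_min = log(2) / alpha,
    converged = TRUE, saturated = saturated,
    reason = if (saturated) "alpha at ceiling: faster than the grid resolves"
      else NA_character_,
    rss = rss,
    n_points = length(t)
  )
}

#' Fit kinetic rates for every host gene of a labeling experiment
#'
#' Runs [fit_approach_to_equilibrium()] on each host gene of a normalized
#' labeling table (replicates fit jointly as separate residuals), then
#' derives per-transcript half-lives, abundances and synthesis rates from
#' the normalized steady-state table.
#'
#' Abundance calibration: normalized steady-state counts are converted to
#' molecules per cell through a single `molecules_per_unit` factor. By
#' default it is anchored on the table at hand (that genotype's mean host
#' total equals `cfg$total_mrna_per_cell`); pass the factor computed from a
#' reference genotype ([molecules_per_unit()]) when comparing genotypes, so
#' that global abundance shifts measured by the spike-ins survive the
#' conversion.
#'
#' @param table Normalized labeling `count_table` (filter + normalize
#'   first); only samples of `genotype` and host genes are used.
#' @param steady Normalized steady-state `count_table` for the same
#'   experiment.
#' @param genotype A [genotype_spec()]; supplies the sample subset and
#'   `alpha_growth`.
#' @param cfg A [fit_config()].
#' @param mpu Molecules per normalized count unit; `NULL` anchors on
#'   `steady`'s own host total.
#' @return List of class `rate_fit` with `estimates` (converged genes:
#'   `gene_id`, `alpha`, `alpha_rna`, `half_life_min`, `m_eq`, `synthesis`,
#'   `yeq`, `rss`, `n_points`) and `failures` (`gene_id`, `reason`).
#' @export
batch_fit <- function(table, steady, genotype, cfg = fit_config(),
                      mpu = NULL) {
  stopifnot(inherits(table, "count_table"), inherits(steady, "count_table"),
            inherits(genotype, "genotype_spec"))
  assert_that(table$normalized && steady$normalized,
              "batch_fit expects spike-normalized tables")
  lab <- ct_subset(table,
                   sample_ids = table$samples$sample_id[
                     table$samples$genotype == genotype$name])
  ss <- ct_subset(steady,
                  sample_ids = steady$samples$sample_id[
                    steady$samples$genotype == genotype$name])
  assert_that(ncol(lab$counts) > 0 && ncol(ss$counts) > 0,
              sprintf("no samples found for genotype '%s'", genotype$name))
  host <- split_species(lab)$host
  ss_host <- split_species(ss)$host
  if (nrow(host$counts) == 0) {
    return(structure(list(
      estimates = tibble::tibble(
        gene_id = character(), alpha = numeric(), alpha_rna = numeric(),
        half_life_min = numeric(), m_eq = numeric(), synthesis = numeric(),
        yeq = numeric(), saturated = logical(), rss = numeric(),
        n_points = integer()),
      failures = tibble::tibble(gene_id = character(), reason = character()),
      genotype = genotype$name, mpu = NA_real_), class = "rate_fit"))
  }
  if (is.null(mpu)) mpu <- molecules_per_unit(steady, genotype$name, cfg)
  m_eq_all <- rowMeans(ss_host$counts) * mpu

  times <- host$samples$time_min
  fits <- lapply(seq_len(nrow(host$counts)), function(i) {
    fit_approach_to_equilibrium(times, host$counts[i, ], cfg,
                                alpha_growth = genotype$alpha_growth,
                                gene_id = host$genes$gene_id[i])
  })
  fits <- dplyr::bind_rows(fits)
  est <- fits[fits$converged, , drop = FALSE]
  est$m_eq <- m_eq_all[match(est$gene_id, ss_host$genes$gene_id)]
  est$synthesis <- est$alpha * est$m_eq
  estimates <- est[, c("gene_id", "alpha", "alpha_rna", "half_life_min",
                       "m_eq", "synthesis", "yeq", "saturated", "rss",
                       "n_points")]
  failures <- fits[!fits$converged, c("gene_id", "reason")]
  structure(list(estimates = tibble::as_tibble(estimates),
                 failures = tibble::as_tibble(failures),
                 genotype = genotype$name, mpu = mpu),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> genotype %s: %d converged, %d failed\n",
              x$genotype, nrow(x$estimates), nrow(x$failures)))
  invisible(x)
}

#' Molecules-per-normalized-count calibration factor
#'
#' Anchors the conversion from normalized steady-state counts to molecules
#' per cell: the reference genotype's mean per-sample host total is set to
#' `cfg$total_mrna_per_cell`. Computed once per experiment and shared
#' across genotypes so spike-in-measured global abundance shifts are
#' preserved.
#'
#' @param steady Normalized steady-state `count_table`.
#' @param reference_genotype Genotype name whose cells are assumed to hold
#'   `cfg$total_mrna_per_cell` mRNA molecules.
#' @param cfg A [fit_config()].
#' @return A positive scalar.
#' @export
molecules_per_unit <- function(steady, reference_genotype,
                               cfg = fit_config()) {
  stopifnot(inherits(steady, "count_table"))
  assert_that(steady$normalized, "steady table must be normalized")
  ref <- ct_subset(steady,
                   sample_ids = steady$samples$sample_id[
                     steady$samples$genotype == reference_genotype])
  assert_that(ncol(ref$counts) > 0,
              sprintf("no steady samples for reference genotype '%s'",
                      reference_genotype))
  host <- split_species(ref)$host
  total <- mean(colSums(host$counts))
  assert_that(total > 0, "reference host counts are all zero")
  cfg$total_mrna_per_cell / total
}

#' Write a rate-estimate table as TSV
#'
#' @param fit A `rate_fit` from [batch_fit()].
#' @param path Output file.
#' @return `read_rate_estimates` returns the estimates tibble.
#' @export
write_rate_estimates <- function(fit, path) {
  stopifnot(inherits(fit, "rate_fit"))
  readr::write_tsv(fit$estimates, path)
  invisible(path)
}

#' @rdname write_rate_estimates
#' @export
read_rate_estimates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
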