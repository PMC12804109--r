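# Genotype comparison and transcript-buffering analysis: fold changes,
# rank correlation, rank-sum tests, percentile/threshold selections,
# gene-set overlaps and a surrogate differential-expression test.

#' A named gene set
#'
#' @param name Set label.
#' @param members Character vector of gene ids (de-duplicated).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  structure(list(name = name, members = unique(as.character(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Fold-change threshold rule
#'
#' Selection rule of the form "fold change above `min_fold_change` (or
#' below its reciprocal) at adjusted p below `max_p`", with strict
#' inequalities (a gene at exactly the fold cutoff is excluded).
#'
#' @param min_fold_change Fold-change cutoff (>= 1), linear scale.
#' @param max_p Significance cutoff in (0, 1).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(min_fold_change = 2, max_p = 0.01) {
  assert_that(min_fold_change >= 1, "min_fold_change must be >= 1")
  assert_that(max_p > 0 && max_p < 1, "max_p must be in (0, 1)")
  structure(list(min_fold_change = min_fold_change, max_p = max_p),
            class = "threshold_rule")
}

#' Per-transcript mutant/WT rate fold changes
#'
#' Joins two rate-estimate tables on the genes converged in both and
#' returns log2 mutant/WT ratios for synthesis and decay — the quantities
#' whose correlation measures transcript buffering.
#'
#' @param wt,mut Estimate tibbles (from `batch_fit()$estimates` or
#'   [read_rate_estimates()]), keyed by `gene_id` with columns `alpha` and
#'   `synthesis`.
#' @return Tibble: `gene_id`, `log2fc_synthesis`, `log2fc_decay`.
#' @export
rate_fold_changes <- function(wt, mut) {
  shared <- intersect(wt$gene_id, mut$gene_id)
  assert_that(length(shared) > 0, "no genes shared between the two tables")
  wt <- wt[match(shared, wt$gene_id), ]
  mut <- mut[match(shared, mut$gene_id), ]
  tibble::tibble(
    gene_id = shared,
    log2fc_synthesis = log2(mut$synthesis / wt$synthesis),
    log2fc_decay = log2(mut$alpha / wt$alpha)
  )
}

#' Transcript-buffering correlation
#'
#' Spearman rank correlation between per-transcript decay and synthesis
#' fold changes (ties mid-ranked). A strong positive value means global
#' synthesis changes are met by matching decay changes, buffering
#' steady-state levels.
#'
#' @param cmp Tibble from [rate_fold_changes()] (>= 3 finite rows).
#' @return List with `rho` and `n`.
#' @export
buffering_correlation <- function(cmp) {
  ok <- is.finite(cmp$log2fc_synthesis) & is.finite(cmp$log2fc_decay)
  assert_that(sum(ok) >= 3, "at least 3 genes with finite fold changes required")
  x <- cmp$log2fc_synthesis[ok]; y <- cmp$log2fc_decay[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    # fold changes constant on an axis (e.g. a table compared with itself)
    return(list(rho = NA_real_, n = sum(ok),
                note = "rank correlation undefined: constant fold changes"))
  }
  list(rho = cor(x, y, method = "spearman"), n = sum(ok))
}

# Exact two-sided rank-sum p by full enumeration of all C(n1+n2, n1)
# assignments of the pooled (tie-midranked) ranks to group 1.
rank_sum_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  sets <- combn(length(r), n1)
  w_all <- colSums(matrix(r[sets], nrow = n1))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Compare two rate distributions
#'
#' Reports medians, the WT/mutant median ratio, and a two-sided Wilcoxon
#' rank-sum (Mann-Whitney) p-value: exact by full permutation enumeration
#' when both samples have at most `exact_max` values, and the
#' tie-corrected normal approximation otherwise.
#'
#' @param wt,mut Numeric samples (non-empty), e.g. per-transcript decay
#'   constants of each genotype.
#' @param exact_max Largest per-group size for which the exact enumeration
#'   is used.
#' @return List: `median_wt`, `median_mut`, `median_ratio` (WT/mutant, so
#'   a mutant globally lowered x-fold gives a ratio of x), `p_value`,
#'   `method`.
#' @export
compare_rate_distributions <- function(wt, mut, exact_max = 10) {
  assert_that(length(wt) > 0 && length(mut) > 0, "both samples must be non-empty")
  if (length(wt) <= exact_max && length(mut) <= exact_max) {
    p <- rank_sum_exact_p(wt, mut)
    method <- "exact permutation"
  } else {
    p <- suppressWarnings(wilcox.test(wt, mut, exact = FALSE)$p.value)
    method <- "normal approximation (tie-corrected)"
  }
  list(median_wt = median(wt), median_mut = median(mut),
       median_ratio = median(wt) / median(mut),
       p_value = p, method = method)
}

#' Genes in the top percentile of a fold-change magnitude
#'
#' Selects the `ceiling(n * pct / 100)` genes with the largest absolute
#' value of the chosen metric (e.g. the top 20th percentile of synthesis
#' reduction); ties broken deterministically by `gene_id`.
#'
#' @param cmp Tibble from [rate_fold_changes()].
#' @param metric `"synthesis"` or `"decay"` (column `log2fc_<metric>`).
#' @param pct Percentile in (0, 100].
#' @return A [gene_set()].
#' @export
top_percentile <- function(cmp, metric = c("synthesis", "decay"), pct = 20) {
  metric <- match.arg(metric)
  assert_that(pct > 0 && pct <= 100, "pct must be in (0, 100]")
  v <- abs(cmp[[paste0("log2fc_", metric)]])
  ord <- order(-v, cmp$gene_id)
  k <- ceiling(nrow(cmp) * pct / 100)
  gene_set(sprintf("top%g_%s", pct, metric), cmp$gene_id[ord][seq_len(k)])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: ascending p(i) scaled by n/i, monotonicity
#' enforced from the largest down, capped at 1, original order restored.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  assert_that(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Select up/down gene sets by fold change and adjusted p
#'
#' Strict inequalities throughout: up-regulated genes have
#' `fold_change > min_fold_change`, down-regulated
#' `fold_change < 1/min_fold_change`, both at `p_adjusted < max_p`.
#'
#' @param gene_id Gene ids.
#' @param fold_change Linear (not log) fold changes, aligned with `gene_id`.
#' @param p_adjusted Adjusted p-values, aligned.
#' @param rule A [threshold_rule()].
#' @return List of [gene_set()]s `up` and `down`.
#' @export
threshold_select <- function(gene_id, fold_change, p_adjusted,
                             rule = threshold_rule()) {
  stopifnot(inherits(rule, "threshold_rule"))
  assert_that(length(gene_id) == length(fold_change) &&
                length(gene_id) == length(p_adjusted),
              "inputs must be aligned vectors of equal length")
  sig <- p_adjusted < rule$max_p
  list(
    up = gene_set("up", gene_id[sig & fold_change > rule$min_fold_change]),
    down = gene_set("down", gene_id[sig & fold_change < 1 / rule$min_fold_change])
  )
}

#' Overlap of two gene sets with hypergeometric enrichment p
#'
#' Venn-style overlap count plus the one-sided upper hypergeometric tail
#' `P(X >= overlap)` for drawing `|b|` genes from a universe containing
#' `|a|` marked genes. The p-value is an added convenience (a Venn diagram
#' itself carries no test).
#'
#' @param a,b [gene_set()]s, both subsets of `universe`.
#' @param universe A [gene_set()] of all assayed genes.
#' @return List: `overlap`, `p_value`, `size_a`, `size_b`, `size_universe`.
#' @export
set_overlap <- function(a, b, universe) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"),
            inherits(universe, "gene_set"))
  assert_that(all(a$members %in% universe$members) &&
                all(b$members %in% universe$members),
              "both sets must be subsets of the universe")
  k <- length(intersect(a$members, b$members))
  m <- length(a$members); n <- length(universe$members) - m
  p <- phyper(k - 1, m, n, length(b$members), lower.tail = FALSE)
  list(overlap = k, p_value = p, size_a = m, size_b = length(b$members),
       size_universe = length(universe$members))
}

#' Surrogate differential-expression test
#'
#' A deliberately simple stand-in for a count-based DE model, enabling
#' end-to-end synthetic runs: per-gene two-sided Welch t-test on
#' `log2(normalized count + 0.5)` between two replicate matrices, BH
#' adjusted. Genes with zero pooled variance get p = 1 (equal means) or
#' p = 0 (different means). Output metadata labels the method "surrogate".
#'
#' @param norm_a,norm_b Gene x replicate matrices of normalized counts
#'   (same genes; >= 2 replicates each).
#' @return Tibble: `gene_id`, `log2fc` (b over a), `p_value`, `p_adjusted`;
#'   attribute `method = "surrogate_t"`.
#' @export
surrogate_de_test <- function(norm_a, norm_b) {
  norm_a <- as.matrix(norm_a); norm_b <- as.matrix(norm_b)
  assert_that(nrow(norm_a) == nrow(norm_b), "gene sets must match")
  assert_that(ncol(norm_a) >= 2 && ncol(norm_b) >= 2,
              "at least 2 replicates per condition required")
  la <- log2(norm_a + 0.5); lb <- log2(norm_b + 0.5)
  res <- vapply(seq_len(nrow(la)), function(i) {
    a <- la[i, ]; b <- lb[i, ]
    d <- mean(b) - mean(a)
    if (var(a) + var(b) == 0) {
      c(d, if (d == 0) 1 else 0)
    } else {
      c(d, t.test(a, b)$p.value)
    }
  }, numeric(2))
  ids <- rownames(norm_a)
  if (is.null(ids)) ids <- sprintf("gene_%05d", seq_len(nrow(norm_a)))
  out <- tibble::tibble(gene_id = ids, log2fc = res[1, ], p_value = res[2, ],
                        p_adjusted = bh_adjust(res[2, ]))
  attr(out, "method") <- "surrogate_t"
  out
}
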