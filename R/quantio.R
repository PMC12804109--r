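# Count-table handling: species split, spike-in size factors,
# normalization and the low-count filter.

#' Split a count table into host and spike-in genes
#'
#' Exact, order-preserving partition by the gene sheet's `species` column.
#'
#' @param table A [count_table()].
#' @return A list with `count_table` elements `host` and `spike` (either may
#'   have zero genes).
#' @export
split_species <- function(table) {
  stopifnot(inherits(table, "count_table"))
  pick <- function(sp) {
    keep <- table$genes$species == sp
    count_table(table$counts[keep, , drop = FALSE],
                table$genes[keep, , drop = FALSE],
                table$samples, normalized = table$normalized)
  }
  list(host = pick("host"), spike = pick("spike"))
}

#' Spike-in size factors (median of ratios)
#'
#' Per-sample scaling factors computed from the spike-in genes only, DESeq2
#' style: each usable spike gene's counts are divided by its geometric mean
#' across samples, the per-sample factor is the median of those ratios, and
#' factors are rescaled to geometric mean 1 (absolute scale is carried by
#' the abundance calibration, not by normalization). Spike genes with a
#' zero count in any sample are excluded (their log-ratio is undefined); if
#' none remain the function falls back to total-spike-count scaling with a
#' warning. Dividing counts by these factors equalizes the spike-in signal
#' across samples, which is what preserves genuine global shifts in the
#' host transcriptome.
#'
#' @param table A `count_table`; spike genes are taken from its gene sheet
#'   (a spike-only table works too).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
spike_size_factors <- function(table) {
  stopifnot(inherits(table, "count_table"))
  spike <- table$counts[table$genes$species == "spike", , drop = FALSE]
  assert_that(nrow(spike) >= 1, "at least one spike-in gene is required")
  assert_that(all(colSums(spike) > 0),
              "every sample needs a nonzero spike-in count")
  usable <- spike[apply(spike > 0, 1, all), , drop = FALSE]
  if (nrow(usable) == 0) {
    warning("no spike gene observed in every sample; ",
            "falling back to total-spike-count scaling")
    sf <- colSums(spike)
  } else {
    ratios <- usable / apply(usable, 1, geomean)
    sf <- apply(ratios, 2, median)
  }
  sf <- sf / geomean(sf)
  setNames(sf, colnames(table$counts))
}

#' Divide counts by per-sample size factors
#'
#' @param table A `count_table`.
#' @param size_factors Named positive factors covering the table's samples,
#'   e.g. from [spike_size_factors()].
#' @return A normalized (real-valued) `count_table`.
#' @export
normalize_counts <- function(table, size_factors) {
  stopifnot(inherits(table, "count_table"))
  assert_that(all(colnames(table$counts) %in% names(size_factors)),
              "size factors must cover every sample in the table")
  sf <- size_factors[colnames(table$counts)]
  assert_that(all(sf > 0), "size factors must be > 0")
  count_table(sweep(table$counts, 2, sf, "/"), table$genes, table$samples,
              normalized = TRUE)
}

#' Remove genes with low total raw counts
#'
#' Drops genes whose summed raw counts across *all* samples of the
#' experiment fall below `min_total` (default 15, i.e. genes with fewer
#' than 15 reads across samples are filtered out). Applies to raw counts
#' only; run it before normalization.
#'
#' @param table A raw `count_table`.
#' @param min_total Minimum summed count a gene must reach to be kept.
#' @return The filtered `count_table`.
#' @export
filter_low_counts <- function(table, min_total = 15) {
  stopifnot(inherits(table, "count_table"))
  assert_that(min_total >= 0, "min_total must be >= 0")
  assert_that(!table$normalized,
              "the low-count filter applies to raw counts, not normalized values")
  keep <- rowSums(table$counts) >= min_total
  count_table(table$counts[keep, , drop = FALSE],
              table$genes[keep, , drop = FALSE],
              table$samples, normalized = FALSE)
}
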