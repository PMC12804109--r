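#' Gene-by-sample count table with species and sample metadata
#'
#' Container for the count matrices this package works with: rows are genes
#' (host transcripts plus whole-cell spike-in genes from a second species),
#' columns are sequencing samples. Sample metadata records the genotype, the
#' 4tU labeling duration in minutes (`NA` for steady-state libraries) and the
#' replicate index. Raw tables hold non-negative integers; after spike-in
#' normalization values are real and the table is flagged `normalized`.
#'
#' @param counts Numeric gene x sample matrix, non-negative. Integer-valued
#'   unless `normalized = TRUE`.
#' @param genes Data frame with columns `gene_id`, `species` (each species
#'   either `"host"` or `"spike"`), one row per matrix row, same order.
#' @param samples Data frame with columns `sample_id`, `genotype`,
#'   `time_min`, `replicate`, one row per matrix column, same order.
#' @param normalized Logical; `TRUE` once counts have been divided by size
#'   factors (values then need not be integers).
#'
#' @return An object of class `count_table` (a list with elements `counts`,
#'   `genes`, `samples`, `normalized`).
#' @export
count_table <- function(counts, genes, samples, normalized = FALSE) {
  counts <- as.matrix(counts)
  genes <- tibble::as_tibble(genes)
  samples <- tibble::as_tibble(samples)
  assert_that(all(c("gene_id", "species") %in% names(genes)),
              "`genes` needs columns gene_id, species")
  assert_that(all(c("sample_id", "genotype", "time_min", "replicate") %in%
                    names(samples)),
              "`samples` needs columns sample_id, genotype, time_min, replicate")
  assert_that(nrow(genes) == nrow(counts),
              "one `genes` row per count matrix row required")
  assert_that(nrow(samples) == ncol(counts),
              "one `samples` row per count matrix column required")
  assert_that(!anyNA(genes$species) && all(genes$species %in% c("host", "spike")),
              "every gene needs a species label in {host, spike}")
  assert_that(!anyDuplicated(genes$gene_id), "gene_id must be unique")
  assert_that(!anyDuplicated(samples$sample_id), "sample_id must be unique")
  assert_that(is.numeric(counts) && all(is.finite(counts)) && all(counts >= 0),
              "counts must be finite and non-negative")
  if (!normalized) {
    assert_that(all(abs(counts - round(counts)) < 1e-8),
                "raw counts must be integers; use normalized = TRUE for real values")
    counts <- round(counts)
  }
  dimnames(counts) <- list(genes$gene_id, samples$sample_id)
  structure(
    list(counts = counts, genes = genes, samples = samples,
         normalized = isTRUE(normalized)),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "<count_table> %d genes (%d host, %d spike) x %d samples%s\n",
    nrow(x$counts), sum(x$genes$species == "host"),
    sum(x$genes$species == "spike"), ncol(x$counts),
    if (x$normalized) " [normalized]" else ""
  ))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by gene ids or sample ids
#'
#' @param table A [count_table()].
#' @param gene_ids,sample_ids Character vectors of ids to keep (in the
#'   table's own order); `NULL` keeps everything.
#' @return A `count_table`.
#' @export
ct_subset <- function(table, gene_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(table, "count_table"))
  gi <- if (is.null(gene_ids)) rep(TRUE, nrow(table$counts)) else
    table$genes$gene_id %in% gene_ids
  si <- if (is.null(sample_ids)) rep(TRUE, ncol(table$counts)) else
    table$samples$sample_id %in% sample_ids
  count_table(table$counts[gi, si, drop = FALSE],
              table$genes[gi, , drop = FALSE],
              table$samples[si, , drop = FALSE],
              normalized = table$normalized)
}

#' Combine the samples of two count tables over the same genes
#'
#' Used to assemble one jointly-normalizable experiment from per-genotype
#' simulations (same transcriptome, different sample sets).
#'
#' @param a,b `count_table`s with identical gene sheets.
#' @return A `count_table` with the samples of `a` followed by those of `b`.
#' @export
ct_cbind <- function(a, b) {
  stopifnot(inherits(a, "count_table"), inherits(b, "count_table"))
  assert_that(identical(a$genes$gene_id, b$genes$gene_id) &&
                identical(a$genes$species, b$genes$species),
              "tables must share an identical gene sheet")
  assert_that(a$normalized == b$normalized,
              "cannot mix raw and normalized tables")
  count_table(cbind(a$counts, b$counts), a$genes,
              dplyr::bind_rows(a$samples, b$samples),
              normalized = a$normalized)
}

#' Write / read a count table as plain TSV files
#'
#' Three files are written under `dir`: `<prefix>_counts.tsv` (first column
#' `gene_id`, one column per sample), `<prefix>_samples.tsv` (sample sheet)
#' and `<prefix>_genes.tsv` (gene sheet). Raw integer tables round-trip
#' bit-exactly.
#'
#' @param table A [count_table()].
#' @param dir Directory (created if needed).
#' @param prefix File name prefix.
#' @return `write_count_table` invisibly returns the three paths;
#'   `read_count_table` returns a `count_table`.
#' @export
write_count_table <- function(table, dir, prefix) {
  stopifnot(inherits(table, "count_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_counts.tsv", "_samples.tsv",
                                           "_genes.tsv")))
  wide <- tibble::as_tibble(table$counts)
  wide <- dplyr::bind_cols(tibble::tibble(gene_id = table$genes$gene_id), wide)
  readr::write_tsv(wide, paths[1])
  readr::write_tsv(table$samples, paths[2])
  readr::write_tsv(table$genes, paths[3])
  invisible(paths)
}

#' @rdname write_count_table
#' @param normalized Logical, whether the stored counts are normalized
#'   (real-valued) rather than raw integers.
#' @export
read_count_table <- function(dir, prefix, normalized = FALSE) {
  paths <- file.path(dir, paste0(prefix, c("_counts.tsv", "_samples.tsv",
                                           "_genes.tsv")))
  assert_that(all(file.exists(paths)),
              sprintf("missing count table files for prefix '%s' in %s",
                      prefix, dir))
  wide <- readr::read_tsv(paths[1], show_col_types = FALSE)
  samples <- readr::read_tsv(paths[2], show_col_types = FALSE,
                             col_types = readr::cols(
                               sample_id = "c", genotype = "c",
                               time_min = "d", replicate = "i"))
  genes <- readr::read_tsv(paths[3], show_col_types = FALSE,
                           col_types = readr::cols(gene_id = "c", species = "c"))
  counts <- as.matrix(wide[, -1, drop = FALSE])
  rownames(counts) <- wide$gene_id
  assert_that(identical(wide$gene_id, genes$gene_id),
              "gene sheet and count matrix disagree")
  count_table(counts[, samples$sample_id, drop = FALSE], genes, samples,
              normalized = normalized)
}
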