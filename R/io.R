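#' Read a BED3/BED6 file of peaks
#'
#' Reads a tab-separated BED file (no header). The first three columns are
#' `chrom`, `start`, `end` (0-based half-open); a fourth column, when
#' present, becomes `peak_id`.
#'
#' @param path Path to the BED file.
#' @param stage Optional stage label attached as a `stage` column.
#' @return A tibble of intervals.
#' @export
read_peak_bed <- function(path, stage = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "peak_id"
  x <- x[, intersect(c("chrom", "start", "end", "peak_id"), names(x))]
  if (!is.null(stage)) x$stage <- stage
  check_intervals(x, "BED record")
  as_tibble(x)
}

#' Write intervals as BED
#'
#' @param x Data frame with `chrom`, `start`, `end` and optional further
#'   columns (written in order after the first three).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  first <- c("chrom", "start", "end")
  x <- x[, c(first, setdiff(names(x), first))]
  readr::write_tsv(x, path, col_names = FALSE)
  invisible(path)
}

#' Read a long count table
#'
#' Expects a TSV with header columns `peak_id`, `stage`, `count`.
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_count_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("peak_id", "stage", "count")
  if (!all(req %in% names(x))) {
    abort("count table needs columns peak_id, stage, count")
  }
  as_tibble(x[, req])
}

#' Read a library-size table
#'
#' Expects a TSV with header columns `stage`, `total_reads`.
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_library_sizes <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("stage", "total_reads") %in% names(x))) {
    abort("library-size table needs columns stage, total_reads")
  }
  as_tibble(x)
}

#' Read a gene-by-stage expression table
#'
#' Expects a TSV with a `gene_id` column followed by one RPKM column per
#' stage, in temporal order.
#' @param path Path to the TSV.
#' @return A tibble with attribute `stages`.
#' @export
read_expression_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(x)[1] != "gene_id") abort("first column must be gene_id")
  structure(as_tibble(x), stages = names(x)[-1])
}

#' Read a TSS annotation table
#'
#' Expects a TSV with header columns `gene_id`, `chrom`, `tss`, `strand`.
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_tss_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("gene_id", "chrom", "tss", "strand")
  if (!all(req %in% names(x))) {
    abort("TSS table needs columns gene_id, chrom, tss, strand")
  }
  as_tibble(x[, req])
}

#' Read a cis contact matrix from triplet TSV
#'
#' Expects a TSV with header columns `chrom`, `bin_i`, `bin_j`, `count`
#' (0-based bin indices at a fixed resolution). Only one chromosome per
#' file/call is supported; the matrix is symmetrized.
#'
#' @param path Path to the triplet TSV.
#' @param resolution Bin size in bp.
#' @param n_bins Number of bins; defaults to `max(bin) + 1`.
#' @return A `contact_matrix` (see [contact_matrix()]).
#' @export
read_contact_triplets <- function(path, resolution, n_bins = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("chrom", "bin_i", "bin_j", "count")
  if (!all(req %in% names(x))) {
    abort("contact triplets need columns chrom, bin_i, bin_j, count")
  }
  if (length(unique(x$chrom)) != 1) abort("one chromosome per contact file")
  contact_matrix(x, resolution = resolution, n_bins = n_bins)
}

#' Read a PC1 compartment track from bedGraph
#'
#' Four tab-separated columns, no header: `chrom`, `start`, `end`, `pc1`.
#' Bins must tile the chromosome at a fixed width.
#'
#' @param path Path to the bedGraph.
#' @return A tibble `chrom`, `start`, `end`, `pc1`.
#' @export
read_pc1_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "pc1"),
                       show_col_types = FALSE, comment = "#")
  as_tibble(x)
}

#' Write a signal matrix as TSV
#'
#' @param x A `signal_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
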