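#' Peak-by-cell count matrix
#'
#' The central container: sparse nonnegative integer fragment counts with
#' peaks (0-based half-open intervals) on rows and cell barcodes on columns,
#' plus an optional barcode -> tissue/cell-type annotation. Counts are kept
#' in their original count form, never binarized.
#'
#' @param counts A matrix or `Matrix::dgCMatrix` of nonnegative counts,
#'   peaks x cells.
#' @param peaks Interval tibble (`chrom`, `start`, `end`) with one row per
#'   matrix row. Rows are sorted by (chrom, start) and the matrix reordered
#'   to match.
#' @param barcodes Character vector of unique cell identifiers, one per
#'   matrix column.
#' @param labels Optional named character vector (or two-column data frame
#'   `barcode`, `cell_type`) annotating barcodes; may cover only a subset.
#' @return An object of class `peak_matrix`: a list with elements `counts`
#'   (dgCMatrix), `peaks` (tibble), `barcodes`, `labels`.
#' @examples
#' pm <- peak_matrix(matrix(0:5, nrow = 2),
#'                   genomic_intervals("chr1", c(0, 500), c(100, 700)),
#'                   c("bc1", "bc2", "bc3"))
#' dim(pm)
#' @export
peak_matrix <- function(counts, peaks, barcodes, labels = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  validate_intervals(peaks, "peak")
  if (nrow(counts) != nrow(peaks)) {
    stop("matrix has ", nrow(counts), " rows but ", nrow(peaks),
         " peaks were supplied", call. = FALSE)
  }
  if (ncol(counts) != length(barcodes)) {
    stop("matrix has ", ncol(counts), " columns but ", length(barcodes),
         " barcodes were supplied", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("barcodes must be unique", call. = FALSE)
  }
  if (length(counts@x) && any(counts@x < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  peaks <- peaks[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- peak_id_string(peaks)
  colnames(counts) <- barcodes
  labels <- normalize_labels(labels)
  structure(
    list(counts = counts, peaks = peaks,
         barcodes = as.character(barcodes), labels = labels),
    class = "peak_matrix"
  )
}

normalize_labels <- function(labels) {
  if (is.null(labels)) return(NULL)
  if (is.data.frame(labels)) {
    stopifnot(all(c("barcode", "cell_type") %in% names(labels)))
    labels <- stats::setNames(as.character(labels$cell_type),
                              labels$barcode)
  }
  stopifnot(!is.null(names(labels)))
  labels
}

#' @export
dim.peak_matrix <- function(x) dim(x$counts)

#' @export
#' @method print peak_matrix
print.peak_matrix <- function(x, ...) {
  cat("<peak_matrix> ", nrow(x$counts), " peaks x ", ncol(x$counts),
      " cells; ", length(x$counts@x), " nonzero entries\n", sep = "")
  if (!is.null(x$labels)) {
    lab <- x$labels[x$barcodes]
    cat("  labelled cells: ", sum(!is.na(lab)), " across ",
        length(unique(stats::na.omit(lab))), " cell types\n", sep = "")
  }
  invisible(x)
}

#' @export
as_tibble.peak_matrix <- function(x, ...) {
  tr <- methods::as(x$counts, "TsparseMatrix")
  tibble::tibble(
    peak = rownames(x$counts)[tr@i + 1L],
    barcode = colnames(x$counts)[tr@j + 1L],
    count = tr@x
  )
}

peak_ids <- function(pm) rownames(pm$counts)

subset_peak_matrix <- function(pm, peaks = NULL, cells = NULL) {
  counts <- pm$counts
  pk <- pm$peaks
  bc <- pm$barcodes
  if (!is.null(peaks)) {
    counts <- counts[peaks, , drop = FALSE]
    pk <- pk[peaks, , drop = FALSE]
  }
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
    bc <- bc[cells]
  }
  out <- pm
  out$counts <- counts
  out$peaks <- pk
  out$barcodes <- bc
  out
}
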