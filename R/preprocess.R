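#' Quality-control filters for peak-by-cell matrices
#'
#' The standard preprocessing applied before enhancer calling, in this
#' fixed order: cells first, then peaks, then the split into cell-type
#' sub-matrices. "Peaks per cell" always means the number of peaks with a
#' nonzero count, not total fragments, and every threshold is strict
#' ("fewer than"), so a cell with exactly `min_peaks` nonzero peaks
#' survives. All filters are idempotent.
#'
#' @param pm A [peak_matrix()].
#' @param min_peaks Cells with fewer than this many nonzero peaks are
#'   removed (default 200).
#' @return The filtered `peak_matrix`, with a QC record appended to its
#'   `qc` attribute (see [qc_report()]).
#' @export
filter_cells_min_peaks <- function(pm, min_peaks = 200L) {
  nz <- Matrix::colSums(pm$counts > 0)
  keep <- which(nz >= min_peaks)
  if (length(keep) == 0L) {
    stop("all ", ncol(pm$counts), " cells have fewer than ", min_peaks,
         " nonzero peaks; nothing left after cell filtering", call. = FALSE)
  }
  out <- subset_peak_matrix(pm, cells = keep)
  add_qc(out, pm, "filter_cells_min_peaks")
}

#' @rdname filter_cells_min_peaks
#' @param min_cells Peaks nonzero in fewer than this many cells are removed
#'   (default 10).
#' @param uncommon_chrom_patterns Regular expressions naming chromosomes to
#'   exclude regardless of counts. The default list covers mitochondrial
#'   contigs (chrM/chrMT/MT) and scaffold/random/alt/unplaced names; pass
#'   `character()` to disable.
#' @export
filter_peaks <- function(pm, min_cells = 10L,
                         uncommon_chrom_patterns = c(
                           "^(chr)?MT?$", "_random$", "_alt$", "_hap",
                           "^chrUn", "scaffold", "^GL", "^KI"
                         )) {
  support <- Matrix::rowSums(pm$counts > 0)
  uncommon <- rep(FALSE, nrow(pm$peaks))
  for (p in uncommon_chrom_patterns) {
    uncommon <- uncommon | grepl(p, pm$peaks$chrom)
  }
  keep <- which(support >= min_cells & !uncommon)
  if (length(keep) == 0L) {
    warning("no peaks survive the peak filter", call. = FALSE)
  }
  out <- subset_peak_matrix(pm, peaks = keep)
  add_qc(out, pm, "filter_peaks")
}

#' Split a matrix into cell-type-specific sub-matrices
#'
#' Uses the barcode labels to partition cells by tissue/cell type, dropping
#' types represented by fewer than `min_cells_per_type` cells (strict; a
#' type with exactly the minimum survives) and, within each sub-matrix,
#' peaks with no signal across that type's cells. Unlabeled cells are
#' excluded with a warning.
#'
#' @inheritParams filter_cells_min_peaks
#' @param min_cells_per_type Minimum cells per surviving type (default 100).
#' @return Named list of `peak_matrix` objects, one per surviving type.
#' @export
split_by_cell_type <- function(pm, min_cells_per_type = 100L) {
  if (is.null(pm$labels)) {
    stop("matrix has no cell-type labels; cannot split", call. = FALSE)
  }
  lab <- unname(pm$labels[pm$barcodes])
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " unlabeled cell(s) excluded from the split",
            call. = FALSE)
  }
  sizes <- table(lab[!is.na(lab)])
  keep_types <- names(sizes)[sizes >= min_cells_per_type]
  if (length(keep_types) == 0L) {
    stop("no cell type has at least ", min_cells_per_type,
         " cells (largest: ",
         if (length(sizes)) max(sizes) else 0, ")", call. = FALSE)
  }
  out <- lapply(keep_types, function(ct) {
    sub <- subset_peak_matrix(pm, cells = which(!is.na(lab) & lab == ct))
    nz <- Matrix::rowSums(sub$counts) > 0
    sub <- subset_peak_matrix(sub, peaks = which(nz))
    add_qc(sub, pm, paste0("split:", ct))
  })
  stats::setNames(out, keep_types)
}

add_qc <- function(out, before, step) {
  rec <- tibble::tibble(
    step = step,
    n_cells_in = ncol(before$counts), n_cells_out = ncol(out$counts),
    n_peaks_in = nrow(before$counts), n_peaks_out = nrow(out$counts),
    n_cells_removed = ncol(before$counts) - ncol(out$counts),
    n_peaks_removed = nrow(before$counts) - nrow(out$counts)
  )
  attr(out, "qc") <- dplyr::bind_rows(attr(before, "qc"), rec)
  out
}

#' Retrieve the accumulated QC report of a filtered matrix
#'
#' @param pm A `peak_matrix` that has passed through one or more filters.
#' @return Tibble with one row per filtering step: cells/peaks in and out
#'   and removal counts.
#' @export
qc_report <- function(pm) {
  qc <- attr(pm, "qc")
  if (is.null(qc)) {
    return(tibble::tibble(step = character(), n_cells_in = integer(),
                          n_cells_out = integer(), n_peaks_in = integer(),
                          n_peaks_out = integer(),
                          n_cells_removed = integer(),
                          n_peaks_removed = integer()))
  }
  qc
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying [filter_cells_min_peaks()], then
#' [filter_peaks()], then [split_by_cell_type()].
#'
#' @inheritParams filter_cells_min_peaks
#' @inheritParams filter_peaks
#' @inheritParams split_by_cell_type
#' @return Named list of per-type `peak_matrix` objects.
#' @export
preprocess_matrix <- function(pm, min_peaks = 200L, min_cells = 10L,
                              min_cells_per_type = 100L,
                              uncommon_chrom_patterns = c(
                                "^(chr)?MT?$", "_random$", "_alt$", "_hap",
                                "^chrUn", "scaffold", "^GL", "^KI"
                              )) {
  pm <- filter_cells_min_peaks(pm, min_peaks)
  pm <- filter_peaks(pm, min_cells, uncommon_chrom_patterns)
  split_by_cell_type(pm, min_cells_per_type)
}
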