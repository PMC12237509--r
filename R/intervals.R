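#' Genomic interval tibbles
#'
#' Intervals travel through the package as plain tibbles with columns
#' `chrom` (character), `start`, `end` (0-based half-open integers) and,
#' optionally, `name`, `score` and `strand`. These helpers validate the
#' convention and convert to/from `GenomicRanges::GRanges` (1-based closed)
#' for interval algebra.
#'
#' @param chrom,start,end,name,score,strand Interval fields; `start`/`end`
#'   are 0-based half-open.
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @examples
#' genomic_intervals("chr1", 0L, 100L)
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  tbl <- tibble::tibble(chrom = as.character(chrom),
                        start = as.integer(start), end = as.integer(end))
  if (!is.null(name)) tbl$name <- as.character(name)
  if (!is.null(score)) tbl$score <- as.numeric(score)
  if (!is.null(strand)) tbl$strand <- as.character(strand)
  validate_intervals(tbl)
  tbl
}

validate_intervals <- function(tbl, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(tbl)))
  if (nrow(tbl) == 0L) return(invisible(tbl))
  if (anyNA(tbl$start) || anyNA(tbl$end)) {
    stop(what, " table contains missing coordinates", call. = FALSE)
  }
  if (any(tbl$start < 0)) {
    stop(what, " start must be >= 0 (0-based half-open)", call. = FALSE)
  }
  bad <- which(tbl$end <= tbl$start)
  if (length(bad)) {
    stop(what, " with end <= start at row ", bad[1],
         " (", tbl$chrom[bad[1]], ":", tbl$start[bad[1]], "-",
         tbl$end[bad[1]], "); intervals are half-open [start, end)",
         call. = FALSE)
  }
  invisible(tbl)
}

# 0-based half-open tibble -> 1-based closed GRanges
intervals_to_granges <- function(tbl) {
  strand <- if ("strand" %in% names(tbl)) {
    s <- tbl$strand
    s[is.na(s) | !s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

granges_to_intervals <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

sort_intervals <- function(tbl) {
  dplyr::arrange(tbl, .data$chrom, .data$start, .data$end)
}

#' Merge overlapping or abutting intervals
#'
#' Collapses a set of intervals into maximal disjoint intervals
#' (the base-pair union).
#'
#' @param tbl Interval tibble.
#' @return Tibble of merged intervals, sorted.
#' @export
merge_intervals <- function(tbl) {
  validate_intervals(tbl)
  if (nrow(tbl) == 0L) return(tbl[, c("chrom", "start", "end")])
  sort_intervals(granges_to_intervals(
    GenomicRanges::reduce(intervals_to_granges(tbl), ignore.strand = TRUE)
  ))
}

peak_id_string <- function(tbl) {
  paste0(tbl$chrom, ":", tbl$start, "-", tbl$end)
}

parse_peak_id <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) {
    stop("cannot parse peak identifier '", x[bad[1]],
         "' (expected chrom:start-end)", call. = FALSE)
  }
  tibble::tibble(
    chrom = vapply(m, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 3L)),
    end = as.integer(vapply(m, `[[`, "", 4L))
  )
}
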