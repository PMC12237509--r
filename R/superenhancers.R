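#' Stitch candidate enhancers into candidate super-enhancer regions
#'
#' Single left-to-right pass per chromosome merging consecutive candidates
#' whose gap (`next start - current end`) is at most `d`; overlapping or
#' abutting candidates always merge (gap <= 0). Singletons become size-1
#' stitched regions. Stitching is idempotent and the resulting spans are
#' pairwise disjoint per chromosome.
#'
#' @param candidates Interval tibble of candidate enhancers
#'   (e.g. [read_narrowpeak()]).
#' @param d Stitch distance in bp. Species defaults in the field: 12500
#'   (human), 12500 (mouse), 2000 (fly); see [stitch_distance_preset()].
#' @return Tibble of stitched regions: `chrom`, `start`, `end`,
#'   `n_members`, and a `members` list-column of member-row indices into
#'   the sorted candidate set.
#' @examples
#' stitch(genomic_intervals("chr1", c(100, 10000, 23500),
#'                          c(600, 10400, 24000)), d = 12500)
#' @export
stitch <- function(candidates, d) {
  validate_intervals(candidates, "candidate")
  if (nrow(candidates) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_members = integer(),
                          members = list()))
  }
  cand <- sort_intervals(candidates)
  out <- lapply(split(seq_len(nrow(cand)), cand$chrom), function(rows) {
    s <- cand$start[rows]; e <- cand$end[rows]
    # running maximum end so contained intervals do not reopen a gap
    run_end <- cummax(e)
    gap <- s[-1L] - run_end[-length(run_end)]
    grp <- cumsum(c(1L, as.integer(gap > d)))
    tibble::tibble(
      chrom = cand$chrom[rows[1L]],
      start = as.integer(tapply(s, grp, min)),
      end = as.integer(tapply(e, grp, max)),
      n_members = as.integer(tapply(rows, grp, length)),
      members = unname(tapply(rows, grp, c, simplify = FALSE))
    )
  })
  sort_intervals(dplyr::bind_rows(out))
}

#' Stitch distance presets per species
#'
#' @param species One of `"human"`, `"mouse"`, `"fly"`.
#' @return Stitch distance in bp (12.5 kb, 12.5 kb, 2 kb respectively).
#' @export
stitch_distance_preset <- function(species = c("human", "mouse", "fly")) {
  c(human = 12500L, mouse = 12500L, fly = 2000L)[[match.arg(species)]]
}

#' Integrated fragment signal per stitched region
#'
#' The total signal of a region is the sum of the `count` fields of all
#' fragments from the given barcode set overlapping it by at least 1 bp —
#' the discrete form of integrating the ATAC signal over the region. A
#' fragment spanning two regions contributes to each (regions are scored
#' independently).
#'
#' @param regions Interval tibble (e.g. from [stitch()]).
#' @param fragments Fragment tibble.
#' @param barcodes Barcodes defining the cell-type partition; must be
#'   nonempty.
#' @return Numeric vector of total signals, one per region row.
#' @export
region_signal <- function(regions, fragments, barcodes) {
  if (length(barcodes) == 0L) {
    stop("empty barcode set: the cell-type partition must contain at ",
         "least one cell", call. = FALSE)
  }
  validate_intervals(regions, "region")
  frag <- fragments[fragments$barcode %in% barcodes, , drop = FALSE]
  signal <- numeric(nrow(regions))
  if (nrow(frag) == 0L || nrow(regions) == 0L) return(signal)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_to_granges(regions[, c("chrom", "start", "end")]),
    intervals_to_granges(frag[, c("chrom", "start", "end")])
  ))
  if (length(hits)) {
    agg <- rowsum(frag$count[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    signal[as.integer(rownames(agg))] <- agg[, 1L]
  }
  signal
}

#' Rank curve and slope-one cutoff over region signals
#'
#' Regions are ranked by signal in ascending order and both axes are
#' min-max scaled to `[0, 1]`. The cutoff is the lower tangent point of a
#' slope-1 line: the index minimizing `scaled_y - scaled_x` (every point
#' lies on or above the slope-1 line anchored there). Ties break to the
#' largest index (the most stringent cutoff); a flat curve degenerates to
#' `cutoff_index = n`, classifying nothing as super.
#'
#' @param signals Nonnegative numeric vector, length >= 2.
#' @return A `rank_curve`: tibble (`rank`, `signal`, `scaled_x`,
#'   `scaled_y`) with attributes `cutoff_index`, `cutoff_signal`,
#'   `degenerate`.
#' @examples
#' curve <- rank_and_cutoff(c(1, 2, 3, 5, 20, 90))
#' attr(curve, "cutoff_signal") # 20
#' @export
rank_and_cutoff <- function(signals) {
  stopifnot(length(signals) >= 2L, all(signals >= 0))
  n <- length(signals)
  s <- sort(signals)
  x <- (seq_len(n) - 1) / (n - 1)
  degenerate <- max(s) == min(s)
  if (degenerate) {
    y <- rep(0, n)
    cutoff_index <- n
  } else {
    y <- (s - min(s)) / (max(s) - min(s))
    dvec <- y - x
    cutoff_index <- max(which(dvec <= min(dvec) + 1e-12))
  }
  out <- tibble::tibble(rank = seq_len(n), signal = s,
                        scaled_x = x, scaled_y = y)
  attr(out, "cutoff_index") <- cutoff_index
  attr(out, "cutoff_signal") <- s[cutoff_index]
  attr(out, "degenerate") <- degenerate
  class(out) <- c("rank_curve", class(out))
  out
}

#' Classify stitched regions as true/false super-enhancers
#'
#' A region is a super-enhancer iff its signal strictly exceeds the rank
#' curve's cutoff signal (the cutoff region itself is not super).
#'
#' @param regions Stitched-region tibble with a `total_signal` column (or
#'   a separate `signals` vector).
#' @param curve A [rank_and_cutoff()] result computed from these signals.
#' @return `regions` with `rank` (ascending signal order) and `is_super`
#'   columns added.
#' @export
classify_superenhancers <- function(regions, curve) {
  cutoff <- attr(curve, "cutoff_signal")
  regions$rank <- rank(regions$total_signal, ties.method = "first")
  regions$is_super <- regions$total_signal > cutoff
  regions
}

#' Retain true super-enhancers that intersect typical enhancers
#'
#' The final filter: only regions classified super AND overlapping (>= 1
#' bp) at least one typical (consensus) enhancer are retained.
#'
#' @param calls Output of [classify_superenhancers()].
#' @param typical_enhancers Interval tibble of typical enhancers from the
#'   same cell type (e.g. the `is_enhancer` rows of
#'   [call_consensus_enhancers()]).
#' @return `calls` with a `retained` logical column
#'   (`retained` implies `is_super`).
#' @export
intersect_with_consensus <- function(calls, typical_enhancers) {
  if (nrow(typical_enhancers) == 0L || nrow(calls) == 0L) {
    calls$retained <- rep(FALSE, nrow(calls))
    return(calls)
  }
  ov <- IRanges::overlapsAny(
    intervals_to_granges(calls[, c("chrom", "start", "end")]),
    intervals_to_granges(typical_enhancers[, c("chrom", "start", "end")])
  )
  calls$retained <- calls$is_super & ov
  calls
}

#' Call super-enhancers for one cell type
#'
#' End-to-end: stitch candidates, integrate fragment signal over the
#' barcode set, rank, cut at the slope-1 tangent, classify, and (when
#' typical enhancers are supplied) apply the intersection filter.
#'
#' @inheritParams stitch
#' @inheritParams region_signal
#' @param typical_enhancers Optional typical-enhancer intervals for the
#'   retention filter; without them `retained` is `NA`.
#' @param stitch_dist Stitch distance in bp (default human preset, 12500).
#' @return Tibble of stitched regions with `total_signal`, `rank`,
#'   `is_super`, `retained`; the [rank_and_cutoff()] curve is attached as
#'   attribute `rank_curve`.
#' @export
call_superenhancers <- function(candidates, fragments, barcodes,
                                stitch_dist = 12500L,
                                typical_enhancers = NULL) {
  regions <- stitch(candidates, stitch_dist)
  regions$total_signal <- region_signal(regions, fragments, barcodes)
  curve <- rank_and_cutoff(regions$total_signal)
  calls <- classify_superenhancers(regions, curve)
  if (is.null(typical_enhancers)) {
    calls$retained <- NA
  } else {
    calls <- intersect_with_consensus(calls, typical_enhancers)
  }
  attr(calls, "rank_curve") <- curve
  calls
}
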