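#' Tanimoto similarity between two count vectors
#'
#' `T(A, B) = A.B / (|A|^2 + |B|^2 - A.B)`, the continuous extension of the
#' Jaccard index: on binary vectors the two coincide exactly. Used to score
#' how similar two single cells' peak profiles are while keeping counts
#' un-binarized.
#'
#' @param a,b Nonnegative numeric vectors of equal length.
#' @return A coefficient in `[0, 1]`; two all-zero vectors give 0 with a
#'   warning.
#' @examples
#' tanimoto(c(1, 2, 0, 1), c(0, 2, 1, 1)) # 5/7
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) {
    stop("tanimoto is defined for nonnegative count vectors", call. = FALSE)
  }
  ab <- sum(a * b)
  den <- sum(a * a) + sum(b * b) - ab
  if (den == 0) {
    warning("both vectors are all-zero; returning 0", call. = FALSE)
    return(0)
  }
  ab / den
}

#' Pairwise Tanimoto matrix over all cells
#'
#' Computes the m x m similarity matrix between cell columns using sparse
#' cross-products (the peaks x peaks side is never formed).
#'
#' @param pm A [peak_matrix()] or a (sparse) peaks x cells matrix.
#' @return Symmetric m x m matrix with unit diagonal for nonzero cells.
#' @export
tanimoto_matrix <- function(pm) {
  x <- if (inherits(pm, "peak_matrix")) pm$counts else pm
  g <- as.matrix(Matrix::crossprod(x))   # m x m Gram matrix
  sq <- diag(g)
  den <- outer(sq, sq, `+`) - g
  tt <- ifelse(den == 0, 0, g / den)
  dimnames(tt) <- list(colnames(x), colnames(x))
  tt
}

#' Per-cell quality weights from a Tanimoto matrix
#'
#' Each cell's weight is its summed similarity to every other cell,
#' normalized by the sum over all ordered pairs of distinct cells, so the
#' weights are nonnegative and sum to exactly 1. Cells resembling the rest
#' of the population (higher-quality profiles) receive larger weights.
#'
#' @param tmat Output of [tanimoto_matrix()].
#' @return Named numeric vector of weights summing to 1. If all cells are
#'   mutually disjoint the weights fall back to uniform with a warning.
#' @export
cell_weights <- function(tmat) {
  stopifnot(nrow(tmat) == ncol(tmat), nrow(tmat) >= 2L)
  num <- rowSums(tmat) - diag(tmat)
  den <- sum(tmat) - sum(diag(tmat))
  if (den == 0) {
    warning("all cells mutually disjoint; using uniform weights",
            call. = FALSE)
    w <- rep(1 / nrow(tmat), nrow(tmat))
  } else {
    w <- num / den
  }
  stats::setNames(w, rownames(tmat))
}

#' Weighted combined peak signal
#'
#' The consensus signal of peak i is the weight-weighted sum of its
#' fragment counts over cells, linear in the counts.
#'
#' @param pm A [peak_matrix()] or peaks x cells matrix.
#' @param weights Per-cell weights aligned with the matrix columns
#'   (checked by name when both are named).
#' @return Named numeric vector of per-peak scores.
#' @export
combined_peak_signal <- function(pm, weights) {
  x <- if (inherits(pm, "peak_matrix")) pm$counts else pm
  stopifnot(length(weights) == ncol(x))
  if (!is.null(names(weights)) && !is.null(colnames(x))) {
    stopifnot(identical(names(weights), colnames(x)))
  }
  drop(as.matrix(x %*% weights))
}

#' Shuffle-null threshold for combined peak signals
#'
#' Builds the criterion-iii null: in each replicate every peak is relocated
#' uniformly at random within its own chromosome (width preserved, overlaps
#' among shuffled peaks allowed), fragments are re-counted per cell at the
#' new positions, and the weighted combined score recomputed. The returned
#' threshold is the given percentile of the pooled null scores across all
#' replicates and peaks.
#'
#' @param fragments Fragment tibble ([read_fragments()]).
#' @param peaks Interval tibble of the peaks being tested.
#' @param weights Named per-cell weights (barcode -> weight); fragments
#'   from other barcodes contribute nothing.
#' @param genome Named vector chrom -> length (bp) covering all peak
#'   chromosomes.
#' @param n_shuffles Number of genome-shuffle replicates (default 20).
#' @param percentile Percentile of the pooled null (default 95).
#' @param seed RNG seed for the relocations.
#' @return The null threshold (a single number).
#' @export
shuffle_null_threshold <- function(fragments, peaks, weights, genome,
                                   n_shuffles = 20L, percentile = 95,
                                   seed = 1L) {
  validate_intervals(peaks, "peak")
  missing_chrom <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chrom)) {
    stop("genome sizes missing for: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  if (nrow(fragments) == 0L) return(0)
  w_frag <- weights[fragments$barcode]
  w_frag[is.na(w_frag)] <- 0
  keep <- which(w_frag != 0)
  frag_gr <- intervals_to_granges(fragments[keep, c("chrom", "start",
                                                    "end")])
  frag_wt <- (fragments$count * w_frag)[keep]
  widths <- peaks$end - peaks$start
  chrlen <- genome[peaks$chrom]
  with_local_seed(seed, {
    null_scores <- lapply(seq_len(n_shuffles), function(r) {
      new_start <- floor(runif(nrow(peaks)) * (chrlen - widths + 1))
      shuf <- tibble::tibble(chrom = peaks$chrom,
                             start = as.integer(new_start),
                             end = as.integer(new_start + widths))
      hits <- GenomicRanges::findOverlaps(intervals_to_granges(shuf),
                                          frag_gr)
      score <- numeric(nrow(peaks))
      if (length(hits)) {
        agg <- rowsum(frag_wt[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
        score[as.integer(rownames(agg))] <- agg[, 1L]
      }
      score
    })
    unname(quantile(unlist(null_scores), percentile / 100))
  })
}

#' Call consensus (typical) enhancers with the four-criteria QC
#'
#' Scores every peak of a cell-type sub-matrix with the weighted combined
#' signal and flags the four quality criteria: (i) signal support in at
#' least `support_fraction` of cells (`ceiling(m * support_fraction)`,
#' counting cells with a nonzero raw count); (ii) no >= 1 bp overlap with
#' promoter windows or exons; (iii) combined signal strictly exceeding the
#' genome-shuffle null threshold; (iv) co-accessibility of at least
#' `coaccess_cutoff` with some promoter-overlapping site. A peak is a
#' typical enhancer iff all four pass.
#'
#' @param pm Cell-type-specific [peak_matrix()].
#' @param weights Per-cell weights from [cell_weights()].
#' @param gene_models Gene models ([read_gene_models()]).
#' @param null_threshold Threshold from [shuffle_null_threshold()], or
#'   `NA` to skip criterion iii (it is then flagged `NA` and not required).
#' @param coaccess_links Pair tibble from [coaccessibility_scores()], or
#'   `NULL` to skip criterion iv likewise.
#' @param support_fraction Minimum supporting cell fraction (default 1/3).
#' @param coaccess_cutoff Minimum promoter co-accessibility (default 0.1).
#' @param promoter_upstream,promoter_downstream Promoter window extents
#'   around the TSS passed to [promoter_windows()].
#' @return Tibble with one row per peak: coordinates, `combined_score`,
#'   `support_fraction`, `max_promoter_coaccess`, the four `crit_*` flags
#'   and `is_enhancer`.
#' @export
call_consensus_enhancers <- function(pm, weights, gene_models,
                                     null_threshold = NA_real_,
                                     coaccess_links = NULL,
                                     support_fraction = 1 / 3,
                                     coaccess_cutoff = 0.1,
                                     promoter_upstream = 2000L,
                                     promoter_downstream = 100L) {
  m <- ncol(pm$counts)
  score <- unname(combined_peak_signal(pm, weights))
  support_n <- unname(Matrix::rowSums(pm$counts > 0))
  crit_support <- support_n >= ceiling(m * support_fraction)

  proms <- promoter_windows(gene_models, promoter_upstream,
                            promoter_downstream)
  exons <- dplyr::bind_rows(gene_models$exons)
  annot <- dplyr::bind_rows(proms[, c("chrom", "start", "end")],
                            exons[, c("chrom", "start", "end")])
  pk_gr <- intervals_to_granges(pm$peaks)
  hit_annot <- IRanges::overlapsAny(
    pk_gr, intervals_to_granges(annot)
  )
  crit_annotation <- !hit_annot

  crit_null <- if (is.na(null_threshold)) {
    rep(NA, nrow(pm$peaks))
  } else {
    score > null_threshold
  }

  max_coaccess <- rep(NA_real_, nrow(pm$peaks))
  crit_coaccess <- rep(NA, nrow(pm$peaks))
  if (!is.null(coaccess_links) && nrow(coaccess_links)) {
    max_coaccess <- promoter_coaccessibility(
      peak_ids(pm), coaccess_links, proms
    )
    crit_coaccess <- !is.na(max_coaccess) & max_coaccess >= coaccess_cutoff
  }

  passes <- crit_support & crit_annotation &
    (is.na(crit_null) | crit_null) &
    (if (all(is.na(crit_coaccess))) TRUE else
       (!is.na(crit_coaccess) & crit_coaccess))
  tibble::tibble(
    peak_id = peak_ids(pm),
    chrom = pm$peaks$chrom, start = pm$peaks$start, end = pm$peaks$end,
    combined_score = unname(score),
    support_fraction = support_n / m,
    max_promoter_coaccess = max_coaccess,
    crit_support = crit_support,
    crit_annotation = crit_annotation,
    crit_null = crit_null,
    crit_coaccess = crit_coaccess,
    is_enhancer = passes
  )
}

# best co-accessibility score linking each peak to a promoter-overlapping
# site
promoter_coaccessibility <- function(ids, links, proms) {
  prom_gr <- intervals_to_granges(proms[, c("chrom", "start", "end")])
  side_overlaps <- function(id) {
    iv <- parse_peak_id(id)
    IRanges::overlapsAny(intervals_to_granges(iv), prom_gr)
  }
  all_sites <- unique(c(links$peak_a, links$peak_b))
  site_prom <- stats::setNames(side_overlaps(all_sites), all_sites)
  a_prom <- site_prom[links$peak_a]
  b_prom <- site_prom[links$peak_b]
  # a peak's promoter co-accessibility: the partner side must overlap a
  # promoter window
  long <- dplyr::bind_rows(
    tibble::tibble(id = links$peak_a[b_prom], score = links$score[b_prom]),
    tibble::tibble(id = links$peak_b[a_prom], score = links$score[a_prom])
  )
  if (nrow(long) == 0L) return(rep(NA_real_, length(ids)))
  best <- dplyr::summarise(dplyr::group_by(long, .data$id),
                           score = max(.data$score), .groups = "drop")
  best$score[match(ids, best$id)]
}
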