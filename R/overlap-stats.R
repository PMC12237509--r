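#' Count overlapping intervals between two sets
#'
#' @param query,reference Interval tibbles on a shared assembly.
#' @param min_bp Minimum overlap in bp to count (default 1).
#' @return List with `k_query` (query intervals touching any reference),
#'   `k_ref` (the symmetric count) and `pairs`, a tibble of all
#'   overlapping (query_index, ref_index) pairs.
#' @export
interval_overlap_count <- function(query, reference, min_bp = 1L) {
  validate_intervals(query, "query")
  validate_intervals(reference, "reference")
  if (nrow(query) == 0L || nrow(reference) == 0L) {
    return(list(k_query = 0L, k_ref = 0L,
                pairs = tibble::tibble(query_index = integer(),
                                       ref_index = integer())))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_to_granges(query), intervals_to_granges(reference),
    minoverlap = min_bp
  ))
  list(
    k_query = length(unique(S4Vectors::queryHits(hits))),
    k_ref = length(unique(S4Vectors::subjectHits(hits))),
    pairs = tibble::tibble(query_index = S4Vectors::queryHits(hits),
                           ref_index = S4Vectors::subjectHits(hits))
  )
}

#' Size of the union universe of two interval sets
#'
#' The number of maximal merged regions in the base-pair union of both
#' sets — the `N` of the hypergeometric overlap test.
#'
#' @param set_a,set_b Interval tibbles.
#' @return Integer count of merged union regions.
#' @export
union_region_count <- function(set_a, set_b) {
  both <- dplyr::bind_rows(set_a[, c("chrom", "start", "end")],
                           set_b[, c("chrom", "start", "end")])
  if (nrow(both) == 0L) return(0L)
  nrow(merge_intervals(both))
}

#' Hypergeometric overlap test
#'
#' Given a universe of `N` regions of which `K` belong to the reference
#' set, drawing `n` query regions and observing `k` overlaps:
#' `p_point` is the hypergeometric mass at exactly `k`, and `p_tail` the
#' upper-tail probability `P(X >= k)` — the enrichment significance.
#' Both are computed in log space via the stable base distributions.
#'
#' @param N,K,n,k Universe, reference, query and overlap counts.
#' @return An `overlap_htest` list: the four counts, `p_point`, `p_tail`.
#' @examples
#' hypergeometric_test(10, 5, 4, 3)$p_point # 50/210
#' @export
hypergeometric_test <- function(N, K, n, k) {
  if (k > min(n, K) || n > N || K > N || k < 0) {
    stop("infeasible counts: need k <= min(n, K) and n, K <= N",
         call. = FALSE)
  }
  if (n - k > N - K) {
    stop("infeasible counts: n - k query regions cannot avoid the ",
         "reference (n - k > N - K)", call. = FALSE)
  }
  structure(list(
    N = N, K = K, n = n, k = k,
    p_point = dhyper(k, K, N - K, n),
    p_tail = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  ), class = "overlap_htest")
}

#' @export
#' @method print overlap_htest
print.overlap_htest <- function(x, ...) {
  cat("Hypergeometric overlap test\n",
      "  N (union regions) = ", x$N, ", K (reference) = ", x$K,
      ", n (query) = ", x$n, ", k (overlap) = ", x$k, "\n",
      "  P(X = k)  = ", format(x$p_point, digits = 4), "\n",
      "  P(X >= k) = ", format(x$p_tail, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Overlap percentage, rounded half-up to two decimals
#'
#' @param k Overlap count; `n` set size (must be positive).
#' @param n Denominator.
#' @return `100 * k / n` rounded half-up to 2 decimals (e.g. 109/312
#'   gives 34.94).
#' @export
overlap_percent <- function(k, n) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  # the 1e-9 guard keeps exact halves (e.g. 1.005) rounding up despite
  # binary floating point
  floor(100 * k / n * 100 + 0.5 + 1e-9) / 100
}

#' Compare signals of overlapping vs non-overlapping regions
#'
#' Log2 fold change of group means plus a two-sided two-sample t-test
#' (Welch by default).
#'
#' @param overlapping,nonoverlapping Numeric signal vectors (nonempty).
#' @param var_equal Pool variances (classic Student) instead of Welch.
#' @return Tibble with `l2fc`, `p_value`, `mean_overlapping`,
#'   `mean_nonoverlapping`.
#' @export
signal_compare <- function(overlapping, nonoverlapping,
                           var_equal = FALSE) {
  stopifnot(length(overlapping) > 0, length(nonoverlapping) > 0)
  m1 <- mean(overlapping)
  m0 <- mean(nonoverlapping)
  if (m0 == 0) {
    warning("non-overlapping mean is zero; using a small epsilon in the ",
            "fold change", call. = FALSE)
    m0 <- 1e-9
  }
  p <- tryCatch(
    t.test(overlapping, nonoverlapping, var.equal = var_equal)$p.value,
    error = function(e) 1  # constant data: no evidence of a difference
  )
  tibble::tibble(
    l2fc = log2(m1 / m0), p_value = p,
    mean_overlapping = mean(overlapping),
    mean_nonoverlapping = mean(nonoverlapping)
  )
}

#' Base-pair Jaccard similarity of two interval sets
#'
#' Intersection over union in base pairs, computed on the merged sets, so
#' the coefficient is invariant to how intervals are split into abutting
#' pieces.
#'
#' @param set_a,set_b Interval tibbles.
#' @return Coefficient in `[0, 1]`; 0 with a warning when both sets are
#'   empty.
#' @export
jaccard <- function(set_a, set_b) {
  if (nrow(set_a) == 0L && nrow(set_b) == 0L) {
    warning("both interval sets are empty; Jaccard undefined, ",
            "returning 0", call. = FALSE)
    return(0)
  }
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) return(0)
  a <- GenomicRanges::reduce(intervals_to_granges(set_a),
                             ignore.strand = TRUE)
  b <- GenomicRanges::reduce(intervals_to_granges(set_b),
                             ignore.strand = TRUE)
  inter <- sum(GenomicRanges::width(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(
    GenomicRanges::union(a, b, ignore.strand = TRUE)))
  inter / uni
}

#' Full overlap validation of a query set against a reference catalogue
#'
#' Combines [interval_overlap_count()], [union_region_count()],
#' [hypergeometric_test()], [overlap_percent()] and [jaccard()] into the
#' one-stop comparison used to validate predicted super-enhancers against
#' a reference database: the universe `N` is the union of both sets,
#' `K` the reference count, `n` the query count, `k` the overlapping query
#' count.
#'
#' @inheritParams interval_overlap_count
#' @return An `overlap_report` tibble with one row: the four counts, both
#'   overlap percentages, `p_point`, `p_tail` (the reported significance)
#'   and the base-pair Jaccard coefficient.
#' @export
overlap_report <- function(query, reference, min_bp = 1L) {
  cnt <- interval_overlap_count(query, reference, min_bp)
  N <- union_region_count(query, reference)
  ht <- hypergeometric_test(N, min(nrow(reference), N),
                            min(nrow(query), N), min(cnt$k_query, N))
  out <- tibble::tibble(
    N = ht$N, K = nrow(reference), n = nrow(query), k = cnt$k_query,
    k_ref = cnt$k_ref,
    percent_query = overlap_percent(cnt$k_query, nrow(query)),
    percent_ref = overlap_percent(cnt$k_ref, nrow(reference)),
    p_point = ht$p_point, p_tail = ht$p_tail,
    jaccard = jaccard(query, reference)
  )
  class(out) <- c("overlap_report", class(out))
  out
}
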