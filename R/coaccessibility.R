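#' TF-IDF transform of a peak-by-cell count matrix
#'
#' Latent-semantic-indexing style transform giving the sparse counts a
#' continuous representation: entry `(i, j)` becomes
#' `ln(1 + (count / cell_total_j) * (m / n_cells_with_peak_i) * 1e4)`.
#' Zero counts stay exactly zero, as do all-zero peaks; doubling a cell's
#' counts leaves its column unchanged (term frequency is depth-normalized).
#'
#' @param pm A [peak_matrix()] or sparse peaks x cells matrix with no
#'   all-zero cells.
#' @return A `dgCMatrix` of the same shape.
#' @export
tfidf_transform <- function(pm) {
  x <- if (inherits(pm, "peak_matrix")) pm$counts else pm
  cell_tot <- Matrix::colSums(x)
  if (any(cell_tot == 0)) {
    stop("matrix has all-zero cells; filter them before the TF-IDF ",
         "transform", call. = FALSE)
  }
  m <- ncol(x)
  npk <- Matrix::rowSums(x > 0)
  idf <- ifelse(npk > 0, m / npk, 0)
  out <- x %*% Matrix::Diagonal(x = 1 / cell_tot)
  out <- Matrix::Diagonal(x = idf) %*% out
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x * 1e4)
  dimnames(out) <- dimnames(x)
  out
}

#' LSI embedding by truncated SVD
#'
#' Singular value decomposition of the TF-IDF matrix; cell coordinates are
#' `V * d`. The first component is conventionally depth-correlated and is
#' excluded from `retained` (components 2..n are used downstream).
#' Component signs are fixed so the largest-magnitude loading is positive,
#' making the embedding deterministic.
#'
#' @param tfidf Matrix from [tfidf_transform()].
#' @param n_components Number of components to compute (capped at
#'   `min(dim) - 1` with a warning when the matrix is too small).
#' @param seed Seed for the randomized solver used on large matrices.
#' @return An `lsi_embedding`: list with `coords` (cells x n_components),
#'   `retained` (column indices used downstream, 2..n), `d` (singular
#'   values).
#' @export
lsi_embed <- function(tfidf, n_components = 50L, seed = 1L) {
  n_max <- min(dim(tfidf)) - 1L
  if (n_components > n_max) {
    warning("requested ", n_components, " components but only ", n_max,
            " are available; returning ", n_max, call. = FALSE)
    n_components <- n_max
  }
  stopifnot(n_components >= 2L)
  if (min(dim(tfidf)) <= 600L) {
    sv <- svd(as.matrix(tfidf), nu = 0L, nv = n_components)
    v <- sv$v
    d <- sv$d[seq_len(n_components)]
  } else {
    sv <- with_local_seed(seed,
                          irlba::irlba(tfidf, nv = n_components))
    v <- sv$v
    d <- sv$d
  }
  # sign convention: largest-|coordinate| entry positive per component
  for (j in seq_len(ncol(v))) {
    piv <- which.max(abs(v[, j]))
    if (v[piv, j] < 0) v[, j] <- -v[, j]
  }
  coords <- sweep(v, 2L, d, `*`)
  rownames(coords) <- colnames(tfidf)
  structure(list(coords = coords,
                 retained = seq(2L, n_components),
                 d = d),
            class = "lsi_embedding")
}

lsi_retained <- function(emb) {
  emb$coords[, emb$retained, drop = FALSE]
}

#' Two-dimensional embedding of cells
#'
#' Nonlinear UMAP embedding of the retained LSI components (deterministic
#' under a fixed seed; single-threaded layout). `method = "lsi"` is a
#' documented pass-through that returns retained LSI components 2-3
#' unchanged, useful as a fast deterministic stand-in.
#'
#' @param emb An `lsi_embedding` (or a plain coordinate matrix).
#' @param seed RNG seed.
#' @param method `"umap"` (default) or `"lsi"` (pass-through).
#' @param n_neighbors UMAP neighborhood size.
#' @return Cells x 2 coordinate matrix.
#' @export
umap_embed <- function(emb, seed = 1L, method = c("umap", "lsi"),
                       n_neighbors = 15L) {
  method <- match.arg(method)
  coords <- if (inherits(emb, "lsi_embedding")) lsi_retained(emb) else emb
  if (method == "lsi") {
    out <- coords[, 1:2, drop = FALSE]
    colnames(out) <- c("dim1", "dim2")
    return(out)
  }
  if (nrow(coords) < 10L) {
    stop("need at least 10 cells for a UMAP embedding", call. = FALSE)
  }
  n_neighbors <- min(n_neighbors, nrow(coords) - 1L)
  out <- with_local_seed(seed, uwot::umap(
    coords, n_neighbors = n_neighbors, n_threads = 1,
    n_sgd_threads = 0, batch = TRUE
  ))
  dimnames(out) <- list(rownames(coords), c("dim1", "dim2"))
  out
}

#' Aggregate cells into overlapping metacells
#'
#' Densifies sparse counts before covariance estimation: candidate
#' metacells are the `k` nearest neighbors (in the embedding) of randomly
#' ordered seed cells, accepted greedily unless they share more than
#' `max_overlap * k` members with an already accepted metacell. Counts are
#' summed over members.
#'
#' @param pm A [peak_matrix()] (or peaks x cells matrix).
#' @param coords Per-cell embedding coordinates (rows match cells).
#' @param k Cells per metacell (default 50). If fewer cells than `k` are
#'   available a single all-cell metacell is returned with a warning.
#' @param max_overlap Maximum member-sharing fraction between accepted
#'   metacells (default 0.8).
#' @param seed RNG seed for the seed-cell order.
#' @return A `metacell_matrix`: list with `counts` (peaks x metacells) and
#'   `members` (list of member column indices).
#' @export
aggregate_metacells <- function(pm, coords, k = 50L, max_overlap = 0.8,
                                seed = 1L) {
  x <- if (inherits(pm, "peak_matrix")) pm$counts else pm
  m <- ncol(x)
  if (m < k) {
    warning("only ", m, " cells for metacell size ", k,
            "; returning a single metacell of all cells", call. = FALSE)
    members <- list(seq_len(m))
  } else {
    d2 <- as.matrix(stats::dist(coords))
    order_seeds <- with_local_seed(seed, sample.int(m))
    max_shared <- floor(max_overlap * k)
    members <- list()
    for (s in order_seeds) {
      cand <- order(d2[s, ])[seq_len(k)]
      ok <- TRUE
      for (acc in members) {
        if (length(intersect(cand, acc)) > max_shared) { ok <- FALSE; break }
      }
      if (ok) members[[length(members) + 1L]] <- sort(cand)
    }
  }
  ind <- Matrix::sparseMatrix(
    i = unlist(members),
    j = rep(seq_along(members), lengths(members)),
    x = 1, dims = c(m, length(members))
  )
  counts <- methods::as(x %*% ind, "CsparseMatrix")
  colnames(counts) <- paste0("meta", seq_along(members))
  structure(list(counts = counts, members = members),
            class = "metacell_matrix")
}

# graphical lasso with an elementwise penalty matrix (blockwise coordinate
# descent; Friedman, Hastie & Tibshirani's algorithm). The diagonal is
# unpenalized. Returns the precision matrix Theta, or NULL on
# non-convergence.
glasso_fit <- function(S, P, max_iter = 200L, tol = 1e-4) {
  p <- ncol(S)
  if (p == 1L) return(matrix(1 / S[1, 1], 1, 1))
  W <- S
  B <- matrix(0, p, p)
  off <- mean(abs(S[upper.tri(S)])) + 1e-12
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      beta <- lasso_cd(W[idx, idx, drop = FALSE], S[idx, j], P[idx, j],
                       B[idx, j])
      B[idx, j] <- beta
      w12 <- W[idx, idx, drop = FALSE] %*% beta
      W[idx, j] <- W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < tol * off) { converged <- TRUE; break }
  }
  if (!converged) return(NULL)
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    t_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    Theta[j, j] <- t_jj
    Theta[idx, j] <- -B[idx, j] * t_jj
  }
  (Theta + t(Theta)) / 2
}

# coordinate descent for min_b 1/2 b'Wb - s'b + sum(rho |b|)
lasso_cd <- function(W, s, rho, beta, max_iter = 500L, tol = 1e-6) {
  p <- length(s)
  Wb <- as.numeric(W %*% beta)
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      r <- s[j] - Wb[j] + W[j, j] * beta[j]
      bj_new <- sign(r) * max(abs(r) - rho[j], 0) / W[j, j]
      dj <- bj_new - beta[j]
      if (dj != 0) {
        Wb <- Wb + W[, j] * dj
        beta[j] <- bj_new
        delta_max <- max(delta_max, abs(dj))
      }
    }
    if (delta_max < tol) break
  }
  beta
}

#' Distance-penalized co-accessibility scores
#'
#' Estimates partial-correlation co-accessibility between peaks on the
#' same chromosome within `max_dist` of each other. The genome is tiled
#' into overlapping windows of width `2 * max_dist` (half-window step);
#' within each window, metacell counts are depth-normalized and
#' unit-variance scaled, their correlation matrix is regularized by a
#' graphical lasso whose off-diagonal penalty grows linearly with genomic
#' distance (`penalty_scale * d / max_dist`, infinite beyond `max_dist`),
#' and the score of pair (i, j) is `-Theta_ij / sqrt(Theta_ii Theta_jj)`.
#' Pairs falling in several windows keep the score from the window whose
#' center is nearest the pair midpoint. Only pairs with a nonzero penalized
#' precision entry are returned.
#'
#' @param metacells A `metacell_matrix` from [aggregate_metacells()] (or a
#'   peaks x metacells matrix).
#' @param peaks Interval tibble matching the metacell matrix rows.
#' @param max_dist Maximum pair distance in bp (default 500000).
#' @param penalty_scale Scale of the linear distance penalty (default 1:
#'   the penalty equals the distance fraction of `max_dist`, so a pair can
#'   only survive if its correlation exceeds that fraction).
#' @param ridge Diagonal shrinkage applied to the window correlation
#'   matrices for numerical stability.
#' @return Tibble of pairs: `peak_a`, `peak_b` (ids, a < b by position),
#'   coordinates, `distance` (midpoint distance), `score` in `[-1, 1]`.
#'   Windows that fail to converge are skipped with a warning.
#' @export
coaccessibility_scores <- function(metacells, peaks, max_dist = 500000,
                                   penalty_scale = 1, ridge = 0.01) {
  x <- if (inherits(metacells, "metacell_matrix")) metacells$counts
       else metacells
  stopifnot(nrow(x) == nrow(peaks))
  if (ncol(x) < 5L) {
    stop("need at least 5 metacells to estimate co-accessibility",
         call. = FALSE)
  }
  # depth-normalize metacells, then unit-variance scaling happens via the
  # correlation matrix inside each window
  xn <- as.matrix(x %*% Matrix::Diagonal(x = 1 / Matrix::colSums(x)))
  mid <- (peaks$start + peaks$end) / 2
  ids <- peak_id_string(peaks)

  results <- list()
  skipped <- 0L
  for (chrom in unique(peaks$chrom)) {
    on_chrom <- which(peaks$chrom == chrom)
    if (length(on_chrom) < 2L) next
    lo <- min(mid[on_chrom]); hi <- max(mid[on_chrom])
    win_starts <- seq(max(0, lo - max_dist), hi, by = max_dist)
    for (ws in win_starts) {
      idx <- on_chrom[mid[on_chrom] >= ws & mid[on_chrom] < ws + 2 * max_dist]
      if (length(idx) < 2L) next
      sub <- xn[idx, , drop = FALSE]
      keep <- apply(sub, 1L, stats::sd) > 0
      idx <- idx[keep]
      if (length(idx) < 2L) next
      S <- stats::cor(t(xn[idx, , drop = FALSE]))
      S <- (1 - ridge) * S + ridge * diag(length(idx))
      d_ij <- abs(outer(mid[idx], mid[idx], `-`))
      P <- penalty_scale * d_ij / max_dist
      P[d_ij > max_dist] <- 10  # >= max|S|, forces exact zeros
      diag(P) <- 0
      Theta <- glasso_fit(S, P)
      if (is.null(Theta)) { skipped <- skipped + 1L; next }
      sc <- -Theta / sqrt(outer(diag(Theta), diag(Theta)))
      ut <- which(upper.tri(sc) & sc != 0 & d_ij <= max_dist,
                  arr.ind = TRUE)
      if (nrow(ut) == 0L) next
      i <- idx[ut[, 1L]]; j <- idx[ut[, 2L]]
      results[[length(results) + 1L]] <- tibble::tibble(
        ia = pmin(i, j), ib = pmax(i, j),
        score = sc[ut],
        window_center = ws + max_dist
      )
    }
  }
  if (skipped > 0L) {
    warning(skipped, " window(s) skipped: graphical lasso did not ",
            "converge", call. = FALSE)
  }
  if (length(results) == 0L) {
    return(tibble::tibble(peak_a = character(), peak_b = character(),
                          chrom = character(), start_a = integer(),
                          end_a = integer(), start_b = integer(),
                          end_b = integer(), distance = numeric(),
                          score = numeric()))
  }
  all_pairs <- dplyr::bind_rows(results)
  pair_mid <- (mid[all_pairs$ia] + mid[all_pairs$ib]) / 2
  all_pairs$center_gap <- abs(pair_mid - all_pairs$window_center)
  best <- dplyr::slice_min(
    dplyr::group_by(all_pairs, .data$ia, .data$ib),
    .data$center_gap, n = 1L, with_ties = FALSE
  )
  best <- dplyr::ungroup(best)
  tibble::tibble(
    peak_a = ids[best$ia], peak_b = ids[best$ib],
    chrom = peaks$chrom[best$ia],
    start_a = peaks$start[best$ia], end_a = peaks$end[best$ia],
    start_b = peaks$start[best$ib], end_b = peaks$end[best$ib],
    distance = abs(mid[best$ib] - mid[best$ia]),
    score = best$score
  )
}

#' Link enhancers to promoters through co-accessibility
#'
#' Keeps pairs with exactly one side overlapping a promoter window and a
#' score of at least `cutoff`; the gene comes from the promoter side.
#' Pairs with both sides in promoters are promoter-promoter interactions,
#' not enhancer-promoter links, and are excluded.
#'
#' @param pairs Tibble from [coaccessibility_scores()].
#' @param promoters Promoter windows ([promoter_windows()]).
#' @param cutoff Minimum co-accessibility score (default 0.1).
#' @return Tibble: enhancer coordinates, promoter coordinates, `gene_id`,
#'   `score`.
#' @export
link_enhancer_promoter <- function(pairs, promoters, cutoff = 0.1) {
  empty <- tibble::tibble(
    enhancer = character(), chrom = character(),
    enh_start = integer(), enh_end = integer(),
    promoter_site = character(), prom_start = integer(),
    prom_end = integer(), gene_id = character(), score = numeric()
  )
  if (nrow(pairs) == 0L) return(empty)
  prom_gr <- intervals_to_granges(promoters[, c("chrom", "start", "end")])
  a_gr <- intervals_to_granges(
    tibble::tibble(chrom = pairs$chrom, start = pairs$start_a,
                   end = pairs$end_a))
  b_gr <- intervals_to_granges(
    tibble::tibble(chrom = pairs$chrom, start = pairs$start_b,
                   end = pairs$end_b))
  a_prom <- IRanges::overlapsAny(a_gr, prom_gr)
  b_prom <- IRanges::overlapsAny(b_gr, prom_gr)
  sel <- which(xor(a_prom, b_prom) & pairs$score >= cutoff)
  if (length(sel) == 0L) return(empty)
  prom_is_b <- b_prom[sel]
  link <- tibble::tibble(
    enhancer = ifelse(prom_is_b, pairs$peak_a[sel], pairs$peak_b[sel]),
    chrom = pairs$chrom[sel],
    enh_start = ifelse(prom_is_b, pairs$start_a[sel], pairs$start_b[sel]),
    enh_end = ifelse(prom_is_b, pairs$end_a[sel], pairs$end_b[sel]),
    promoter_site = ifelse(prom_is_b, pairs$peak_b[sel],
                           pairs$peak_a[sel]),
    prom_start = ifelse(prom_is_b, pairs$start_b[sel],
                        pairs$start_a[sel]),
    prom_end = ifelse(prom_is_b, pairs$end_b[sel], pairs$end_a[sel]),
    score = pairs$score[sel]
  )
  # attach the gene(s) whose promoter window the promoter side overlaps
  link_gr <- intervals_to_granges(
    tibble::tibble(chrom = link$chrom, start = link$prom_start,
                   end = link$prom_end))
  hits <- GenomicRanges::findOverlaps(link_gr, prom_gr)
  out <- link[S4Vectors::queryHits(hits), ]
  out$gene_id <- promoters$gene_id[S4Vectors::subjectHits(hits)]
  dplyr::arrange(
    out[, c("enhancer", "chrom", "enh_start", "enh_end", "promoter_site",
            "prom_start", "prom_end", "gene_id", "score")],
    .data$chrom, .data$enh_start, .data$gene_id
  )
}
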