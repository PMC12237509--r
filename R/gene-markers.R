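#' Gene activity scores from peak accessibility
#'
#' For every gene, sums the counts of all peaks overlapping (>= 1 bp) its
#' strand-aware activity window: the gene body plus `upstream_d` bp
#' upstream of the TSS (default 2 kb) to capture the promoter. A peak
#' overlapping two genes' windows counts toward both.
#'
#' @param pm A [peak_matrix()].
#' @param gene_models Gene model tibble ([read_gene_models()]).
#' @param upstream_d Promoter distance upstream of the TSS in bp.
#' @return Sparse genes x cells matrix with gene ids as row names. Genes
#'   on chromosomes absent from the matrix get zero rows with a warning.
#' @export
gene_activity <- function(pm, gene_models, upstream_d = 2000L) {
  plus <- gene_models$strand == "+"
  win <- tibble::tibble(
    chrom = gene_models$chrom,
    start = pmax(0L, as.integer(ifelse(plus,
                                       gene_models$start - upstream_d,
                                       gene_models$start))),
    end = as.integer(ifelse(plus, gene_models$end,
                            gene_models$end + upstream_d))
  )
  off_chrom <- !win$chrom %in% unique(pm$peaks$chrom)
  if (any(off_chrom)) {
    warning(sum(off_chrom), " gene(s) on chromosomes absent from the ",
            "matrix; their activity is zero", call. = FALSE)
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals_to_granges(win),
                                intervals_to_granges(pm$peaks)))
  ind <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits),
    j = S4Vectors::subjectHits(hits),
    x = 1,
    dims = c(nrow(gene_models), nrow(pm$peaks))
  )
  act <- methods::as(ind %*% pm$counts, "CsparseMatrix")
  dimnames(act) <- list(gene_models$gene_id, pm$barcodes)
  act
}

#' Log-normalize a gene activity matrix
#'
#' Per cell: `x -> ln(1 + scale * x / cell_total)` (library-size
#' normalization followed by log1p). Cells with zero total are left zero.
#'
#' @param activity Genes x cells matrix from [gene_activity()].
#' @param scale Scale factor (default 1e4).
#' @return Matrix of the same shape.
#' @export
normalize_activity <- function(activity, scale = 1e4) {
  tot <- Matrix::colSums(activity)
  tot[tot == 0] <- Inf  # zero cells stay zero
  out <- methods::as(activity %*% Matrix::Diagonal(x = scale / tot),
                     "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(activity)
  out
}

#' One-vs-rest marker detection on gene activity
#'
#' For each cell type, tests each gene's normalized activity in that type
#' against all other cells with a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction). Genes are prefiltered by expression
#' fraction (`pct_in >= min_pct`) and fold change
#' (`log2((mean_in + 1) / (mean_out + 1)) >= min_log2fc`, means taken on
#' de-logged normalized values), and Bonferroni correction uses the number
#' of genes actually tested per type. A gene is a marker iff
#' `p_adjusted < alpha_adj`.
#'
#' @param normalized Genes x cells matrix from [normalize_activity()].
#' @param labels Named character vector barcode -> cell type covering the
#'   matrix columns.
#' @param min_pct Minimum expressing-cell fraction in the type
#'   (default 0.3).
#' @param min_log2fc Minimum log2 fold change (default 0.585, ~1.5x).
#' @param alpha_adj Adjusted p-value cutoff (default 1e-5).
#' @return Tibble of markers: `gene`, `cell_type`, `log2_fold_change`,
#'   `pct_in`, `pct_out`, `p_value`, `p_adjusted`, ordered by type and
#'   adjusted p. Requires at least three cell types with >= 3 cells each.
#' @export
find_markers <- function(normalized, labels, min_pct = 0.3,
                         min_log2fc = 0.585, alpha_adj = 1e-5) {
  lab <- unname(labels[colnames(normalized)])
  if (anyNA(lab)) {
    stop("labels missing for ", sum(is.na(lab)), " cell(s)", call. = FALSE)
  }
  types <- sort(unique(lab))
  if (length(types) < 3L) {
    stop("marker detection requires at least three annotated cell types ",
         "(got ", length(types), ")", call. = FALSE)
  }
  small <- table(lab) < 3L
  if (any(small)) {
    stop("cell type(s) with fewer than 3 cells: ",
         paste(names(small)[small], collapse = ", "), call. = FALSE)
  }
  dense <- as.matrix(normalized)
  delogged <- expm1(dense)
  out <- list()
  for (ct in types) {
    in_idx <- lab == ct
    x_in <- dense[, in_idx, drop = FALSE]
    x_out <- dense[, !in_idx, drop = FALSE]
    pct_in <- rowMeans(x_in > 0)
    pct_out <- rowMeans(x_out > 0)
    mean_in <- rowMeans(delogged[, in_idx, drop = FALSE])
    mean_out <- rowMeans(delogged[, !in_idx, drop = FALSE])
    l2fc <- log2((mean_in + 1) / (mean_out + 1))
    tested <- which(pct_in >= min_pct & l2fc >= min_log2fc)
    if (length(tested) == 0L) next
    pvals <- vapply(tested, function(g) {
      suppressWarnings(
        wilcox.test(x_in[g, ], x_out[g, ], alternative = "two.sided",
                    exact = FALSE, correct = TRUE)$p.value
      )
    }, numeric(1))
    p_adj <- pmin(pvals * length(tested), 1)
    keep <- which(p_adj < alpha_adj)
    if (length(keep) == 0L) next
    out[[ct]] <- tibble::tibble(
      gene = rownames(dense)[tested[keep]],
      cell_type = ct,
      log2_fold_change = l2fc[tested[keep]],
      pct_in = unname(pct_in[tested[keep]]),
      pct_out = unname(pct_out[tested[keep]]),
      p_value = pvals[keep],
      p_adjusted = p_adj[keep]
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(gene = character(), cell_type = character(),
                          log2_fold_change = numeric(),
                          pct_in = numeric(), pct_out = numeric(),
                          p_value = numeric(), p_adjusted = numeric()))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$cell_type, .data$p_adjusted,
                 dplyr::desc(.data$log2_fold_change))
}
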