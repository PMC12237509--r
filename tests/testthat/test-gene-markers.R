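test_that("gene activity sums counts over the strand-aware window", {
  # + strand gene [5000, 8000), upstream 2000 -> window [3000, 8000)
  peaks <- genomic_intervals("chr1", c(3500, 7000, 9000),
                             c(3600, 7100, 9100))
  counts <- matrix(c(2, 1, 5), 3, 1)
  pm <- peak_matrix(counts, peaks, "b1")
  act <- gene_activity(pm, toy_gene(start = 5000, end = 8000), 2000)
  expect_equal(unname(act[1, 1]), 3)  # 2 + 1; the peak at 9000 excluded

  # minus strand: upstream extends to larger coordinates
  act_m <- gene_activity(pm, toy_gene(start = 5000, end = 8000,
                                      strand = "-"), 2000)
  expect_equal(unname(act_m[1, 1]), 1 + 5)  # window [5000, 10000)

  # gene on a chromosome absent from the matrix: zero row with warning
  expect_warning(
    act0 <- gene_activity(pm, toy_gene(chrom = "chrX"), 2000),
    "absent")
  expect_equal(sum(act0), 0)
})

test_that("gene activity is additive over peak memberships (oracle)", {
  set.seed(17)
  sim <- get_fixture("tiny_sim2", function() {
    simulate_dataset(sim_config(
      n_cell_types = 2, cells_per_type = 20,
      n_specific_peaks_per_type = 3, se_clusters_per_type = 1,
      n_marker_genes_per_type = 2, n_housekeeping_genes = 4,
      mean_fragments_per_cell = 150, seed = 9
    ))
  })
  act <- gene_activity(sim$matrix, sim$gene_models)
  g <- sample(nrow(sim$gene_models), 3)
  for (gi in g) {
    gm <- sim$gene_models[gi, ]
    win_start <- if (gm$strand == "+") gm$start - 2000 else gm$start
    win_end <- if (gm$strand == "+") gm$end else gm$end + 2000
    in_win <- sim$matrix$peaks$chrom == gm$chrom &
      sim$matrix$peaks$end > win_start & sim$matrix$peaks$start < win_end
    expect_equal(unname(as.matrix(act)[gi, ]),
                 unname(Matrix::colSums(sim$matrix$counts[in_win, ,
                                                          drop = FALSE])))
  }
})

test_that("normalization matches the closed form and is depth-invariant", {
  act <- Matrix::Matrix(rbind(c(10, 20), c(90, 180)), sparse = TRUE)
  nrm <- normalize_activity(act, scale = 1e4)
  expect_equal(nrm[1, 1], log(1 + 1e4 * 10 / 100), tolerance = 1e-12)
  expect_equal(nrm[1, 1], nrm[1, 2])  # proportional cells -> identical
  expect_equal(normalize_activity(Matrix::Matrix(0, 2, 2))[1, 1], 0)
})

test_that("marker detection refuses fewer than three cell types", {
  m <- Matrix::Matrix(matrix(1, 4, 20), sparse = TRUE)
  rownames(m) <- paste0("g", 1:4); colnames(m) <- paste0("b", 1:20)
  labels <- stats::setNames(rep(c("A", "B"), 10), colnames(m))
  expect_error(find_markers(m, labels), "three annotated cell types")
})

test_that("markers honor the pct and fold-change prefilters", {
  set.seed(4)
  n_per <- 40
  labels <- stats::setNames(rep(c("A", "B", "C"), each = n_per),
                            paste0("b", 1:(3 * n_per)))
  n_genes <- 30
  base <- matrix(rpois(n_genes * 3 * n_per, 5) + 1, n_genes, 3 * n_per)
  # g1: genuine marker of A; g2: huge fold change in only 20% of A cells
  base[1, 1:n_per] <- base[1, 1:n_per] * 10
  base[2, ] <- 0
  base[2, 1:8] <- 500
  m <- normalize_activity(Matrix::Matrix(base, sparse = TRUE))
  rownames(m) <- paste0("g", 1:n_genes); colnames(m) <- names(labels)
  mk <- find_markers(m, labels, alpha_adj = 1e-3)
  expect_true("g1" %in% mk$gene[mk$cell_type == "A"])
  expect_false("g2" %in% mk$gene)  # pct_in 0.2 < 0.3: never tested
  # identically distributed genes are not markers
  expect_false(any(paste0("g", 3:n_genes) %in% mk$gene))
  expect_true(all(mk$pct_in >= 0.3))
  expect_true(all(mk$p_adjusted >= mk$p_value))
})

test_that("marker output is invariant to cell and gene order", {
  set.seed(6)
  n_per <- 30
  labels <- stats::setNames(rep(c("A", "B", "C"), each = n_per),
                            paste0("b", 1:(3 * n_per)))
  base <- matrix(rpois(6 * 3 * n_per, 4) + 1, 6, 3 * n_per)
  base[2, seq_len(n_per) + n_per] <- base[2, seq_len(n_per) + n_per] * 8
  m <- normalize_activity(Matrix::Matrix(base, sparse = TRUE))
  rownames(m) <- paste0("g", 1:6); colnames(m) <- names(labels)
  ref <- find_markers(m, labels, alpha_adj = 1e-3)
  pc <- sample(ncol(m)); pg <- sample(nrow(m))
  got <- find_markers(m[pg, pc], labels, alpha_adj = 1e-3)
  expect_equal(got, ref)
})
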