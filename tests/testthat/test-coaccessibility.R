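test_that("TF-IDF entries match the closed form", {
  # peak present in all cells (IDF = 1), count 1 of cell total 2
  x <- Matrix::Matrix(rbind(c(1, 1), c(1, 1)), sparse = TRUE)
  tf <- tfidf_transform(x)
  expect_equal(tf[1, 1], log(1 + 0.5 * 1 * 1e4), tolerance = 1e-12)
  # zero counts stay zero
  x2 <- Matrix::Matrix(rbind(c(2, 0), c(1, 3)), sparse = TRUE)
  expect_equal(tfidf_transform(x2)[1, 2], 0)
  # doubling a cell's counts leaves its column unchanged
  x3 <- x2; x3[, 1] <- x3[, 1] * 2
  expect_equal(as.matrix(tfidf_transform(x3))[, 1],
               as.matrix(tfidf_transform(x2))[, 1])
  # all-zero cells are a hard error
  expect_error(tfidf_transform(rbind(c(1, 0), c(1, 0))), "all-zero cells")
})

test_that("LSI coordinates agree with a dense eigendecomposition oracle", {
  set.seed(13)
  x <- Matrix::Matrix(matrix(rpois(30 * 20, 1.5), 30, 20), sparse = TRUE)
  x <- x[Matrix::rowSums(x) > 0, ]
  tf <- tfidf_transform(x)
  emb <- lsi_embed(tf, n_components = 10)
  # oracle: eigen-decomposition of the Gram matrix gives V and d^2
  g <- eigen(crossprod(as.matrix(tf)), symmetric = TRUE)
  oracle <- g$vectors[, 1:10] %*% diag(sqrt(g$values[1:10]))
  expect_equal(abs(unname(emb$coords)), abs(oracle), tolerance = 1e-8)
  expect_equal(emb$retained, 2:10)
})

test_that("rank-1 input leaves nothing beyond the first component", {
  x <- outer(c(1, 2, 3, 4), c(2, 1, 3, 1, 2))
  emb <- lsi_embed(Matrix::Matrix(x, sparse = TRUE), n_components = 3)
  expect_lt(max(abs(emb$coords[, 2:3])), 1e-8)
})

test_that("umap embedding is seeded and the lsi fallback is exact", {
  sim <- get_fixture("tiny_sim2", function() {
    simulate_dataset(sim_config(
      n_cell_types = 2, cells_per_type = 20,
      n_specific_peaks_per_type = 3, se_clusters_per_type = 1,
      n_marker_genes_per_type = 2, n_housekeeping_genes = 4,
      mean_fragments_per_cell = 150, seed = 9
    ))
  })
  tf <- tfidf_transform(sim$matrix)
  emb <- lsi_embed(tf, n_components = 10)
  u1 <- umap_embed(emb, seed = 4)
  u2 <- umap_embed(emb, seed = 4)
  expect_identical(u1, u2)
  fb <- umap_embed(emb, method = "lsi")
  expect_equal(unname(fb), unname(emb$coords[, 2:3]))
  # the two simulated types separate: inter-type > intra-type distance
  lab <- sim$matrix$labels[sim$matrix$barcodes]
  d <- as.matrix(dist(u1))
  same <- outer(lab, lab, `==`)
  expect_gt(mean(d[!same]), mean(d[same & upper.tri(same)]))
})

test_that("metacell aggregation sums its recorded members", {
  set.seed(5)
  x <- Matrix::Matrix(matrix(rpois(50 * 40, 1), 50, 40), sparse = TRUE)
  coords <- matrix(rnorm(80), 40, 2)
  meta <- aggregate_metacells(x, coords, k = 8, max_overlap = 0.5,
                              seed = 2)
  for (j in seq_along(meta$members)) {
    expect_equal(unname(as.matrix(meta$counts)[, j]),
                 unname(Matrix::rowSums(x[, meta$members[[j]],
                                          drop = FALSE])))
  }
  # k = m collapses to a single metacell of row sums
  expect_warning(one <- aggregate_metacells(x, coords, k = 41), "single")
  expect_equal(unname(as.matrix(one$counts)[, 1]),
               unname(Matrix::rowSums(x)))
  # k = 1 with no overlap allowed gives distinct single cells
  singles <- aggregate_metacells(x, coords, k = 1, max_overlap = 0,
                                 seed = 2)
  expect_equal(sort(unlist(singles$members)), 1:40)
})

test_that("co-accessibility respects chromosome and distance bounds", {
  set.seed(8)
  counts <- Matrix::Matrix(matrix(rpois(4 * 30, 5), 4, 30), sparse = TRUE)
  peaks <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0L, 10000L, 610000L, 5000L),
    end = c(500L, 10500L, 610500L, 5500L)
  )
  pairs <- coaccessibility_scores(counts, peaks, max_dist = 500000,
                                  penalty_scale = 0.1)
  key <- paste(pairs$peak_a, pairs$peak_b)
  # peaks 600 kb apart and peaks on different chromosomes never pair
  expect_false(any(grepl("chr2", key) & grepl("chr1", key)))
  expect_true(all(pairs$distance <= 500000))
  expect_false("chr1:10000-10500 chr1:610000-610500" %in% key)
})

test_that("a planted co-varying pair outscores independent background", {
  set.seed(21)
  n_meta <- 60
  base <- matrix(rpois(8 * n_meta, 20), 8, n_meta)
  driver <- rpois(n_meta, 30)
  counts <- rbind(driver + rpois(n_meta, 2),
                  driver + rpois(n_meta, 2), base)
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(seq(0, by = 10000, length.out = 10)),
    end = as.integer(seq(0, by = 10000, length.out = 10) + 500)
  )
  pairs <- coaccessibility_scores(Matrix::Matrix(counts, sparse = TRUE),
                                  peaks, max_dist = 500000)
  key <- paste(pairs$peak_a, pairs$peak_b)
  planted <- pairs$score[key == "chr1:0-500 chr1:10000-10500"]
  expect_gt(planted, 0.5)  # two-variable partial corr ~ Pearson corr
  expect_true(all(planted >= pairs$score))
})

test_that("pairs are emitted once, ordered, and symmetric in value", {
  sim <- get_fixture("coaccess_sim", function() {
    simulate_dataset(sim_config(
      n_cell_types = 1, cells_per_type = 120,
      n_specific_peaks_per_type = 6, se_clusters_per_type = 0,
      n_marker_genes_per_type = 0, n_housekeeping_genes = 6,
      mean_fragments_per_cell = 400, seed = 31
    ))
  })
  links <- coaccess_pipeline(sim$matrix, pipeline_config(), seed = 3)
  expect_true(all(links$start_a <= links$start_b))
  expect_equal(anyDuplicated(paste(links$peak_a, links$peak_b)), 0L)
  expect_true(all(abs(links$score) <= 1))
  expect_true(all(links$distance <= 5e5))
})

test_that("raising the penalty never increases strong-pair count", {
  sim <- get_fixture("coaccess_sim", function() {
    simulate_dataset(sim_config(
      n_cell_types = 1, cells_per_type = 120,
      n_specific_peaks_per_type = 6, se_clusters_per_type = 0,
      n_marker_genes_per_type = 0, n_housekeeping_genes = 6,
      mean_fragments_per_cell = 400, seed = 31
    ))
  })
  tf <- tfidf_transform(sim$matrix)
  coords <- umap_embed(lsi_embed(tf, 20), seed = 3)
  meta <- aggregate_metacells(sim$matrix, coords, k = 12,
                              max_overlap = 0.75, seed = 3)
  n_strong <- vapply(c(0.5, 1, 2, 4), function(sc) {
    p <- coaccessibility_scores(meta, sim$matrix$peaks,
                                penalty_scale = sc)
    sum(abs(p$score) >= 0.1)
  }, numeric(1))
  expect_true(all(diff(n_strong) <= 0))
})

test_that("enhancer-promoter linking follows the cutoff and sidedness", {
  proms <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L,
                          gene_id = "g1", gene_name = "G1", strand = "+")
  mk_pair <- function(sa, sb, score) {
    tibble::tibble(peak_a = paste0("chr1:", sa, "-", sa + 100),
                   peak_b = paste0("chr1:", sb, "-", sb + 100),
                   chrom = "chr1", start_a = sa, end_a = sa + 100L,
                   start_b = sb, end_b = sb + 100L,
                   distance = abs(sb - sa), score = score)
  }
  pairs <- dplyr::bind_rows(
    mk_pair(1100L, 50000L, 0.15),   # promoter <-> enhancer, linked
    mk_pair(1100L, 60000L, 0.05),   # below cutoff
    mk_pair(1100L, 1500L, 0.9),     # both sides in the promoter
    mk_pair(70000L, 80000L, 0.8),   # neither side in a promoter
    mk_pair(90000L, 95000L, 0.09)
  )
  links <- link_enhancer_promoter(pairs, proms, cutoff = 0.1)
  expect_equal(nrow(links), 1L)
  expect_equal(links$enh_start, 50000L)
  expect_equal(links$gene_id, "g1")
})
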