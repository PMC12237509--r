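test_that("tanimoto matches hand-computed values and edge cases", {
  expect_equal(tanimoto(c(1, 2, 0, 1), c(0, 2, 1, 1)), 5 / 7)
  a <- c(3, 0, 2)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 2)), 0)
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_equal(tanimoto(c(1, 2), c(2, 1)), tanimoto(c(2, 1), c(1, 2)))
})

test_that("tanimoto equals Jaccard on binary vectors (property)", {
  set.seed(20)
  for (i in 1:200) {
    a <- rbinom(30, 1, 0.4); b <- rbinom(30, 1, 0.4)
    if (sum(a) + sum(b) == 0) next
    inter <- sum(a & b); uni <- sum(a | b)
    expect_equal(tanimoto(a, b), inter / uni)
  }
})

test_that("tanimoto_matrix equals the brute-force double loop", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(rpois(15 * 8, 0.8), 15, 8)
    tm <- tanimoto_matrix(Matrix::Matrix(x, sparse = TRUE))
    brute <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      brute[i, j] <- suppressWarnings(tanimoto(x[, i], x[, j]))
    }
    expect_equal(unname(tm), brute, tolerance = 1e-12)
  }
  # permutation equivariance
  x <- matrix(rpois(20 * 6, 1), 20, 6)
  p <- sample(6)
  expect_equal(unname(tanimoto_matrix(x[, p])),
               unname(tanimoto_matrix(x)[p, p]))
})

test_that("cell weights follow the ordered-pair normalization", {
  x <- cbind(c(1, 0), c(1, 0), c(0, 1))
  w <- cell_weights(tanimoto_matrix(x))
  expect_equal(unname(w), c(0.5, 0.5, 0))
  expect_equal(sum(w), 1)
  # two identical cells split the weight
  w2 <- cell_weights(tanimoto_matrix(cbind(c(1, 2), c(1, 2))))
  expect_equal(unname(w2), c(0.5, 0.5))
  # disjoint cells: uniform fallback with warning
  expect_warning(w3 <- cell_weights(tanimoto_matrix(diag(3))), "disjoint")
  expect_equal(unname(w3), rep(1 / 3, 3))
  # weights always sum to one
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(rpois(40 * 9, 0.7), 40, 9)
    expect_equal(sum(cell_weights(suppressWarnings(tanimoto_matrix(x)))),
                 1, tolerance = 1e-12)
  }
})

test_that("combined signal is the weighted count sum with invariances", {
  x <- rbind(c(2, 4, 6), c(0, 0, 0))
  w <- c(0.5, 0.5, 0)
  s <- combined_peak_signal(x, w)
  expect_equal(unname(s), c(3, 0))
  # uniform weights give the mean count
  wu <- rep(1 / 3, 3)
  expect_equal(unname(combined_peak_signal(x, wu))[1], mean(c(2, 4, 6)))
  # simultaneous permutation of cells and weights changes nothing
  p <- c(3, 1, 2)
  expect_equal(combined_peak_signal(x[, p], w[p]),
               combined_peak_signal(x, w))
  # monotonicity: raising a count under positive weight never lowers it
  x2 <- x; x2[1, 1] <- x2[1, 1] + 5
  expect_gte(combined_peak_signal(x2, w)[1],
             combined_peak_signal(x, w)[1])
})

test_that("shuffle null is deterministic and zero without fragments", {
  peaks <- genomic_intervals("chr1", c(0, 2000), c(500, 2500))
  genome <- c(chr1 = 100000)
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), barcode = character(),
                          count = integer())
  expect_equal(shuffle_null_threshold(empty, peaks,
                                      c(b1 = 0.5, b2 = 0.5), genome), 0)
  frags <- tibble::tibble(
    chrom = "chr1", start = seq(0, 99000, by = 1000),
    end = seq(0, 99000, by = 1000) + 400,
    barcode = rep(c("b1", "b2"), 50), count = 1L
  )
  t1 <- shuffle_null_threshold(frags, peaks, c(b1 = 0.5, b2 = 0.5),
                               genome, seed = 3)
  t2 <- shuffle_null_threshold(frags, peaks, c(b1 = 0.5, b2 = 0.5),
                               genome, seed = 3)
  expect_identical(t1, t2)
  expect_gt(t1, 0)
})

test_that("under uniform coverage the null matches the real signal", {
  # fragments tile the chromosome at constant per-cell depth, so shuffled
  # peaks see the same coverage as the real ones
  genome <- c(chr1 = 200000)
  frags <- dplyr::bind_rows(lapply(c("b1", "b2", "b3"), function(bc) {
    tibble::tibble(chrom = "chr1", start = seq(0, 199990, by = 10),
                   end = seq(0, 199990, by = 10) + 1,
                   barcode = bc, count = 1L)
  }))
  peaks <- genomic_intervals("chr1", seq(1000, by = 5000, length.out = 10),
                             seq(1000, by = 5000, length.out = 10) + 1000)
  w <- c(b1 = 1, b2 = 1, b3 = 1) / 3
  counts <- matrix(0, 10, 3)
  fr_gr <- scregulon:::intervals_to_granges(frags)
  pk_gr <- scregulon:::intervals_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(pk_gr, fr_gr)
  for (h in seq_along(hits)) {
    i <- S4Vectors::queryHits(hits)[h]
    j <- match(frags$barcode[S4Vectors::subjectHits(hits)[h]],
               c("b1", "b2", "b3"))
    counts[i, j] <- counts[i, j] + 1
  }
  real <- combined_peak_signal(counts, w)
  thr <- shuffle_null_threshold(frags, peaks, w, genome,
                                n_shuffles = 40, seed = 2)
  expect_equal(thr, mean(real), tolerance = 0.05)
})

test_that("four-criteria QC flags behave at their boundaries", {
  # 9 cells; ceiling(9/3) = 3 supporting cells needed for criterion i
  counts <- rbind(
    c(1, 1, 1, 0, 0, 0, 0, 0, 0),   # exactly one third: passes
    c(1, 1, 0, 0, 0, 0, 0, 0, 0),   # below: fails
    c(9, 9, 9, 9, 9, 9, 9, 9, 9)    # strong but sits inside an exon
  )
  peaks <- genomic_intervals("chr1", c(100000, 200000, 305000),
                             c(100500, 200500, 305500))
  pm <- peak_matrix(counts, peaks, paste0("b", 1:9))
  gene <- toy_gene(start = 304000, end = 308000)  # peak 3 in the exon
  w <- rep(1 / 9, 9)
  res <- call_consensus_enhancers(pm, w, gene)
  expect_equal(res$crit_support, c(TRUE, FALSE, TRUE))
  expect_equal(res$crit_annotation, c(TRUE, TRUE, FALSE))
  expect_false(res$is_enhancer[3])  # exonic peak rejected despite signal
  expect_true(res$is_enhancer[1])   # criteria iii/iv skipped when absent
  # with a null threshold, exceeding is strict
  res2 <- call_consensus_enhancers(pm, w, gene,
                                   null_threshold = res$combined_score[1])
  expect_false(res2$crit_null[1])
})

test_that("criterion iv keys on promoter-linked co-accessibility", {
  counts <- matrix(1, 2, 6)
  peaks <- genomic_intervals("chr1", c(100000, 200000),
                             c(100500, 200500))
  pm <- peak_matrix(counts, peaks, paste0("b", 1:6))
  gene <- toy_gene(start = 201000, end = 205000)  # promoter covers peak 2
  links <- tibble::tibble(
    peak_a = "chr1:100000-100500", peak_b = "chr1:200000-200500",
    chrom = "chr1", start_a = 100000L, end_a = 100500L,
    start_b = 200000L, end_b = 200500L, distance = 1e5, score = 0.4
  )
  res <- call_consensus_enhancers(pm, rep(1 / 6, 6), gene,
                                  coaccess_links = links)
  expect_equal(res$max_promoter_coaccess[1], 0.4)
  expect_true(res$crit_coaccess[1])
  # below the 0.1 cutoff the same link no longer qualifies
  links$score <- 0.09
  res2 <- call_consensus_enhancers(pm, rep(1 / 6, 6), gene,
                                   coaccess_links = links)
  expect_false(res2$crit_coaccess[1])
})
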