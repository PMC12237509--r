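test_that("stitching merges by gap with hand-checked arithmetic", {
  cand <- genomic_intervals("chr1", c(100, 10000, 23500),
                            c(600, 10400, 24000))
  st <- stitch(cand, d = 12500)
  # gaps: 9400 (merge), 13100 (split)
  expect_equal(nrow(st), 2L)
  expect_equal(st$start, c(100L, 23500L))
  expect_equal(st$end, c(10400L, 24000L))
  expect_equal(st$n_members, c(2L, 1L))

  # d = 0: only overlapping/abutting intervals merge
  cand0 <- genomic_intervals("chr1", c(0, 100, 300), c(100, 200, 400))
  st0 <- stitch(cand0, d = 0)
  expect_equal(nrow(st0), 2L)
  expect_equal(st0$end[1], 200L)
})

test_that("stitching is idempotent, conservative and disjoint", {
  set.seed(33)
  cand <- genomic_intervals(
    sample(c("chr1", "chr2"), 60, replace = TRUE),
    s <- sample.int(200000, 60), s + sample(100:800, 60, replace = TRUE)
  )
  st <- stitch(cand, d = 3000)
  expect_equal(sum(st$n_members), nrow(cand))  # conservation
  again <- stitch(st[, c("chrom", "start", "end")], d = 3000)
  expect_equal(again[, c("chrom", "start", "end")],
               st[, c("chrom", "start", "end")])
  # spans pairwise disjoint per chromosome
  for (ch in unique(st$chrom)) {
    s_ch <- st[st$chrom == ch, ]
    expect_true(all(s_ch$start[-1] > s_ch$end[-nrow(s_ch)]))
  }
})

test_that("region signal integrates overlapping fragment counts", {
  regions <- genomic_intervals("chr1", c(1000, 5000), c(2000, 6000))
  frags <- tibble::tibble(
    chrom = "chr1",
    start = c(900L, 1500L, 1990L, 3000L, 4900L),
    end = c(1100L, 1600L, 2100L, 3100L, 5100L),
    barcode = c("a", "a", "b", "a", "c"),
    count = c(1L, 2L, 1L, 5L, 4L)
  )
  sig <- region_signal(regions, frags, c("a", "b", "c"))
  expect_equal(sig, c(4, 4))  # region 1: 1+2+1; region 2: 4
  # barcode restriction
  expect_equal(region_signal(regions, frags, "a"), c(3, 0))
  # no overlap -> 0; empty barcode set -> error
  expect_equal(region_signal(genomic_intervals("chr9", 0, 10),
                             frags, "a"), 0)
  expect_error(region_signal(regions, frags, character(0)), "empty")
  # a fragment spanning two abutting regions counts once in each
  reg2 <- genomic_intervals("chr1", c(1000, 2050), c(2000, 3000))
  span <- tibble::tibble(chrom = "chr1", start = 1900L, end = 2200L,
                         barcode = "a", count = 1L)
  expect_equal(region_signal(reg2, span, "a"), c(1, 1))
})

test_that("rank curve finds the slope-one tangent with scaled axes", {
  curve <- rank_and_cutoff(c(1, 2, 3, 5, 20, 90))
  expect_equal(attr(curve, "cutoff_index"), 5L)
  expect_equal(attr(curve, "cutoff_signal"), 20)
  expect_equal(curve$scaled_y - curve$scaled_x,
               c(0, 1 / 89 - 0.2, 2 / 89 - 0.4, 4 / 89 - 0.6,
                 19 / 89 - 0.8, 0),
               tolerance = 1e-12)
  # degenerate flat curve: cutoff at n, nothing classified super
  flat <- rank_and_cutoff(rep(4, 5))
  expect_true(attr(flat, "degenerate"))
  expect_equal(attr(flat, "cutoff_index"), 5L)
  # scale invariance
  c2 <- rank_and_cutoff(c(1, 2, 3, 5, 20, 90) * 37.5)
  expect_equal(attr(c2, "cutoff_index"), 5L)
})

test_that("the cutoff equals the exhaustive tangent oracle", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(5:120, 1)
    s <- sort(rgamma(n, 0.8, 0.1))
    expect_equal(attr(rank_and_cutoff(s), "cutoff_index"),
                 tangent_oracle(s))
  }
})

test_that("classification is strict and retention needs both conditions", {
  regions <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(seq(0, by = 10000, length.out = 6)),
    end = as.integer(seq(0, by = 10000, length.out = 6) + 1000),
    total_signal = c(1, 2, 3, 5, 20, 90)
  )
  curve <- rank_and_cutoff(regions$total_signal)
  calls <- classify_superenhancers(regions, curve)
  expect_equal(sum(calls$is_super), 1L)           # only the 90 region
  expect_false(calls$is_super[regions$total_signal == 20])  # strict
  # all-equal signals: zero supers
  flat <- tibble::tibble(chrom = "chr1", start = c(0L, 5000L),
                         end = c(1000L, 6000L), total_signal = c(7, 7))
  flat_calls <- classify_superenhancers(flat,
                                        rank_and_cutoff(flat$total_signal))
  expect_equal(sum(flat_calls$is_super), 0L)

  # retention: a true SE without typical-enhancer overlap is dropped;
  # a false SE overlapping many typical enhancers stays out
  typ <- genomic_intervals("chr1", c(100, 10100, 20100), c(200, 10200,
                                                           20200))
  kept <- intersect_with_consensus(calls, typ)
  expect_true(all(kept$retained <= kept$is_super))
  far <- calls; far$start <- far$start + 1000000L
  far$end <- far$end + 1000000L
  expect_false(any(intersect_with_consensus(far, typ)$retained))
})
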