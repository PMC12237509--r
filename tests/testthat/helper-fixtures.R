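# Shared fixtures: simulations and derived statistics are expensive, so
# they are computed lazily once per test run and cached across files.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# small peak matrix straight from a dense count matrix; peaks tile chr1
toy_pm <- function(counts, chrom = "chr1", labels = NULL) {
  n <- nrow(counts)
  peaks <- genomic_intervals(rep(chrom, length.out = n),
                             seq(0, by = 1000, length.out = n),
                             seq(500, by = 1000, length.out = n))
  peak_matrix(counts, peaks,
              paste0("bc", seq_len(ncol(counts))), labels = labels)
}

# single-gene models for window tests
toy_gene <- function(chrom = "chr1", start = 5000, end = 8000,
                     strand = "+", gene_id = "g1") {
  tibble::tibble(
    gene_id = gene_id, gene_name = toupper(gene_id), chrom = chrom,
    strand = strand, start = start, end = end,
    tss = if (strand == "+") start else end,
    tes = if (strand == "+") end else start,
    exons = list(tibble::tibble(chrom = chrom, start = start, end = end))
  )
}

# the 2-cell-type recovery conditions: consensus enhancers and
# super-enhancers are scored against the planted truth for one seed
recovery_stats <- function(seed) {
  get_fixture(paste0("recovery_", seed), function() {
    sim <- simulate_dataset(sim_config(n_cell_types = 2, seed = seed))
    by_type <- preprocess_matrix(sim$matrix)
    cfg <- pipeline_config()
    out <- lapply(names(by_type), function(ct) {
      sub <- by_type[[ct]]
      links <- coaccess_pipeline(sub, cfg, seed = seed + 1L)
      w <- cell_weights(tanimoto_matrix(sub))
      thr <- shuffle_null_threshold(sim$fragments, sub$peaks, w,
                                    sim$genome, seed = seed + 2L)
      enh <- call_consensus_enhancers(sub, w, sim$gene_models, thr, links)
      called <- enh$peak_id[enh$is_enhancer]
      tp <- sim$truth$peaks
      spec <- sim$truth$specific_enhancers
      spec_ids <- spec$peak_id[spec$cell_type == ct]
      planted_ids <- tp$peak_id[!is.na(tp$cell_type) &
                                  tp$cell_type == ct &
                                  tp$role %in% c("specific_enhancer",
                                                 "se_member")]
      typical <- enh[enh$is_enhancer, c("chrom", "start", "end")]
      se <- call_superenhancers(sub$peaks, sim$fragments, sub$barcodes,
                                stitch_dist = 12500,
                                typical_enhancers = typical)
      clusters <- sim$truth$se_clusters[
        sim$truth$se_clusters$cell_type == ct, ]
      retained <- se[se$retained, c("chrom", "start", "end")]
      planted_iv <- tp[!is.na(tp$cell_type) & tp$cell_type == ct &
                         tp$role %in% c("specific_enhancer", "se_member"),
                       c("chrom", "start", "end")]
      list(
        recall = mean(spec_ids %in% called),
        precision = if (length(called)) mean(called %in% planted_ids)
                    else NA_real_,
        se_recovered = interval_overlap_count(clusters, retained)$k_query,
        se_total = nrow(clusters),
        bg_retained = nrow(retained) -
          interval_overlap_count(retained, planted_iv)$k_query
      )
    })
    names(out) <- names(by_type)
    out
  })
}

# marker recovery at the default three-type conditions for one seed
marker_stats <- function(seed) {
  get_fixture(paste0("markers_", seed), function() {
    sim <- simulate_dataset(sim_config(seed = seed))
    act <- gene_activity(sim$matrix, sim$gene_models)
    mk <- find_markers(normalize_activity(act), sim$matrix$labels)
    truth <- sim$truth$markers
    hit <- merge(mk, truth, by.x = c("gene", "cell_type"),
                 by.y = c("gene_id", "cell_type"))
    cross <- merge(mk, truth, by.x = "gene", by.y = "gene_id")
    list(
      recall = nrow(hit) / nrow(truth),
      cross_type_fp = sum(cross$cell_type.x != cross$cell_type.y),
      min_pct_reported = if (nrow(mk)) min(mk$pct_in) else NA_real_
    )
  })
}

# exhaustive slope-1 tangent oracle: an anchor is feasible when every
# curve point lies on or above the slope-1 line through it; ties break to
# the largest index
tangent_oracle <- function(signals) {
  n <- length(signals)
  s <- sort(signals)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  feasible <- vapply(seq_len(n), function(a) {
    all(y >= y[a] + (x - x[a]) - 1e-12)
  }, logical(1))
  max(which(feasible))
}

# log-space hypergeometric tail by direct binomial-coefficient summation
hyper_tail_oracle <- function(N, K, n, k) {
  js <- seq(k, min(n, K))
  js <- js[(n - js) <= (N - K)]
  if (length(js) == 0L) return(0)
  lp <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
  m <- max(lp)
  exp(m) * sum(exp(lp - m))
}
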