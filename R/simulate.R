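#' Simulation configuration
#'
#' Describes a synthetic scATAC-seq experiment with planted structure at
#' every level the pipeline looks for: cell-type-specific accessible peaks
#' co-varying with a target-gene promoter, clustered high-signal peak
#' groups (planted super-enhancers) whose members burst independently while
#' their promoter integrates the cluster state, promoter/gene-body peaks
#' open in all types, marker genes with elevated accessibility in one type,
#' and per-cell depth variation (gamma depth factor mixing the Poisson
#' counts into overdispersed, negative-binomial-like integers).
#'
#' Every cell type owns `n_marker_genes_per_type` marker genes,
#' `n_specific_peaks_per_type` target genes (each paired with one planted
#' intergenic enhancer through a shared per-cell on/off state), and
#' `se_clusters_per_type` super-enhancer clusters parked near a dedicated
#' target gene. Genes are laid out in well-separated blocks alternating
#' across chromosomes; peaks never overlap and keep >= 200 bp gaps except
#' inside SE clusters, whose intra-cluster spacing must stay below the
#' stitch distance.
#'
#' @param n_cell_types,cells_per_type Population structure.
#' @param genome Named vector chrom -> length (bp); `NULL` auto-sizes two
#'   chromosomes to fit the layout.
#' @param n_specific_peaks_per_type Planted type-specific enhancers per
#'   type (one per target gene).
#' @param se_clusters_per_type,se_peaks_per_cluster,se_cluster_spacing
#'   Planted super-enhancer clusters: count per type, member peaks per
#'   cluster, and the gap (bp) between consecutive members (must be below
#'   `stitch_distance`).
#' @param signal_multiplier Fold elevation of planted peaks over the
#'   baseline open-peak mean in the owning type.
#' @param n_marker_genes_per_type Marker genes per type (all their peaks
#'   elevated `signal_multiplier`-fold in the owning type).
#' @param n_housekeeping_genes Type-independent genes whose promoter and
#'   body peaks are open at the baseline rate in every cell type; they
#'   keep per-cell peak complexity realistic regardless of how many cell
#'   types are simulated.
#' @param n_body_peaks_per_gene Gene-body peaks per gene; together with the
#'   promoter peak these are the shared peaks open in all types.
#' @param mean_fragments_per_cell Expected sequenced fragments per cell.
#' @param background_fraction Fraction of fragments falling outside peaks.
#' @param enhancer_on_prob Per-cell probability that a planted
#'   enhancer/promoter pair (or SE member) is in its "on" state.
#' @param noise_rate Expected fragment count a closed (wrong-type) peak
#'   still receives per cell; 0 makes closed peaks exactly silent.
#' @param depth_shape Gamma shape (= rate) of the per-cell depth factor;
#'   mean 1, variance `1/depth_shape`.
#' @param peak_width,gene_length Element sizes in bp.
#' @param stitch_distance Stitch distance the planted clusters are designed
#'   against (used only for validation here).
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return A `sim_config` list.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_cell_types = 3L,
                       cells_per_type = 150L,
                       genome = NULL,
                       n_specific_peaks_per_type = 30L,
                       se_clusters_per_type = 2L,
                       se_peaks_per_cluster = 8L,
                       se_cluster_spacing = 1000L,
                       signal_multiplier = 8,
                       n_marker_genes_per_type = 5L,
                       n_housekeeping_genes = 40L,
                       n_body_peaks_per_gene = 2L,
                       mean_fragments_per_cell = 1500,
                       background_fraction = 0.2,
                       enhancer_on_prob = 0.5,
                       noise_rate = 0.01,
                       depth_shape = 10,
                       peak_width = 500L,
                       gene_length = 20000L,
                       stitch_distance = 12500L,
                       seed = 1L) {
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    cells_per_type = as.integer(cells_per_type),
    genome = genome,
    n_specific_peaks_per_type = as.integer(n_specific_peaks_per_type),
    se_clusters_per_type = as.integer(se_clusters_per_type),
    se_peaks_per_cluster = as.integer(se_peaks_per_cluster),
    se_cluster_spacing = as.integer(se_cluster_spacing),
    signal_multiplier = signal_multiplier,
    n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
    n_housekeeping_genes = as.integer(n_housekeeping_genes),
    n_body_peaks_per_gene = as.integer(n_body_peaks_per_gene),
    mean_fragments_per_cell = mean_fragments_per_cell,
    background_fraction = background_fraction,
    enhancer_on_prob = enhancer_on_prob,
    noise_rate = noise_rate,
    depth_shape = depth_shape,
    peak_width = as.integer(peak_width),
    gene_length = as.integer(gene_length),
    stitch_distance = as.integer(stitch_distance),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_cell_types >= 1L, cfg$cells_per_type >= 1L,
    cfg$n_specific_peaks_per_type >= 0L, cfg$se_clusters_per_type >= 0L,
    cfg$se_peaks_per_cluster >= 2L, cfg$signal_multiplier > 0,
    cfg$mean_fragments_per_cell > 0,
    cfg$background_fraction >= 0, cfg$background_fraction < 1,
    cfg$enhancer_on_prob > 0, cfg$enhancer_on_prob <= 1,
    cfg$noise_rate >= 0, cfg$noise_rate < 1,
    cfg$peak_width >= 100L
  )
  if (cfg$se_cluster_spacing >= cfg$stitch_distance) {
    stop("se_cluster_spacing must be below the stitch distance (",
         cfg$stitch_distance, " bp) or planted clusters cannot stitch",
         call. = FALSE)
  }
  cfg$genes_per_type <- cfg$n_marker_genes_per_type +
    cfg$n_specific_peaks_per_type + cfg$se_clusters_per_type
  cfg$n_genes <- cfg$n_cell_types * cfg$genes_per_type +
    cfg$n_housekeeping_genes
  cfg$n_shared_peaks <- cfg$n_genes * (1L + cfg$n_body_peaks_per_gene)
  structure(cfg, class = "sim_config")
}

# deterministic genome layout: gene blocks alternate across chromosomes
sim_layout <- function(cfg) {
  n_chrom <- if (is.null(cfg$genome)) 2L else length(cfg$genome)
  chrom_names <- if (is.null(cfg$genome)) {
    c("chr1", "chr2")[seq_len(n_chrom)]
  } else names(cfg$genome)
  cursor <- stats::setNames(rep(0, n_chrom), chrom_names)
  pw <- cfg$peak_width
  types <- paste0("type", LETTERS[seq_len(cfg$n_cell_types)])

  genes <- list(); peaks <- list(); gi <- 0L
  plan <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(seq_len(cfg$n_cell_types), function(t) {
      tibble::tibble(
        type = types[t],
        role = c(rep("marker", cfg$n_marker_genes_per_type),
                 rep("target", cfg$n_specific_peaks_per_type),
                 rep("se_target", cfg$se_clusters_per_type))
      )
    })),
    tibble::tibble(type = NA_character_,
                   role = rep("housekeeping", cfg$n_housekeeping_genes))
  )
  for (pi in seq_len(nrow(plan))) {
    t_name <- plan$type[pi]
    r <- plan$role[pi]
    {
      gi <- gi + 1L
      chrom <- chrom_names[((gi - 1L) %% n_chrom) + 1L]
      gap <- 60000 + floor(runif(1) * 40000)
      b0 <- cursor[[chrom]] + gap
      strand <- if (gi %% 2L == 1L) "+" else "-"
      gstart <- b0 + 3000
      gend <- gstart + cfg$gene_length
      tss <- if (strand == "+") gstart else gend
      gene_id <- sprintf("gene%03d", gi)
      genes[[gi]] <- tibble::tibble(
        gene_id = gene_id, gene_name = toupper(gene_id), chrom = chrom,
        strand = strand, start = gstart, end = gend, tss = tss,
        tes = if (strand == "+") gend else gstart,
        cell_type = t_name, role = r
      )
      prom <- if (strand == "+") c(tss - 600, tss - 200)
              else c(tss + 200, tss + 600)
      pk <- list(tibble::tibble(
        chrom = chrom, start = prom[1], end = prom[2],
        role = "promoter", cell_type = t_name, gene_id = gene_id
      ))
      body_at <- gstart + round(
        seq_len(cfg$n_body_peaks_per_gene) * cfg$gene_length /
          (cfg$n_body_peaks_per_gene + 1L)
      )
      pk <- c(pk, list(tibble::tibble(
        chrom = chrom, start = body_at, end = body_at + pw,
        role = "gene_body", cell_type = t_name, gene_id = gene_id
      )))
      block_end <- gend + 700  # room for the - strand promoter peak
      if (r == "target") {
        es <- gend + 20000 + floor(runif(1) * 4000)
        pk <- c(pk, list(tibble::tibble(
          chrom = chrom, start = es, end = es + pw,
          role = "specific_enhancer", cell_type = t_name,
          gene_id = gene_id
        )))
        block_end <- es + pw
      } else if (r == "se_target") {
        cs <- gend + 15000
        starts <- cs + (seq_len(cfg$se_peaks_per_cluster) - 1L) *
          (pw + cfg$se_cluster_spacing)
        pk <- c(pk, list(tibble::tibble(
          chrom = chrom, start = starts, end = starts + pw,
          role = "se_member", cell_type = t_name, gene_id = gene_id
        )))
        block_end <- max(starts) + pw
      }
      peaks[[gi]] <- dplyr::bind_rows(pk)
      cursor[[chrom]] <- block_end
    }
  }
  genes <- dplyr::bind_rows(genes)
  peaks <- dplyr::bind_rows(peaks)
  genome <- cfg$genome
  if (is.null(genome)) {
    genome <- ceiling((cursor + 200000) / 1e5) * 1e5
  } else {
    over <- cursor > unlist(genome)[names(cursor)]
    if (any(over)) {
      stop("genome too small to place the requested elements on ",
           paste(names(cursor)[over], collapse = ", "),
           " (need ", max(cursor[over]), " bp)", call. = FALSE)
    }
  }
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  peaks$peak_id <- peak_id_string(peaks)
  # independent "state groups": a target gene's promoter+enhancer share one
  # burst state; SE members burst independently, the promoter integrates
  list(genes = genes, peaks = peaks, genome = genome, types = types)
}

#' Simulate a full scATAC-seq dataset with planted ground truth
#'
#' Draws a peak-by-cell count matrix, the matching fragment file, cell-type
#' labels, gene models and truth tables from a [sim_config()]. Counts are
#' Poisson draws whose rates mix a per-cell gamma depth factor with
#' peak-role means (overdispersed marginals); every in-peak count unit
#' becomes one fragment record, and background fragments are placed
#' strictly outside peaks so the fragment-file total equals the matrix
#' total plus the reported background count.
#'
#' @param config A [sim_config()].
#' @return A `scregulon_sim` list: `config`, `fragments` (tibble),
#'   `matrix` ([peak_matrix()] with labels), `gene_models`, `truth` (list
#'   of tibbles: `peaks`, `specific_enhancers`, `se_clusters`,
#'   `se_members`, `markers`, `coaccess_pairs`), `genome`, and `marginal`
#'   (fragment bookkeeping).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  lay <- sim_layout(cfg)
  peaks <- lay$peaks
  genes <- lay$genes
  types <- lay$types
  n_peaks <- nrow(peaks)
  pw_vec <- peaks$end - peaks$start

  # expected relative weight of each peak in its owning type, for depth
  # calibration
  mult <- cfg$signal_multiplier
  e_state <- 0.2 + mult  # E[0.2 + (mult/p_on) * Bernoulli(p_on)]
  role_weight <- function(role, owned) {
    w <- rep(1, length(role))
    w[role %in% c("specific_enhancer", "se_member") & !owned] <- 0
    w[role %in% c("specific_enhancer", "se_member") & owned] <- e_state
    w
  }

  barcodes <- character(0); labels <- character(0)
  count_blocks <- list(); depth_all <- numeric(0)
  states_env <- list()
  mu0_by_type <- numeric(length(types))

  for (ti in seq_along(types)) {
    ct <- types[ti]
    m <- cfg$cells_per_type
    bc <- sprintf("%s_bc%04d", ct, seq_len(m))
    depth <- rgamma(m, shape = cfg$depth_shape, rate = cfg$depth_shape)

    owned <- !is.na(genes$cell_type) & genes$cell_type == ct
    marker_gene <- genes$gene_id[owned & genes$role == "marker"]
    target_gene <- genes$gene_id[owned & genes$role == "target"]
    se_gene <- genes$gene_id[owned & genes$role == "se_target"]

    # expected weight sum for this type (depth calibration)
    w_exp <- rep(1, n_peaks)
    shared <- peaks$role %in% c("promoter", "gene_body")
    w_exp[shared & peaks$gene_id %in% marker_gene] <- mult
    w_exp[peaks$role == "promoter" &
            peaks$gene_id %in% c(target_gene, se_gene)] <- e_state
    planted <- peaks$role %in% c("specific_enhancer", "se_member")
    w_exp[planted] <- ifelse(peaks$cell_type[planted] == ct, e_state, 0)
    mu0 <- cfg$mean_fragments_per_cell * (1 - cfg$background_fraction) /
      sum(w_exp)
    mu0_by_type[ti] <- mu0

    # per-cell rate matrix (peaks x cells), in count units
    A <- matrix(mu0, n_peaks, m)
    A[shared & peaks$gene_id %in% marker_gene, ] <- mu0 * mult
    A[planted & peaks$cell_type != ct, ] <- cfg$noise_rate

    p_on <- cfg$enhancer_on_prob
    boost <- mult / p_on
    # target genes: promoter and enhancer share one on/off state per cell
    for (g in target_gene) {
      s <- rbinom(m, 1L, p_on)
      rows <- which(peaks$gene_id == g &
                      peaks$role %in% c("promoter", "specific_enhancer"))
      A[rows, ] <- rep(mu0 * (0.2 + boost * s), each = length(rows))
    }
    # SE clusters: members burst independently; promoter integrates
    for (g in se_gene) {
      mem <- which(peaks$gene_id == g & peaks$role == "se_member")
      s_mem <- matrix(rbinom(length(mem) * m, 1L, p_on),
                      nrow = length(mem))
      A[mem, ] <- mu0 * (0.2 + boost * s_mem)
      prow <- which(peaks$gene_id == g & peaks$role == "promoter")
      A[prow, ] <- mu0 * (0.2 + boost * colMeans(s_mem))
    }
    lam <- sweep(A, 2L, depth, `*`)
    cnt <- matrix(rpois(length(lam), lam), n_peaks, m)
    count_blocks[[ti]] <- cnt
    barcodes <- c(barcodes, bc)
    labels <- c(labels, stats::setNames(rep(ct, m), bc))
    depth_all <- c(depth_all, depth)
  }

  counts <- do.call(cbind, count_blocks)
  colnames(counts) <- barcodes

  # generation-time sanity: planted SE member means exceed the multiplied
  # baseline mean in the owning type (within 3 standard errors)
  for (ti in seq_along(types)) {
    ct <- types[ti]
    blk <- count_blocks[[ti]]
    se_rows <- which(peaks$role == "se_member" & peaks$cell_type == ct)
    base_rows <- which(peaks$role == "gene_body" &
                         !peaks$gene_id %in%
                           genes$gene_id[!is.na(genes$cell_type) &
                                           genes$cell_type == ct &
                                           genes$role == "marker"])
    if (length(se_rows) && length(base_rows)) {
      se_vals <- as.numeric(blk[se_rows, ])
      base_vals <- as.numeric(blk[base_rows, ])
      se_comb <- sqrt(sd(se_vals)^2 / length(se_vals) +
                        (mult * sd(base_vals))^2 / length(base_vals))
      if (mean(se_vals) < mult * mean(base_vals) - 3 * se_comb) {
        stop("simulated SE cluster signal fell below the configured ",
             "multiplier over baseline; check config", call. = FALSE)
      }
    }
  }

  pm <- peak_matrix(counts,
                    peaks[, c("chrom", "start", "end")],
                    barcodes, labels = labels)

  # fragments: one record per in-peak count unit, plus background placed
  # strictly outside peaks
  frag_in <- expand_fragments(counts, peaks, pw_vec)
  frag_bg <- background_fragments(cfg, lay, depth_all, barcodes)
  fragments <- dplyr::bind_rows(frag_in, frag_bg)
  fragments <- fragments[order(fragments$chrom, fragments$start,
                               fragments$end, fragments$barcode), ]

  gene_models <- genes[, c("gene_id", "gene_name", "chrom", "strand",
                           "start", "end", "tss", "tes")]
  gene_models$exons <- lapply(seq_len(nrow(genes)), function(i) {
    tibble::tibble(chrom = genes$chrom[i], start = genes$start[i],
                   end = genes$end[i])
  })

  truth <- build_truth(peaks, genes)
  structure(list(
    config = cfg,
    fragments = fragments,
    matrix = pm,
    gene_models = gene_models,
    truth = truth,
    genome = lay$genome,
    marginal = list(
      total_fragments = nrow(fragments),
      in_peak_fragments = nrow(frag_in),
      background_fragments = nrow(frag_bg),
      matrix_total = sum(counts)
    )
  ), class = "scregulon_sim")
}

expand_fragments <- function(counts, peaks, pw_vec) {
  nz <- which(counts > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), barcode = character(),
                          count = integer()))
  }
  reps <- counts[nz]
  pk <- rep(nz[, 1L], reps)
  cell <- rep(nz[, 2L], reps)
  n <- length(pk)
  wmax <- pmin(500L, pw_vec[pk])
  w <- 50L + floor(runif(n) * (wmax - 50L + 1L))
  s <- peaks$start[pk] + floor(runif(n) * (pw_vec[pk] - w + 1L))
  tibble::tibble(chrom = peaks$chrom[pk], start = as.integer(s),
                 end = as.integer(s + w),
                 barcode = colnames(counts)[cell], count = 1L)
}

background_fragments <- function(cfg, lay, depth_all, barcodes) {
  nbg <- rpois(length(barcodes),
               depth_all * cfg$mean_fragments_per_cell *
                 cfg$background_fraction)
  total <- sum(nbg)
  if (total == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), barcode = character(),
                          count = integer()))
  }
  # complement of the peak set, per chromosome (out to the genome ends)
  glen <- lay$genome
  pk_gr <- intervals_to_granges(lay$peaks[, c("chrom", "start", "end")])
  GenomeInfoDb::seqlengths(pk_gr) <-
    glen[GenomeInfoDb::seqlevels(pk_gr)]
  gaps_gr <- GenomicRanges::gaps(GenomicRanges::reduce(
    pk_gr, ignore.strand = TRUE
  ))
  gaps_gr <- gaps_gr[GenomicRanges::strand(gaps_gr) == "*"]
  gaps <- granges_to_intervals(gaps_gr)
  gaps <- gaps[gaps$end - gaps$start >= 100, ]
  gw <- gaps$end - gaps$start
  gidx <- sample.int(nrow(gaps), total, replace = TRUE, prob = gw)
  w <- pmin(50L + floor(runif(total) * 451), gw[gidx])
  s <- gaps$start[gidx] + floor(runif(total) * (gw[gidx] - w + 1L))
  tibble::tibble(chrom = gaps$chrom[gidx], start = as.integer(s),
                 end = as.integer(s + w),
                 barcode = rep(barcodes, nbg), count = 1L)
}

build_truth <- function(peaks, genes) {
  spec <- peaks[peaks$role == "specific_enhancer", ]
  se <- peaks[peaks$role == "se_member", ]
  if (nrow(se)) {
    se_cl <- dplyr::summarise(
      dplyr::group_by(se, .data$gene_id, .data$cell_type, .data$chrom),
      start = min(.data$start), end = max(.data$end),
      n_peaks = dplyr::n(), .groups = "drop"
    )
    se_cl$cluster_id <- paste0("cluster_", se_cl$gene_id)
  } else {
    se_cl <- tibble::tibble(gene_id = character(), cell_type = character(),
                            chrom = character(), start = integer(),
                            end = integer(), n_peaks = integer(),
                            cluster_id = character())
  }
  prom <- peaks[peaks$role == "promoter", ]
  prom_of <- stats::setNames(seq_len(nrow(prom)), prom$gene_id)
  pair_rows <- spec
  pairs <- tibble::tibble(
    peak_a = pair_rows$peak_id,
    peak_b = prom$peak_id[prom_of[pair_rows$gene_id]],
    chrom = pair_rows$chrom,
    cell_type = pair_rows$cell_type,
    gene_id = pair_rows$gene_id,
    distance = abs((pair_rows$start + pair_rows$end) / 2 -
                     (prom$start[prom_of[pair_rows$gene_id]] +
                        prom$end[prom_of[pair_rows$gene_id]]) / 2)
  )
  list(
    peaks = peaks,
    specific_enhancers = spec[, c("chrom", "start", "end", "peak_id",
                                  "cell_type", "gene_id")],
    se_clusters = se_cl[, c("cluster_id", "cell_type", "chrom", "start",
                            "end", "n_peaks", "gene_id")],
    se_members = se[, c("chrom", "start", "end", "peak_id", "cell_type",
                        "gene_id")],
    markers = genes[genes$role == "marker",
                    c("gene_id", "gene_name", "cell_type")],
    coaccess_pairs = pairs
  )
}

#' Write a simulated dataset to disk
#'
#' Emits `fragments.tsv.gz`, the MTX triplet plus `labels.tsv` (under
#' `matrix/`), `genes.gtf`, `genome.tsv` and `truth_*.tsv` tables.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
sim_write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fragments(sim$fragments, file.path(dir, "fragments.tsv.gz"))
  write_peak_matrix(sim$matrix, file.path(dir, "matrix"))
  write_gtf(sim$gene_models, file.path(dir, "genes.gtf"))
  readr::write_tsv(tibble::tibble(chrom = names(sim$genome),
                                  length = unname(sim$genome)),
                   file.path(dir, "genome.tsv"), progress = FALSE)
  for (nm in c("specific_enhancers", "se_clusters", "se_members",
               "markers", "coaccess_pairs")) {
    readr::write_tsv(sim$truth[[nm]],
                     file.path(dir, paste0("truth_", nm, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' @export
#' @method print scregulon_sim
print.scregulon_sim <- function(x, ...) {
  cat("<scregulon_sim> ", nrow(x$matrix$peaks), " peaks x ",
      ncol(x$matrix$counts), " cells (",
      x$config$n_cell_types, " cell types), ",
      nrow(x$fragments), " fragments\n", sep = "")
  invisible(x)
}
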