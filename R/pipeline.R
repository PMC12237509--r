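#' Pipeline configuration with the published defaults
#'
#' Collects every tunable of the end-to-end pipeline with its default:
#' QC minima (cells with < 200 nonzero peaks removed, peaks in < 10 cells
#' removed, cell types with < 100 cells dropped), the one-third support
#' fraction and 0.1 co-accessibility cutoff of the four-criteria enhancer
#' QC, the 500 kb co-accessibility distance bound, species stitch
#' distances (12.5 kb human/mouse, 2 kb fly), the 2 kb promoter distance,
#' and the marker thresholds (adjusted p < 1e-5, min fraction 0.3,
#' log2 fold change 0.585).
#'
#' @param species Stitch-distance preset; overridden by `stitch_dist`.
#' @param stitch_dist,max_dist,promoter_upstream,promoter_downstream
#'   Distances in bp.
#' @param min_peaks,min_cells_per_peak,min_cells_per_type QC minima.
#' @param support_fraction,coaccess_cutoff,n_shuffles,shuffle_percentile
#'   Consensus-enhancer QC parameters.
#' @param penalty_scale,metacell_k,metacell_max_overlap,lsi_components,
#'   embedding Co-accessibility parameters; `metacell_k = NULL` picks
#'   `min(50, max(10, floor(m / 10)))` so covariance estimation keeps a
#'   usable number of metacells at small cell counts.
#' @param min_pct,min_log2fc,alpha_adj Marker thresholds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(species = c("human", "mouse", "fly"),
                            stitch_dist = NULL,
                            max_dist = 500000,
                            promoter_upstream = 2000L,
                            promoter_downstream = 100L,
                            min_peaks = 200L,
                            min_cells_per_peak = 10L,
                            min_cells_per_type = 100L,
                            support_fraction = 1 / 3,
                            coaccess_cutoff = 0.1,
                            n_shuffles = 20L,
                            shuffle_percentile = 95,
                            penalty_scale = 1,
                            metacell_k = NULL,
                            metacell_max_overlap = 0.75,
                            lsi_components = 50L,
                            embedding = c("umap", "lsi"),
                            min_pct = 0.3,
                            min_log2fc = 0.585,
                            alpha_adj = 1e-5) {
  species <- match.arg(species)
  structure(list(
    species = species,
    stitch_dist = stitch_dist %||% stitch_distance_preset(species),
    max_dist = max_dist,
    promoter_upstream = promoter_upstream,
    promoter_downstream = promoter_downstream,
    min_peaks = min_peaks,
    min_cells_per_peak = min_cells_per_peak,
    min_cells_per_type = min_cells_per_type,
    support_fraction = support_fraction,
    coaccess_cutoff = coaccess_cutoff,
    n_shuffles = n_shuffles,
    shuffle_percentile = shuffle_percentile,
    penalty_scale = penalty_scale,
    metacell_k = metacell_k,
    metacell_max_overlap = metacell_max_overlap,
    lsi_components = lsi_components,
    embedding = match.arg(embedding),
    min_pct = min_pct,
    min_log2fc = min_log2fc,
    alpha_adj = alpha_adj
  ), class = "pipeline_config")
}

#' Co-accessibility links for one cell-type sub-matrix
#'
#' Convenience wrapper chaining [tfidf_transform()], [lsi_embed()],
#' [umap_embed()], [aggregate_metacells()] and
#' [coaccessibility_scores()].
#'
#' @param pm Cell-type [peak_matrix()] (all-zero peaks/cells removed).
#' @param config A [pipeline_config()].
#' @param seed RNG seed for the embedding and metacell sampling.
#' @return Pair tibble from [coaccessibility_scores()].
#' @export
coaccess_pipeline <- function(pm, config = pipeline_config(), seed = 1L) {
  tf <- tfidf_transform(pm)
  n_comp <- min(config$lsi_components, min(dim(tf)) - 1L)
  emb <- lsi_embed(tf, n_components = n_comp, seed = seed)
  coords <- umap_embed(emb, seed = seed, method = config$embedding)
  m <- ncol(pm$counts)
  k <- config$metacell_k %||% min(50L, max(10L, floor(m / 10)))
  meta <- aggregate_metacells(pm, coords, k = k,
                              max_overlap = config$metacell_max_overlap,
                              seed = seed)
  coaccessibility_scores(meta, pm$peaks, max_dist = config$max_dist,
                         penalty_scale = config$penalty_scale)
}

#' Run the full pipeline on a dataset directory
#'
#' Expects the layout written by [sim_write_dataset()]: a `matrix/` MTX
#' triplet with `labels.tsv`, `genes.gtf`, optionally
#' `fragments.tsv.gz` and `genome.tsv`. Executes preprocessing, per-type
#' co-accessibility, consensus enhancer calling, super-enhancer calling
#' (when fragments are available; otherwise downgraded with a warning),
#' gene markers (when >= 3 cell types survive), and writes per-stage TSV
#' tables plus a `manifest.json` capturing parameters and derived seeds.
#' Outputs are byte-identical across runs with the same inputs and seed.
#'
#' @param input_dir Dataset directory.
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Invisibly, a list with the per-type result tibbles and the
#'   manifest.
#' @export
run_all <- function(input_dir, out_dir, config = pipeline_config(),
                    seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat_dir <- file.path(input_dir, "matrix")
  labels_path <- file.path(mat_dir, "labels.tsv")
  if (!file.exists(labels_path)) {
    stop("labels.tsv not found under ", mat_dir, call. = FALSE)
  }
  labels <- read_labels(labels_path)
  pm <- read_peak_matrix(file.path(mat_dir, "matrix.mtx"),
                         file.path(mat_dir, "peaks.bed"),
                         file.path(mat_dir, "barcodes.tsv"),
                         labels = labels)
  missing <- setdiff(pm$barcodes, names(labels))
  if (length(missing)) {
    stop("barcode(s) present in the matrix but missing from labels: ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) " ...", call. = FALSE)
  }
  genes <- read_gene_models(file.path(input_dir, "genes.gtf"))

  frag_path <- file.path(input_dir, "fragments.tsv.gz")
  if (!file.exists(frag_path)) {
    frag_path <- file.path(input_dir, "fragments.tsv")
  }
  fragments <- NULL
  if (file.exists(frag_path)) {
    fragments <- read_fragments(frag_path)
  } else {
    warning("no fragment file found: super-enhancer calling and the ",
            "shuffle-null criterion are skipped", call. = FALSE)
  }
  genome_path <- file.path(input_dir, "genome.tsv")
  genome <- if (file.exists(genome_path)) {
    g <- readr::read_tsv(genome_path, col_types = "cd", progress = FALSE)
    stats::setNames(g[[2]], g[[1]])
  } else if (!is.null(fragments)) {
    warning("genome.tsv missing; chromosome sizes estimated from the ",
            "data", call. = FALSE)
    ends <- tapply(c(fragments$end, pm$peaks$end),
                   c(fragments$chrom, pm$peaks$chrom), max)
    stats::setNames(as.numeric(ends) + 1e5, names(ends))
  } else NULL

  by_type <- preprocess_matrix(
    pm, min_peaks = config$min_peaks,
    min_cells = config$min_cells_per_peak,
    min_cells_per_type = config$min_cells_per_type
  )
  qc <- dplyr::bind_rows(lapply(names(by_type), function(ct) {
    dplyr::mutate(qc_report(by_type[[ct]]), cell_type = ct)
  }))
  readr::write_tsv(qc, file.path(out_dir, "qc_report.tsv"),
                   progress = FALSE)

  proms <- promoter_windows(genes, config$promoter_upstream,
                            config$promoter_downstream)
  enh_tables <- list(); se_tables <- list(); link_tables <- list()
  stage_seeds <- list()
  for (ti in seq_along(by_type)) {
    ct <- names(by_type)[ti]
    sub <- by_type[[ti]]
    seed_co <- derive_seed(seed + ti, "coaccess")
    seed_sh <- derive_seed(seed + ti, "shuffle")
    stage_seeds[[ct]] <- c(coaccess = seed_co, shuffle = seed_sh)

    links <- coaccess_pipeline(sub, config, seed = seed_co)
    link_tables[[ct]] <- dplyr::mutate(
      link_enhancer_promoter(links, proms, config$coaccess_cutoff),
      cell_type = ct)

    tm <- tanimoto_matrix(sub)
    w <- cell_weights(tm)
    null_thr <- NA_real_
    if (!is.null(fragments) && !is.null(genome)) {
      null_thr <- shuffle_null_threshold(
        fragments, sub$peaks, w, genome,
        n_shuffles = config$n_shuffles,
        percentile = config$shuffle_percentile, seed = seed_sh
      )
    }
    enh <- call_consensus_enhancers(
      sub, w, genes, null_threshold = null_thr, coaccess_links = links,
      support_fraction = config$support_fraction,
      coaccess_cutoff = config$coaccess_cutoff,
      promoter_upstream = config$promoter_upstream,
      promoter_downstream = config$promoter_downstream
    )
    enh_tables[[ct]] <- dplyr::mutate(enh, cell_type = ct)

    if (!is.null(fragments)) {
      typical <- enh[enh$is_enhancer, c("chrom", "start", "end")]
      se <- call_superenhancers(
        sub$peaks, fragments, sub$barcodes,
        stitch_dist = config$stitch_dist, typical_enhancers = typical
      )
      se$members <- NULL
      se_tables[[ct]] <- dplyr::mutate(se, cell_type = ct)
    }
  }
  readr::write_tsv(dplyr::bind_rows(enh_tables),
                   file.path(out_dir, "enhancers.tsv"), progress = FALSE)
  readr::write_tsv(dplyr::bind_rows(link_tables),
                   file.path(out_dir, "links.tsv"), progress = FALSE)
  if (length(se_tables)) {
    readr::write_tsv(dplyr::bind_rows(se_tables),
                     file.path(out_dir, "superenhancers.tsv"),
                     progress = FALSE)
  }

  markers <- NULL
  if (length(by_type) >= 3L) {
    # markers are detected on the full filtered matrix across types
    pm_f <- filter_cells_min_peaks(pm, config$min_peaks)
    pm_f <- filter_peaks(pm_f, config$min_cells_per_peak)
    keep <- pm_f$barcodes %in%
      unlist(lapply(by_type, function(s) s$barcodes))
    pm_f <- subset_peak_matrix(pm_f, cells = which(keep))
    act <- gene_activity(pm_f, genes,
                         upstream_d = config$promoter_upstream)
    markers <- find_markers(
      normalize_activity(act), pm_f$labels[pm_f$barcodes],
      min_pct = config$min_pct, min_log2fc = config$min_log2fc,
      alpha_adj = config$alpha_adj
    )
    readr::write_tsv(markers, file.path(out_dir, "markers.tsv"),
                     progress = FALSE)
  } else {
    warning("fewer than three cell types survive preprocessing; ",
            "marker detection skipped", call. = FALSE)
  }

  manifest <- list(
    package = "scregulon",
    version = as.character(utils::packageVersion("scregulon")),
    seed = seed,
    stage_seeds = stage_seeds,
    parameters = unclass(config),
    cell_types = names(by_type),
    n_enhancers = sum(dplyr::bind_rows(enh_tables)$is_enhancer),
    n_links = nrow(dplyr::bind_rows(link_tables)),
    n_retained_superenhancers = if (length(se_tables)) {
      sum(dplyr::bind_rows(se_tables)$retained)
    } else NA,
    n_markers = if (is.null(markers)) NA else nrow(markers)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(enhancers = dplyr::bind_rows(enh_tables),
                 links = dplyr::bind_rows(link_tables),
                 superenhancers = if (length(se_tables)) {
                   dplyr::bind_rows(se_tables)
                 } else NULL,
                 markers = markers, qc = qc, manifest = manifest))
}
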