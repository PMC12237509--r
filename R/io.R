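#' Read a 10x-style fragment file
#'
#' Parses a tab-separated fragment file (plain or gzipped) with columns
#' chrom, start, end, barcode and an optional count column (defaulting to 1
#' when absent, the common dialect difference between fragment files).
#' Coordinates are taken as given, 0-based half-open; comment lines starting
#' with `#` are skipped. Files need not be coordinate-sorted; operations
#' that count fragments in regions sort internally.
#'
#' @param path Path to a `.tsv` or `.tsv.gz` fragment file.
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`,
#'   `count`, in file order.
#' @seealso [write_fragments()]
#' @export
read_fragments <- function(path) {
  raw <- read_tsv_chr(path)
  if (nrow(raw) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), barcode = character(),
                          count = integer()))
  }
  if (ncol(raw) < 4L) {
    stop("fragment file ", path, " has ", ncol(raw),
         " columns; at least 4 (chrom, start, end, barcode) are required",
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  if (ncol(raw) >= 5L) {
    count_raw <- raw[[5L]]
    count <- suppressWarnings(as.integer(count_raw))
    # ragged rows with a missing 5th field default to 1
    missing_count <- is.na(count_raw) | count_raw == ""
    count[missing_count] <- 1L
    bad_count <- !missing_count & is.na(count)
  } else {
    count <- rep(1L, nrow(raw))
    bad_count <- logical(nrow(raw))
  }
  bad <- which(is.na(start) | is.na(end) | is.na(raw[[4L]]) | bad_count)
  if (length(bad)) {
    stop("malformed fragment record at line ",
         data_row_to_line(path, bad[1]), " of ", path,
         ": non-integer coordinates or count", call. = FALSE)
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("invalid fragment at line ", data_row_to_line(path, bad[1]),
         " of ", path, ": end <= start (intervals are half-open)",
         call. = FALSE)
  }
  if (any(start < 0)) stop("fragment start < 0 in ", path, call. = FALSE)
  if (any(count < 1L)) {
    stop("fragment count < 1 at line ",
         data_row_to_line(path, which(count < 1L)[1]), " of ", path,
         call. = FALSE)
  }
  tibble::tibble(chrom = raw[[1L]], start = start, end = end,
                 barcode = raw[[4L]], count = count)
}

read_tsv_chr <- function(path) {
  out <- suppressWarnings(readr::read_tsv(
    path, col_names = FALSE, comment = "#", progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    na = character()
  ))
  if (ncol(out) == 0L) return(out)
  out[!is.na(out[[1L]]) & nzchar(out[[1L]]), , drop = FALSE]
}

# map a data-row index back to a 1-based file line number, accounting for
# comment/empty lines (only consulted on the error path)
data_row_to_line <- function(path, row) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  data_lines <- which(!startsWith(lines, "#") & nzchar(lines))
  if (row <= length(data_lines)) data_lines[row] else row
}

#' Write fragments as TSV
#'
#' @param fragments Fragment tibble as returned by [read_fragments()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  readr::write_tsv(fragments[, c("chrom", "start", "end",
                                 "barcode", "count")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a peak-by-cell matrix from an MTX triplet
#'
#' Reads a MatrixMarket counts file together with its peak and barcode
#' sidecars. Peaks may be BED lines (0-based half-open) or
#' `chrom:start-end` strings.
#'
#' @param mtx_path MatrixMarket file (peaks x cells).
#' @param peaks_path BED file or one `chrom:start-end` string per line.
#' @param barcodes_path One barcode per line.
#' @param labels Optional labels passed on to [peak_matrix()], or a path to
#'   a two-column TSV (barcode, cell type).
#' @return A [peak_matrix()].
#' @export
read_peak_matrix <- function(mtx_path, peaks_path, barcodes_path,
                             labels = NULL) {
  counts <- Matrix::readMM(mtx_path)
  peak_lines <- readLines(peaks_path, warn = FALSE)
  peak_lines <- peak_lines[nzchar(peak_lines)]
  peaks <- if (length(peak_lines) && grepl("\t", peak_lines[1])) {
    parts <- strsplit(peak_lines, "\t", fixed = TRUE)
    tibble::tibble(
      chrom = vapply(parts, `[[`, "", 1L),
      start = as.integer(vapply(parts, `[[`, "", 2L)),
      end = as.integer(vapply(parts, `[[`, "", 3L))
    )
  } else {
    parse_peak_id(peak_lines)
  }
  barcodes <- readLines(barcodes_path, warn = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(counts) != nrow(peaks)) {
    stop("MTX declares ", nrow(counts), " rows but ", peaks_path,
         " has ", nrow(peaks), " peaks", call. = FALSE)
  }
  if (ncol(counts) != length(barcodes)) {
    stop("MTX declares ", ncol(counts), " columns but ", barcodes_path,
         " has ", length(barcodes), " barcodes", call. = FALSE)
  }
  if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
    labels <- read_labels(labels)
  }
  peak_matrix(counts, peaks, barcodes, labels)
}

#' Write a peak matrix as an MTX triplet
#'
#' Emits `matrix.mtx`, `peaks.bed`, `barcodes.tsv` and, when labels are
#' present, `labels.tsv` under `dir`.
#'
#' @param pm A [peak_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_peak_matrix <- function(pm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(pm$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(pm$peaks[, c("chrom", "start", "end")],
                   file.path(dir, "peaks.bed"), col_names = FALSE,
                   progress = FALSE)
  writeLines(pm$barcodes, file.path(dir, "barcodes.tsv"))
  if (!is.null(pm$labels)) {
    readr::write_tsv(
      tibble::tibble(barcode = names(pm$labels),
                     cell_type = unname(pm$labels)),
      file.path(dir, "labels.tsv"), progress = FALSE
    )
  }
  invisible(dir)
}

#' Read a labels TSV (barcode, cell_type)
#'
#' @param path Two-column TSV with a header or not; the first column is the
#'   barcode, the second the tissue/cell type.
#' @return Named character vector barcode -> cell type.
#' @export
read_labels <- function(path) {
  raw <- read_tsv_chr(path)
  if (ncol(raw) < 2L) stop("labels file needs two columns", call. = FALSE)
  if (nrow(raw) && identical(tolower(raw[[1L]][1]), "barcode")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  stats::setNames(raw[[2L]], raw[[1L]])
}

#' Read candidate enhancer regions (narrowPeak or BED)
#'
#' Accepts ENCODE narrowPeak (10 columns; `signalValue` becomes `score`) or
#' plain BED with at least 3 columns. Output is sorted by (chrom, start).
#'
#' @param path narrowPeak/BED path.
#' @return Interval tibble with `name`, `score`, `strand` columns
#'   (empty name / `NA` score when the input lacks them).
#' @export
read_narrowpeak <- function(path) {
  raw <- read_tsv_chr(path)
  if (nrow(raw) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = numeric(), strand = character()))
  }
  if (ncol(raw) < 3L) {
    stop(path, " has fewer than 3 columns; not a BED/narrowPeak file",
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinates at line ",
         data_row_to_line(path, which(is.na(start) | is.na(end))[1]),
         " of ", path, call. = FALSE)
  }
  tbl <- tibble::tibble(
    chrom = raw[[1L]], start = start, end = end,
    name = if (ncol(raw) >= 4L) raw[[4L]] else "",
    # narrowPeak: column 7 is signalValue; BED5/6: column 5 is the score
    score = if (ncol(raw) >= 10L) {
      suppressWarnings(as.numeric(raw[[7L]]))
    } else if (ncol(raw) >= 5L) {
      suppressWarnings(as.numeric(raw[[5L]]))
    } else NA_real_,
    strand = if (ncol(raw) >= 6L) raw[[6L]] else "."
  )
  validate_intervals(tbl, "peak")
  sort_intervals(tbl)
}

#' Write intervals as BED
#'
#' @param tbl Interval tibble; `name`, `score`, `strand` are included when
#'   present (missing scores are written as 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tbl, path) {
  validate_intervals(tbl)
  out <- tbl[, c("chrom", "start", "end")]
  if (any(c("name", "score", "strand") %in% names(tbl))) {
    out$name <- if ("name" %in% names(tbl)) tbl$name else "."
    sc <- if ("score" %in% names(tbl)) tbl$score else 0
    sc[is.na(sc)] <- 0
    out$score <- sc
    out$strand <- if ("strand" %in% names(tbl)) tbl$strand else "."
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports gene and exon features, converts the 1-based inclusive GTF
#' coordinates to the package's 0-based half-open convention, and assigns
#' TSS/TES strand-aware: on `+` the TSS is the smaller coordinate of the
#' span, on `-` the larger (so the upstream promoter extends rightward).
#' Genes without a `+`/`-` strand are dropped with a warning.
#'
#' @param gtf_path Path to a GTF file with `gene` and/or `exon` features.
#' @return Tibble with one row per gene: `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `tes`, and a list-column `exons` of
#'   interval tibbles.
#' @export
read_gene_models <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gid <- as.character(md$gene_id)
  gname <- if ("gene_name" %in% names(md)) {
    as.character(md$gene_name)
  } else gid
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))

  keep <- type %in% c("gene", "exon")
  unstranded <- unique(gid[keep & !strand %in% c("+", "-")])
  if (length(unstranded)) {
    warning("dropping ", length(unstranded),
            " gene(s) without strand: ",
            paste(utils::head(unstranded, 3), collapse = ", "),
            call. = FALSE)
  }
  keep <- keep & strand %in% c("+", "-") & !gid %in% unstranded
  if (!any(keep)) {
    return(tibble::tibble(gene_id = character(), gene_name = character(),
                          chrom = character(), strand = character(),
                          start = integer(), end = integer(),
                          tss = integer(), tes = integer(),
                          exons = list()))
  }
  tbl <- tibble::tibble(
    gene_id = gid[keep], gene_name = gname[keep], type = type[keep],
    chrom = chrom[keep], strand = strand[keep],
    start = start0[keep], end = end0[keep]
  )
  genes <- dplyr::bind_rows(lapply(split(tbl, tbl$gene_id), function(g) {
    ex <- g[g$type == "exon", c("chrom", "start", "end")]
    tibble::tibble(
      gene_id = g$gene_id[1], gene_name = g$gene_name[1],
      chrom = g$chrom[1], strand = g$strand[1],
      start = min(g$start), end = max(g$end),
      exons = list(ex)
    )
  }))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes[, c("gene_id", "gene_name", "chrom", "strand", "start", "end",
            "tss", "tes", "exons")]
}

#' Write gene models as GTF
#'
#' Inverse of [read_gene_models()]: emits one `gene` line per gene plus its
#' exon lines, converting back to 1-based inclusive GTF coordinates.
#'
#' @param genes Gene model tibble from [read_gene_models()] or
#'   [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  fmt <- function(chrom, feat, s0, e0, strand, gid, gname) {
    paste0(chrom, "\tscregulon\t", feat, "\t", s0 + 1L, "\t", e0, "\t.\t",
           strand, "\t.\t", 'gene_id "', gid, '"; gene_name "', gname, '";')
  }
  lines <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    c(fmt(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id,
          g$gene_name),
      if (!is.null(ex) && nrow(ex)) {
        fmt(if ("chrom" %in% names(ex)) ex$chrom else g$chrom, "exon",
            ex$start, ex$end, g$strand, g$gene_id, g$gene_name)
      })
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Promoter windows around gene TSSs
#'
#' Strand-aware promoter windows covering `upstream` bp upstream and
#' `downstream` bp downstream of each TSS (default 2000/100, consistent
#' with the 2 kb promoter distance used for gene activity scoring).
#'
#' @param genes Gene model tibble.
#' @param upstream,downstream Window extents in bp.
#' @return Interval tibble with `gene_id`, `gene_name`, `strand`.
#' @export
promoter_windows <- function(genes, upstream = 2000L, downstream = 100L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  tibble::tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(start)),
    end = as.integer(end),
    gene_id = genes$gene_id,
    gene_name = genes$gene_name,
    strand = genes$strand
  )
}
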