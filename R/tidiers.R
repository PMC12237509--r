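#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a rank curve
#'
#' @param x A [rank_and_cutoff()] result.
#' @param ... Unused.
#' @return Tibble of curve points with an `is_super` flag.
#' @export
tidy.rank_curve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$is_super <- out$signal > attr(x, "cutoff_signal")
  out
}

#' @rdname tidy.rank_curve
#' @export
glance.rank_curve <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    cutoff_index = attr(x, "cutoff_index"),
    cutoff_signal = attr(x, "cutoff_signal"),
    n_super = sum(x$signal > attr(x, "cutoff_signal")),
    degenerate = attr(x, "degenerate")
  )
}

#' Plot a super-enhancer rank curve
#'
#' The classic hockey-stick: scaled rank against scaled signal with the
#' slope-1 tangent cutoff marked; points above the cutoff are the called
#' super-enhancers.
#'
#' @param object A [rank_and_cutoff()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_curve <- function(object, ...) {
  df <- tidy(object)
  cut_x <- object$scaled_x[attr(object, "cutoff_index")]
  cut_y <- object$scaled_y[attr(object, "cutoff_index")]
  ggplot2::ggplot(df, ggplot2::aes(.data$scaled_x, .data$scaled_y)) +
    ggplot2::geom_abline(slope = 1, intercept = cut_y - cut_x,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_super),
                        size = 1.2) +
    ggplot2::annotate("point", x = cut_x, y = cut_y, shape = 1,
                      size = 3) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      name = "super-enhancer") +
    ggplot2::labs(x = "scaled rank", y = "scaled signal",
                  title = "Stitched-enhancer rank curve",
                  subtitle = sprintf("cutoff signal = %.3g; %d super",
                                     attr(object, "cutoff_signal"),
                                     sum(df$is_super))) +
    ggplot2::theme_minimal()
}

#' Tidy an overlap test
#'
#' @param x An [hypergeometric_test()] result.
#' @param ... Unused.
#' @return One-row tibble of counts and p-values.
#' @export
tidy.overlap_htest <- function(x, ...) {
  tibble::tibble(N = x$N, K = x$K, n = x$n, k = x$k,
                 p_point = x$p_point, p_tail = x$p_tail)
}

#' @rdname tidy.overlap_htest
#' @export
glance.overlap_htest <- function(x, ...) tidy(x)

#' Plot a cell embedding coloured by label
#'
#' @param coords Cells x 2 coordinate matrix (e.g. [umap_embed()]).
#' @param labels Optional named vector barcode -> cell type.
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, labels = NULL) {
  df <- tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2])
  if (!is.null(labels)) {
    df$cell_type <- unname(labels[rownames(coords)])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  p <- if (is.null(labels)) {
    p + ggplot2::geom_point(size = 0.8, alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$cell_type),
                            size = 0.8, alpha = 0.7)
  }
  p + ggplot2::labs(x = "dim 1", y = "dim 2") + ggplot2::theme_minimal()
}
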