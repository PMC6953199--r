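#' Manhattan plot of an association scan
#'
#' @param result an `assoc_result` tibble.
#' @param threshold p-value threshold drawn as a dashed line (optional).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(result, threshold = NULL) {
  df <- dplyr::filter(tibble::as_tibble(result), is.finite(.data$p))
  chroms <- unique(df$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch) {
    max(df$pos[df$chrom == ch])
  }, numeric(1))))[seq_along(chroms)]
  names(offs) <- chroms
  df$x <- df$pos + offs[df$chrom]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, -log10(.data$p),
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "genome position",
                  y = expression(-log[10](italic(p))),
                  title = attr(result, "trait")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' QQ plot of observed vs expected p-values
#'
#' @param object a `qq_result` from [qq_and_inflation()].
#' @param ... ignored.
#' @return A ggplot object annotated with the genomic inflation factor.
#' @export
autoplot.qq_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(p))),
      y = expression(Observed ~ -log[10](italic(p))),
      subtitle = sprintf("lambda[GC] = %.3f", object$lambda_gc)) +
    ggplot2::theme_minimal()
}

#' LD decay profile plot
#'
#' @param object an `ld_profile` from [ld_decay_profile()].
#' @param ... ignored.
#' @return A ggplot object; the half-maximum distance is marked when
#'   reached.
#' @export
autoplot.ld_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(.data$mid_bp / 1000,
                                    .data$mean_r2)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_r2),
                       colour = "firebrick") +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
  if (object$half_max_reached) {
    p <- p + ggplot2::geom_vline(xintercept = object$half_max_bp / 1000,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' PCA scatter plot
#'
#' @param object a `pca_result` from [pca()].
#' @param labels optional per-sample group labels for colouring.
#' @param dims which two components to draw.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, labels = NULL, dims = c(1, 2),
                                ...) {
  df <- object$coords
  df$label <- labels %||% "sample"
  nm <- paste0("PC", dims)
  pct <- round(100 * object$explained[dims], 1)
  ggplot2::ggplot(df, ggplot2::aes(.data[[nm[1]]], .data[[nm[2]]],
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", nm[1], pct[1]),
                  y = sprintf("%s (%.1f%%)", nm[2], pct[2])) +
    ggplot2::theme_minimal()
}
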