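## Base-graphics visualizations: expression heat map (green/white/magenta),
## normalization scatter, and raw intensity density profiles.

#' Diverging low/average/high expression palette
#'
#' Green for low transcript abundance, white for average, magenta for
#' high — the conventional palette for median-scaled expression heat maps.
#'
#' @param n number of colors.
#' @return Character vector of colors.
#' @export
gwmPalette <- function(n = 75L) {
  grDevices::colorRampPalette(c("green3", "white", "magenta3"))(n)
}

#' Heat map of (median-scaled) expression
#'
#' Renders a probe-set x array heat map with rows median-centred (so color
#' shows deviation from each gene's typical level) and ordered by
#' average-linkage Pearson clustering; columns keep their input order.
#'
#' @param expr an \linkS4class{ExpressionMatrix} or numeric log2 matrix.
#' @param median_scale subtract row medians first (default TRUE).
#' @param cluster_rows order rows by \code{\link{clusterExpression}}
#'   (default TRUE).
#' @param main plot title.
#' @return Invisibly, the matrix as drawn (rows in display order).
#' @export
plotExpressionHeatmap <- function(expr, median_scale = TRUE,
                                  cluster_rows = TRUE, main = "") {
  m <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  if (median_scale) m <- medianScaleRows(m)
  if (cluster_rows && nrow(m) > 2L)
    m <- m[clusterExpression(m)$leaf_order, , drop = FALSE]
  lim <- max(abs(m))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(-lim, lim), col = gwmPalette(), axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1L, at = seq_len(ncol(m)), labels = colnames(m), las = 2L,
                 cex.axis = 0.7)
  graphics::box()
  invisible(m)
}

#' Scatter plot of a normalization comparison
#'
#' Test-versus-reference log2 expression scatter from a
#' \code{ComparisonReport}, colored by probe-set category when available,
#' with the identity line and pooled r in the title.
#'
#' @param report a \code{ComparisonReport} from
#'   \code{\link{compareToReference}}.
#' @param ... further arguments passed to \code{\link[graphics]{plot}}.
#' @export
plotComparison <- function(report, ...) {
  s <- report$scatter
  pal <- c(defl = "black", invariant = "green4", marker = "blue",
           meg = "grey40", control = "grey70")
  col <- pal[s$category]
  col[is.na(col)] <- "black"
  graphics::plot(s$reference, s$test, col = col, pch = 1L, cex = 0.4,
                 xlab = "reference log2 expression",
                 ylab = paste(report$method_tag, "log2 expression"),
                 main = sprintf("%s vs reference (r = %.3f)",
                                report$method_tag, report$overall_r), ...)
  graphics::abline(0, 1, col = "red")
  invisible(report)
}

#' Per-array raw intensity density plot
#'
#' Overlays the per-array log2(PM) kernel density curves from
#' \code{\link{intensityDensity}}; the background mode appears as a large
#' low-intensity peak, and divergence between curves signals a
#' distribution shift between arrays.
#'
#' @param dens output of \code{\link{intensityDensity}}.
#' @param ... further arguments passed to \code{\link[graphics]{matplot}}.
#' @export
plotIntensityDensity <- function(dens, ...) {
  graphics::matplot(dens$x, dens$y, type = "l", lty = 1L,
                    xlab = "log2 PM intensity", ylab = "density",
                    main = "Raw intensity distributions", ...)
  invisible(dens)
}
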