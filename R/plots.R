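# ggplot2 displays for the result objects. All plots are plain ggplot objects
# so callers can restyle them.

#' Ordination scatter for a PCA
#'
#' @param object a `parid_pca`.
#' @param axes two component names to plot.
#' @param colour optional name of an id column of the scores to map to
#'   colour (e.g. `"species"`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.parid_pca <- function(object, axes = c("PC1", "PC2"), colour = NULL, ...) {
  sc <- object$scores
  vf <- object$variance_fraction
  idx <- match(axes, paste0("PC", seq_along(vf)))
  labs <- sprintf("%s (%.1f%%)", axes, 100 * vf[idx])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data[[axes[[1L]]]], y = .data[[axes[[2L]]]]))
  if (!is.null(colour) && colour %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = labs[[1L]], y = labs[[2L]]) + ggplot2::theme_minimal()
}

#' Canonical variate scatter
#'
#' @param object a `parid_cva`.
#' @param ... unused.
#' @return a ggplot of the first two canonical axes, coloured by group.
#' @export
autoplot.parid_cva <- function(object, ...) {
  sc <- object$scores
  if (!"CV2" %in% names(sc)) sc$CV2 <- 0
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$CV1, y = .data$CV2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "CV1", y = "CV2") +
    ggplot2::theme_minimal()
}

#' Aligned shapes and consensus
#'
#' Aligned landmark scatter with the consensus configuration drawn on top;
#' the standard check that superimposition behaved.
#'
#' @param object a `parid_gpa`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.parid_gpa <- function(object, ...) {
  pts <- tidy(object)
  cons <- tibble::tibble(point = seq_len(nrow(object$consensus)),
                         x = object$consensus[, 1L], y = object$consensus[, 2L],
                         role = object$roles)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_point(data = cons, ggplot2::aes(shape = .data$role),
                        colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Phylomorphospace plot
#'
#' Tips at their ordination scores, internal nodes at squared-change
#' parsimony reconstructions, edges connecting parent and child.
#'
#' @param object a `parid_phylomorphospace`.
#' @param label draw tip labels.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.parid_phylomorphospace <- function(object, label = TRUE, ...) {
  ax <- object$axes
  nd <- object$nodes
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = object$edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data[[ax[[1L]]]], y = .data[[ax[[2L]]]],
                                     shape = .data$type),
                        size = 2) +
    ggplot2::labs(x = ax[[1L]], y = ax[[2L]]) +
    ggplot2::theme_minimal()
  if (label) {
    tips <- nd[nd$type == "tip", ]
    p <- p + ggplot2::geom_text(data = tips,
                                ggplot2::aes(x = .data[[ax[[1L]]]], y = .data[[ax[[2L]]]],
                                             label = .data$label),
                                vjust = -0.8, size = 3)
  }
  p
}
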