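#' Principal coordinate analysis (classical metric MDS)
#'
#' Double-centers `-d^2/2` (Gower centering) and eigendecomposes. Coordinates
#' are eigenvectors scaled by the square root of their (positive) eigenvalues;
#' axes are ordered by descending eigenvalue. Negative eigenvalues (possible
#' for non-Euclidean genetic distances) are reported but excluded from the
#' coordinates, and the per-axis percentage of variance is taken over the
#' positive eigenvalues.
#'
#' @param dm labeled symmetric distance matrix (zero diagonal).
#' @param n_axes number of axes to return (default 3, capped at the number of
#'   positive eigenvalues).
#' @return object of class `ssr_pcoa`: list with `coordinates` (tibble:
#'   `entity`, `axis`, `coordinate`), `eigenvalues`, `percent_variance`,
#'   and `n_axes`.
#' @export
pcoa <- function(dm, n_axes = 3) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8) {
    abort("pcoa requires a symmetric square distance matrix")
  }
  if (n_axes < 1) abort("n_axes must be >= 1")
  n <- nrow(dm)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  a <- -0.5 * dm^2
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- centering %*% a %*% centering
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- eig$values > 1e-9 * max(abs(eig$values), 1e-300)
  k <- min(n_axes, sum(pos))
  coords <- if (k > 0) {
    eig$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(eig$values[seq_len(k)]), k, k)
  } else {
    matrix(0, n, 0)
  }
  pct <- rep(0, length(eig$values))
  if (any(pos)) pct[pos] <- 100 * eig$values[pos] / sum(eig$values[pos])
  coord_tbl <- tibble::tibble(
    entity = rep(labels, times = max(k, 1))[seq_len(n * k)],
    axis = rep(seq_len(k), each = n),
    coordinate = as.vector(coords)
  )
  structure(list(coordinates = coord_tbl, eigenvalues = eig$values,
                 percent_variance = pct, n_axes = k, labels = labels),
            class = "ssr_pcoa")
}

#' @export
print.ssr_pcoa <- function(x, ...) {
  cat("PCoA:", length(x$labels), "entities,", x$n_axes, "axes\n")
  cat("  % variance:", paste(round(x$percent_variance[seq_len(x$n_axes)], 2),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ssr_pcoa <- function(x, ...) {
  x$coordinates |>
    tidyr::pivot_wider(names_from = "axis", values_from = "coordinate",
                       names_prefix = "axis")
}

#' @export
autoplot.ssr_pcoa <- function(object, ...) {
  wide <- tidy(object)
  if (object$n_axes < 2) abort("need at least 2 axes to plot")
  ggplot2::ggplot(wide, ggplot2::aes(.data$axis1, .data$axis2, label = .data$entity)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("Coord. 1 (%.1f%%)", object$percent_variance[1]),
      y = sprintf("Coord. 2 (%.1f%%)", object$percent_variance[2]),
      title = "Principal coordinate analysis"
    ) +
    ggplot2::theme_minimal()
}
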