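#' UPGMA clustering of a distance matrix
#'
#' Agglomerative average-linkage clustering producing a rooted ultrametric
#' tree: each merge is placed at half the average distance between the merged
#' clusters, so every root-to-leaf path has equal length. Ties in the minimum
#' distance are broken deterministically by merging the pair whose (sorted)
#' cluster labels are lexicographically smallest, where a cluster is labeled
#' by its alphabetically first leaf.
#'
#' @param dm labeled symmetric distance matrix with no NaN entries.
#' @return object of class `ssr_upgma`: list with `newick` (string, 6-decimal
#'   branch lengths), `phylo` (an [ape::read.tree()] object), and `heights`
#'   (merge heights in input distance units / 2).
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  if (anyNA(dm)) abort("upgma requires a complete distance matrix (no NaN)")
  if (nrow(dm) < 2L) abort("upgma needs at least two labels")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(dm)))

  clusters <- lapply(seq_along(labels), function(i) {
    list(newick = labels[i], height = 0, size = 1L, key = labels[i])
  })
  d <- dm
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      dij <- d[i, j]
      if (dij < best_d - 1e-12) {
        best_d <- dij
        best <- c(i, j)
      } else if (abs(dij - best_d) <= 1e-12) {
        # lexicographic tie-break on sorted cluster keys
        cand <- sort(c(clusters[[i]]$key, clusters[[j]]$key))
        cur <- sort(c(clusters[[best[1]]]$key, clusters[[best[2]]]$key))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    heights <- c(heights, h)
    if (clusters[[j]]$key < clusters[[i]]$key) {
      tmp <- i; i <- j; j <- tmp  # children ordered by leaf label
    }
    ci <- clusters[[i]]; cj <- clusters[[j]]
    newick <- sprintf("(%s:%.6f,%s:%.6f)",
                      ci$newick, h - ci$height, cj$newick, h - cj$height)
    merged <- list(newick = newick, height = h, size = ci$size + cj$size,
                   key = min(ci$key, cj$key))
    keep <- setdiff(seq_len(m), c(i, j))
    # average-linkage (group-average) distance update
    new_d <- (ci$size * d[i, keep] + cj$size * d[j, keep]) / (ci$size + cj$size)
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d), c(new_d, 0))
    clusters <- c(clusters[keep], list(merged))
  }
  newick <- paste0(clusters[[1]]$newick, ";")
  structure(list(newick = newick,
                 phylo = ape::read.tree(text = newick),
                 heights = heights),
            class = "ssr_upgma")
}

#' @export
print.ssr_upgma <- function(x, ...) {
  cat("UPGMA tree:", x$newick, "\n")
  invisible(x)
}

#' Write a UPGMA tree to a Newick file
#' @param tree `ssr_upgma` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
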