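#' Smouse-Peakall squared genotypic distance at one locus
#'
#' Half the squared Euclidean distance between the two genotypes'
#' allele-count vectors. For diploids this takes values in {0, 1, 2, 3, 4}:
#' (AA,AA) = 0, (AA,AB) = 1, (AB,CD) = 2, (AA,BC) = 3, (AA,BB) = 4.
#' Returns NA when either genotype is missing (callers apply pairwise
#' deletion over loci).
#'
#' @param g1,g2 length-2 integer vectors of allele states, or NA.
#' @return a single squared distance (integer-valued numeric).
#' @export
squared_genotypic_distance <- function(g1, g2) {
  if (anyNA(g1) || anyNA(g2)) return(NA_real_)
  s <- sum(outer(g1, g2, "=="))
  q1 <- if (g1[1] == g1[2]) 2 else 1
  q2 <- if (g2[1] == g2[2]) 2 else 1
  q1 + q2 - s
}

#' Pairwise inter-individual squared-distance matrix
#'
#' Multilocus Smouse-Peakall squared distance: the per-locus squared genotypic
#' distances summed over loci at which both individuals are scored (pairwise
#' deletion of missing data).
#'
#' @param data genotype tibble.
#' @return N x N labeled symmetric matrix of summed squared distances.
#' @export
genotype_distance_matrix <- function(data) {
  ord <- data |> dplyr::arrange(.data$population, .data$individual, .data$locus)
  ids <- unique(ord$individual)
  nl <- length(loci(data))
  n <- length(ids)
  a1 <- matrix(ord$allele_1, nrow = nl)
  a2 <- matrix(ord$allele_2, nrow = nl)
  total <- matrix(0, n, n, dimnames = list(ids, ids))
  for (l in seq_len(nl)) {
    x1 <- a1[l, ]
    x2 <- a2[l, ]
    s <- (outer(x1, x1, "==") + outer(x1, x2, "==") +
          outer(x2, x1, "==") + outer(x2, x2, "=="))
    q <- ifelse(x1 == x2, 2, 1)
    d <- outer(q, q, "+") - s
    d[is.na(d)] <- 0  # pairwise deletion: missing locus contributes nothing
    total <- total + d
  }
  diag(total) <- 0
  total
}

#' AMOVA: among- vs within-population partition of molecular variance
#'
#' Excoffier-style analysis of molecular variance on individual-level
#' Smouse-Peakall squared distances. Sums of squares come from the distance
#' matrix (`SS_total = sum_{i<j} d2/N`, `SS_within` summed per population with
#' its own `n`), degrees of freedom are `k - 1` among and `N - k` within, and
#' variance components follow the method of moments with
#' `n0 = (N - sum(n_k^2)/N) / (k - 1)`. Significance of the among-population
#' component is assessed by permuting individuals among populations (observed
#' configuration included in the permutation distribution).
#'
#' @param data genotype tibble with >= 2 populations, each of size >= 2.
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return object of class `ssr_amova`: list with `table` (tibble: source, df,
#'   SS, variance component `sigma2`, `percent`, `p_value`), `phi_st`, `n0`,
#'   and `n_permutations`.
#' @export
amova <- function(data, n_permutations = 999, seed = 1) {
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  pops_tbl <- data |> dplyr::distinct(.data$individual, .data$population) |>
    dplyr::arrange(.data$population, .data$individual)
  labels <- as.integer(droplevels(pops_tbl$population))
  k <- max(labels)
  n <- length(labels)
  if (k < 2L) abort("amova needs at least two populations")
  sizes <- tabulate(labels, k)
  if (any(sizes < 2L)) abort("amova needs every population to have N >= 2")
  d2 <- genotype_distance_matrix(data)

  ss_within_for <- function(lab) {
    s <- 0
    for (g in seq_len(k)) {
      idx <- which(lab == g)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_total <- sum(d2) / (2 * n)
  ss_within <- ss_within_for(labels)
  ss_among <- ss_total - ss_within
  df_among <- k - 1L
  df_within <- n - k
  df_total <- n - 1L
  sigma2_within <- ss_within / df_within
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  sigma2_among <- max((ss_among / df_among - sigma2_within) / n0, 0)
  sigma2_total <- sigma2_among + sigma2_within
  phi_st <- if (sigma2_total > 0) sigma2_among / sigma2_total else 0

  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      ss_total - ss_within_for(sample(labels))
    }, numeric(1))
  })
  # among-SS is a monotone statistic for the among component at fixed sizes
  p_value <- (sum(perm_stats >= ss_among - 1e-12) + 1) / (n_permutations + 1)

  table <- tibble::tibble(
    source = c("Among populations", "Within populations", "Total"),
    df = c(df_among, df_within, df_total),
    SS = c(ss_among, ss_within, ss_total),
    sigma2 = c(sigma2_among, sigma2_within, sigma2_total),
    percent = 100 * c(sigma2_among, sigma2_within, sigma2_total) / sigma2_total,
    p_value = c(p_value, p_value, NA_real_)
  )
  structure(list(table = table, phi_st = phi_st, n0 = n0,
                 n_permutations = n_permutations),
            class = "ssr_amova")
}

#' @export
print.ssr_amova <- function(x, ...) {
  cat("AMOVA (", x$n_permutations, " permutations)\n", sep = "")
  df <- as.data.frame(x$table)
  df$SS <- round(df$SS, 3)
  df$sigma2 <- round(df$sigma2, 3)
  df$percent <- round(df$percent)
  print(df, row.names = FALSE)
  cat("Phi_ST =", format(x$phi_st, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.ssr_amova <- function(x, ...) x$table

#' @export
glance.ssr_amova <- function(x, ...) {
  tibble::tibble(
    phi_st = x$phi_st,
    p_value = x$table$p_value[1],
    percent_among = x$table$percent[1],
    percent_within = x$table$percent[2],
    n_permutations = x$n_permutations
  )
}

#' Percentage-of-variation from printed variance components
#'
#' Utility for re-deriving a report table's percentage column from its
#' estimated variance components.
#'
#' @param components numeric vector of variance components (among..., within).
#' @return percentages summing to 100.
#' @export
percent_of_variation <- function(components) 100 * components / sum(components)
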