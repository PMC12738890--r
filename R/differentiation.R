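#' Island-model gene flow from FST
#'
#' Wright's island-model effective number of migrants, `Nm = (1/FST - 1)/4`.
#' Undefined (NA, with a warning) for `FST <= 0`.
#'
#' @param fst numeric vector of fixation indices in (0, 1].
#' @return numeric vector of Nm values.
#' @export
#' @examples
#' nm_from_fst(0.2)    # 1
#' nm_from_fst(0.094)  # ~2.41
nm_from_fst <- function(fst) {
  bad <- !is.na(fst) & fst <= 0
  if (any(bad)) warn("Nm undefined for FST <= 0; returning NA")
  ifelse(is.na(fst) | fst <= 0, NA_real_, (1 / fst - 1) / 4)
}

# per-locus HS/HT table for a set of populations: HS = unweighted mean of the
# populations' 1 - sum(p^2); HT = 1 - sum(p_bar^2) with p_bar the unweighted
# mean of population frequencies.
hs_ht_by_locus <- function(freqs) {
  k <- dplyr::n_distinct(freqs$population)
  hs <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(he = 1 - sum(.data$freq^2), .groups = "drop") |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(HS = mean(.data$he), n_pops = dplyr::n(), .groups = "drop")
  ht <- freqs |>
    dplyr::group_by(.data$locus, .data$allele) |>
    dplyr::summarise(p_bar = sum(.data$freq) / k, .groups = "drop_last") |>
    dplyr::summarise(HT = 1 - sum(.data$p_bar^2), .groups = "drop")
  dplyr::inner_join(hs, ht, by = "locus") |>
    dplyr::filter(.data$n_pops == k)  # loci observed in every population
}

#' Global FST over a set of populations
#'
#' Nei-style `FST = (HT - HS) / HT` with per-locus HT and HS summed over loci
#' (ratio of sums), HT from the unweighted mean of population allele
#' frequencies. This is the GenAlEx-flavoured estimator; it is a different
#' quantity from the AMOVA percentage of variation and both are reported by
#' the pipeline.
#'
#' @param data genotype tibble (optionally pre-filtered to one species).
#' @return a single FST value.
#' @export
global_fst <- function(data) {
  tab <- hs_ht_by_locus(allele_frequencies(droplevels(data)))
  if (sum(tab$HT) <= 0) return(0)
  (sum(tab$HT) - sum(tab$HS)) / sum(tab$HT)
}

#' Pairwise FST and gene flow between populations
#'
#' For every population pair, per-locus `HS` (mean within-population expected
#' heterozygosity) and `HT` (expected heterozygosity of the unweighted pooled
#' pair frequencies) are summed over loci and combined as
#' `FST = (HT - HS)/HT` (default, GenAlEx-style). The Weir-Cockerham (1984)
#' theta is available with `estimator = "wc"`. `Nm` is attached via
#' [nm_from_fst()]. A pair monomorphic across all loci has `FST = 0`.
#'
#' @param data genotype tibble.
#' @param estimator `"nei"` (default) or `"wc"`.
#' @return tibble with `pop1`, `pop2`, `fst`, `nm` for each unordered pair,
#'   pairs ordered by the dataset's population order.
#' @export
pairwise_fst <- function(data, estimator = c("nei", "wc")) {
  estimator <- match.arg(estimator)
  pops <- populations(data)
  if (length(pops) < 2L) abort("pairwise_fst needs at least two populations")
  pairs <- utils::combn(pops, 2L)
  fst <- vapply(seq_len(ncol(pairs)), function(j) {
    sub <- droplevels(dplyr::filter(data, .data$population %in% pairs[, j]))
    if (estimator == "nei") global_fst(sub) else wc_theta(sub)
  }, numeric(1))
  tibble::tibble(
    pop1 = factor(pairs[1, ], levels = pops),
    pop2 = factor(pairs[2, ], levels = pops),
    fst = fst,
    nm = suppressWarnings(nm_from_fst(fst))
  )
}

# Weir & Cockerham (1984) theta for an arbitrary number of populations,
# summed over alleles and loci (ratio of sums of variance components a, a+b+c).
wc_theta <- function(data) {
  freqs <- allele_frequencies(data)
  hets <- data |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::mutate(het = .data$allele_1 != .data$allele_2)
  num <- 0
  den <- 0
  for (loc in loci(data)) {
    fl <- dplyr::filter(freqs, .data$locus == loc)
    if (nrow(fl) == 0L) next
    ns <- fl |>
      dplyr::distinct(.data$population, .data$n_copies) |>
      dplyr::mutate(n = .data$n_copies / 2)
    r <- nrow(ns)
    if (r < 2L) next
    n_i <- ns$n
    n_bar <- mean(n_i)
    if (n_bar <= 1) next
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    alleles <- unique(fl$allele)
    hl <- dplyr::filter(hets, .data$locus == loc)
    for (al in alleles) {
      p_i <- vapply(ns$population, function(pp) {
        v <- fl$freq[fl$population == pp & fl$allele == al]
        if (length(v)) v else 0
      }, numeric(1))
      p_bar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
      # h_i: frequency of heterozygotes carrying allele `al` in pop i
      h_i <- vapply(ns$population, function(pp) {
        sub <- hl[hl$population == pp, ]
        if (nrow(sub) == 0L) return(0)
        mean(sub$het & (sub$allele_1 == al | sub$allele_2 == al))
      }, numeric(1))
      h_bar <- sum(n_i * h_i) / sum(n_i)
      a <- n_bar / nc * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
      b <- n_bar / (n_bar - 1) *
        (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
      cc <- h_bar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den <= 0) return(0)
  num / den
}

#' Combined FST / Nm square matrix
#'
#' Assembles the familiar report layout: pairwise FST below the diagonal, Nm
#' above, zeros on the diagonal.
#'
#' @param pairwise output of [pairwise_fst()].
#' @return a labeled square matrix.
#' @export
differentiation_matrix <- function(pairwise) {
  labels <- levels(pairwise$pop1)
  m <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  for (i in seq_len(nrow(pairwise))) {
    p1 <- as.character(pairwise$pop1[i])
    p2 <- as.character(pairwise$pop2[i])
    m[p2, p1] <- pairwise$fst[i]  # below diagonal (row later than column)
    m[p1, p2] <- pairwise$nm[i]   # above diagonal
  }
  m
}

#' Nei (1978) unbiased genetic distance between populations
#'
#' `D = -log(I)` where the normalized identity `I` uses Nei's small-sample
#' bias correction: per locus, unbiased within-population identities
#' `(2n J - 1)/(2n - 1)` with `J = sum(p^2)`, arithmetic means over loci, and
#' `I = Jxy / sqrt(Jx Jy)`. Pairs with identity <= 0 (no shared alleles) get a
#' large finite sentinel (1e9) with a warning so downstream clustering stays
#' well-defined.
#'
#' @param data genotype tibble.
#' @return a labeled symmetric distance matrix.
#' @export
nei_distance <- function(data) {
  pops <- populations(data)
  if (length(pops) < 2L) abort("nei_distance needs at least two populations")
  freqs <- allele_frequencies(data)
  jx <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(j = sum(.data$freq^2), n_copies = .data$n_copies[1],
                     .groups = "drop") |>
    dplyr::mutate(j_unb = pmax((.data$n_copies * .data$j - 1) / (.data$n_copies - 1), 0))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  any_inf <- FALSE
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    fi <- dplyr::filter(freqs, .data$population == pops[i])
    fj <- dplyr::filter(freqs, .data$population == pops[j])
    shared_loci <- intersect(unique(fi$locus), unique(fj$locus))
    jxy <- vapply(shared_loci, function(loc) {
      a <- fi[fi$locus == loc, c("allele", "freq")]
      b <- fj[fj$locus == loc, c("allele", "freq")]
      mm <- merge(a, b, by = "allele")
      if (nrow(mm) == 0L) 0 else sum(mm$freq.x * mm$freq.y)
    }, numeric(1))
    jxm <- mean(jx$j_unb[jx$population == pops[i] & jx$locus %in% shared_loci])
    jym <- mean(jx$j_unb[jx$population == pops[j] & jx$locus %in% shared_loci])
    ident <- mean(jxy) / sqrt(jxm * jym)
    if (!is.finite(ident) || ident <= 0) {
      any_inf <- TRUE
      d <- 1e9
    } else {
      d <- max(-log(ident), 0)
    }
    m[i, j] <- m[j, i] <- d
  }
  if (any_inf) warn("zero genetic identity between some populations; distance set to 1e9 sentinel")
  m
}
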