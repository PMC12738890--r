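#' ABC summary statistics of a grouped SSR dataset
#'
#' The fixed named vector used as ABC features. Per group: `A` (mean observed
#' alleles per locus), `H` (mean genic diversity `1 - sum(p^2)`), `V` (mean
#' allele-size variance in repeat units), `M` (mean Garza-Williamson ratio,
#' alleles / (repeat-unit range + 1)). Per group pair: `FST` (pooled-pair
#' HT/HS estimator, ratio of locus sums), `DAS` (shared-allele distance,
#' `1 - sum(min(p1, p2))` averaged over loci, 0 for identical frequency
#' vectors) and `dmu2` (squared difference of mean allele size in repeat
#' units, averaged over loci).
#' Names carry 1-based group indices in the grouping's order, e.g. `A.1`,
#' `FST.1.2`.
#'
#' @param data genotype tibble.
#' @param grouping optional named character vector mapping population label to
#'   group label; defaults to one group per population.
#' @param motif repeat motif length in nt (default 2).
#' @return named numeric vector with attribute `groups` (labels in index
#'   order).
#' @export
summary_stats <- function(data, grouping = NULL, motif = 2L) {
  pops <- populations(data)
  if (is.null(grouping)) grouping <- setNames(pops, pops)
  missing_pops <- setdiff(pops, names(grouping))
  if (length(missing_pops)) {
    abort(paste0("grouping does not cover population(s): ",
                 paste(missing_pops, collapse = ", ")))
  }
  group_levels <- unique(unname(grouping[pops]))
  df <- data |>
    dplyr::mutate(group = factor(unname(grouping[as.character(.data$population)]),
                                 levels = group_levels)) |>
    dplyr::filter(!is.na(.data$allele_1))

  dropped <- tidyr::expand_grid(group = factor(group_levels, levels = group_levels),
                                locus = factor(loci(data), levels = loci(data))) |>
    dplyr::anti_join(dplyr::distinct(df, .data$group, .data$locus),
                     by = c("group", "locus"))
  if (nrow(dropped) > 0L) {
    warn(paste0("locus with no observed calls in a group dropped from means: ",
                paste(unique(as.character(dropped$locus)), collapse = ", ")))
    df <- dplyr::filter(df, !(.data$locus %in% dropped$locus))
  }

  long <- df |>
    tidyr::pivot_longer(c("allele_1", "allele_2"),
                        names_to = NULL, values_to = "allele")
  per_gl <- long |>
    dplyr::group_by(.data$group, .data$locus) |>
    dplyr::summarise(
      A = dplyr::n_distinct(.data$allele),
      H = 1 - sum((table(.data$allele) / dplyr::n())^2),
      V = var(.data$allele / motif),
      M = dplyr::n_distinct(.data$allele) /
        (floor((max(.data$allele) - min(.data$allele)) / motif) + 1),
      mean_rep = mean(.data$allele) / motif,
      .groups = "drop"
    )
  per_group <- per_gl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(c("A", "H", "V", "M"), mean), .groups = "drop")

  ng <- length(group_levels)
  stats <- c()
  for (s in c("A", "H", "V", "M")) {
    v <- per_group[[s]]
    names(v) <- paste0(s, ".", seq_len(ng))
    stats <- c(stats, v)
  }

  if (ng >= 2L) {
    pairs <- utils::combn(seq_len(ng), 2L)
    fst <- das <- dmu2 <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      g1 <- group_levels[pairs[1, j]]
      g2 <- group_levels[pairs[2, j]]
      sub1 <- dplyr::filter(long, .data$group == g1)
      sub2 <- dplyr::filter(long, .data$group == g2)
      shared_loci <- intersect(unique(sub1$locus), unique(sub2$locus))
      sum_ht <- sum_hs <- das_acc <- dmu_acc <- 0
      for (loc in shared_loci) {
        al1 <- sub1$allele[sub1$locus == loc]
        al2 <- sub2$allele[sub2$locus == loc]
        p1 <- table(al1) / length(al1)
        p2 <- table(al2) / length(al2)
        pool <- unique(c(names(p1), names(p2)))
        pbar <- (ifelse(pool %in% names(p1), p1[pool], 0) +
                 ifelse(pool %in% names(p2), p2[pool], 0)) / 2
        sum_ht <- sum_ht + (1 - sum(pbar^2))
        sum_hs <- sum_hs + (1 - sum(p1^2) + 1 - sum(p2^2)) / 2
        dmu_acc <- dmu_acc + (mean(al1) / motif - mean(al2) / motif)^2
        q1 <- ifelse(pool %in% names(p1), p1[pool], 0)
        q2 <- ifelse(pool %in% names(p2), p2[pool], 0)
        das_acc <- das_acc + (1 - sum(pmin(q1, q2)))
      }
      nl <- length(shared_loci)
      fst[j] <- if (sum_ht > 0) (sum_ht - sum_hs) / sum_ht else 0
      das[j] <- das_acc / nl
      dmu2[j] <- dmu_acc / nl
    }
    tags <- paste0(pairs[1, ], ".", pairs[2, ])
    stats <- c(stats, setNames(fst, paste0("FST.", tags)),
               setNames(das, paste0("DAS.", tags)),
               setNames(dmu2, paste0("dmu2.", tags)))
  }
  attr(stats, "groups") <- group_levels
  stats
}

#' Build an ABC reference table by simulating from the priors
#'
#' For each draw: sample scenario parameters from the priors, a mutation
#' model from its hyperpriors, simulate a dataset of the configured shape
#' through the coalescent engine, and record the summary-statistic vector.
#' Statistics are computed through the compiled fast path (identical to
#' [summary_stats()] on complete data, which tests assert).
#'
#' @param scenario `ssr_scenario` or id.
#' @param n_draws number of simulations.
#' @param sample_sizes diploid individuals per group (length 4).
#' @param n_loci number of loci.
#' @param seed RNG seed.
#' @param mut optional fixed `ssr_mutmodel` applied to every draw; the default
#'   (NULL) draws a fresh mutation model from the hyperpriors per simulation.
#' @return tibble: `scenario`, the parameter columns, the mutation-model means
#'   (`mu_mean`, `p_mean`, `sni_mean`), then the summary statistics.
#' @export
build_reference_table <- function(scenario, n_draws, sample_sizes, n_loci, seed,
                                  mut = NULL) {
  if (!inherits(scenario, "ssr_scenario")) scenario <- demographic_scenario(scenario)
  params <- sample_priors(scenario, n_draws, seed = seed)
  sampled <- sample_sizes > 0
  group_idx <- rep(seq_along(sample_sizes)[sampled],
                   times = 2L * sample_sizes[sampled])
  n_groups <- sum(sampled)
  # compact to sampled groups for the statistic path
  group_idx <- as.integer(factor(group_idx))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n_draws))
  rows <- vector("list", n_draws)
  mut_means <- matrix(0, n_draws, 3L,
                      dimnames = list(NULL, c("mu_mean", "p_mean", "sni_mean")))
  fixed_mut <- mut
  for (i in seq_len(n_draws)) {
    mut_i <- fixed_mut %||% sample_mutation_model(n_loci, seed = seeds[2L * i - 1L])
    mut_means[i, ] <- c(mut_i$mu_mean, mut_i$p_mean, mut_i$sni_mean)
    p <- params[i, ]
    events <- scenario_events(scenario, p)
    res <- sim_coalescent_cpp(
      sample_sizes = as.integer(2L * sample_sizes),
      pop_sizes = as.numeric(c(p$N1, p$N2, p$N3, p$N4)),
      events = events,
      mu_l = mut_i$mu_l, p_l = mut_i$p_l, sni_l = mut_i$sni_l,
      motif = mut_i$motif, range_width = mut_i$range_width,
      founder_repeat = mut_i$founder_repeat, base_size = 100L,
      seed = seeds[2L * i]
    )
    rows[[i]] <- sumstats_cpp(res$alleles, group_idx, mut_i$motif, n_groups)
  }
  stats <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(scenario = scenario$id), params,
                   tibble::as_tibble(mut_means), stats)
}

#' Summary statistics of an observed dataset via the compiled fast path
#'
#' Applies the same statistic definitions as [build_reference_table()] to an
#' observed genotype tibble (complete data only).
#'
#' @inheritParams summary_stats
#' @return named numeric vector.
#' @export
observed_stats <- function(data, grouping = NULL, motif = 2L) {
  if (anyNA(data$allele_1)) {
    return(summary_stats(data, grouping, motif))  # R path handles missing
  }
  pops <- populations(data)
  if (is.null(grouping)) grouping <- setNames(pops, pops)
  group_levels <- unique(unname(grouping[pops]))
  ord <- data |>
    dplyr::mutate(group = factor(unname(grouping[as.character(.data$population)]),
                                 levels = group_levels)) |>
    dplyr::arrange(.data$group, .data$individual, .data$locus)
  nl <- length(loci(data))
  a1 <- matrix(ord$allele_1, nrow = nl)
  a2 <- matrix(ord$allele_2, nrow = nl)
  n <- ncol(a1)
  alleles <- matrix(0L, 2L * n, nl)
  alleles[seq(1L, 2L * n, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * n, by = 2L), ] <- t(a2)
  grp <- as.integer(ord$group[seq(1L, by = nl, length.out = n)])
  out <- sumstats_cpp(alleles, rep(grp, each = 2L), as.integer(motif),
                      length(group_levels))
  attr(out, "groups") <- group_levels
  out
}
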