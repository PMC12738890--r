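#' Allele frequencies per population and locus
#'
#' Frequencies are computed over observed (non-missing) allele copies, so a
#' missing genotype removes two copies from the denominator. Loci where a
#' population has no observed calls are dropped (they carry no frequency
#' information).
#'
#' @param data genotype tibble.
#' @return tibble with columns `population`, `locus`, `allele`, `count`,
#'   `freq`, and `n_copies` (the denominator at that population x locus).
#' @export
allele_frequencies <- function(data) {
  long <- data |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    tidyr::pivot_longer(c("allele_1", "allele_2"),
                        names_to = NULL, values_to = "allele")
  long |>
    dplyr::count(.data$population, .data$locus, .data$allele, name = "count") |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::mutate(n_copies = sum(.data$count), freq = .data$count / .data$n_copies) |>
    dplyr::ungroup()
}

#' Inbreeding coefficient from observed and expected heterozygosity
#'
#' `FIS = (He - Ho) / He`; undefined (NA) when `He = 0` (monomorphic locus),
#' matching the convention of leaving monomorphic loci blank.
#'
#' @param ho,he observed and expected heterozygosity (vectorized).
#' @return numeric vector of FIS values.
#' @export
fis <- function(ho, he) {
  ifelse(he > 0, (he - ho) / he, NA_real_)
}

#' Per-locus, per-population diversity statistics
#'
#' For each population x locus: `Na` = number of observed alleles, `Ne` =
#' effective number of alleles `1 / sum(p^2)`, `I` = Shannon's information
#' index `-sum(p log p)`, `Ho` = fraction of non-missing genotypes with two
#' distinct alleles, `He` = expected heterozygosity `1 - sum(p^2)` (the biased
#' GenAlEx-style estimator; set `unbiased = TRUE` for `2n/(2n-1)` correction),
#' and `Fis = (He - Ho)/He` (NA at monomorphic loci).
#'
#' @param data genotype tibble.
#' @param unbiased use the small-sample-corrected He (default `FALSE`).
#' @return tibble with one row per population x locus.
#' @export
locus_diversity <- function(data, unbiased = FALSE) {
  freqs <- allele_frequencies(data)
  per_freq <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      Na = dplyr::n(),
      Ne = 1 / sum(.data$freq^2),
      I = -sum(.data$freq * log(.data$freq)),
      He = 1 - sum(.data$freq^2),
      n_copies = .data$n_copies[1],
      .groups = "drop"
    )
  if (unbiased) {
    per_freq <- per_freq |>
      dplyr::mutate(He = .data$He * .data$n_copies / (.data$n_copies - 1))
  }
  hobs <- data |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(Ho = mean(.data$allele_1 != .data$allele_2), .groups = "drop")
  per_freq |>
    dplyr::left_join(hobs, by = c("population", "locus")) |>
    dplyr::mutate(Fis = fis(.data$Ho, .data$He)) |>
    dplyr::select("population", "locus", "Na", "Ne", "I", "Ho", "He", "Fis", "n_copies")
}

#' Per-population diversity summary (means and standard errors across loci)
#'
#' Mirrors the usual "value +/- SE" diversity table: for each population, each
#' statistic is averaged over loci and its standard error is the across-locus
#' standard deviation divided by `sqrt(n_loci)`. The population-level FIS is
#' the mean of per-locus `(He - Ho)/He` with monomorphic loci excluded.
#'
#' @inheritParams locus_diversity
#' @param species optional named character vector mapping population label to
#'   species/group; when supplied a `species` column is added.
#' @return tibble with one row per population: `Na`, `Ne`, `I`, `Ho`, `He`,
#'   `Fis`, each paired with a `<stat>_se` column, plus `n_loci`.
#' @export
diversity_summary <- function(data, species = NULL, unbiased = FALSE) {
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(0)
    sd(x) / sqrt(length(x))
  }
  out <- locus_diversity(data, unbiased = unbiased) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      dplyr::across(c("Na", "Ne", "I", "Ho", "He", "Fis"),
                    list(mean = ~mean(.x, na.rm = TRUE), se = ~se(.x))),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~sub("_mean$", "", .x))
  if (!is.null(species)) {
    out <- out |>
      dplyr::mutate(species = unname(species[as.character(.data$population)]),
                    .after = "population")
  }
  out
}

#' Species-level means of a diversity summary
#'
#' Averages the per-population statistics within each species and reports the
#' standard error across populations, the layout of a per-species "Mean" row.
#'
#' @param summary output of [diversity_summary()] with a `species` column.
#' @return tibble with one row per species.
#' @export
species_means <- function(summary) {
  if (!"species" %in% names(summary)) {
    abort("summary must carry a `species` column (see diversity_summary(species = ...))")
  }
  se <- function(x) if (length(x) < 2L) 0 else sd(x) / sqrt(length(x))
  summary |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_populations = dplyr::n(),
      dplyr::across(c("Na", "Ne", "I", "Ho", "He"),
                    list(mean = ~mean(.x), se = ~se(.x))),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~sub("_mean$", "", .x))
}
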