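#' Build a genotype tibble from components
#'
#' The package represents a diploid SSR dataset as a long-format tibble with
#' one row per individual x locus and columns `individual`, `population`,
#' `locus`, `allele_1`, `allele_2`. Allele states are absolute fragment sizes
#' in nucleotides (positive integers); a missing genotype has `NA` in both
#' allele columns. `population` and `locus` are factors whose level order is
#' the dataset's population / locus order; every individual belongs to exactly
#' one population. Genotype pairs are unordered and stored sorted ascending.
#'
#' @param individual character vector of individual IDs.
#' @param population population label per row (one label per individual).
#' @param locus locus name per row.
#' @param allele_1,allele_2 integer allele sizes (nt); both `NA` when missing.
#' @param pop_levels,locus_levels optional explicit level orders.
#' @return a genotype tibble.
#' @export
genotype_tibble <- function(individual, population, locus, allele_1, allele_2,
                            pop_levels = NULL, locus_levels = NULL) {
  if (is.null(pop_levels)) pop_levels <- unique(as.character(population))
  if (is.null(locus_levels)) locus_levels <- unique(as.character(locus))
  a1 <- as.integer(allele_1)
  a2 <- as.integer(allele_2)
  if (any(xor(is.na(a1), is.na(a2)))) {
    abort("half-missing genotypes are not representable: both alleles must be NA or neither")
  }
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  ok <- !is.na(lo)
  if (any(lo[ok] <= 0L)) abort("allele states must be positive integers (fragment sizes in nt)")
  out <- tibble::tibble(
    individual = as.character(individual),
    population = factor(as.character(population), levels = pop_levels),
    locus = factor(as.character(locus), levels = locus_levels),
    allele_1 = lo,
    allele_2 = hi
  )
  multi <- out |>
    dplyr::distinct(.data$individual, .data$population) |>
    dplyr::count(.data$individual) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    abort(paste0("individual(s) assigned to more than one population: ",
                 paste(multi$individual, collapse = ", ")))
  }
  # canonical row order, so datasets built in any order compare equal
  dplyr::arrange(out, .data$population, .data$individual, .data$locus)
}

#' Locus names of a genotype tibble, in dataset order
#' @param data genotype tibble.
#' @return character vector.
#' @export
loci <- function(data) levels(data$locus)

#' Population labels of a genotype tibble, in dataset order
#' @param data genotype tibble.
#' @return character vector.
#' @export
populations <- function(data) levels(data$population)

#' Number of individuals in a genotype tibble
#' @param data genotype tibble.
#' @return integer count of distinct individuals.
#' @export
n_individuals <- function(data) dplyr::n_distinct(data$individual)

#' Per-population sample sizes
#' @param data genotype tibble.
#' @return tibble with `population` and `n`.
#' @export
population_sizes <- function(data) {
  data |>
    dplyr::distinct(.data$individual, .data$population) |>
    dplyr::count(.data$population, name = "n", .drop = FALSE)
}

#' Validate a genotype dataset
#'
#' Report-only check of dataset health: per-locus missing fractions,
#' per-population sample sizes (with a flag on degenerate N = 1 populations),
#' and monomorphic loci. The dataset is not modified and no default filtering
#' is applied.
#'
#' @param data genotype tibble.
#' @return a list of class `ssr_validation` with elements `n`, `per_locus`
#'   (tibble: locus, n_missing, missing_fraction, monomorphic), `per_population`
#'   (tibble: population, n, degenerate), and `warnings` (character).
#' @export
validate_genotypes <- function(data) {
  per_locus <- data |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_missing = sum(is.na(.data$allele_1)),
      missing_fraction = mean(is.na(.data$allele_1)),
      monomorphic = dplyr::n_distinct(c(.data$allele_1[!is.na(.data$allele_1)],
                                        .data$allele_2[!is.na(.data$allele_2)])) <= 1L,
      .groups = "drop"
    )
  per_pop <- population_sizes(data) |>
    dplyr::mutate(degenerate = .data$n <= 1L)
  warnings <- character()
  if (any(per_pop$degenerate)) {
    warnings <- c(warnings, paste0(
      "population(s) with N <= 1: ",
      paste(as.character(per_pop$population[per_pop$degenerate]), collapse = ", ")))
  }
  if (any(per_locus$monomorphic)) {
    warnings <- c(warnings, paste0(
      "monomorphic locus/loci: ",
      paste(as.character(per_locus$locus[per_locus$monomorphic]), collapse = ", ")))
  }
  structure(
    list(n = n_individuals(data), per_locus = per_locus,
         per_population = per_pop, warnings = warnings),
    class = "ssr_validation"
  )
}

#' @export
print.ssr_validation <- function(x, ...) {
  cat("SSR dataset validation: N =", x$n, "individuals,",
      nrow(x$per_locus), "loci,", nrow(x$per_population), "populations\n")
  cat("  total missing fraction:",
      format(sum(x$per_locus$n_missing) / (x$n * nrow(x$per_locus)), digits = 4), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
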