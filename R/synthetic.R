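#' Population specifications of the 11-site two-species study design
#'
#' Eight populations of the first species and three of the second, with the
#' published sample sizes (N = 242 in total). Coordinates and altitudes are
#' opaque metadata for this package and are not carried.
#'
#' @return tibble with `label`, `species`, `n`.
#' @export
study_population_specs <- function() {
  tibble::tibble(
    label = c("TS", "LU", "YDS", "ZS", "LS", "DGL", "MPS", "DXG",
              "HS", "MS", "TMS"),
    species = c(rep("T. amurensis", 8L), rep("T. japonica", 3L)),
    n = c(26L, 26L, 22L, 22L, 29L, 21L, 13L, 25L, 24L, 19L, 15L)
  )
}

#' Four-group map used by the demographic analysis
#'
#' Maps the 11 study populations to the four demographic groups: Pop1 =
#' Northeast sites (DGL, MPS, DXG), Pop2 = North sites (YDS, ZS), Pop3 =
#' Shandong sites (TS, LU, LS), Pop4 = the second species (HS, MS, TMS).
#'
#' @return named character vector population label -> group label.
#' @export
study_group_map <- function() {
  c(DGL = "Pop1", MPS = "Pop1", DXG = "Pop1",
    YDS = "Pop2", ZS = "Pop2",
    TS = "Pop3", LU = "Pop3", LS = "Pop3",
    HS = "Pop4", MS = "Pop4", TMS = "Pop4")
}

#' Build a per-population allele-frequency model
#'
#' @param freqs tibble with columns `population`, `locus`, `allele`, `freq`;
#'   each population x locus frequency vector must sum to 1 within 1e-12.
#' @param f named numeric vector of per-population inbreeding coefficients in
#'   \[0, 1\] (one f per population, constant across loci).
#' @return object of class `ssr_freqmodel`.
#' @export
frequency_model <- function(freqs, f) {
  sums <- freqs |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(s = sum(.data$freq), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-12)) {
    abort("each population x locus frequency vector must sum to 1 (within 1e-12)")
  }
  pops <- unique(as.character(freqs$population))
  if (!all(pops %in% names(f))) abort("f must name every population")
  if (any(f < 0 | f > 1)) abort("inbreeding coefficients must be in [0, 1]")
  structure(list(freqs = freqs, f = f), class = "ssr_freqmodel")
}

#' Sample diploid genotypes from an allele-frequency model
#'
#' Genotypes are drawn per population x locus under the inbreeding model:
#' with probability `f` the two allele copies are identical by descent (one
#' draw from the frequency vector), otherwise they are two independent draws.
#' This gives `P(homozygote ii) = p_i^2 + f p_i (1 - p_i)` and
#' `P(heterozygote ij) = 2 p_i p_j (1 - f)`, so the expected He is
#' `1 - sum(p^2)` regardless of `f` and the expected Ho is `(1 - f) He`.
#'
#' @param model an `ssr_freqmodel`.
#' @param pop_sizes named integer vector: diploid individuals per population.
#' @param seed RNG seed.
#' @return genotype tibble.
#' @export
sample_genotypes <- function(model, pop_sizes, seed) {
  freqs <- model$freqs
  pops <- names(pop_sizes)
  locs <- unique(as.character(freqs$locus))
  covered <- freqs |> dplyr::distinct(.data$population, .data$locus)
  need <- tidyr::expand_grid(population = pops, locus = locs)
  gap <- dplyr::anti_join(need, covered,
                          by = c("population", "locus"))
  if (nrow(gap)) abort("frequency model does not cover every population x locus")
  withr::with_seed(seed, {
    chunks <- list()
    idx <- 0L
    for (p in pops) {
      n <- pop_sizes[[p]]
      ids <- sprintf("%s_%03d", p, seq_len(n))
      fp <- model$f[[p]]
      for (loc in locs) {
        fv <- freqs |> dplyr::filter(.data$population == p, .data$locus == loc)
        ibd <- runif(n) < fp
        draw <- function(k) fv$allele[sample.int(nrow(fv), k, replace = TRUE,
                                                 prob = fv$freq)]
        a1 <- draw(n)
        a2 <- ifelse(ibd, a1, draw(n))
        idx <- idx + 1L
        chunks[[idx]] <- tibble::tibble(individual = ids, population = p,
                                        locus = loc, allele_1 = a1, allele_2 = a2)
      }
    }
    all <- dplyr::bind_rows(chunks)
    genotype_tibble(all$individual, all$population, all$locus,
                    all$allele_1, all$allele_2,
                    pop_levels = pops, locus_levels = locs)
  })
}

#' Generate the study-shaped synthetic fixture
#'
#' An 11-population, 15-locus diploid SSR dataset with the published sample
#' sizes (N = 242) and two internally-similar species clusters. Per locus,
#' each species gets an independent Dirichlet-drawn base frequency vector over
#' 6-8 alleles (a dinucleotide ladder), and each population's frequencies are
#' drawn from a Dirichlet concentrated around its species base, so
#' between-species differentiation exceeds within-species differentiation by
#' construction. Per-population inbreeding coefficients are drawn uniformly
#' from \[0, 0.2\], spanning the heterozygote deficits typical of outcrossing
#' trees. A pure function of the seed.
#'
#' @param seed RNG seed (mandatory).
#' @param n_loci number of loci (default 15).
#' @param specs population specs tibble (default [study_population_specs()]).
#' @param concentration within-species Dirichlet concentration (default 60;
#'   larger = more similar populations within a species).
#' @return genotype tibble.
#' @export
make_study_fixture <- function(seed, n_loci = 15L,
                               specs = study_population_specs(),
                               concentration = 60) {
  withr::with_seed(seed, {
    species <- unique(specs$species)
    locs <- sprintf("L%02d", seq_len(n_loci))
    rdirichlet <- function(alpha) {
      g <- rgamma(length(alpha), shape = alpha)
      g / sum(g)
    }
    freq_rows <- list()
    i <- 0L
    for (loc in locs) {
      n_alleles <- sample(6:8, 1L)
      ladder <- 100L + 2L * (seq_len(n_alleles) - 1L) + 2L * sample(0:20, 1L)
      base <- lapply(species, function(s) rdirichlet(rep(0.8, n_alleles)))
      names(base) <- species
      for (r in seq_len(nrow(specs))) {
        p <- rdirichlet(concentration * base[[specs$species[r]]] + 1e-3)
        p <- p / sum(p)
        i <- i + 1L
        freq_rows[[i]] <- tibble::tibble(population = specs$label[r],
                                         locus = loc, allele = ladder, freq = p)
      }
    }
    f <- setNames(runif(nrow(specs), 0, 0.2), specs$label)
    model <- frequency_model(dplyr::bind_rows(freq_rows), f)
    sample_genotypes(model, setNames(specs$n, specs$label),
                     seed = sample.int(.Machine$integer.max - 1L, 1L))
  })
}
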