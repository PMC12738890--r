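#' One generalized-stepwise mutation step
#'
#' Signed repeat-count change of a GSM mutation: magnitude geometric on
#' {1, 2, ...} with `P(|step| = k) = (1 - p) p^(k-1)` and an equiprobable
#' sign. `p = 0` recovers the strict stepwise model (all steps +/-1).
#'
#' @param n number of steps to draw.
#' @param p geometric coefficient in \[0, 1).
#' @param seed RNG seed.
#' @return integer vector of signed steps.
#' @export
gsm_step <- function(n, p, seed) {
  if (p < 0 || p >= 1) abort("GSM coefficient p must be in [0, 1)")
  withr::with_seed(seed, {
    mag <- stats::rgeom(n, 1 - p) + 1L
    sgn <- sample(c(-1L, 1L), n, replace = TRUE)
    mag * sgn
  })
}

#' Simulate a diploid SSR dataset under a demographic scenario
#'
#' Backward-in-time coalescent per locus: within a group of diploid size `N`
#' each lineage pair coalesces at rate `1/(2N)` per generation
#' (continuous-time approximation); at scenario events lineages move between
#' groups (splits / admixture) and the ancestral size takes over. Mutations
#' are laid on the genealogy as a Poisson process with the per-locus rate:
#' GSM repeat steps on a bounded ladder of `range_width` contiguous states
#' centred on the founding allele, plus SNI events shifting the allele size by
#' +/-1 nt. Alleles are reported as total fragment sizes in nucleotides and
#' haploids are paired into diploid individuals.
#'
#' @param scenario `ssr_scenario` or id.
#' @param params one-row tibble of scenario parameters (see [sample_priors()]).
#' @param mut an `ssr_mutmodel`.
#' @param sample_sizes diploid individuals per group (length 4; zeros allowed
#'   for unsampled groups but not everywhere).
#' @param n_loci number of loci (must match `mut`).
#' @param seed RNG seed.
#' @return genotype tibble with populations `Pop1..Pop4` (sampled groups only)
#'   and attribute `tmrca` (per-locus time to the MRCA, in generations).
#' @export
simulate_coalescent <- function(scenario, params, mut, sample_sizes, n_loci, seed) {
  if (!inherits(scenario, "ssr_scenario")) scenario <- demographic_scenario(scenario)
  if (length(sample_sizes) != scenario$n_groups) {
    abort("sample_sizes must have one entry per group")
  }
  if (all(sample_sizes == 0)) abort("at least one group must be sampled")
  if (length(mut$mu_l) != n_loci) abort("mutation model does not cover n_loci loci")
  p <- as.list(params)
  events <- scenario_events(scenario, p)
  res <- sim_coalescent_cpp(
    sample_sizes = as.integer(2L * sample_sizes),
    pop_sizes = as.numeric(c(p$N1, p$N2, p$N3, p$N4)),
    events = events,
    mu_l = mut$mu_l, p_l = mut$p_l, sni_l = mut$sni_l,
    motif = mut$motif, range_width = mut$range_width,
    founder_repeat = mut$founder_repeat, base_size = 100L,
    seed = as.integer(seed %% .Machine$integer.max)
  )
  dataset_from_haploid(res$alleles, sample_sizes, tmrca = res$tmrca)
}

# shared assembly: haploid allele matrix (2 rows per individual, grouped) to
# a genotype tibble with populations Pop1..Pop<k>
dataset_from_haploid <- function(alleles, sample_sizes, tmrca = NULL,
                                 pop_labels = NULL) {
  n_loci <- ncol(alleles)
  k <- length(sample_sizes)
  if (is.null(pop_labels)) pop_labels <- paste0("Pop", seq_len(k))
  sampled <- sample_sizes > 0
  pop_per_ind <- rep(pop_labels[sampled], times = sample_sizes[sampled])
  n <- sum(sample_sizes)
  ids <- sprintf("ind_%03d", seq_len(n))
  locus_names <- sprintf("L%02d", seq_len(n_loci))
  a1 <- alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  out <- genotype_tibble(
    individual = rep(ids, each = n_loci),
    population = rep(pop_per_ind, each = n_loci),
    locus = rep(locus_names, times = n),
    allele_1 = as.vector(t(a1)),
    allele_2 = as.vector(t(a2)),
    pop_levels = pop_labels[sampled],
    locus_levels = locus_names
  )
  if (!is.null(tmrca)) attr(out, "tmrca") <- tmrca
  out
}

#' Simulate a dataset from a scenario with priors drawn on the fly
#'
#' Convenience wrapper: draws one parameter vector from the priors, one
#' mutation model from its hyperpriors, and simulates.
#'
#' @inheritParams simulate_coalescent
#' @param seed RNG seed (spawns distinct sub-seeds for priors, mutation model
#'   and the coalescent).
#' @return genotype tibble with attributes `params` and `tmrca`.
#' @export
simulate_dataset <- function(scenario, sample_sizes, n_loci, seed) {
  params <- sample_priors(scenario, 1L, seed = seed)
  mut <- sample_mutation_model(n_loci, seed = seed + 1L)
  out <- simulate_coalescent(scenario, params, mut, sample_sizes, n_loci,
                             seed = seed + 2L)
  attr(out, "params") <- params
  out
}
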