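# small genotype tibbles built in code, shared across test files

# two populations, two loci, fully scored
tiny_dataset <- function() {
  genotype_tibble(
    individual = rep(c("a1", "a2", "b1", "b2"), each = 2L),
    population = rep(c("A", "A", "B", "B"), each = 2L),
    locus = rep(c("L1", "L2"), times = 4L),
    allele_1 = c(180L, 100L, 180L, 100L, 182L, 102L, 182L, 102L),
    allele_2 = c(180L, 100L, 182L, 104L, 182L, 102L, 184L, 102L)
  )
}

# dataset with prescribed per-population allele frequencies at one locus,
# realized exactly by genotype counts
freq_dataset <- function(geno_a, geno_b) {
  n_a <- length(geno_a)
  n_b <- length(geno_b)
  genotype_tibble(
    individual = c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b))),
    population = c(rep("A", n_a), rep("B", n_b)),
    locus = "L1",
    allele_1 = vapply(c(geno_a, geno_b), `[[`, integer(1), 1L),
    allele_2 = vapply(c(geno_a, geno_b), `[[`, integer(1), 2L)
  )
}

# brute-force half-squared-Euclidean distance on allele-count vectors
oracle_genotypic_d2 <- function(g1, g2) {
  alphabet <- sort(unique(c(g1, g2)))
  count_vec <- function(g) vapply(alphabet, function(a) sum(g == a), numeric(1))
  sum((count_vec(g1) - count_vec(g2))^2) / 2
}
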