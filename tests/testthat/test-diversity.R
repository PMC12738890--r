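test_that("allele frequencies count observed copies, missing-aware", {
  # genotypes (180/180), (180/182): p(180) = 0.75
  d <- freq_dataset(list(c(180L, 180L), c(180L, 182L)), list(c(180L, 180L)))
  fr <- allele_frequencies(d)
  a <- dplyr::filter(fr, population == "A")
  expect_equal(a$freq[a$allele == 180], 0.75)
  expect_equal(a$freq[a$allele == 182], 0.25)
  expect_equal(dplyr::filter(fr, population == "B")$freq, 1)

  # one missing genotype of 3: denominator is 4 copies
  d2 <- genotype_tibble(
    individual = c("i1", "i2", "i3"), population = "A", locus = "L1",
    allele_1 = c(180L, 182L, NA), allele_2 = c(180L, 182L, NA)
  )
  fr2 <- allele_frequencies(d2)
  expect_equal(unique(fr2$n_copies), 4)
  expect_equal(fr2$freq, c(0.5, 0.5))
})

test_that("per-locus diversity matches hand-computed values", {
  # p = (0.5, 0.5) realized as AA, AB, BB, AB
  d <- freq_dataset(list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L)),
                    list(c(1L, 1L)))
  ld <- dplyr::filter(locus_diversity(d), population == "A")
  expect_equal(ld$Na, 2)
  expect_equal(ld$Ne, 2)
  expect_equal(ld$I, log(2))
  expect_equal(ld$He, 0.5)
  expect_equal(ld$Ho, 0.5)

  # monomorphic population
  lb <- dplyr::filter(locus_diversity(d), population == "B")
  expect_equal(lb$Na, 1)
  expect_equal(lb$Ne, 1)
  expect_equal(lb$I, 0)
  expect_equal(lb$He, 0)
  expect_true(is.na(lb$Fis))

  # p = (0.7, 0.2, 0.1): Ne = 1/0.54, I = -sum p log p, He = 0.46
  # realized over 10 individuals: 14 x allele1, 4 x allele2, 2 x allele3
  g <- list(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L),
            c(1L, 1L), c(1L, 1L), c(2L, 2L), c(2L, 2L), c(3L, 3L))
  d3 <- freq_dataset(g, list(c(1L, 1L)))
  l3 <- dplyr::filter(locus_diversity(d3), population == "A")
  expect_equal(l3$Ne, 1 / 0.54, tolerance = 1e-12)
  expect_equal(l3$Ne, 1.8519, tolerance = 1e-4)
  expect_equal(l3$I, -(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1)))
  expect_equal(l3$I, 0.8018, tolerance = 1e-4)
  expect_equal(l3$He, 0.46)
})

test_that("FIS is (He - Ho)/He, undefined at monomorphic loci", {
  expect_equal(fis(0.5, 0.5), 0)
  expect_equal(fis(0, 0.5), 1)
  expect_equal(fis(0.329, 0.458), (0.458 - 0.329) / 0.458)
  expect_equal(fis(0.329, 0.458), 0.2817, tolerance = 1e-3)
  expect_true(is.na(fis(0, 0)))
})

test_that("population summary averages over loci with SE = sd/sqrt(n_loci)", {
  # two loci engineered to He = 0.5 and Ho = 0.5 each -> SE 0 for He
  d <- genotype_tibble(
    individual = rep(c("i1", "i2", "i3", "i4"), each = 2L),
    population = "A",
    locus = rep(c("L1", "L2"), 4L),
    allele_1 = c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L),
    allele_2 = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L)
  )
  s <- diversity_summary(d)
  expect_equal(s$He, 0.5)
  expect_equal(s$He_se, 0)

  # monomorphic dataset: everything at its floor
  dm <- genotype_tibble(
    individual = rep(c("i1", "i2"), each = 2L), population = "A",
    locus = rep(c("L1", "L2"), 2L),
    allele_1 = 100L, allele_2 = 100L
  )
  sm <- diversity_summary(dm)
  expect_equal(sm$Na, 1)
  expect_equal(sm$Ne, 1)
  expect_equal(sm$I, 0)
  expect_equal(sm$Ho, 0)
  expect_equal(sm$He, 0)
  expect_equal(sm$Na_se, 0)

  # two-point SE: loci with He 0.4 and 0.6 give mean 0.5, SE 0.1
  two <- tibble::tibble(he = c(0.4, 0.6))
  expect_equal(sd(two$he) / sqrt(2), 0.1, tolerance = 1e-12)
  d2 <- genotype_tibble(
    individual = rep(sprintf("i%d", 1:5), each = 2L),
    population = "A",
    locus = rep(c("L1", "L2"), 5L),
    # L1: p = (0.8, 0.2) -> He = 0.32 ; L2: p = (0.5, 0.5) -> He = 0.5
    allele_1 = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L),
    allele_2 = c(1L, 1L, 1L, 2L, 1L, 2L, 1L, 2L, 2L, 2L)
  )
  s2 <- diversity_summary(d2)
  expect_equal(s2$He, mean(c(0.32, 0.5)))
  expect_equal(s2$He_se, sd(c(0.32, 0.5)) / sqrt(2))
})

test_that("per-locus identities hold over random frequency vectors", {
  withr::local_seed(7)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    p <- as.vector(rmultinom(1, 200, rep(1 / k, k))) / 200
    p <- p[p > 0]
    na <- length(p)
    ne <- 1 / sum(p^2)
    he <- 1 - sum(p^2)
    i_sh <- -sum(p * log(p))
    expect_lte(ne, na + 1e-12)
    expect_equal(he, 1 - 1 / ne)
    expect_gte(i_sh, log(ne) - 1e-12)
  }
  # equality of I and log(Ne) at uniform frequencies
  p <- rep(0.25, 4)
  expect_equal(-sum(p * log(p)), log(1 / sum(p^2)))
})

test_that("species means average population rows", {
  d <- make_study_fixture(seed = 3)
  sp <- study_population_specs()
  s <- diversity_summary(d, species = setNames(sp$species, sp$label))
  m <- species_means(s)
  expect_equal(nrow(m), 2L)
  first <- m$species[1]
  expect_equal(m$He[1], mean(s$He[s$species == first]))
})
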