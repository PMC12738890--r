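test_that("prior draws satisfy every support and ordering constraint", {
  for (sid in 1:3) {
    p <- sample_priors(sid, 10000, seed = 123)
    expect_equal(nrow(p), 10000L)
    sizes <- as.matrix(p[c("N1", "N2", "N3", "N4", "Nanc")])
    expect_true(all(sizes >= 10 & sizes <= 20000))
    expect_true(all(p$N1 >= p$Nanc & p$N2 >= p$Nanc &
                    p$N3 >= p$Nanc & p$N4 >= p$Nanc))
    times <- as.matrix(p[c("t1", "t2", "t3", "t4")])
    expect_true(all(times >= 10 & times <= 10000))
    if (sid == 3L) {
      expect_true(all(p$t1 <= p$t4))
    } else {
      expect_true(all(p$t1 <= p$t2 & p$t2 <= p$t3 & p$t3 <= p$t4))
    }
    if (sid == 2L) {
      expect_true(all(p$ra > 0 & p$ra < 1))
    } else {
      expect_true(all(is.na(p$ra)))
    }
  }
  expect_identical(sample_priors(1, 50, seed = 9), sample_priors(1, 50, seed = 9))
})

test_that("mutation-model hyperpriors respect their published ranges", {
  for (s in 1:5) {
    m <- sample_mutation_model(15, seed = s)
    expect_true(m$mu_mean >= 1e-4 && m$mu_mean <= 1e-3)
    expect_true(all(m$mu_l >= 1e-5 & m$mu_l <= 1e-2))
    expect_true(m$p_mean >= 0.1 && m$p_mean <= 0.3)
    expect_true(all(m$p_l >= 0.01 & m$p_l <= 0.9))
    expect_true(m$sni_mean >= 1e-8 && m$sni_mean <= 1e-4)
    expect_true(all(m$sni_l >= 1e-9 & m$sni_l <= 1e-3))
  }
})

test_that("GSM steps have geometric magnitudes and balanced signs", {
  s <- gsm_step(1e6, p = 0.3, seed = 1)
  m <- mean(abs(s))
  # E|step| = 1/(1-P); Var|step| = P/(1-P)^2
  se_abs <- sqrt(0.3 / 0.7^2 / 1e6)
  expect_lt(abs(m - 1 / 0.7), 3 * se_abs)
  se_sign <- sqrt(mean(s^2) / 1e6)
  expect_lt(abs(mean(s)), 3 * se_sign)
  s0 <- gsm_step(1e4, p = 0, seed = 2)
  expect_true(all(abs(s0) == 1L))
  expect_error(gsm_step(10, p = 1, seed = 1), "\\[0, 1\\)")
})

test_that("pairwise coalescence time averages 2N generations", {
  p <- tibble::tibble(N1 = 1000, N2 = 1000, N3 = 1000, N4 = 1000, Nanc = 1000,
                      t1 = 1e7, t2 = 1e7, t3 = 1e7, t4 = 1e7, ra = NA)
  mut <- fixed_mutation_model(5000, mu = 0)
  d <- simulate_coalescent(1, p, mut, c(1, 0, 0, 0), 5000, seed = 42)
  tm <- attr(d, "tmrca")
  # exponential with mean 2N: se = 2N / sqrt(reps)
  expect_lt(abs(mean(tm) - 2000), 3 * 2000 / sqrt(5000))
})

test_that("equilibrium heterozygosity matches the stepwise-model closed form", {
  # He = 1 - (1 + 2 theta)^(-1/2) under SMM, theta = 4 N mu
  n_loci <- 500
  mut <- fixed_mutation_model(n_loci, mu = 2.5e-4, p = 0)
  p <- tibble::tibble(N1 = 1000, N2 = 1, N3 = 1, N4 = 1, Nanc = 1000,
                      t1 = 1e6, t2 = 1e6, t3 = 1e6, t4 = 1e6, ra = NA)
  d <- simulate_coalescent(1, p, mut, c(25, 0, 0, 0), n_loci, seed = 7)
  ld <- locus_diversity(d)
  theta <- 4 * 1000 * 2.5e-4
  expected <- 1 - (1 + 2 * theta)^(-1 / 2)
  se <- sd(ld$He) / sqrt(n_loci)
  expect_lt(abs(mean(ld$He) - expected), 3 * se)
})

test_that("mean squared allele-size divergence grows as 2 mu t after a split", {
  mu <- 5e-4
  t_split <- 2000
  p <- tibble::tibble(N1 = 500, N2 = 500, N3 = 500, N4 = 500, Nanc = 500,
                      t1 = t_split, t2 = 9e5, t3 = 9.5e5, t4 = 1e6, ra = NA)
  reps <- 40
  withr::local_seed(31)
  v <- vapply(seq_len(reps), function(i) {
    mut <- fixed_mutation_model(20, mu = mu, p = 0)
    d <- simulate_coalescent(1, p, mut, c(0, 25, 25, 0), 20,
                             seed = sample.int(1e8, 1))
    unname(observed_stats(d)["dmu2.1.2"])
  }, numeric(1))
  se <- sd(v) / sqrt(reps)
  expect_lt(abs(mean(v) - 2 * mu * t_split), 3 * se)
})

test_that("the coalescent is scale invariant: doubling N and t preserves FST", {
  base <- tibble::tibble(N1 = 500, N2 = 500, N3 = 500, N4 = 500, Nanc = 500,
                         t1 = 500, t2 = 800, t3 = 1200, t4 = 2000, ra = NA)
  doubled <- dplyr::mutate(base, dplyr::across(dplyr::everything(), ~.x * 2))
  doubled$ra <- NA
  fst_sample <- function(pp, seeds) {
    vapply(seeds, function(s) {
      # mutation rate halved so theta and mu*t stay fixed under the rescaling
      mu <- if (pp$N1 == 500) 4e-4 else 2e-4
      mut <- fixed_mutation_model(10, mu = mu, p = 0)
      d <- simulate_coalescent(1, pp, mut, c(8, 8, 8, 8), 10, seed = s)
      unname(observed_stats(d)["FST.1.4"])
    }, numeric(1))
  }
  withr::local_seed(17)
  a <- fst_sample(base, sample.int(1e8, 120))
  b <- fst_sample(doubled, sample.int(1e8, 120))
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("no divergence means no differentiation; more time means more", {
  # scenario 3, equal sizes, tiny t1: FST ~ 0 within sampling error
  p0 <- tibble::tibble(N1 = 2000, N2 = 2000, N3 = 2000, N4 = 2000, Nanc = 2000,
                       t1 = 10, t2 = NA, t3 = NA, t4 = 10, ra = NA)
  mut <- fixed_mutation_model(30, mu = 5e-4, p = 0)
  d0 <- simulate_coalescent(3, p0, mut, c(10, 10, 10, 10), 30, seed = 5)
  s0 <- observed_stats(d0)
  fst0 <- s0[grep("^FST", names(s0))]
  expect_lt(max(abs(fst0)), 0.08)

  # scenario 1 with a large t3: Pop4-vs-rest FST exceeds the within-group FSTs
  p1 <- tibble::tibble(N1 = 2000, N2 = 2000, N3 = 2000, N4 = 2000, Nanc = 500,
                       t1 = 100, t2 = 200, t3 = 8000, t4 = 9000, ra = NA)
  withr::local_seed(23)
  wins <- 0L
  for (r in 1:10) {
    d1 <- simulate_coalescent(1, p1, mut, c(10, 10, 10, 10), 30,
                              seed = sample.int(1e8, 1))
    s1 <- observed_stats(d1)
    cross <- mean(s1[c("FST.1.4", "FST.2.4", "FST.3.4")])
    within <- mean(s1[c("FST.1.2", "FST.1.3", "FST.2.3")])
    wins <- wins + (cross > within)
  }
  expect_gte(wins, 9L)
})

test_that("scenario 2 with ra -> 1 collapses to the pure Pop2-ancestry topology", {
  # Under ra = 1 every Pop3 lineage moves to Pop2 at t1, which is exactly
  # scenario 1's t1 merge; the FST distribution across replicates must match.
  pars <- list(N1 = 1000, N2 = 1000, N3 = 1000, N4 = 1000, Nanc = 500,
               t1 = 300, t2 = 600, t3 = 3000, t4 = 5000)
  p2 <- tibble::as_tibble(c(pars, ra = 1 - 1e-12))
  p1 <- tibble::as_tibble(c(pars, ra = NA))
  mut <- fixed_mutation_model(5, mu = 5e-4, p = 0)
  withr::local_seed(13)
  fst <- function(scen, pp) {
    vapply(1:500, function(i) {
      d <- simulate_coalescent(scen, pp, mut, c(5, 5, 5, 5), 5,
                               seed = sample.int(1e8, 1))
      unname(observed_stats(d)["FST.2.3"])
    }, numeric(1))
  }
  a <- fst(2, p2)
  b <- fst(1, p1)
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulator rejects empty sampling and mismatched mutation models", {
  p <- sample_priors(1, 1, seed = 1)
  mut <- fixed_mutation_model(5, mu = 1e-4)
  expect_error(simulate_coalescent(1, p, mut, c(0, 0, 0, 0), 5, seed = 1),
               "at least one group")
  expect_error(simulate_coalescent(1, p, mut, c(2, 0, 0, 0), 10, seed = 1),
               "n_loci")
})
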