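test_that("PCoA handles degenerate and closed-form cases", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  res <- pcoa(z, n_axes = 2)
  expect_equal(res$n_axes, 0L)

  # 3 equidistant points: two equal positive eigenvalues, equilateral layout
  m <- matrix(1, 3, 3) - diag(3)
  dimnames(m) <- list(letters[1:3], letters[1:3])
  res3 <- pcoa(m, n_axes = 2)
  ev <- res3$eigenvalues[1:2]
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_gt(ev[1], 0)
  coords <- as.matrix(tidy(res3)[, c("axis1", "axis2")])
  pair_d <- as.matrix(dist(coords))
  expect_equal(unname(pair_d[lower.tri(pair_d)]), rep(1, 3), tolerance = 1e-9)
})

test_that("PCoA agrees with classical MDS on collinear points", {
  x <- c(0, 1, 2, 3)
  dm <- as.matrix(dist(x))
  dimnames(dm) <- list(paste0("p", 1:4), paste0("p", 1:4))
  res <- pcoa(dm, n_axes = 2)
  ax1 <- tidy(res)$axis1
  expect_true(all(order(ax1) == 1:4) || all(order(ax1) == 4:1))  # up to sign
  ref <- cmdscale(dm, k = 1)
  expect_equal(abs(ax1), abs(as.vector(ref)), tolerance = 1e-9)
  # a Euclidean-embeddable matrix has no meaningfully negative eigenvalues
  expect_gte(min(res$eigenvalues), -1e-9 * max(res$eigenvalues))
})

test_that("PCoA refuses asymmetric input", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(m), "symmetric")
})

test_that("UPGMA reproduces the textbook three-leaf tree", {
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(m)
  expect_equal(tr$newick, "((A:1.000000,B:1.000000):1.000000,C:2.000000);")
  m2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma(m2)$newick, "(A:1.500000,B:1.500000);")
})

test_that("UPGMA is ultrametric and deterministic under ties", {
  m <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(c("B", "A", "C"), c("B", "A", "C")))
  t1 <- upgma(m)$newick
  t2 <- upgma(m)$newick
  expect_equal(t1, t2)
  expect_match(t1, "\\(A:1.000000,B:1.000000\\)")  # lexicographic tie-break

  # UPGMA on cophenetic distances of an ultrametric tree recovers it exactly
  withr::local_seed(5)
  for (i in 1:5) {
    ref <- ape::rcoal(6)
    dm <- ape::cophenetic.phylo(ref)
    tr <- upgma(dm)
    dm_back <- ape::cophenetic.phylo(tr$phylo)
    expect_equal(dm_back[rownames(dm), colnames(dm)], dm, tolerance = 1e-5)
  }
})

test_that("UPGMA matches the phangorn reference implementation on random matrices", {
  skip_if_not_installed("phangorn")
  withr::local_seed(11)
  for (i in 1:5) {
    x <- matrix(rnorm(8 * 3), 8)
    dm <- as.matrix(dist(x))
    dimnames(dm) <- list(paste0("t", 1:8), paste0("t", 1:8))
    ours <- upgma(dm)$phylo
    ref <- phangorn::upgma(as.dist(dm))
    expect_equal(ape::cophenetic.phylo(ours)[paste0("t", 1:8), paste0("t", 1:8)],
                 ape::cophenetic.phylo(ref)[paste0("t", 1:8), paste0("t", 1:8)],
                 tolerance = 1e-5)
  }
})

test_that("delta-K reproduces the hand-worked series and its scale properties", {
  ll <- tidyr::expand_grid(K = 1:4, run = 1:3)
  means <- c(-100, -50, -45, -44)
  withr::local_seed(1)
  ll$logL <- means[ll$K] + rep(c(-1, 0, 1), times = 4)  # sd = 1 at every K
  res <- evanno_delta_k(ll)
  expect_equal(res$best_k, 2L)
  expect_equal(res$table$delta_k[res$table$K == 2], 45)
  expect_equal(res$table$delta_k[res$table$K == 3], 4)
  expect_true(is.na(res$table$delta_k[1]) && is.na(res$table$delta_k[4]))

  # linear means: zero second difference everywhere
  lin <- tidyr::expand_grid(K = 1:4, run = 1:2)
  lin$logL <- -10 * lin$K + rep(c(-1, 1), times = 4)
  expect_equal(evanno_delta_k(lin)$table$delta_k[2:3], c(0, 0))

  # doubling the sd halves delta-K; adding a constant changes nothing
  ll2 <- ll
  ll2$logL <- means[ll2$K] + 2 * rep(c(-1, 0, 1), times = 4)
  expect_equal(evanno_delta_k(ll2)$table$delta_k[2:3],
               res$table$delta_k[2:3] / 2)
  ll3 <- ll
  ll3$logL <- ll3$logL + 500
  expect_equal(evanno_delta_k(ll3)$table$delta_k, res$table$delta_k)
})

test_that("delta-K flags zero-sd and malformed inputs", {
  flat <- tidyr::expand_grid(K = 1:3, run = 1:2)
  flat$logL <- c(-100, -100, -50, -50, -45, -45)
  expect_warning(res <- evanno_delta_k(flat), "sd")
  expect_true(is.na(res$table$delta_k[2]))
  expect_error(evanno_delta_k(data.frame(K = c(1, 2), run = 1, logL = 1)),
               "3 consecutive")
  expect_error(evanno_delta_k(data.frame(K = c(1, 3, 5), run = 1, logL = 1)),
               "consecutive|replicate")
})
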