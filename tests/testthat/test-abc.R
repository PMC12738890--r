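make_ref <- function(n, seed, shift = 0) {
  withr::with_seed(seed, {
    tibble::tibble(
      s1 = rnorm(n) + shift, s2 = rnorm(n, sd = 2) + shift,
      s3 = runif(n), theta = exp(rnorm(n))
    )
  })
}

test_that("rejection keeps the nearest fraction and honors exact matches", {
  ref <- make_ref(500, 1)
  obs <- c(s1 = ref$s1[17], s2 = ref$s2[17], s3 = ref$s3[17])
  acc <- abc_reject(obs, ref, tolerance = 0.05)
  expect_equal(nrow(acc), 25L)
  expect_equal(acc$distance[1], 0)
  expect_equal(acc$theta[1], ref$theta[17])
  # tolerance 1 accepts everything
  expect_equal(nrow(abc_reject(obs, ref, 1)), 500L)
  # duplicating the table at halved tolerance reproduces the accepted set:
  # the 25 nearest of the doubled table are the 12 nearest originals twice
  # plus one copy of the 13th (ranking is invariant to the sd rescaling)
  acc2 <- abc_reject(obs, dplyr::bind_rows(ref, ref), tolerance = 0.025)
  expect_equal(sort(acc2$theta),
               sort(c(rep(acc$theta[1:12], 2), acc$theta[13])))
})

test_that("zero-variance statistics are excluded with a warning", {
  ref <- make_ref(100, 2)
  ref$s3 <- 1
  obs <- c(s1 = 0, s2 = 0, s3 = 1)
  expect_warning(acc <- abc_reject(obs, ref, 0.1), "zero-variance")
  expect_equal(nrow(acc), 10L)
})

test_that("indistinguishable scenarios split the posterior evenly and sum to 1", {
  refs <- list("1" = make_ref(400, 3), "2" = make_ref(400, 4))
  obs <- c(s1 = 0, s2 = 0, s3 = 0.5)
  res <- scenario_posterior_logistic(obs, refs, n_closest = 200, seed = 1)
  expect_equal(sum(res$table$posterior), 1, tolerance = 1e-6)
  expect_lt(max(abs(res$table$posterior - 0.5)), 0.2)
  expect_true(all(res$table$lower <= res$table$posterior + 1e-12))
  expect_true(all(res$table$upper >= res$table$posterior - 1e-12))
})

test_that("a separable scenario wins with high posterior", {
  refs <- list("1" = make_ref(400, 5, shift = 0), "2" = make_ref(400, 6, shift = 6))
  obs <- c(s1 = 0, s2 = 0, s3 = 0.5)
  # complete separation: the losing scenario drops out of the closest set
  expect_warning(
    res <- scenario_posterior_logistic(obs, refs, n_closest = 200, seed = 1),
    "probability 0")
  expect_equal(res$best_scenario, "1")
  expect_gt(res$table$posterior[1], 0.9)
  expect_equal(sum(res$table$posterior), 1, tolerance = 1e-6)
})

test_that("the in-package multinomial fit matches glmnet at matched shrinkage", {
  skip_if_not_installed("glmnet")
  withr::local_seed(8)
  n <- 300
  x <- cbind(rnorm(n), rnorm(n))
  lp <- 1.2 * x[, 1] - 0.8 * x[, 2]
  y <- factor(1 + rbinom(n, 1, plogis(lp)) + rbinom(n, 1, 0.15))
  fit <- ssrpop:::fit_multinom(x, y, ridge = 1e-4)
  pred <- ssrpop:::predict_multinom(fit, c(0.3, -0.2))
  g <- glmnet::glmnet(x, y, family = "multinomial", lambda = 1e-6, alpha = 0,
                      standardize = FALSE)
  pg <- drop(predict(g, matrix(c(0.3, -0.2), 1), type = "response"))
  expect_equal(unname(pred$probs), unname(pg), tolerance = 0.02)
})

test_that("local-linear adjustment is a no-op at the accepted-set centroid", {
  withr::local_seed(9)
  n <- 400
  ref <- tibble::tibble(s1 = rnorm(n), s2 = rnorm(n), theta = exp(rnorm(n)))
  obs <- c(s1 = 0, s2 = 0)
  acc <- abc_reject(obs, ref, 0.5)
  post <- adjust_parameters_loclinear(acc, "theta")
  raw_med <- median(acc$theta)
  # uncorrelated statistics: correction is noise-level only
  expect_equal(post$summary$median, raw_med, tolerance = 0.15 * raw_med)
})

test_that("adjustment recovers a linear signal and collapses degenerate posteriors", {
  withr::local_seed(10)
  n <- 600
  s1 <- rnorm(n)
  theta <- exp(1 + 0.9 * s1 + rnorm(n, sd = 0.05))
  ref <- tibble::tibble(s1 = s1, s2 = rnorm(n), theta = theta)
  obs <- c(s1 = 1.5, s2 = 0)
  acc <- abc_reject(obs, ref, 0.25)
  post <- adjust_parameters_loclinear(acc, "theta")
  expect_equal(post$summary$median, exp(1 + 0.9 * 1.5), tolerance = 0.1)
  # identical accepted parameters collapse to that value
  ref2 <- ref
  ref2$theta <- 7
  acc2 <- abc_reject(obs, ref2, 0.25)
  post2 <- suppressWarnings(adjust_parameters_loclinear(acc2, "theta"))
  expect_equal(unique(round(post2$samples$theta, 6)), 7)
  # collinear statistics make the design singular: fall back with a warning
  s <- rnorm(40)
  ref3 <- tibble::tibble(s1 = s, s2 = 2 * s, theta = exp(rnorm(40)))
  acc3 <- abc_reject(c(s1 = 0, s2 = 0), ref3, 1)
  expect_warning(adjust_parameters_loclinear(acc3, "theta"), "singular|unadjusted")
})

test_that("generation-to-calendar conversion matches the worked examples", {
  expect_equal(convert_generations(2090, 100), 209)
  expect_equal(convert_generations(4880, 100), 488)
  expect_equal(convert_generations(10, 100), 1)
  expect_equal(convert_generations(c(287, 416), 100), c(28.7, 41.6))
  expect_error(convert_generations(-5), "positive")
})

test_that("PCA model checking localizes the observed point correctly", {
  withr::local_seed(12)
  sim <- tibble::tibble(s1 = rnorm(2000), s2 = rnorm(2000), s3 = rnorm(2000))
  # observed at the simulated mean projects to the origin
  obs <- colMeans(sim)
  chk <- model_check_pca(setNames(as.numeric(obs), names(sim)), sim)
  expect_equal(chk$observed_coords, c(0, 0), tolerance = 0.1)
  # observed copied from a simulated row projects onto that row
  obs2 <- setNames(as.numeric(sim[5, ]), names(sim))
  chk2 <- model_check_pca(obs2, sim)
  expect_equal(chk2$observed_coords,
               as.numeric(as.matrix(chk2$simulated_coords)[5, ]),
               tolerance = 1e-8)
  # an outlier 10 reference-sd away sits beyond the 99th percentile radius
  obs3 <- c(s1 = 10, s2 = 0, s3 = 0)
  chk3 <- model_check_pca(obs3, sim)
  expect_gt(chk3$percentile_radius, 99)
})
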