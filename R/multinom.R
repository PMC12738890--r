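# Weighted multinomial logistic regression by Newton-Raphson, with the
# observed-information inverse kept for delta-method confidence intervals.
# Small, dense problems only (ABC scenario choice on a few hundred accepted
# simulations); a tiny ridge keeps the Hessian invertible under separation.
fit_multinom <- function(x, y, weights = NULL, ridge = 1e-6, max_iter = 50,
                         tol = 1e-8) {
  x <- cbind(1, as.matrix(x))
  n <- nrow(x)
  p <- ncol(x)
  y <- factor(y)
  k <- nlevels(y)
  if (k < 2L) abort("need at least two classes")
  if (is.null(weights)) weights <- rep(1, n)
  ymat <- matrix(0, n, k)
  ymat[cbind(seq_len(n), as.integer(y))] <- 1

  beta <- matrix(0, p, k - 1L)  # class 1 is the reference
  for (iter in seq_len(max_iter)) {
    eta <- x %*% beta
    expeta <- exp(cbind(0, eta) - apply(cbind(0, eta), 1, max))
    probs <- expeta / rowSums(expeta)
    grad <- numeric(p * (k - 1L))
    hess <- matrix(0, p * (k - 1L), p * (k - 1L))
    for (a in seq_len(k - 1L)) {
      ra <- ymat[, a + 1L] - probs[, a + 1L]
      grad[((a - 1L) * p + 1L):(a * p)] <- crossprod(x, weights * ra)
      for (b in seq_len(k - 1L)) {
        wab <- weights * probs[, a + 1L] * ((a == b) - probs[, b + 1L])
        hess[((a - 1L) * p + 1L):(a * p), ((b - 1L) * p + 1L):(b * p)] <-
          crossprod(x, x * wab)
      }
    }
    grad <- grad - ridge * as.vector(beta)
    hess <- hess + ridge * diag(p * (k - 1L))
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + matrix(step, p, k - 1L)
    if (max(abs(step)) < tol) break
  }
  eta <- x %*% beta
  expeta <- exp(cbind(0, eta) - apply(cbind(0, eta), 1, max))
  probs <- expeta / rowSums(expeta)
  # recompute observed information at the solution for the vcov
  hess <- matrix(0, p * (k - 1L), p * (k - 1L))
  for (a in seq_len(k - 1L)) {
    for (b in seq_len(k - 1L)) {
      wab <- weights * probs[, a + 1L] * ((a == b) - probs[, b + 1L])
      hess[((a - 1L) * p + 1L):(a * p), ((b - 1L) * p + 1L):(b * p)] <-
        crossprod(x, x * wab)
    }
  }
  hess <- hess + ridge * diag(p * (k - 1L))
  vcov <- tryCatch(solve(hess), error = function(e) {
    MASS_ginv(hess)
  })
  list(beta = beta, vcov = vcov, levels = levels(y), p = p, k = k)
}

# minimal Moore-Penrose fallback (avoids a MASS dependency for one edge case)
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# class probabilities (and delta-method SEs) of a fitted multinomial model at
# a single covariate vector x0 (without intercept)
predict_multinom <- function(fit, x0) {
  x0 <- c(1, x0)
  eta <- as.vector(t(fit$beta) %*% x0)
  expeta <- exp(c(0, eta) - max(c(0, eta)))
  probs <- expeta / sum(expeta)
  # gradient of p_k wrt vec(beta): dp_k/dbeta_aj = p_k (1[k=a+1] - p_{a+1}) x0_j
  k <- fit$k
  p <- fit$p
  se <- numeric(k)
  for (cls in seq_len(k)) {
    g <- numeric(p * (k - 1L))
    for (a in seq_len(k - 1L)) {
      g[((a - 1L) * p + 1L):(a * p)] <-
        probs[cls] * ((cls == a + 1L) - probs[a + 1L]) * x0
    }
    se[cls] <- sqrt(max(as.numeric(t(g) %*% fit$vcov %*% g), 0))
  }
  list(probs = setNames(probs, fit$levels), se = setNames(se, fit$levels))
}
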