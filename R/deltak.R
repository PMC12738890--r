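#' Evanno delta-K from STRUCTURE log-likelihoods
#'
#' Consumes a plain table of replicate STRUCTURE runs (the MCMC itself is an
#' external tool) and computes, per assumed cluster number K, the mean and
#' standard deviation of the log-likelihood over replicates, and for interior
#' K the Evanno statistic
#' `delta_K = |mean(L(K+1)) - 2 mean(L(K)) + mean(L(K-1))| / sd(L(K))`.
#' The supported cluster number is the K maximizing delta_K. K values where
#' the replicate standard deviation is zero get `NA` with a warning rather
#' than a silent infinity.
#'
#' @param logliks data frame with columns `K`, `run`, `logL` (a 3-column CSV
#'   of K, replicate id, log-likelihood).
#' @return object of class `ssr_deltak`: list with `table` (tibble: `K`,
#'   `n_runs`, `mean_logL`, `sd_logL`, `delta_k`) and `best_k`.
#' @export
#' @examples
#' ll <- tidyr::expand_grid(K = 1:4, run = 1:3)
#' ll$logL <- c(-100, -100, -100, -50, -51, -49, -45, -44, -46, -44, -45, -43)
#' evanno_delta_k(ll)
evanno_delta_k <- function(logliks) {
  logliks <- tibble::as_tibble(logliks)
  names(logliks)[match(tolower(names(logliks)), c("k", "run", "logl"))[!is.na(
    match(tolower(names(logliks)), c("k", "run", "logl")))]] <-
    c("K", "run", "logL")[stats::na.omit(match(tolower(names(logliks)), c("k", "run", "logl")))]
  if (!all(c("K", "logL") %in% names(logliks))) {
    abort("logliks must have columns K, run, logL")
  }
  tab <- logliks |>
    dplyr::group_by(K = as.integer(.data$K)) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     mean_logL = mean(.data$logL),
                     sd_logL = sd(.data$logL),
                     .groups = "drop") |>
    dplyr::arrange(.data$K)
  if (nrow(tab) < 3L) abort("delta-K needs at least 3 consecutive K values")
  if (any(diff(tab$K) != 1L)) abort("K values must be consecutive")
  if (any(tab$n_runs < 2L)) abort("delta-K needs >= 2 replicate runs per K")
  m <- tab$mean_logL
  second_diff <- c(NA, abs(m[-c(1, 2)] - 2 * m[-c(1, nrow(tab))] + m[-c(nrow(tab) - 1, nrow(tab))]), NA)
  delta_k <- second_diff / tab$sd_logL
  zero_sd <- !is.na(second_diff) & tab$sd_logL == 0
  if (any(zero_sd)) {
    warn(paste0("sd of log-likelihood is 0 at K = ",
                paste(tab$K[zero_sd], collapse = ", "), "; delta-K undefined there"))
    delta_k[zero_sd] <- NA_real_
  }
  tab$delta_k <- delta_k
  best_k <- if (all(is.na(delta_k))) NA_integer_ else tab$K[which.max(delta_k)]
  structure(list(table = tab, best_k = best_k), class = "ssr_deltak")
}

#' @export
print.ssr_deltak <- function(x, ...) {
  print(as.data.frame(x$table), row.names = FALSE)
  cat("best K =", x$best_k, "\n")
  invisible(x)
}

#' @export
tidy.ssr_deltak <- function(x, ...) x$table

#' @export
autoplot.ssr_deltak <- function(object, ...) {
  tab <- dplyr::filter(object$table, !is.na(.data$delta_k))
  ggplot2::ggplot(tab, ggplot2::aes(.data$K, .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K),
                  title = "Evanno delta-K") +
    ggplot2::theme_minimal()
}
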