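#' ABC rejection step
#'
#' Ranks reference-table simulations by Euclidean distance to the observed
#' summary-statistic vector, with every statistic standardized by its
#' reference-table standard deviation, and keeps the closest
#' `ceiling(tolerance * n)` rows. Zero-variance statistics are excluded from
#' the distance with a warning.
#'
#' @param observed named numeric vector of summary statistics.
#' @param reference tibble containing (at least) the columns named in
#'   `observed`; extra columns (parameters, scenario ids) are carried along.
#' @param tolerance accepted fraction in (0, 1].
#' @return tibble of accepted rows sorted by distance, with a `distance`
#'   column and attributes `stat_cols`, `stat_sd`, `observed`.
#' @export
abc_reject <- function(observed, reference, tolerance) {
  if (nrow(reference) == 0L) abort("reference table is empty")
  if (tolerance <= 0 || tolerance > 1) abort("tolerance must be in (0, 1]")
  stat_cols <- names(observed)
  missing_cols <- setdiff(stat_cols, names(reference))
  if (length(missing_cols)) {
    abort(paste0("reference table lacks statistic column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ref_stats <- as.matrix(reference[stat_cols])
  sds <- apply(ref_stats, 2L, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warn(paste0("zero-variance statistic(s) excluded from distance: ",
                paste(stat_cols[!keep], collapse = ", ")))
  }
  z <- sweep(ref_stats[, keep, drop = FALSE], 2L, observed[keep], "-")
  z <- sweep(z, 2L, sds[keep], "/")
  distance <- sqrt(rowSums(z^2))
  n_accept <- ceiling(tolerance * nrow(reference))
  ord <- order(distance)[seq_len(n_accept)]
  out <- reference[ord, ]
  out$distance <- distance[ord]
  attr(out, "stat_cols") <- stat_cols
  attr(out, "stat_sd") <- sds
  attr(out, "observed") <- observed
  out
}

#' Scenario posterior probabilities by multinomial logistic regression
#'
#' Pools the per-scenario reference tables, standardizes the statistics by
#' the pooled standard deviation, keeps the `n_closest` simulations nearest to
#' the observed vector, and fits a multinomial logistic regression of the
#' scenario label on the centred statistics (Epanechnikov-weighted by
#' distance). Evaluating the fit at the observed point (the origin of the
#' centred covariates) gives the posterior probability of each scenario;
#' 95% confidence intervals come from the delta method on the fitted
#' coefficients, clipped to \[0, 1\]. A scenario absent from the closest set
#' is reported with probability 0 and a warning.
#'
#' @param observed named numeric vector of summary statistics.
#' @param references named list of per-scenario reference tibbles (each with a
#'   `scenario` column or named by scenario).
#' @param n_closest number of pooled simulations used for the regression.
#' @param seed RNG seed (reserved for tie-breaking reproducibility).
#' @param ridge ridge penalty on the standardized covariates (default 0.1); a
#'   weak shrinkage that keeps the fit finite when the closest simulations are
#'   completely separable by scenario, without materially biasing the
#'   probabilities.
#' @return object of class `ssr_abc_scenarios`: tibble `table` with
#'   `scenario`, `posterior`, `lower`, `upper`; plus `best_scenario`.
#' @export
scenario_posterior_logistic <- function(observed, references, n_closest, seed = 1,
                                        ridge = 0.1) {
  pooled <- dplyr::bind_rows(purrr::imap(references, function(tbl, nm) {
    if (!"scenario" %in% names(tbl)) tbl$scenario <- nm
    tbl
  }))
  if (dplyr::n_distinct(pooled$scenario) < 2L) {
    abort("scenario choice needs at least two scenarios")
  }
  if (n_closest > nrow(pooled)) abort("n_closest exceeds the pooled table size")
  accepted <- suppressWarnings(
    abc_reject(observed, pooled, tolerance = n_closest / nrow(pooled)))
  accepted <- accepted[seq_len(n_closest), ]
  scen_levels <- sort(unique(pooled$scenario))
  present <- sort(unique(accepted$scenario))
  if (length(present) < length(scen_levels)) {
    warn(paste0("scenario(s) absent from the closest set get probability 0: ",
                paste(setdiff(scen_levels, present), collapse = ", ")))
  }
  stat_cols <- attr(accepted, "stat_cols")
  sds <- attr(accepted, "stat_sd")
  keep <- sds > 0
  x <- sweep(as.matrix(accepted[stat_cols])[, keep, drop = FALSE], 2L,
             observed[keep], "-")
  x <- sweep(x, 2L, sds[keep], "/")
  dmax <- max(accepted$distance)
  w <- if (dmax > 0) 1 - (accepted$distance / dmax)^2 else rep(1, nrow(accepted))
  w <- pmax(w, 1e-8)

  if (length(present) >= 2L) {
    fit <- fit_multinom(x, factor(accepted$scenario, levels = present),
                        weights = w, ridge = ridge)
    pred <- predict_multinom(fit, rep(0, ncol(x)))
    probs <- setNames(rep(0, length(scen_levels)), scen_levels)
    ses <- setNames(rep(0, length(scen_levels)), scen_levels)
    probs[names(pred$probs)] <- pred$probs
    ses[names(pred$se)] <- pred$se
  } else {
    probs <- setNames(as.numeric(scen_levels == present), scen_levels)
    ses <- setNames(rep(0, length(scen_levels)), scen_levels)
  }
  table <- tibble::tibble(
    scenario = scen_levels,
    posterior = unname(probs),
    lower = pmax(unname(probs) - 1.96 * unname(ses), 0),
    upper = pmin(unname(probs) + 1.96 * unname(ses), 1)
  )
  structure(list(table = table,
                 best_scenario = scen_levels[which.max(probs)],
                 n_closest = n_closest),
            class = "ssr_abc_scenarios")
}

#' @export
print.ssr_abc_scenarios <- function(x, ...) {
  cat("ABC scenario choice (logistic regression on", x$n_closest, "closest simulations)\n")
  print(as.data.frame(x$table), row.names = FALSE)
  cat("best scenario:", x$best_scenario, "\n")
  invisible(x)
}

#' @export
tidy.ssr_abc_scenarios <- function(x, ...) x$table

#' @export
glance.ssr_abc_scenarios <- function(x, ...) {
  tibble::tibble(best_scenario = x$best_scenario,
                 best_posterior = max(x$table$posterior),
                 n_closest = x$n_closest)
}

#' Local-linear (Beaumont) adjustment of accepted ABC parameters
#'
#' Regresses each parameter on the standardized summary statistics over the
#' accepted simulations with Epanechnikov weights in the rejection distance,
#' and corrects each accepted draw to the observed point:
#' `theta_adj = theta - b' (s - s_obs)`. Size and time parameters are
#' log-transformed before the regression and back-transformed after. A
#' rank-deficient design falls back to the unadjusted rejection posterior
#' with a warning. Posterior summaries are Epanechnikov-weighted medians and
#' 2.5/97.5% quantiles.
#'
#' @param accepted output of [abc_reject()] (carries the observed vector and
#'   standardization attributes).
#' @param param_cols names of the parameter columns to adjust.
#' @param log_transform log-transform parameters before regression (default
#'   TRUE; applies to all `param_cols`, which must then be positive).
#' @return object of class `ssr_abc_posterior`: list with `samples` (tibble of
#'   adjusted draws plus `weight`) and `summary` (tibble: `parameter`,
#'   `median`, `q2.5`, `q97.5`).
#' @export
adjust_parameters_loclinear <- function(accepted, param_cols, log_transform = TRUE) {
  if (nrow(accepted) < 2L * length(param_cols)) {
    abort("need at least 2 x parameter-count accepted simulations")
  }
  stat_cols <- attr(accepted, "stat_cols")
  sds <- attr(accepted, "stat_sd")
  observed <- attr(accepted, "observed")
  if (is.null(stat_cols) || is.null(observed)) {
    abort("accepted must come from abc_reject() (missing attributes)")
  }
  keep <- sds > 0
  s <- sweep(as.matrix(accepted[stat_cols])[, keep, drop = FALSE], 2L,
             observed[keep], "-")
  s <- sweep(s, 2L, sds[keep], "/")
  dmax <- max(accepted$distance)
  w <- if (dmax > 0) 1 - (accepted$distance / dmax)^2 else rep(1, nrow(accepted))
  w <- pmax(w, 1e-8)
  x <- cbind(1, s)
  adjusted <- tibble::tibble(.rows = nrow(accepted))
  for (pc in param_cols) {
    y <- accepted[[pc]]
    ty <- if (log_transform) log(y) else y
    fit <- tryCatch(lm.wfit(x, ty, w), error = function(e) NULL)
    rank_ok <- !is.null(fit) && fit$rank == ncol(x)
    if (!rank_ok) {
      warn(paste0("singular design for parameter '", pc,
                  "': falling back to unadjusted rejection posterior"))
      adj <- ty
    } else {
      b <- fit$coefficients[-1]
      adj <- ty - as.vector(s %*% b)
    }
    adjusted[[pc]] <- if (log_transform) exp(adj) else adj
  }
  adjusted$weight <- w
  summary <- purrr::map_dfr(param_cols, function(pc) {
    q <- weighted_quantile(adjusted[[pc]], w, c(0.025, 0.5, 0.975))
    tibble::tibble(parameter = pc, median = q[2], q2.5 = q[1], q97.5 = q[3])
  })
  structure(list(samples = adjusted, summary = summary),
            class = "ssr_abc_posterior")
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' @export
print.ssr_abc_posterior <- function(x, ...) {
  cat("ABC adjusted parameter posterior (", nrow(x$samples), " draws)\n", sep = "")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.ssr_abc_posterior <- function(x, ...) x$summary

#' @export
autoplot.ssr_abc_posterior <- function(object, ...) {
  long <- object$samples |>
    dplyr::select(-"weight") |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(title = "Adjusted parameter posteriors") +
    ggplot2::theme_minimal()
}

#' Convert generations to calendar age
#'
#' `age_ka = t * generation_time / 1000` thousand years before present.
#'
#' @param t time in generations.
#' @param generation_time generation time in years (default 100, a
#'   conservative value for long-lived trees).
#' @return age in ka BP.
#' @export
#' @examples
#' convert_generations(2090)  # 209 ka BP
convert_generations <- function(t, generation_time = 100) {
  if (any(t <= 0)) abort("t must be positive")
  t * generation_time / 1000
}

#' PCA model checking of an ABC scenario
#'
#' Fits a PCA on the standardized simulated summary statistics and projects
#' the observed vector into the same space. The returned percentile radius is
#' the fraction of simulations whose distance from the origin (in the
#' retained components) is at most the observed point's; values near 100%
#' flag an observed dataset outside the simulated cloud. Constant statistics
#' are dropped before the PCA with a warning.
#'
#' @param observed named numeric vector of summary statistics.
#' @param simulated reference tibble of simulated statistics.
#' @param n_components number of principal components (default 2).
#' @return list with `observed_coords`, `simulated_coords` (tibble),
#'   `percent_variance`, and `percentile_radius`.
#' @export
model_check_pca <- function(observed, simulated, n_components = 2) {
  stat_cols <- names(observed)
  x <- as.matrix(simulated[stat_cols])
  if (nrow(x) < n_components) abort("need at least n_components simulated rows")
  sds <- apply(x, 2L, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warn(paste0("constant statistic(s) dropped before PCA: ",
                paste(stat_cols[!keep], collapse = ", ")))
  }
  x <- x[, keep, drop = FALSE]
  ctr <- colMeans(x)
  z <- sweep(sweep(x, 2L, ctr, "-"), 2L, sds[keep], "/")
  fit <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  sim_coords <- fit$x[, seq_len(k), drop = FALSE]
  obs_z <- (observed[keep] - ctr) / sds[keep]
  obs_coords <- as.vector(obs_z %*% fit$rotation[, seq_len(k), drop = FALSE])
  radii <- sqrt(rowSums(sim_coords^2))
  obs_radius <- sqrt(sum(obs_coords^2))
  list(
    observed_coords = obs_coords,
    simulated_coords = tibble::as_tibble(sim_coords, .name_repair = "minimal"),
    percent_variance = 100 * fit$sdev^2 / sum(fit$sdev^2),
    percentile_radius = 100 * mean(radii <= obs_radius)
  )
}
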