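#' Demographic scenarios for the four-group SSR analysis
#'
#' Three competing histories for four population groups (Pop1..Pop4) and an
#' ancestral population, described backwards in time:
#'
#' * **Scenario 1** (nested splits): Pop3 joins Pop2 at `t1`, Pop2 joins Pop1
#'   at `t2`, Pop1 joins Pop4 at `t3` (the two-species divergence), and the
#'   ancestral population takes size `Nanc` at `t4`.
#' * **Scenario 2** (admixture origin of Pop3): at `t1` each Pop3 lineage
#'   traces to Pop2 with probability `ra` and to Pop4 with probability
#'   `1 - ra`; Pop2 joins Pop1 at `t2`, Pop1 joins Pop4 at `t3`, ancestral
#'   size `Nanc` at `t4`.
#' * **Scenario 3** (simultaneous merge): all four groups merge at `t1`, where
#'   the ancestral size `Nanc` takes over immediately; `t4` is carried in the
#'   priors (with `t1 <= t4`) but triggers no further event by default.
#'
#' @param id scenario id: 1, 2 or 3.
#' @return object of class `ssr_scenario`.
#' @export
demographic_scenario <- function(id) {
  id <- as.integer(id)
  if (!id %in% 1:3) abort("scenario id must be 1, 2 or 3")
  structure(list(
    id = id,
    n_groups = 4L,
    groups = paste0("Pop", 1:4),
    has_admixture = id == 2L,
    time_symbols = if (id == 3L) c("t1", "t4") else c("t1", "t2", "t3", "t4")
  ), class = "ssr_scenario")
}

#' @export
print.ssr_scenario <- function(x, ...) {
  desc <- switch(x$id,
    "splits: Pop3->Pop2 (t1), Pop2->Pop1 (t2), Pop1->Pop4 (t3), Nanc at t4",
    "admixture: Pop3 from Pop2/Pop4 with rate ra (t1), Pop2->Pop1 (t2), Pop1->Pop4 (t3), Nanc at t4",
    "simultaneous merge of all groups at t1 (Nanc takes over)")
  cat("Scenario", x$id, "-", desc, "\n")
  invisible(x)
}

#' Draw demographic parameters from the uniform priors
#'
#' Effective sizes `N1..N4` and `Nanc` are uniform on \[10, 20000\] with the
#' constraint `Ni >= Nanc`; event times are uniform on \[10, 10000\] generations
#' with the ordering `t1 <= t2 <= t3 <= t4` (scenarios 1 and 2) or `t1 <= t4`
#' (scenario 3); the admixture proportion `ra` is uniform on (0, 1) for
#' scenario 2. Constraints are enforced by rejection.
#'
#' @param scenario an `ssr_scenario` or scenario id.
#' @param n_draws number of parameter draws.
#' @param seed RNG seed.
#' @param n_range,t_range prior supports for sizes and times.
#' @return tibble with columns `N1..N4`, `Nanc`, `t1..t4`, `ra` (NA outside
#'   scenario 2), one row per draw.
#' @export
sample_priors <- function(scenario, n_draws, seed,
                          n_range = c(10, 20000), t_range = c(10, 10000)) {
  if (!inherits(scenario, "ssr_scenario")) scenario <- demographic_scenario(scenario)
  if (n_draws < 1) abort("n_draws must be >= 1")
  withr::with_seed(seed, {
    out <- NULL
    tried <- 0L
    batch <- max(1000L, as.integer(n_draws * 2L))
    while (sum_rows(out) < n_draws) {
      tried <- tried + batch
      ns <- matrix(runif(batch * 5L, n_range[1], n_range[2]), ncol = 5L)
      ts <- matrix(runif(batch * 4L, t_range[1], t_range[2]), ncol = 4L)
      ok_n <- ns[, 1] >= ns[, 5] & ns[, 2] >= ns[, 5] &
              ns[, 3] >= ns[, 5] & ns[, 4] >= ns[, 5]
      ok_t <- if (scenario$id == 3L) {
        ts[, 1] <= ts[, 4]
      } else {
        ts[, 1] <= ts[, 2] & ts[, 2] <= ts[, 3] & ts[, 3] <= ts[, 4]
      }
      keep <- which(ok_n & ok_t)
      if (length(keep)) {
        chunk <- tibble::tibble(
          N1 = ns[keep, 1], N2 = ns[keep, 2], N3 = ns[keep, 3],
          N4 = ns[keep, 4], Nanc = ns[keep, 5],
          t1 = ts[keep, 1], t2 = ts[keep, 2], t3 = ts[keep, 3], t4 = ts[keep, 4],
          ra = if (scenario$has_admixture) runif(length(keep)) else NA_real_
        )
        out <- if (is.null(out)) chunk else dplyr::bind_rows(out, chunk)
      }
      if (tried >= 1e4 && sum_rows(out) / tried < 1e-4) {
        abort("prior acceptance rate below 1e-4: pathological constraint configuration")
      }
    }
    dplyr::slice_head(out, n = n_draws)
  })
}

sum_rows <- function(x) if (is.null(x)) 0L else nrow(x)

#' Backward-time event list for a scenario and one parameter draw
#'
#' Internal plumbing shared by the simulator: encodes the scenario's merges,
#' admixture and ancestral size change as a table the coalescent engine
#' consumes (type 1 = merge `from` into `to`, 2 = admixture split of `from`
#' into `to`/`to2` with probability `prob`, 3 = resize `from` to `size`).
#'
#' @param scenario `ssr_scenario` or id.
#' @param params one-row data frame (or list) of scenario parameters.
#' @return data frame of events ordered by time.
#' @export
scenario_events <- function(scenario, params) {
  if (!inherits(scenario, "ssr_scenario")) scenario <- demographic_scenario(scenario)
  p <- as.list(params)
  ev <- function(time, type, from, to = 1L, to2 = 1L, prob = 0, size = 0) {
    data.frame(time = time, type = type, from = from, to = to, to2 = to2,
               prob = prob, size = size)
  }
  events <- switch(scenario$id,
    rbind(ev(p$t1, 1L, 3L, 2L),
          ev(p$t2, 1L, 2L, 1L),
          ev(p$t3, 1L, 1L, 4L),
          ev(p$t4, 3L, 4L, size = p$Nanc)),
    rbind(ev(p$t1, 2L, 3L, 2L, 4L, prob = p$ra),
          ev(p$t2, 1L, 2L, 1L),
          ev(p$t3, 1L, 1L, 4L),
          ev(p$t4, 3L, 4L, size = p$Nanc)),
    rbind(ev(p$t1, 1L, 1L, 4L),
          ev(p$t1, 1L, 2L, 4L),
          ev(p$t1, 1L, 3L, 4L),
          ev(p$t1, 3L, 4L, size = p$Nanc))
  )
  events[order(events$time), , drop = FALSE]
}

#' Draw a mutation model from its hyperpriors
#'
#' The generalized stepwise model with single-nucleotide indels: the mean
#' microsatellite rate is uniform on \[1e-4, 1e-3\] per generation and
#' per-locus rates are Gamma-distributed (shape 2) around it, truncated to
#' \[1e-5, 1e-2\]; the mean geometric coefficient P is uniform on \[0.1, 0.3\]
#' with per-locus values Gamma(shape 2) truncated to \[0.01, 0.9\]; the mean
#' SNI rate is log-uniform on \[1e-8, 1e-4\] with per-locus values Gamma
#' (shape 2) truncated to \[1e-9, 1e-3\].
#'
#' @param n_loci number of loci.
#' @param seed RNG seed.
#' @param motif repeat motif length in nt (default 2).
#' @param range_width number of contiguous repeat states allowed (default 40).
#' @return object of class `ssr_mutmodel`: list with `mu_mean`, `mu_l`,
#'   `p_mean`, `p_l`, `sni_mean`, `sni_l`, `motif`, `range_width`,
#'   `founder_repeat`.
#' @export
sample_mutation_model <- function(n_loci, seed, motif = 2L, range_width = 40L) {
  trunc_gamma <- function(n, mean, lower, upper) {
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      draw <- rgamma(length(need), shape = 2, scale = mean / 2)
      ok <- draw >= lower & draw <= upper
      out[need[ok]] <- draw[ok]
      need <- need[!ok]
    }
    out
  }
  withr::with_seed(seed, {
    mu_mean <- runif(1, 1e-4, 1e-3)
    p_mean <- runif(1, 0.1, 0.3)
    sni_mean <- 10^runif(1, -8, -4)
    structure(list(
      mu_mean = mu_mean,
      mu_l = trunc_gamma(n_loci, mu_mean, 1e-5, 1e-2),
      p_mean = p_mean,
      p_l = trunc_gamma(n_loci, p_mean, 0.01, 0.9),
      sni_mean = sni_mean,
      sni_l = trunc_gamma(n_loci, sni_mean, 1e-9, 1e-3),
      motif = as.integer(motif),
      range_width = as.integer(range_width),
      founder_repeat = 20L
    ), class = "ssr_mutmodel")
  })
}

#' Fixed mutation model (no hyperprior draw)
#'
#' Convenience constructor for oracle tests and controlled simulations: every
#' locus gets the same rate and GSM coefficient.
#'
#' @param n_loci number of loci.
#' @param mu per-locus microsatellite mutation rate.
#' @param p GSM geometric coefficient (0 gives the strict stepwise model).
#' @param sni per-locus SNI rate.
#' @inheritParams sample_mutation_model
#' @return an `ssr_mutmodel`.
#' @export
fixed_mutation_model <- function(n_loci, mu, p = 0, sni = 0, motif = 2L,
                                 range_width = 40L) {
  structure(list(
    mu_mean = mu, mu_l = rep(mu, n_loci),
    p_mean = p, p_l = rep(p, n_loci),
    sni_mean = sni, sni_l = rep(sni, n_loci),
    motif = as.integer(motif), range_width = as.integer(range_width),
    founder_repeat = 20L
  ), class = "ssr_mutmodel")
}
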