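#' Run the full SSR analysis pipeline
#'
#' Orchestrates the whole analysis from a config: load (or synthesize) a
#' genotype dataset, validate it, compute the diversity summary, per-species
#' AMOVA and global FST/Nm, pairwise FST/Nm, Nei distance with PCoA and UPGMA,
#' optionally the Evanno delta-K over a supplied STRUCTURE log-likelihood
#' table, and optionally the coalescent-ABC demographic inference (reference
#' tables, scenario choice, parameter adjustment, calendar conversion). Every
#' stochastic stage gets a sub-seed derived deterministically from the master
#' seed, and all tables are written under `out_dir` together with a run
#' manifest.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   * `fixture`: list(seed) to synthesize the study-shaped dataset, or
#'     `input`: path to a GenAlEx CSV;
#'   * `n_permutations` (default 999), `estimator` ("nei" or "wc");
#'   * `species_map`: named vector population -> species (fixture default
#'     supplied automatically);
#'   * `group_map`: named vector population -> demographic group (fixture
#'     default [study_group_map()]); required for the ABC stage;
#'   * `loglik_file`: optional CSV (K, run, logL) for delta-K;
#'   * `abc`: optional list(n_draws, tolerance, n_closest, sample_sizes,
#'     n_loci, scenarios) switching the ABC stage on;
#'   * `generation_time` (years, default 100);
#'   * `out_dir`: output directory; `seed`: master seed.
#' @return object of class `ssr_report` (a named list of all stage outputs
#'   plus the manifest), invisibly writing CSV/Newick/JSON artifacts.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$seed)) abort("config$seed is required")
  if (is.null(cfg$out_dir)) abort("config$out_dir is required")
  gen_time <- cfg$generation_time %||% 100
  if (gen_time <= 0) abort("generation_time must be positive")
  n_perm <- cfg$n_permutations %||% 999
  estimator <- cfg$estimator %||% "nei"

  seed_for <- function(stage) {
    as.integer((as.numeric(cfg$seed) * 1009 + stage * 9973) %% 2147483646) + 1L
  }
  dir.create(file.path(cfg$out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "trees"), showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "abc"), showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    el <- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    timings[[name]] <<- el
    message(sprintf("[%s] done in %.2fs", name, el))
    out
  }

  data <- stage("load", {
    if (!is.null(cfg$input)) {
      read_genalex(cfg$input)
    } else if (!is.null(cfg$fixture)) {
      make_study_fixture(seed = cfg$fixture$seed %||% seed_for(1L))
    } else {
      abort("config needs either `input` or `fixture`")
    }
  })
  species_map <- cfg$species_map
  if (is.null(species_map) && all(populations(data) %in% study_population_specs()$label)) {
    sp <- study_population_specs()
    species_map <- setNames(sp$species, sp$label)
  }
  group_map <- cfg$group_map
  if (is.null(group_map) && all(populations(data) %in% names(study_group_map()))) {
    group_map <- study_group_map()
  }

  validation <- stage("validate", validate_genotypes(data))

  diversity <- stage("diversity", {
    out <- diversity_summary(data, species = species_map)
    write.csv(out, file.path(cfg$out_dir, "tables", "diversity.csv"),
              row.names = FALSE)
    if (!is.null(species_map)) {
      write.csv(species_means(out),
                file.path(cfg$out_dir, "tables", "diversity_species_means.csv"),
                row.names = FALSE)
    }
    out
  })

  amova_results <- stage("amova", {
    sets <- list(all = data)
    if (!is.null(species_map)) {
      for (sp in unique(unname(species_map))) {
        keep <- names(species_map)[species_map == sp]
        sets[[sp]] <- droplevels(dplyr::filter(data, .data$population %in% keep))
      }
    }
    res <- purrr::imap(sets, function(d, nm) {
      a <- amova(d, n_permutations = n_perm, seed = seed_for(2L))
      safe <- gsub("[^A-Za-z0-9]+", "_", nm)
      write.csv(tidy(a), file.path(cfg$out_dir, "tables",
                                   paste0("amova_", safe, ".csv")),
                row.names = FALSE)
      a
    })
    res
  })

  differentiation <- stage("fst", {
    pw <- pairwise_fst(data, estimator = estimator)
    m <- differentiation_matrix(pw)
    write.csv(m, file.path(cfg$out_dir, "tables", "fst_nm_matrix.csv"))
    global <- if (!is.null(species_map)) {
      purrr::map_dfr(unique(unname(species_map)), function(sp) {
        keep <- names(species_map)[species_map == sp]
        fst <- global_fst(droplevels(dplyr::filter(data, .data$population %in% keep)))
        tibble::tibble(species = sp, fst = fst,
                       nm = suppressWarnings(nm_from_fst(fst)))
      })
    } else {
      NULL
    }
    if (!is.null(global)) {
      write.csv(global, file.path(cfg$out_dir, "tables", "species_fst_nm.csv"),
                row.names = FALSE)
    }
    list(pairwise = pw, matrix = m, species = global)
  })

  nei <- stage("nei_distance", {
    m <- nei_distance(data)
    write.csv(m, file.path(cfg$out_dir, "tables", "nei_distance.csv"))
    m
  })

  ordination <- stage("pcoa", {
    res <- pcoa(nei)
    write.csv(tidy(res), file.path(cfg$out_dir, "tables", "pcoa_coords.csv"),
              row.names = FALSE)
    res
  })

  tree <- stage("upgma", {
    tr <- upgma(nei)
    write_newick(tr, file.path(cfg$out_dir, "trees", "upgma.nwk"))
    tr
  })

  deltak <- if (!is.null(cfg$loglik_file)) {
    stage("deltak", {
      dk <- evanno_delta_k(read.csv(cfg$loglik_file))
      write.csv(tidy(dk), file.path(cfg$out_dir, "tables", "deltak.csv"),
                row.names = FALSE)
      dk
    })
  } else {
    NULL
  }

  abc_block <- if (!is.null(cfg$abc)) {
    if (is.null(group_map)) abort("ABC stage requires a group_map")
    stage("abc", {
      run_abc_stage(data, group_map, cfg$abc, gen_time,
                    seed = seed_for(3L), out_dir = file.path(cfg$out_dir, "abc"))
    })
  } else {
    NULL
  }

  manifest <- list(
    seed = cfg$seed,
    stage_seeds = list(fixture = seed_for(1L), amova = seed_for(2L),
                       abc = seed_for(3L)),
    config = cfg[setdiff(names(cfg), c("species_map", "group_map"))],
    n_individuals = n_individuals(data),
    n_loci = length(loci(data)),
    timings = timings,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ssrpop")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(
    data = data, validation = validation, diversity = diversity,
    amova = amova_results, differentiation = differentiation,
    nei_distance = nei, pcoa = ordination, upgma = tree,
    deltak = deltak, abc = abc_block, manifest = manifest
  ), class = "ssr_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ABC stage: reference tables per scenario, scenario choice, local-linear
# parameter adjustment under the best scenario, calendar conversion.
run_abc_stage <- function(data, group_map, abc_cfg, gen_time, seed, out_dir) {
  scenarios <- abc_cfg$scenarios %||% 1:3
  n_draws <- abc_cfg$n_draws %||% 10000L
  tolerance <- abc_cfg$tolerance %||% 0.01
  n_loci <- abc_cfg$n_loci %||% length(loci(data))
  group_levels <- unique(unname(group_map[populations(data)]))
  sizes_tbl <- population_sizes(data) |>
    dplyr::mutate(group = unname(group_map[as.character(.data$population)])) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  default_sizes <- sizes_tbl$n[match(paste0("Pop", 1:4), sizes_tbl$group)]
  sample_sizes <- abc_cfg$sample_sizes %||% default_sizes
  n_closest <- abc_cfg$n_closest %||% ceiling(0.01 * n_draws * length(scenarios))

  observed <- observed_stats(data, grouping = group_map)
  refs <- purrr::map(scenarios, function(sid) {
    build_reference_table(sid, n_draws, sample_sizes, n_loci,
                          seed = seed + sid)
  })
  names(refs) <- as.character(scenarios)

  choice <- scenario_posterior_logistic(observed, refs, n_closest = n_closest,
                                        seed = seed)
  write.csv(tidy(choice), file.path(out_dir, "scenario_posteriors.csv"),
            row.names = FALSE)

  best <- choice$best_scenario
  best_ref <- refs[[as.character(best)]]
  param_cols <- c("N1", "N2", "N3", "N4", "Nanc",
                  if (as.integer(best) == 3L) c("t1", "t4") else c("t1", "t2", "t3", "t4"))
  accepted <- suppressWarnings(abc_reject(observed, best_ref, tolerance))
  posterior <- adjust_parameters_loclinear(accepted, param_cols)
  write.csv(tidy(posterior), file.path(out_dir, "parameters.csv"),
            row.names = FALSE)

  calendar <- posterior$summary |>
    dplyr::filter(grepl("^t", .data$parameter)) |>
    dplyr::mutate(dplyr::across(c("median", "q2.5", "q97.5"),
                                ~convert_generations(.x, gen_time),
                                .names = "{.col}_ka"))
  write.csv(calendar, file.path(out_dir, "calendar.csv"), row.names = FALSE)

  check <- model_check_pca(observed, best_ref)

  list(observed = observed, references = refs, scenario_choice = choice,
       posterior = posterior, calendar = calendar, model_check = check,
       sample_sizes = sample_sizes)
}

#' @export
print.ssr_report <- function(x, ...) {
  cat("SSR analysis report: N =", x$manifest$n_individuals,
      "individuals,", x$manifest$n_loci, "loci\n")
  cat("stages run:", paste(names(x$manifest$timings), collapse = ", "), "\n")
  if (!is.null(x$abc)) {
    cat("ABC best scenario:", x$abc$scenario_choice$best_scenario, "\n")
  }
  invisible(x)
}
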