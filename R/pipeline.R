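#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis from a single configuration: per-site
#' floral metrics, reproduction summaries and the focal-species filter,
#' piecewise causal-model fits (complete vs simplified, per response, at
#' community and species level), d-separation tests and AIC ranking,
#' cross-species meta-analysis of each simplified-model path, and the
#' Spearman correlations between the flower-richness effect and diet
#' generalization. Optionally writes a report bundle (CSV tables, per-model
#' JSON, claim-level log, reproducibility manifest) to `out_dir`.
#'
#' @param config A list (or path to a YAML file) with fields:
#' \describe{
#'   \item{input}{List of CSV paths `nests`, `sites`, `pollen` — mutually
#'     exclusive with `generator`. The sites table must carry a `stability`
#'     column (an extra column of the sites schema) or be accompanied by
#'     `weekly` (CSV of site/week/plant_species/count) to compute it.}
#'   \item{generator}{List of [generator_config()] overrides; synthetic data
#'     are generated instead of read.}
#'   \item{seed}{Integer seed, mandatory when any stochastic stage runs
#'     (generator, Simpson rarefaction, bootstrap).}
#'   \item{min_nests}{Focal-species filter threshold (default 30).}
#'   \item{aic_formula}{`"shipley_corrected"` (default), `"shipley"` or
#'     `"as_printed"`.}
#'   \item{K_rule}{Free-parameter counting rule for AIC, see
#'     [count_free_parameters()]. The pipeline default is `"edges"`: with
#'     the variance-inclusive count the small-sample correction is undefined
#'     for the complete model at 14 sites (n <= K + 1).}
#'   \item{bootstrap_reps}{Meta-analysis bootstrap replicates (default
#'     100000).}
#'   \item{simpson_reps}{Monte-Carlo replicates for rarefied Simpson
#'     (default 1000).}
#'   \item{diet_depth}{Rarefaction depth for diet indices (default: minimum
#'     pooled grains across focal species).}
#'   \item{out_dir}{Optional output directory for the report bundle.}
#' }
#' @return Object of class `bee_pipeline`: list with `data`, `focal_species`,
#'   `responses`, `fits`, `ranking`, `paths`, `meta`, `generalization`,
#'   `spearman`, `manifest`. Returned invisibly when `out_dir` is written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(
    list(input = NULL, generator = NULL, seed = NULL, min_nests = 30,
         aic_formula = "shipley_corrected", K_rule = "edges",
         bootstrap_reps = 1e5,
         simpson_reps = 1000, diet_depth = NULL, out_dir = NULL),
    config
  )
  if (is.null(cfg$input) == is.null(cfg$generator)) {
    abort("run_pipeline: exactly one of `input` or `generator` is required",
          class = "beesem_config_error")
  }
  if (is.null(cfg$seed)) {
    abort("run_pipeline: `seed` is mandatory (generator / rarefaction / bootstrap are stochastic)",
          class = "beesem_config_error")
  }
  stage <- "load data"
  res <- tryCatch(
    run_pipeline_impl(cfg, function(s) stage <<- s),
    error = function(e) {
      abort(paste0("pipeline failed at stage [", stage, "]: ",
                   conditionMessage(e)),
            class = "beesem_pipeline_error", parent = e)
    }
  )
  if (!is.null(cfg$out_dir)) write_report_bundle(res, cfg$out_dir)
  invisible(res)
}

run_pipeline_impl <- function(cfg, set_stage) {
  # --- data -----------------------------------------------------------
  if (!is.null(cfg$generator)) {
    set_stage("generate synthetic data")
    gcfg <- do.call(generator_config, cfg$generator)
    sim_sites <- generate_sites(gcfg, seed = cfg$seed)
    sim_nests <- generate_nests(gcfg, sim_sites$sites, seed = cfg$seed + 1)
    pollen <- generate_pollen(gcfg, sim_nests$records, seed = cfg$seed + 2)
    sites <- sim_sites$sites
    weekly <- sim_sites$weekly
    nests <- sim_nests$nests
  } else {
    set_stage("read input tables")
    nests <- read_bee_table(cfg$input$nests, "nests")
    sites <- read_bee_table(cfg$input$sites, "sites")
    pollen <- read_bee_table(cfg$input$pollen, "pollen")
    weekly <- if (!is.null(cfg$input$weekly)) {
      readr::read_csv(cfg$input$weekly, show_col_types = FALSE,
                      progress = FALSE)
    }
    if (!"stability" %in% names(sites)) {
      if (is.null(weekly)) {
        abort("sites table lacks `stability` and no weekly series given")
      }
      set_stage("floral metrics")
      fm <- floral_metrics(weekly)
      sites <- dplyr::left_join(
        sites, dplyr::select(fm, "site", "stability"), by = "site")
    }
  }

  # --- focal species and responses ------------------------------------
  set_stage("focal-species filter")
  focal <- filter_focal_species(nests, min_nests = cfg$min_nests)
  nests_focal <- dplyr::filter(nests, .data$bee_species %in% focal)

  set_stage("response tables")
  community <- nests_focal |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(total_cells = sum(.data$total_cells),
                     total_nests = sum(.data$total_nests),
                     .groups = "drop") |>
    dplyr::right_join(sites, by = "site") |>
    dplyr::mutate(total_cells = dplyr::coalesce(.data$total_cells, 0),
                  total_nests = dplyr::coalesce(.data$total_nests, 0L))

  species_data <- lapply(setNames(focal, focal), function(sp) {
    dplyr::left_join(
      sites,
      dplyr::filter(nests_focal, .data$bee_species == sp) |>
        dplyr::select("site", "mean_cells_per_nest", "total_cells",
                      "total_nests"),
      by = "site"
    ) |>
      dplyr::mutate(total_cells = dplyr::coalesce(.data$total_cells, 0),
                    total_nests = dplyr::coalesce(.data$total_nests, 0L))
  })

  # --- model fits ------------------------------------------------------
  set_stage("causal model fits")
  responses_comm <- c("total_cells", "total_nests")
  responses_sp <- c("mean_cells_per_nest", "total_cells", "total_nests")

  fit_pair <- function(data, response) {
    # mean-cells response: only sites where the species nested
    if (response == "mean_cells_per_nest") {
      data <- dplyr::filter(data, !is.na(.data$mean_cells_per_nest))
    }
    m1 <- model_complete(response)
    m2 <- model_simplified(response)
    fits <- list(complete = dsep_test(m1, data),
                 simplified = dsep_test(m2, data))
    list(
      fits = fits,
      ranking = rank_models(
        fits, formula = cfg$aic_formula,
        K = vapply(list(m1, m2), count_free_parameters, integer(1),
                   rule = cfg$K_rule)),
      paths = list(complete = path_coefficients(m1, data),
                   simplified = path_coefficients(m2, data))
    )
  }

  community_fits <- lapply(setNames(responses_comm, responses_comm),
                           function(r) fit_pair(community, r))
  species_fits <- lapply(species_data, function(d) {
    lapply(setNames(responses_sp, responses_sp),
           function(r) fit_pair(d, r))
  })

  # --- meta-analysis across species ------------------------------------
  set_stage("meta-analysis")
  meta_edges <- c("flower_richness_rarefied", "stability", "elevation")
  meta <- list()
  for (response in responses_sp) {
    for (from in meta_edges) {
      coefs <- purrr::map_dfr(focal, function(sp) {
        p <- species_fits[[sp]][[response]]$paths$simplified
        dplyr::filter(p, .data$from == !!from, .data$to == response) |>
          dplyr::mutate(bee_species = sp)
      })
      coefs <- dplyr::filter(coefs, abs(.data$estimate) < 1, .data$n > 3)
      if (nrow(coefs) >= 2) {
        meta[[paste(from, response, sep = " -> ")]] <-
          bootstrap_ci(coefs, B = cfg$bootstrap_reps,
                       seed = cfg$seed + 100 + length(meta))
      }
    }
  }

  # --- generalization --------------------------------------------------
  set_stage("diet generalization")
  pollen_focal <- dplyr::filter(pollen, .data$bee_species %in% focal)
  gen <- generalization_indices(pollen_focal, depth = cfg$diet_depth,
                                reps = cfg$simpson_reps,
                                seed = cfg$seed + 500)

  set_stage("generalization correlations")
  spearman <- purrr::map_dfr(responses_sp, function(response) {
    rich_effect <- purrr::map_dfr(focal, function(sp) {
      p <- species_fits[[sp]][[response]]$paths$simplified
      dplyr::filter(p, .data$from == "flower_richness_rarefied",
                    .data$to == response) |>
        dplyr::mutate(bee_species = sp)
    })
    joined <- dplyr::inner_join(rich_effect, gen, by = "bee_species")
    purrr::map_dfr(
      c(degree = "rarefied_degree", simpson = "rarefied_simpson"),
      function(col) {
        sc <- spearman_correlation(joined[[col]], joined$estimate)
        dplyr::mutate(sc, generalization_index = col, response = response,
                      .before = 1)
      })
  })

  # --- manifest --------------------------------------------------------
  cfg_nodir <- cfg[setdiff(names(cfg), "out_dir")]
  manifest <- list(
    package_version = as.character(utils::packageVersion("beesem")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_hash = rlang::hash(cfg_nodir),
    config = cfg_nodir,
    n_sites = nrow(sites),
    species_recorded = dplyr::n_distinct(nests$bee_species),
    focal_species = focal
  )

  structure(
    list(
      data = list(sites = sites, weekly = weekly, nests = nests,
                  pollen = pollen, community = community,
                  species = species_data),
      focal_species = focal,
      fits = list(community = community_fits, species = species_fits),
      meta = meta,
      generalization = gen,
      spearman = spearman,
      manifest = manifest
    ),
    class = "bee_pipeline"
  )
}

#' @export
print.bee_pipeline <- function(x, ...) {
  cat("<bee_pipeline> ", x$manifest$n_sites, " sites, ",
      x$manifest$species_recorded, " species recorded, ",
      length(x$focal_species), " focal\n", sep = "")
  invisible(x)
}

# table of every model's path coefficients, long format
path_table <- function(res) {
  comm <- purrr::imap_dfr(res$fits$community, function(f, response) {
    purrr::imap_dfr(f$paths, function(p, model) {
      dplyr::mutate(p, level = "community", bee_species = NA_character_,
                    response = response, model = model, .before = 1)
    })
  })
  sp <- purrr::imap_dfr(res$fits$species, function(by_resp, species) {
    purrr::imap_dfr(by_resp, function(f, response) {
      purrr::imap_dfr(f$paths, function(p, model) {
        dplyr::mutate(p, level = "species", bee_species = species,
                      response = response, model = model, .before = 1)
      })
    })
  })
  dplyr::bind_rows(comm, sp)
}

# claim-level d-separation log across all fitted models
claim_table <- function(res) {
  one <- function(f, ...) {
    dplyr::mutate(tidy(f), ..., C = f$C, model_p = f$p_value, .before = 1)
  }
  dplyr::bind_rows(
    purrr::imap_dfr(res$fits$community, function(f, response) {
      purrr::imap_dfr(f$fits, function(fit, model) {
        one(fit, level = "community", bee_species = NA_character_,
            response = response, model = model)
      })
    }),
    purrr::imap_dfr(res$fits$species, function(by_resp, species) {
      purrr::imap_dfr(by_resp, function(f, response) {
        purrr::imap_dfr(f$fits, function(fit, model) {
          one(fit, level = "species", bee_species = species,
              response = response, model = model)
        })
      })
    })
  )
}

# ranking table across all fitted models
ranking_table <- function(res) {
  dplyr::bind_rows(
    purrr::imap_dfr(res$fits$community, function(f, response) {
      dplyr::mutate(f$ranking, level = "community",
                    bee_species = NA_character_, response = response,
                    .before = 1)
    }),
    purrr::imap_dfr(res$fits$species, function(by_resp, species) {
      purrr::imap_dfr(by_resp, function(f, response) {
        dplyr::mutate(f$ranking, level = "species", bee_species = species,
                      response = response, .before = 1)
      })
    })
  )
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(path_table(res), file.path(out_dir,
                                              "path_coefficients.csv"))
  readr::write_csv(claim_table(res), file.path(out_dir, "dsep_claims.csv"))
  readr::write_csv(ranking_table(res), file.path(out_dir,
                                                 "model_ranking.csv"))
  readr::write_csv(res$generalization,
                   file.path(out_dir, "generalization_indices.csv"))
  readr::write_csv(res$spearman,
                   file.path(out_dir, "generalization_correlations.csv"))
  meta_tbl <- purrr::imap_dfr(res$meta, function(m, path) {
    dplyr::mutate(glance(m), path = path, .before = 1)
  })
  readr::write_csv(meta_tbl, file.path(out_dir, "meta_analysis.csv"))
  models_json <- purrr::imap(res$fits$community, function(f, response) {
    lapply(f$fits, function(fit) {
      c(as.list(glance(fit)), list(ranking = f$ranking))
    })
  })
  jsonlite::write_json(models_json, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(
    c("pipeline complete",
      paste0("seed=", res$manifest$seed),
      paste0("config_hash=", res$manifest$config_hash),
      paste0("focal_species=", paste(res$focal_species, collapse = ","))),
    file.path(out_dir, "pipeline.log")
  )
  invisible(out_dir)
}
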