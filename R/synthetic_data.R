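#' Configuration of the synthetic field-survey generator
#'
#' Bundles every knob of the synthetic data generator. The defaults emulate
#' the study conditions of the Monte desert survey: 14 sites along a
#' 1,100–1,500 m elevation gradient sampled weekly over one flowering
#' season, 7 focal cavity-nesting bee species, and site-level covariates
#' linked by a standardized linear causal model (elevation raises rarefied
#' flower richness, lowers flower abundance; richness lowers temporal
#' stability), with bee reproduction responding log-linearly to elevation,
#' richness and stability.
#'
#' @param n_sites Number of study sites.
#' @param elevation_range Elevation bounds, metres; sites are uniform on it.
#' @param fire_range Years since last fire, uniform bounds.
#' @param weeks Weekly sampling occasions per season.
#' @param n_bee_species Number of focal bee species.
#' @param site_model Tibble `from`, `to`, `coef`: standardized linear causal
#'   structure among site covariates.
#' @param richness_scale,abundance_scale,stability_scale Length-2 vectors
#'   `c(mean, sd)` mapping standardized covariates to natural units
#'   (rarefied species, flowers per season, inverse CV respectively).
#' @param n_plant_species Size of the flowering-plant pool.
#' @param base_nests Expected nests per species per site at average
#'   covariates.
#' @param nest_coefs Named vector: effects of standardized site covariates
#'   on the log nest rate.
#' @param base_cells_lambda Poisson mean of (cells per nest − 1) at average
#'   covariates; cells per nest are `1 + Poisson`, so at least one.
#' @param cell_coefs Named vector: effects of standardized site covariates
#'   on the log of that Poisson mean.
#' @param nb_size Optional negative-binomial size for overdispersed nest
#'   counts (`NULL` keeps Poisson).
#' @param grains_mean Mean pollen grains counted per bee individual.
#' @param diet_breadth Vector (length `n_bee_species`) of diet-breadth
#'   scales; plant-use weights decay geometrically with rank at this scale,
#'   so larger values mean more generalist diets.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    n_sites = 14,
    elevation_range = c(1100, 1500),
    fire_range = c(1, 40),
    weeks = 8,
    n_bee_species = 7,
    site_model = tibble(
      from = c("elevation", "elevation", "flower_richness_rarefied"),
      to = c("flower_richness_rarefied", "flower_abundance", "stability"),
      coef = c(0.39, -0.51, -0.54)
    ),
    richness_scale = c(mean = 10, sd = 2),
    abundance_scale = c(mean = 5000, sd = 1000),
    stability_scale = c(mean = 2, sd = 0.4),
    n_plant_species = 25,
    base_nests = 6,
    nest_coefs = c(elevation = -0.3, flower_richness_rarefied = 0.15,
                   stability = 0.15),
    base_cells_lambda = 2,
    cell_coefs = c(elevation = -0.1, flower_richness_rarefied = 0.1,
                   stability = -0.15),
    nb_size = NULL,
    grains_mean = 200,
    diet_breadth = seq(1, 8, length.out = n_bee_species)) {
  cfg <- list(
    n_sites = n_sites, elevation_range = elevation_range,
    fire_range = fire_range, weeks = weeks,
    n_bee_species = n_bee_species, site_model = site_model,
    richness_scale = richness_scale, abundance_scale = abundance_scale,
    stability_scale = stability_scale, n_plant_species = n_plant_species,
    base_nests = base_nests, nest_coefs = nest_coefs,
    base_cells_lambda = base_cells_lambda, cell_coefs = cell_coefs,
    nb_size = nb_size, grains_mean = grains_mean,
    diet_breadth = diet_breadth
  )
  stopifnot(n_sites >= 3, weeks >= 2, n_bee_species >= 1,
            length(diet_breadth) == n_bee_species,
            all(c("from", "to", "coef") %in% names(site_model)))
  if (any(c(richness_scale[2], abundance_scale[2], stability_scale[2]) <= 0)) {
    abort("generator_config: scale sds must be > 0",
          class = "beesem_config_error")
  }
  structure(cfg, class = "generator_config")
}

#' Implied covariance of a standardized linear causal system
#'
#' For a DAG whose edges carry standardized coefficients, with independent
#' unit-variance exogenous variables and each endogenous variable given just
#' enough independent Gaussian noise to have unit variance, returns the
#' population covariance (= correlation) matrix.
#'
#' @param edges Tibble `from`, `to`, `coef`.
#' @param variables Optional variable ordering; defaults to the edge
#'   endpoints (plus any extra names given).
#' @return Correlation matrix with dimnames.
#' @export
implied_covariance <- function(edges, variables = NULL) {
  variables <- variables %||% unique(c(edges$from, edges$to))
  m <- causal_model(edges[c("from", "to")], variables = variables)
  ord <- topological_order(m)
  S <- diag(length(ord))
  dimnames(S) <- list(ord, ord)
  for (v in ord) {
    pa <- m$edges$from[m$edges$to == v]
    if (!length(pa)) next
    b <- edges$coef[match(paste(pa, v), paste(edges$from, edges$to))]
    pred_var <- drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
    if (pred_var > 1 + 1e-12) {
      abort(paste0("implied_covariance: coefficients into '", v,
                   "' imply R^2 > 1; system is not standardizable"),
            class = "beesem_config_error")
    }
    cov_vp <- drop(S[, pa, drop = FALSE] %*% b)  # cov(all, v) via parents
    S[, v] <- cov_vp
    S[v, ] <- cov_vp
    S[v, v] <- 1
  }
  S[variables, variables]
}

#' Population path coefficients implied by a generating system
#'
#' For every edge `X -> Y`, the population Pearson partial correlation of X
#' and Y given Y's other parents, computed from [implied_covariance()]. This
#' is the exact estimand of [path_coefficients()] under the generating
#' model; it equals the generating coefficient for sole-parent edges and is
#' close to it elsewhere.
#'
#' @inheritParams implied_covariance
#' @return Tibble `from`, `to`, `coef` (generating), `partial_r` (implied).
#' @export
implied_path_coefficients <- function(edges) {
  S <- implied_covariance(edges)
  m <- causal_model(edges[c("from", "to")])
  purrr::pmap_dfr(edges, function(from, to, coef) {
    others <- setdiff(model_parents(m, to), from)
    idx <- c(from, to, others)
    P <- solve(S[idx, idx])
    tibble(from = from, to = to, coef = coef,
           partial_r = -P[1, 2] / sqrt(P[1, 1] * P[2, 2]))
  })
}

#' Simulate observations from a standardized linear causal system
#'
#' Draws `n` independent rows; exogenous variables are standard normal,
#' endogenous variables are linear in their parents with just enough
#' Gaussian noise for unit population variance. The workhorse behind the
#' generator and behind calibration experiments (type-I error, parameter
#' recovery).
#'
#' @inheritParams implied_covariance
#' @param n Number of rows.
#' @param seed Optional integer seed (local RNG).
#' @return Tibble with one numeric column per variable.
#' @export
simulate_sem <- function(edges, n, variables = NULL, seed = NULL) {
  variables <- variables %||% unique(c(edges$from, edges$to))
  m <- causal_model(edges[c("from", "to")], variables = variables)
  ord <- topological_order(m)
  S <- implied_covariance(edges, variables)
  run <- function() {
    out <- matrix(NA_real_, n, length(ord), dimnames = list(NULL, ord))
    for (v in ord) {
      pa <- m$edges$from[m$edges$to == v]
      if (!length(pa)) {
        out[, v] <- rnorm(n)
      } else {
        b <- edges$coef[match(paste(pa, v), paste(edges$from, edges$to))]
        pred_var <- drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
        out[, v] <- out[, pa, drop = FALSE] %*% b +
          rnorm(n, sd = sqrt(max(0, 1 - pred_var)))
      }
    }
    as_tibble(out[, variables, drop = FALSE])
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Generate synthetic sites with weekly floral series
#'
#' Elevation is uniform on the configured range and time since fire uniform
#' and independent; rarefied flower richness, flower abundance and temporal
#' stability follow the configured standardized causal model (on
#' standardized covariates) and are mapped to natural units by the
#' configured scales. Weekly flower counts are realised by splitting each
#' site's seasonal total over weeks with a Dirichlet draw whose
#' concentration is tuned so the realised weekly series has the site's
#' target stability (inverse CV) in expectation, then distributing each
#' week's total over the plant species present.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed (local RNG).
#' @param weekly Realise the weekly per-plant-species series (default
#'   `TRUE`); `FALSE` skips it when only the site table is needed.
#' @return List with elements `sites` (sites-schema tibble) and `weekly`
#'   (long tibble: `site`, `week`, `plant_species`, `count`; `NULL` when
#'   not realised).
#' @export
generate_sites <- function(config, seed = NULL, weekly = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  run <- function() {
    n <- config$n_sites
    site <- sprintf("site_%02d", seq_len(n))
    elevation <- runif(n, config$elevation_range[1], config$elevation_range[2])
    fire <- runif(n, config$fire_range[1], config$fire_range[2])

    edges <- config$site_model
    vars <- unique(c(edges$from, edges$to))
    m <- causal_model(edges[c("from", "to")], variables = vars)
    ord <- topological_order(m)
    S <- implied_covariance(edges, vars)
    z <- matrix(NA_real_, n, length(ord), dimnames = list(NULL, ord))
    for (v in ord) {
      pa <- m$edges$from[m$edges$to == v]
      if (!length(pa)) {
        z[, v] <- if (v == "elevation") as.vector(scale(elevation)) else
          if (v == "years_since_fire") as.vector(scale(fire)) else rnorm(n)
      } else {
        b <- edges$coef[match(paste(pa, v), paste(edges$from, edges$to))]
        pred_var <- drop(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
        z[, v] <- z[, pa, drop = FALSE] %*% b +
          rnorm(n, sd = sqrt(max(0, 1 - pred_var)))
      }
    }
    natural <- function(v, scale) {
      # covariates outside the configured causal structure are independent
      zz <- if (v %in% colnames(z)) z[, v] else rnorm(n)
      scale["mean"] + scale["sd"] * zz
    }
    richness <- pmax(1, natural("flower_richness_rarefied",
                                config$richness_scale))
    abundance <- pmax(config$weeks, round(natural("flower_abundance",
                                                  config$abundance_scale)))
    stability <- natural("stability", config$stability_scale)
    # a W-week series cannot have CV above sqrt(W): stability targets at or
    # below 1/sqrt(W) are unrealisable
    floor_s <- 1 / sqrt(config$weeks)
    if (config$stability_scale["mean"] <= floor_s) {
      abort(paste0("generate_sites: configured stability mean <= 1/sqrt(",
                   "weeks); target CV is infeasible for a ", config$weeks,
                   "-week series"),
            class = "beesem_config_error")
    }
    if (any(stability <= floor_s)) {
      warn("generate_sites: clamping tail stability draws to the feasible floor")
      stability <- pmax(stability, floor_s * 1.02)
    }

    sites <- new_bee_table(tibble(
      site = site, elevation = elevation, years_since_fire = fire,
      flower_abundance = as.numeric(abundance),
      flower_richness_rarefied = as.numeric(richness),
      stability = as.numeric(stability)
    ), "sites")

    # weekly realisation: Dirichlet(alpha) split with alpha = 1/cv^2 - 1/W,
    # which makes the expected sample CV across weeks equal the target CV
    W <- config$weeks
    pool <- sprintf("plant_%02d", seq_len(config$n_plant_species))
    weekly_tbl <- if (weekly) {
      purrr::map_dfr(seq_len(n), function(i) {
        cv <- 1 / stability[i]
        alpha <- 1 / cv^2 - 1 / W
        g <- stats::rgamma(W, shape = alpha, rate = 1)
        p <- g / sum(g)
        week_tot <- as.vector(rmultinom(1, abundance[i], p))
        n_sp <- min(config$n_plant_species, max(2, round(1.5 * richness[i])))
        present <- sample(pool, n_sp)
        wts <- stats::rlnorm(n_sp, 0, 1)
        cnt <- vapply(seq_len(W), function(w) {
          as.vector(rmultinom(1, week_tot[w], wts / sum(wts)))
        }, numeric(n_sp))
        tibble(site = site[i], week = rep(seq_len(W), each = n_sp),
               plant_species = rep(present, W), count = as.vector(cnt))
      })
    }
    list(sites = sites, weekly = weekly_tbl)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Generate synthetic trap-nest records
#'
#' For every (bee species, site) combination the nest count is Poisson (or
#' negative binomial) with a log mean linear in the standardized site
#' covariates; brood cells per nest are `1 + Poisson` with a log mean
#' likewise linear in the covariates. Defaults encode the survey's pattern:
#' fewer nests and fewer cells per nest at high elevation, slightly fewer
#' cells per nest at temporally stable sites.
#'
#' @param config A [generator_config()].
#' @param sites Sites tibble from [generate_sites()].
#' @param seed Optional integer seed (local RNG).
#' @return List with `records` (tibble: `nest_id`, `bee_species`, `site`,
#'   `cells`) and `nests` (the [reproduction_summaries()] of those records
#'   over all sites).
#' @export
generate_nests <- function(config, sites, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  run <- function() {
    zcov <- function(nm) as.vector(scale(sites[[nm]]))
    lp <- function(coefs) {
      out <- rep(0, nrow(sites))
      for (nm in names(coefs)) out <- out + coefs[[nm]] * zcov(nm)
      out
    }
    lambda_nests <- config$base_nests * exp(lp(config$nest_coefs))
    lambda_cells <- config$base_cells_lambda * exp(lp(config$cell_coefs))
    species <- sprintf("bee_%02d", seq_len(config$n_bee_species))
    records <- purrr::map_dfr(species, function(sp) {
      n_nests <- if (is.null(config$nb_size)) {
        rpois(nrow(sites), lambda_nests)
      } else {
        stats::rnbinom(nrow(sites), mu = lambda_nests, size = config$nb_size)
      }
      tot <- sum(n_nests)
      if (tot == 0) return(NULL)
      tibble(
        bee_species = sp,
        site = rep(sites$site, n_nests),
        cells = 1 + rpois(tot, rep(lambda_cells, n_nests))
      )
    })
    if (nrow(records) == 0) {
      records <- tibble(bee_species = character(), site = character(),
                        cells = numeric())
      nest_tbl <- tibble(bee_species = character(), site = character(),
                         mean_cells_per_nest = numeric(),
                         total_cells = numeric(), total_nests = integer())
      nest_tbl <- new_bee_table(nest_tbl, "nests")
    } else {
      nest_tbl <- reproduction_summaries(records, sites = sites$site)
    }
    records <- records |>
      dplyr::mutate(nest_id = sprintf("nest_%05d", dplyr::row_number()),
                    .before = 1)
    list(records = records, nests = nest_tbl)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Generate synthetic pollen loads
#'
#' One pollen-bearing individual is sampled per nest; its grain count is
#' `1 + Poisson(grains_mean - 1)` and the grains are multinomial over the
#' plant pool with species-specific use weights that decay geometrically
#' with the plant's rank in that bee species' preference order at the
#' configured diet-breadth scale (small scale = oligolectic, large =
#' polylectic).
#'
#' @param config A [generator_config()].
#' @param nest_records `records` tibble from [generate_nests()].
#' @param seed Optional integer seed (local RNG).
#' @return Pollen-schema tibble (see [bee_schema_registry()]), one row per
#'   (individual, plant species) with a positive grain count.
#' @export
generate_pollen <- function(config, nest_records, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  run <- function() {
    pool <- sprintf("plant_%02d", seq_len(config$n_plant_species))
    species <- sprintf("bee_%02d", seq_len(config$n_bee_species))
    prefs <- lapply(seq_along(species), function(s) {
      order <- sample(pool)
      w <- exp(-(seq_along(order) - 1) / config$diet_breadth[s])
      setNames(w / sum(w), order)[pool]
    })
    names(prefs) <- species
    out <- purrr::pmap_dfr(nest_records[c("nest_id", "bee_species", "site")],
      function(nest_id, bee_species, site) {
        w <- prefs[[bee_species]]
        if (is.null(w)) {  # species outside the configured pool: uniform
          w <- setNames(rep(1 / length(pool), length(pool)), pool)
        }
        total <- 1 + rpois(1, max(config$grains_mean - 1, 0))
        cnt <- as.vector(rmultinom(1, total, w))
        keep <- cnt > 0
        tibble(
          bee_individual = nest_id, bee_species = bee_species, site = site,
          plant_species = pool[keep], grains_of_species = cnt[keep],
          grains_total = total,
          proportion = cnt[keep] / total
        )
      })
    validate_bee_table(out, "pollen")
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
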