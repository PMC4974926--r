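#' Reproduction summaries per bee species and site
#'
#' Collapses per-nest records into the three reproductive response variables:
#' mean brood cells per nest, total brood cells, and total nests, for every
#' (species, site) combination. The mean is defined only where the species
#' nested; at sites where a species is absent its totals are zero (absence is
#' zero abundance) and the mean is `NA`.
#'
#' @param nest_records Data frame with one row per nest: columns
#'   `bee_species`, `site`, `cells` (brood cells in that nest, or the
#'   cell-equivalent from [pollen_length_proxy()]).
#' @param sites Optional character vector of all study sites; combinations of
#'   species x site absent from `nest_records` are filled with zero totals.
#'   Default uses the sites present in the records.
#' @return A validated nests-schema tibble (see [bee_schema_registry()]).
#' @export
reproduction_summaries <- function(nest_records, sites = NULL) {
  if (any(nest_records$cells < 0, na.rm = TRUE)) {
    abort("reproduction_summaries: negative cell count",
          class = "beesem_domain_error")
  }
  sites <- sites %||% unique(nest_records$site)
  out <- nest_records |>
    dplyr::group_by(.data$bee_species, .data$site) |>
    dplyr::summarise(
      mean_cells_per_nest = mean(.data$cells),
      total_cells = sum(.data$cells),
      total_nests = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      bee_species = unique(nest_records$bee_species),
      site = sites,
      fill = list(mean_cells_per_nest = NA_real_, total_cells = 0,
                  total_nests = 0L)
    ) |>
    dplyr::arrange(.data$bee_species, .data$site)
  validate_bee_table(out, "nests")
}

#' Brood-cell equivalents from occupied cavity length
#'
#' For species that lay eggs amidst a bare pollen mass and build no brood
#' cells (e.g. *Trichothurgus laticeps*), reproduction is proxied by the
#' length of trap cavity occupied by pollen, converted to cell-equivalents by
#' a length-per-cell constant. With the default `length_per_cell = 1` the raw
#' length serves as the response; only relative comparisons enter the models.
#'
#' @param occupied_length Occupied cavity length, mm (non-negative).
#' @param length_per_cell Cavity length per cell-equivalent, mm (> 0).
#' @return Cell-equivalents (numeric, same length as `occupied_length`).
#' @export
#' @examples
#' pollen_length_proxy(30, 10)  # 3
pollen_length_proxy <- function(occupied_length, length_per_cell = 1) {
  if (any(length_per_cell <= 0, na.rm = TRUE)) {
    abort("pollen_length_proxy: length_per_cell must be > 0",
          class = "beesem_domain_error")
  }
  if (any(occupied_length < 0, na.rm = TRUE)) {
    abort("pollen_length_proxy: negative occupied length",
          class = "beesem_domain_error")
  }
  occupied_length / length_per_cell
}

#' Focal species passing the minimum nest-count filter
#'
#' Species with fewer nests than the threshold are considered unreliable for
#' the statistical analysis and excluded; the survey's threshold of 30 nests
#' keeps 7 of the 11 recorded species.
#'
#' @param nest_counts Data frame with columns `bee_species` and `total_nests`
#'   (per-site rows are summed per species), or a named numeric vector of
#'   per-species nest totals.
#' @param min_nests Minimum total nests (default 30).
#' @return Character vector of retained species, in stable input order.
#' @export
#' @examples
#' filter_focal_species(monte_nest_census())
filter_focal_species <- function(nest_counts, min_nests = 30) {
  if (min_nests < 0) {
    abort("filter_focal_species: min_nests must be >= 0",
          class = "beesem_domain_error")
  }
  if (is.data.frame(nest_counts)) {
    totals <- nest_counts |>
      dplyr::group_by(.data$bee_species) |>
      dplyr::summarise(total_nests = sum(.data$total_nests),
                       .groups = "drop") |>
      dplyr::arrange(match(.data$bee_species,
                           unique(nest_counts$bee_species)))
    sp <- totals$bee_species
    n <- totals$total_nests
  } else {
    sp <- names(nest_counts)
    n <- as.numeric(nest_counts)
  }
  sp[n >= min_nests]
}

#' Rarefied diet degree
#'
#' Expected number of plant species in a random subsample of `n` pollen
#' grains from a bee species' pooled pollen load — the same hypergeometric
#' expectation as [rarefied_richness()], applied to diet counts. Makes the
#' degree of diet generalization comparable across bee species with unequal
#' pollen sampling effort.
#'
#' @param pollen_counts Integer vector of pollen grain counts per plant
#'   species for one bee species.
#' @param n Subsample size (grains).
#' @return Expected number of plant species (real).
#' @export
rarefied_degree <- function(pollen_counts, n) {
  rarefied_richness(pollen_counts, n)
}

#' Rarefied inverse Simpson diversity of the diet
#'
#' Expected inverse Simpson index `1 / sum(p_i^2)` of a hypergeometric
#' subsample of `n` grains, estimated by Monte-Carlo resampling (no simple
#' closed form exists). Seed-reproducible; the Monte-Carlo standard error of
#' the mean is attached as attribute `"se"`.
#'
#' @inheritParams rarefied_degree
#' @param reps Number of Monte-Carlo subsamples (default 1000).
#' @param seed Optional integer seed for a local, restored RNG state.
#' @return Expected inverse Simpson diversity (real >= 1), with attribute
#'   `se`.
#' @export
#' @examples
#' rarefied_simpson(c(2, 1, 1), 4, reps = 10)  # full sample: exactly 8/3
rarefied_simpson <- function(pollen_counts, n, reps = 1000, seed = NULL) {
  counts <- as.numeric(pollen_counts)
  total <- sum(counts)
  if (length(n) != 1 || n < 1 || n > total) {
    abort(paste0("rarefied_simpson: subsample size must be in [1, ", total,
                 "]"), class = "beesem_domain_error")
  }
  if (reps < 1) {
    abort("rarefied_simpson: reps must be >= 1",
          class = "beesem_domain_error")
  }
  inv_simpson <- function(x) {
    p <- x / sum(x)
    1 / sum(p^2)
  }
  if (n == total) {  # subsample is the full sample: deterministic
    out <- inv_simpson(counts)
    attr(out, "se") <- 0
    return(out)
  }
  run <- function() {
    pool <- rep.int(seq_along(counts), counts)
    draws <- vapply(seq_len(reps), function(i) {
      inv_simpson(tabulate(sample(pool, n), nbins = length(counts)))
    }, numeric(1))
    out <- mean(draws)
    attr(out, "se") <- sd(draws) / sqrt(reps)
    out
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

#' Diet-generalization indices per bee species
#'
#' Pools pollen grain counts per bee species across individuals and sites,
#' then computes rarefied degree and rarefied inverse Simpson diversity at a
#' common rarefaction depth, making diet breadth comparable across species.
#'
#' @param pollen Pollen table (canonical columns, see
#'   [bee_schema_registry()]).
#' @param depth Rarefaction depth in grains. Default: minimum pooled total
#'   across the species present.
#' @param reps,seed Passed to [rarefied_simpson()].
#' @return Tibble: `bee_species`, `rarefied_degree`, `rarefied_simpson`,
#'   `rarefied_simpson_se`, `rarefaction_depth`.
#' @export
generalization_indices <- function(pollen, depth = NULL, reps = 1000,
                                   seed = NULL) {
  pooled <- pollen |>
    dplyr::group_by(.data$bee_species, .data$plant_species) |>
    dplyr::summarise(grains = sum(.data$grains_of_species),
                     .groups = "drop")
  totals <- pooled |>
    dplyr::group_by(.data$bee_species) |>
    dplyr::summarise(total = sum(.data$grains), .groups = "drop")
  depth <- depth %||% min(totals$total)
  species <- unique(pooled$bee_species)
  seeds <- if (is.null(seed)) rep(list(NULL), length(species)) else
    as.list(seed + seq_along(species))
  purrr::map2_dfr(species, seeds, function(sp, sd_i) {
    g <- pooled$grains[pooled$bee_species == sp]
    simp <- rarefied_simpson(g, depth, reps = reps, seed = sd_i)
    tibble(
      bee_species = sp,
      rarefied_degree = rarefied_degree(g, depth),
      rarefied_simpson = as.numeric(simp),
      rarefied_simpson_se = attr(simp, "se"),
      rarefaction_depth = depth
    )
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
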