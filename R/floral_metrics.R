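#' Flower density from per-individual counts
#'
#' Flower density of a plant taxon in a plot or transect is estimated as the
#' mean number of flowers per flowering individual times the number of
#' flowering individuals. For taxa whose individuals cannot be distinguished
#' (some herbs), all flowers are counted directly and the direct count is the
#' density.
#'
#' @param mean_flowers_per_individual Mean open flowers per flowering
#'   individual (non-negative).
#' @param n_flowering_individuals Number of flowering individuals
#'   (non-negative).
#' @param direct_count Optional direct flower count; when supplied (non-`NA`)
#'   it bypasses the product. Vectorised: element-wise choice.
#' @return Numeric vector of flower counts.
#' @export
#' @examples
#' flower_density(5, 10)                 # 50
#' flower_density(NA, NA, direct_count = 123)  # 123
flower_density <- function(mean_flowers_per_individual = NULL,
                           n_flowering_individuals = NULL,
                           direct_count = NULL) {
  if (is.null(direct_count)) {
    m <- mean_flowers_per_individual
    k <- n_flowering_individuals
    if (any(m < 0, na.rm = TRUE) || any(k < 0, na.rm = TRUE)) {
      abort("flower_density: negative input", class = "beesem_domain_error")
    }
    return(as.numeric(m * k))
  }
  if (any(direct_count < 0, na.rm = TRUE)) {
    abort("flower_density: negative direct count",
          class = "beesem_domain_error")
  }
  d <- as.numeric(direct_count)
  if (!is.null(mean_flowers_per_individual) &&
      !is.null(n_flowering_individuals)) {
    prod <- flower_density(mean_flowers_per_individual,
                           n_flowering_individuals)
    d[is.na(direct_count)] <- prod[is.na(direct_count)]
  }
  d
}

#' Temporal stability of weekly flower production
#'
#' Stability of a site's floral resources along the season is the inverse of
#' the coefficient of variation of its weekly flower abundance:
#' `mean(x) / sd(x)` with the sample (n - 1) standard deviation.
#'
#' A constant non-zero series has zero variance; that is reported as an
#' `Inf` sentinel with a warning rather than silently dropped. An all-zero
#' series has an undefined stability and errors.
#'
#' @param x Either a numeric vector of weekly abundances (length >= 2) or a
#'   data frame of a weekly floral series with columns `site`, `week`, and an
#'   abundance column.
#' @param abundance_col Column holding weekly abundance when `x` is a data
#'   frame. Default `"flower_abundance"`.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return For a vector, a single number. For a data frame, a tibble with one
#'   row per site and column `stability`.
#' @export
#' @examples
#' temporal_stability(c(10, 20, 30))  # 2
temporal_stability <- function(x, abundance_col = "flower_abundance",
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.data.frame(x)) {
    return(
      x |>
        dplyr::group_by(.data$site) |>
        dplyr::summarise(
          stability = temporal_stability(.data[[abundance_col]],
                                         sd_type = sd_type),
          .groups = "drop"
        )
    )
  }
  x <- as.numeric(x)
  if (length(x) < 2) {
    abort("temporal_stability: need at least 2 weeks",
          class = "beesem_domain_error")
  }
  if (anyNA(x)) {
    abort("temporal_stability: missing weekly values",
          class = "beesem_domain_error")
  }
  if (all(x == 0)) {
    abort("temporal_stability: all-zero series has undefined stability",
          class = "beesem_domain_error")
  }
  s <- sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (s == 0) {
    warn("temporal_stability: constant series, returning Inf sentinel")
    return(Inf)
  }
  mean(x) / s
}

#' Rarefied species richness
#'
#' Expected number of species in a random subsample of `n` individuals drawn
#' without replacement from a community with the given abundance counts
#' (hypergeometric expectation):
#' \deqn{E[S_n] = \sum_i \left(1 - \binom{N - N_i}{n} / \binom{N}{n}\right)}
#' Computed with `vegan::rarefy()`.
#'
#' @param counts Integer vector of per-species abundances (non-negative; zero
#'   entries are allowed and contribute nothing).
#' @param n Subsample size, `1 <= n <= sum(counts)`.
#' @return Expected species count (a real number).
#' @export
#' @examples
#' rarefied_richness(c(2, 2), 2)  # 5/3
rarefied_richness <- function(counts, n) {
  counts <- as.numeric(counts)
  if (length(counts) == 0 || any(counts < 0) || anyNA(counts)) {
    abort("rarefied_richness: counts must be non-negative and complete",
          class = "beesem_domain_error")
  }
  if (any(counts != floor(counts))) {
    abort("rarefied_richness: counts must be integers",
          class = "beesem_domain_error")
  }
  total <- sum(counts)
  if (total == 0) {
    abort("rarefied_richness: all-zero counts", class = "beesem_domain_error")
  }
  if (length(n) != 1 || is.na(n) || n < 1 || n > total) {
    abort(paste0("rarefied_richness: subsample size must be in [1, ", total,
                 "]"), class = "beesem_domain_error")
  }
  # vegan warns about "counts 1" heuristics on tiny fixtures; irrelevant here
  suppressWarnings(
    unname(vegan::rarefy(matrix(counts, nrow = 1), sample = n)[1])
  )
}

#' Per-site floral metrics table
#'
#' Summarises a weekly floral series into the per-site covariates used by the
#' structural models: seasonal flower abundance, rarefied flower richness and
#' temporal stability.
#'
#' @param series Data frame with columns `site`, `week`,
#'   `flower_abundance` (site-week totals) and optionally `plant_species` +
#'   `count` rows at the species level (long format, one row per
#'   site/week/plant species). When species-level rows are present, weekly
#'   abundance is their sum and richness is rarefied from pooled seasonal
#'   per-species counts.
#' @param rarefaction_depth Number of flowers to rarefy richness to. Default
#'   `NULL` uses the minimum seasonal total across sites (standard practice).
#' @param abundance `"total"` (seasonal sum, default) or `"weekly_mean"`.
#' @param sd_type Passed to [temporal_stability()].
#' @return Tibble with one row per site: `site`, `flower_abundance`,
#'   `flower_richness_rarefied`, `stability`.
#' @export
floral_metrics <- function(series, rarefaction_depth = NULL,
                           abundance = c("total", "weekly_mean"),
                           sd_type = c("sample", "population")) {
  abundance <- match.arg(abundance)
  sd_type <- match.arg(sd_type)
  has_species <- all(c("plant_species", "count") %in% names(series))

  weekly <-
    if (has_species) {
      series |>
        dplyr::group_by(.data$site, .data$week) |>
        dplyr::summarise(flower_abundance = sum(.data$count),
                         .groups = "drop")
    } else {
      dplyr::select(series, "site", "week", "flower_abundance")
    }

  per_site <- weekly |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      flower_abundance = if (abundance == "total") {
        sum(.data$flower_abundance)
      } else {
        mean(.data$flower_abundance)
      },
      .groups = "drop"
    )
  # stability comes from the weekly series, not the aggregate
  stab <- weekly |>
    dplyr::arrange(.data$site, .data$week) |>
    temporal_stability(sd_type = sd_type)
  per_site$stability <- stab$stability[match(per_site$site, stab$site)]

  if (has_species) {
    pooled <- series |>
      dplyr::group_by(.data$site, .data$plant_species) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    totals <- pooled |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(total = sum(.data$count), .groups = "drop")
    depth <- rarefaction_depth %||% min(totals$total)
    rich <- pooled |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(
        flower_richness_rarefied = rarefied_richness(.data$count, depth),
        .groups = "drop"
      )
    per_site <- dplyr::left_join(per_site, rich, by = "site")
  }
  dplyr::relocate(per_site, "site", "flower_abundance",
                  dplyr::any_of("flower_richness_rarefied"), "stability")
}
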