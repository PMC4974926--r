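#' Plot the path coefficients of a fitted causal model
#'
#' Dot-and-whisker plot of the partial-correlation path coefficients, with
#' approximate 95% confidence intervals from the Fisher z transform
#' (`z +/- 1.96 / sqrt(n - 3 - k)` back-transformed).
#'
#' @param object A [dsep_test()] fit (the claims are not plotted; pass the
#'   matching [path_coefficients()] table via `paths`) — or omit `paths` to
#'   recompute from `data`.
#' @param paths Tibble from [path_coefficients()].
#' @param data Site-level data; used only when `paths` is missing.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsep_fit <- function(object, paths = NULL, data = NULL, ...) {
  if (is.null(paths)) {
    if (is.null(data)) {
      abort("autoplot.dsep_fit: supply `paths` or `data`")
    }
    paths <- path_coefficients(object$model, data)
  }
  k <- vapply(paths$to, function(v)
    length(model_parents(object$model, v)) - 1L, integer(1))
  se <- 1 / sqrt(pmax(paths$n - 3 - k, 1))
  z <- fisher_z(pmax(pmin(paths$estimate, 0.999), -0.999))
  paths$lo <- fisher_z_inv(z - 1.96 * se)
  paths$hi <- fisher_z_inv(z + 1.96 * se)
  paths$edge <- paste(paths$from, "→", paths$to)
  ggplot2::ggplot(paths,
                  ggplot2::aes(x = .data$estimate,
                               y = stats::reorder(.data$edge,
                                                  .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "path coefficient (partial correlation)", y = NULL,
      title = paste0("Model '", object$model$name, "': C = ",
                     signif(object$C, 3), ", p = ",
                     signif(object$p_value, 2))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-species meta-analysis
#'
#' Forest-style plot: each species' coefficient sized by its weight, with
#' the weighted mean and bootstrap percentile confidence limits (on the
#' correlation scale).
#'
#' @param object A [bootstrap_ci()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_fit <- function(object, ...) {
  d <- object$inputs
  d$species <- factor(seq_len(nrow(d)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$species)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::annotate("rect", xmin = object$ci_r[1], xmax = object$ci_r[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15,
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$r_w, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$w), shape = 18) +
    ggplot2::scale_size_area(name = "weight (n - 3)", max_size = 5) +
    ggplot2::labs(
      x = "path coefficient", y = "species",
      title = sprintf("weighted mean r = %.3f, %d%% CI (%.3f, %.3f)",
                      object$r_w, round(100 * object$conf_level),
                      object$ci_r[1], object$ci_r[2])
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of path coefficients across species
#'
#' Summarises, per edge of the simplified model, the distribution of the
#' per-species path coefficients — the package's analogue of the published
#' cross-species coefficient summary.
#'
#' @param paths Long tibble of per-species path coefficients with columns
#'   `from`, `to`, `estimate` (e.g. the species rows of the pipeline's
#'   path table).
#' @return A ggplot object.
#' @export
plot_species_paths <- function(paths) {
  paths$edge <- paste(paths$from, "→", paths$to)
  ggplot2::ggplot(paths, ggplot2::aes(x = .data$edge, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "path coefficient across species") +
    ggplot2::theme_minimal()
}

#' Weekly floral series plot
#'
#' Weekly flower abundance per site, the raw material of the temporal
#' stability metric.
#'
#' @param weekly Long tibble `site`, `week`, `plant_species`, `count` (or
#'   already aggregated with a `flower_abundance` column).
#' @return A ggplot object.
#' @export
plot_weekly_floral <- function(weekly) {
  if (!"flower_abundance" %in% names(weekly)) {
    weekly <- weekly |>
      dplyr::group_by(.data$site, .data$week) |>
      dplyr::summarise(flower_abundance = sum(.data$count),
                       .groups = "drop")
  }
  ggplot2::ggplot(weekly, ggplot2::aes(x = .data$week,
                                       y = .data$flower_abundance,
                                       group = .data$site)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "week", y = "flowers per site") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
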