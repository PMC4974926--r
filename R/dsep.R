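#' Pearson partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of the
#' conditioning variables `z` from both. Computed from the precision matrix
#' of `(x, y, z)`; with an empty conditioning set this is the plain Pearson
#' correlation. The two-sided p-value uses the t distribution with
#' `n - 2 - |z|` degrees of freedom.
#'
#' Rows with a missing value in any involved variable are dropped
#' (complete-case filtering) before computation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param z Conditioning set: `NULL`, a numeric vector, a matrix, or a data
#'   frame (one column per conditioning variable).
#' @return One-row tibble: `estimate` (partial r), `statistic` (t),
#'   `p_value`, `df`, `n` (complete cases used), `k` (size of the
#'   conditioning set).
#' @export
#' @examples
#' partial_correlation(1:10, (1:10)^2)
partial_correlation <- function(x, y, z = NULL) {
  z <- if (is.null(z)) NULL else as.matrix(as.data.frame(z))
  n_in <- length(x)
  if (length(y) != n_in || (!is.null(z) && nrow(z) != n_in)) {
    abort("partial_correlation: inputs must have equal length",
          class = "beesem_domain_error")
  }
  m <- cbind(x = x, y = y, z)
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m) - 2L
  if (n < k + 3) {
    abort(paste0("partial_correlation: need at least ", k + 3,
                 " complete observations, got ", n),
          class = "beesem_insufficient_data_error")
  }
  sds <- apply(m, 2, sd)
  if (sds[1] == 0 || sds[2] == 0) {
    abort("partial_correlation: zero variance in x or y",
          class = "beesem_degenerate_error")
  }
  if (k > 0 && any(sds[-(1:2)] == 0)) {
    # constant conditioning variable carries no information; drop it
    m <- m[, c(TRUE, TRUE, sds[-(1:2)] > 0), drop = FALSE]
    k <- ncol(m) - 2L
  }
  r <- if (k == 0) {
    cor(m[, 1], m[, 2])
  } else {
    cm <- cor(m)
    prec <- tryCatch(solve(cm), error = function(e) NULL)
    if (is.null(prec)) {
      abort("partial_correlation: singular correlation matrix (collinear inputs)",
            class = "beesem_degenerate_error")
    }
    -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  }
  r <- max(-1, min(1, r))
  df <- n - 2L - k
  stat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- if (is.infinite(stat)) 0 else 2 * pt(-abs(stat), df)
  tibble(estimate = r, statistic = stat, p_value = p, df = df, n = n, k = k)
}

#' Fisher's C statistic
#'
#' Combines the independence p-values of a basis set into
#' `C = -2 * sum(log(p_i))`. When the causal model is correct, C follows a
#' chi-square distribution with `2k` degrees of freedom (k = number of
#' claims).
#'
#' @param p_values Numeric vector of p-values in (0, 1]. A zero p-value
#'   yields an `Inf` sentinel with a warning (the model is decisively
#'   rejected); values outside \[0, 1\] error.
#' @return Fisher's C (non-negative real, possibly `Inf`).
#' @export
#' @examples
#' fisher_c(c(0.5, 0.5))  # -2 * 2 * log(0.5) = 2.7726
fisher_c <- function(p_values) {
  if (length(p_values) == 0) return(0)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("fisher_c: p-values must lie in [0, 1]",
          class = "beesem_domain_error")
  }
  if (any(p_values == 0)) {
    warn("fisher_c: zero p-value; C is infinite (model decisively rejected)")
    return(Inf)
  }
  -2 * sum(log(p_values))
}

#' Test a causal model by d-separation
#'
#' Evaluates every conditional-independence claim of the model's
#' [basis_set()] on the data with [partial_correlation()], combines the
#' claim p-values into Fisher's C, and compares C to a chi-square
#' distribution with `df = 2k`. A small p-value rejects the causal model. A
#' saturated model (empty basis set) is assigned `C = 0, df = 0, p = 1` by
#' convention and flagged.
#'
#' @param model A [causal_model()].
#' @param data Data frame containing a numeric column for every model
#'   variable (one row per observational unit, e.g. per site).
#' @return An object of class `dsep_fit`: list with `model`, `claims`
#'   (tibble: `x`, `y`, `conditioning`, `estimate`, `p_value`, `n`), `C`,
#'   `k`, `df`, `p_value`, `n`, `saturated`.
#' @seealso [tidy.dsep_fit()], [glance.dsep_fit()], [model_aic()]
#' @export
dsep_test <- function(model, data) {
  missing <- setdiff(model$variables, names(data))
  if (length(missing)) {
    abort(paste0("dsep_test: data lacks model variable(s): ",
                 paste(missing, collapse = ", ")),
          class = "beesem_model_error")
  }
  bs <- basis_set(model)
  claims <- purrr::pmap_dfr(bs, function(x, y, z) {
    pc <- partial_correlation(data[[x]], data[[y]],
                              if (length(z)) data[z] else NULL)
    tibble(x = x, y = y,
           conditioning = paste(z, collapse = ", "),
           estimate = pc$estimate, p_value = pc$p_value, n = pc$n)
  })
  k <- nrow(bs)
  saturated <- k == 0
  if (saturated) {
    inform(paste0("dsep_test: model '", model$name,
                  "' is saturated (empty basis set); p = 1 by convention"))
    C <- 0; p <- 1
  } else {
    C <- fisher_c(claims$p_value)
    p <- if (is.infinite(C)) 0 else pchisq(C, df = 2 * k, lower.tail = FALSE)
  }
  structure(
    list(model = model, claims = claims, C = C, k = k, df = 2L * k,
         p_value = p, n = nrow(data), saturated = saturated),
    class = "dsep_fit"
  )
}

#' @export
print.dsep_fit <- function(x, ...) {
  cat("<dsep_fit> model '", x$model$name, "': C = ", signif(x$C, 4),
      ", df = ", x$df, ", p = ", signif(x$p_value, 3),
      if (x$saturated) " (saturated)", "\n", sep = "")
  invisible(x)
}

#' @rdname dsep_test
#' @param x A `dsep_fit`.
#' @param ... Unused.
#' @export
tidy.dsep_fit <- function(x, ...) x$claims

#' @rdname dsep_test
#' @export
glance.dsep_fit <- function(x, ...) {
  tibble(model = x$model$name, C = x$C, k = x$k, df = x$df,
         p_value = x$p_value, n = x$n, saturated = x$saturated)
}

#' AIC of a piecewise causal model from Fisher's C
#'
#' Three formulas are available:
#' \describe{
#'   \item{shipley}{`AIC = C + 2K` — the standard large-sample form.}
#'   \item{shipley_corrected}{`AIC = C + 2K * n / (n - K - 1)` — the
#'     small-sample correction; the default, appropriate for tens of sites.}
#'   \item{as_printed}{`AIC = 2 * log(C) + 2K` — a formula that circulates in
#'     the applied literature; dimensionally inconsistent with the chi-square
#'     scale of C and undefined for C <= 0, provided for audit only.}
#' }
#'
#' @param fit A [dsep_test()] result, or a bare numeric C value.
#' @param K Free-parameter count; defaults to
#'   [count_free_parameters()] of the fitted model.
#' @param n Sample size; defaults to the fit's.
#' @param formula AIC variant, see Details.
#' @return One-row tibble: `model`, `C`, `K`, `n`, `AIC`, `formula`.
#' @export
model_aic <- function(fit, K = NULL, n = NULL,
                      formula = c("shipley_corrected", "shipley",
                                  "as_printed")) {
  formula <- match.arg(formula)
  if (inherits(fit, "dsep_fit")) {
    C <- fit$C
    K <- K %||% count_free_parameters(fit$model)
    n <- n %||% fit$n
    name <- fit$model$name
  } else {
    C <- fit
    name <- NA_character_
    if (is.null(K) || is.null(n)) {
      abort("model_aic: K and n required when passing a bare C value",
            class = "beesem_domain_error")
    }
  }
  if (K < 1) abort("model_aic: K must be >= 1", class = "beesem_domain_error")
  aic <- switch(formula,
    shipley = C + 2 * K,
    shipley_corrected = {
      if (n <= K + 1) {
        abort("model_aic: corrected form needs n > K + 1",
              class = "beesem_domain_error")
      }
      C + 2 * K * n / (n - K - 1)
    },
    as_printed = {
      if (C <= 0) {
        abort("model_aic: as_printed formula undefined for C <= 0",
              class = "beesem_domain_error")
      }
      2 * log(C) + 2 * K
    }
  )
  tibble(model = name, C = C, K = as.integer(K), n = as.integer(n),
         AIC = aic, formula = formula)
}

#' Rank competing causal models by AIC
#'
#' Computes AIC for each fitted model, the difference `delta_AIC` to the best
#' (lowest-AIC) model, and a verbal support class: `substantial`
#' (delta < 3), `less` (3 <= delta <= 10), `none` (delta > 10). Ties in AIC
#' are broken lexicographically by model name.
#'
#' @param fits List of [dsep_test()] results.
#' @param formula Passed to [model_aic()].
#' @param K Optional vector of parameter counts, one per fit.
#' @return Tibble sorted best-first: `model`, `C`, `K`, `n`, `AIC`,
#'   `delta_AIC`, `support`.
#' @export
rank_models <- function(fits, formula = c("shipley_corrected", "shipley",
                                          "as_printed"), K = NULL) {
  formula <- match.arg(formula)
  rows <- purrr::map_dfr(seq_along(fits), function(i) {
    model_aic(fits[[i]], K = if (is.null(K)) NULL else K[[i]],
              formula = formula)
  })
  rows |>
    dplyr::mutate(delta_AIC = .data$AIC - min(.data$AIC)) |>
    dplyr::mutate(support = dplyr::case_when(
      .data$delta_AIC < 3 ~ "substantial",
      .data$delta_AIC <= 10 ~ "less",
      TRUE ~ "none"
    )) |>
    dplyr::arrange(.data$AIC, .data$model)
}

#' Path coefficients of a causal model
#'
#' The coefficient of an edge `X -> Y` is the Pearson partial correlation of
#' X and Y conditioning on Y's other parents; for a sole-parent edge this
#' reduces to the plain Pearson correlation. The same partial-correlation
#' routine provides the coefficient and its p-value, mirroring the local
#' (piecewise) estimation philosophy: each response is fitted against its
#' direct causes only.
#'
#' @inheritParams dsep_test
#' @return Tibble with one row per edge: `from`, `to`, `estimate`,
#'   `p_value`, `n`, `df`.
#' @export
path_coefficients <- function(model, data) {
  missing <- setdiff(model$variables, names(data))
  if (length(missing)) {
    abort(paste0("path_coefficients: data lacks model variable(s): ",
                 paste(missing, collapse = ", ")),
          class = "beesem_model_error")
  }
  purrr::pmap_dfr(model$edges, function(from, to) {
    others <- setdiff(model_parents(model, to), from)
    pc <- partial_correlation(data[[from]], data[[to]],
                              if (length(others)) data[others] else NULL)
    tibble(from = from, to = to, estimate = pc$estimate,
           p_value = pc$p_value, n = pc$n, df = pc$df)
  })
}
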