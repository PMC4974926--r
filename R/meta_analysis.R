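#' Fisher's z transform of a correlation coefficient
#'
#' `z = 0.5 * log((1 + r) / (1 - r))`. Variance-stabilising: across studies
#' (here, bee species) the sampling variance of z is approximately
#' `1 / (N - 3)`, so inverse-variance weights are `w = N - 3`.
#'
#' @param r Correlation coefficient(s), `|r| < 1`.
#' @return z value(s).
#' @export
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3)
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    abort("fisher_z: |r| must be < 1", class = "beesem_domain_error")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Inverse Fisher z transform
#' @param z Fisher z value(s).
#' @return Correlation coefficient(s) in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Inverse-variance weighted mean of Fisher z values
#'
#' `z_w = sum(w_i * z_i) / sum(w_i)` with `w_i = N_i - 3`, the standard
#' fixed-effect combination of correlations across species.
#'
#' @param z Fisher-z-transformed coefficients, one per species.
#' @param n Sample sizes (sites contributing to each coefficient); all must
#'   exceed 3 for positive weights.
#' @return The weighted mean z (scalar).
#' @export
#' @examples
#' weighted_mean_z(c(0.2, 0.6), c(13, 7))  # (10*0.2 + 4*0.6) / 14
weighted_mean_z <- function(z, n) {
  if (length(z) == 0 || length(z) != length(n)) {
    abort("weighted_mean_z: z and n must be non-empty and of equal length",
          class = "beesem_domain_error")
  }
  if (any(n <= 3)) {
    abort("weighted_mean_z: every n must exceed 3 (weights are n - 3)",
          class = "beesem_domain_error")
  }
  w <- n - 3
  sum(w * z) / sum(w)
}

#' Bootstrap meta-analysis of a path coefficient across species
#'
#' Resamples species (with their `(z, w)` pairs) with replacement `B` times,
#' recomputes the weighted mean z for each resample, and reports the 2.5th
#' and 97.5th percentiles as the 95% confidence limits. Percentile (not BCa)
#' intervals; fully reproducible given `seed`. Results are reported both on
#' the z scale and back-transformed to the correlation scale.
#'
#' @param data Data frame with one row per species: a coefficient column
#'   (`estimate`, a correlation) and a sample-size column (`n`).
#' @param B Bootstrap replicates (default 100000).
#' @param seed Integer seed (local RNG, restored afterwards). `NULL` uses
#'   the current RNG state.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `meta_fit`: list with `z_w`, `r_w`, `ci_z`,
#'   `ci_r`, `B`, `seed`, `conf_level`, `inputs`.
#' @seealso [tidy.meta_fit()], [glance.meta_fit()]
#' @export
bootstrap_ci <- function(data, B = 1e5, seed = NULL, conf_level = 0.95) {
  if (B < 1) abort("bootstrap_ci: B must be >= 1",
                   class = "beesem_domain_error")
  if (nrow(data) == 0) {
    abort("bootstrap_ci: need at least one species",
          class = "beesem_domain_error")
  }
  z <- fisher_z(data$estimate)
  n <- data$n
  if (any(n <= 3)) {
    abort("bootstrap_ci: every n must exceed 3",
          class = "beesem_domain_error")
  }
  w <- n - 3
  k <- length(z)
  run <- function() {
    idx <- matrix(sample.int(k, k * B, replace = TRUE), nrow = k)
    zw <- colSums(matrix(z[idx] * w[idx], nrow = k)) /
      colSums(matrix(w[idx], nrow = k))
    quantile(zw, probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
             names = FALSE)
  }
  ci_z <- if (is.null(seed)) run() else with_local_seed(seed, run())
  structure(
    list(
      z_w = weighted_mean_z(z, n),
      r_w = fisher_z_inv(weighted_mean_z(z, n)),
      ci_z = ci_z,
      ci_r = fisher_z_inv(ci_z),
      B = as.integer(B),
      seed = seed,
      conf_level = conf_level,
      inputs = tibble(estimate = data$estimate, n = n, z = z, w = w)
    ),
    class = "meta_fit"
  )
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("<meta_fit> ", nrow(x$inputs), " species, B = ", x$B,
      "\n  weighted mean r = ", signif(x$r_w, 4), ", ",
      100 * x$conf_level, "% CI (", signif(x$ci_r[1], 4), ", ",
      signif(x$ci_r[2], 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname bootstrap_ci
#' @param x A `meta_fit`.
#' @param ... Unused.
#' @export
tidy.meta_fit <- function(x, ...) x$inputs

#' @rdname bootstrap_ci
#' @export
glance.meta_fit <- function(x, ...) {
  tibble(
    k = nrow(x$inputs), z_w = x$z_w, r_w = x$r_w,
    ci_z_lower = x$ci_z[1], ci_z_upper = x$ci_z[2],
    ci_r_lower = x$ci_r[1], ci_r_upper = x$ci_r[2],
    B = x$B, conf_level = x$conf_level
  )
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho as the Pearson correlation of average ranks (ties averaged).
#' For tie-free samples of up to `exact_max` observations the two-sided
#' p-value is exact, from full enumeration of all `n!` rank permutations;
#' otherwise the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` df is used.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param method `"auto"` (exact when possible, default), `"exact"`, or
#'   `"approximate"`.
#' @param exact_max Largest n for which enumeration is attempted (default 9;
#'   9! = 362880 permutations).
#' @return One-row tibble: `estimate` (rho), `p_value`, `n`, `method`.
#' @export
#' @examples
#' spearman_correlation(1:7, c(2, 1, 4, 3, 7, 5, 6))
spearman_correlation <- function(x, y, method = c("auto", "exact",
                                                  "approximate"),
                                 exact_max = 9) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("spearman_correlation: need n >= 3",
          class = "beesem_insufficient_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("spearman_correlation: constant input has undefined rank correlation",
          class = "beesem_degenerate_error")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  use_exact <- switch(method,
    auto = !ties && n <= exact_max,
    exact = {
      if (ties || n > exact_max) {
        abort(paste0("spearman_correlation: exact method needs tie-free ",
                     "data with n <= ", exact_max),
              class = "beesem_domain_error")
      }
      TRUE
    },
    approximate = FALSE
  )
  if (use_exact) {
    perms <- all_permutations(n)
    # rho for each permutation of y-ranks against fixed x-ranks
    mu <- (n + 1) / 2
    denom <- sum((rx - mu)^2)  # equals sum((ry-mu)^2) when tie-free
    rhos <- as.vector((matrix(ry[perms], nrow = nrow(perms)) %*%
                         (rx - mu))) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    meth <- "exact"
  } else {
    stat <- if (abs(rho) == 1) Inf else rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (is.infinite(stat)) 0 else min(1, 2 * pt(-abs(stat), n - 2))
    meth <- "t-approximation"
  }
  tibble(estimate = rho, p_value = p, n = n, method = meth)
}

# all n! permutations of 1..n as a matrix (n! rows, n cols)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    remapped <- sub + (sub >= i)
    cbind(rep(i, nrow(sub)), remapped)
  }))
}
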