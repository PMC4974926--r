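test_that("partial correlation reduces to Pearson and handles duplicates", {
  set.seed(51)
  x <- rnorm(20); y <- rnorm(20)
  pc <- partial_correlation(x, y)
  expect_equal(pc$estimate, cor(x, y))
  expect_equal(pc$df, 18L)
  dup <- partial_correlation(x, x)
  expect_equal(dup$estimate, 1)
  expect_equal(dup$p_value, 0)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(52)
  for (rep in 1:60) {
    n <- sample(8:30, 1)
    k <- sample(0:3, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    z <- if (k > 0) as.data.frame(matrix(rnorm(n * k), n)) else NULL
    got <- partial_correlation(x, y, z)
    want <- lm_partial_correlation(x, y, z)
    expect_equal(got$estimate, want$estimate, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("partial correlation is symmetric and affine-invariant", {
  set.seed(53)
  x <- rnorm(15); y <- rnorm(15); z <- data.frame(a = rnorm(15))
  a <- partial_correlation(x, y, z)
  expect_equal(partial_correlation(y, x, z)$estimate, a$estimate)
  b <- partial_correlation(3 * x - 7, -2 * y + 1,
                           data.frame(a = 5 * z$a + 2))
  expect_equal(abs(b$estimate), abs(a$estimate), tolerance = 1e-12)
  expect_equal(b$estimate, -a$estimate, tolerance = 1e-12)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
})

test_that("partial correlation rejects degenerate inputs", {
  expect_error(partial_correlation(rep(1, 10), rnorm(10)),
               class = "beesem_degenerate_error")
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   data.frame(a = rnorm(4), b = rnorm(4))),
               class = "beesem_insufficient_data_error")
  expect_error(partial_correlation(1:5, 1:4), class = "beesem_domain_error")
})

test_that("Fisher's C matches closed forms and is additive and monotone", {
  expect_equal(fisher_c(c(1, 1, 1)), 0)
  expect_equal(fisher_c(exp(-1)), 2)
  expect_equal(fisher_c(c(0.5, 0.5)), -2 * 2 * log(0.5))
  set.seed(54)
  p1 <- runif(4); p2 <- runif(3)
  expect_equal(fisher_c(c(p1, p2)), fisher_c(p1) + fisher_c(p2))
  expect_gt(fisher_c(0.01), fisher_c(0.5))
  expect_warning(cc <- fisher_c(c(0.5, 0)), "rejected")
  expect_identical(cc, Inf)
  expect_error(fisher_c(c(0.5, 1.2)), class = "beesem_domain_error")
})

test_that("dsep_test aggregates claims, with the saturated convention", {
  set.seed(55)
  data <- simulate_sem(tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                                      coef = c(0.5, 0.5)), n = 40, seed = 1)
  fit <- dsep_test(causal_model(c("A -> B", "B -> C")), data)
  expect_equal(fit$k, 1)
  expect_equal(fit$df, 2L)
  expect_equal(fit$C, fisher_c(fit$claims$p_value))
  expect_equal(fit$p_value, pchisq(fit$C, 2, lower.tail = FALSE))
  g <- glance(fit)
  expect_equal(g$C, fit$C)
  expect_equal(nrow(tidy(fit)), 1)

  sat <- causal_model(c("A -> B", "A -> C", "B -> C"))
  expect_message(sfit <- dsep_test(sat, data), "saturated")
  expect_equal(sfit$p_value, 1)
  expect_equal(sfit$C, 0)
  expect_equal(sfit$df, 0L)
  expect_true(sfit$saturated)

  expect_error(dsep_test(causal_model("A -> Q"), data),
               class = "beesem_model_error")
})

test_that("AIC variants compute their formulas and classify support", {
  expect_equal(model_aic(10, K = 3, n = 14, formula = "shipley")$AIC, 16)
  expect_equal(
    model_aic(10, K = 3, n = 14, formula = "shipley_corrected")$AIC,
    10 + 2 * 3 * 14 / 10
  )
  expect_equal(model_aic(10, K = 3, n = 14, formula = "as_printed")$AIC,
               2 * log(10) + 6)
  expect_error(model_aic(0, K = 3, n = 14, formula = "as_printed"),
               class = "beesem_domain_error")
  expect_error(model_aic(1, K = 13, n = 14, formula = "shipley_corrected"),
               class = "beesem_domain_error")
  expect_error(model_aic(1, K = 0, n = 14), class = "beesem_domain_error")

  set.seed(56)
  data <- simulate_sem(tibble::tibble(from = "A", to = "B", coef = 0.4),
                       n = 30, variables = c("A", "B", "C"), seed = 2)
  m <- causal_model("A -> B", variables = c("A", "B", "C"))
  fits <- list(m1 = dsep_test(m, data), m2 = dsep_test(m, data))
  rk <- rank_models(fits)
  expect_equal(rk$delta_AIC, c(0, 0))
  expect_equal(rk$support, c("substantial", "substantial"))
  # support classes at the published thresholds
  cls <- function(d) dplyr::case_when(d < 3 ~ "substantial",
                                      d <= 10 ~ "less", TRUE ~ "none")
  expect_equal(cls(c(2.9, 8, 11)), c("substantial", "less", "none"))
})

test_that("path coefficients condition on co-parents only", {
  set.seed(57)
  edges <- tibble::tibble(from = c("A", "B"), to = c("Y", "Y"),
                          coef = c(0.5, 0.3))
  data <- simulate_sem(edges, n = 200, seed = 3)
  m <- causal_model(c("A -> Y", "B -> Y"))
  pc <- path_coefficients(m, data)
  # A -> Y conditions on B, the only co-parent
  expect_equal(pc$estimate[pc$from == "A"],
               partial_correlation(data$A, data$Y,
                                   data["B"])$estimate)
  # sole-parent edge reduces to plain Pearson
  m2 <- causal_model(c("A -> B", "B -> Y"))
  pc2 <- path_coefficients(m2, data)
  expect_equal(pc2$estimate[pc2$from == "A"], cor(data$A, data$B))
})

test_that("path estimates converge to implied values with growing n", {
  edges <- simplified_system_edges("y")
  implied <- implied_path_coefficients(edges)
  m <- causal_model(edges[c("from", "to")], name = "gen")
  errs <- vapply(c(200, 2000), function(n) {
    data <- simulate_sem(edges, n = n, seed = n)
    max(abs(path_coefficients(m, data)$estimate - implied$partial_r))
  }, numeric(1))
  expect_lt(errs[2], 0.1)
  expect_lt(errs[2], errs[1] + 0.02)
})
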