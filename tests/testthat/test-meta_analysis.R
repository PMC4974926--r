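test_that("Fisher z transform and its inverse behave as closed forms", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_equal(fisher_z_inv(fisher_z(0.77)), 0.77)
  expect_error(fisher_z(1), class = "beesem_domain_error")
  expect_error(fisher_z(-1.2), class = "beesem_domain_error")
})

test_that("weighted mean z uses n - 3 weights", {
  expect_equal(weighted_mean_z(c(0.2, 0.6), c(13, 7)),
               (10 * 0.2 + 4 * 0.6) / 14)
  expect_equal(weighted_mean_z(0.37, 10), 0.37)
  # equal n: arithmetic mean
  z <- c(0.1, 0.4, -0.2)
  expect_equal(weighted_mean_z(z, rep(9, 3)), mean(z))
  expect_error(weighted_mean_z(c(0.1, 0.2), c(10, 3)),
               class = "beesem_domain_error")
  expect_error(weighted_mean_z(numeric(0), numeric(0)),
               class = "beesem_domain_error")
})

test_that("bootstrap CI is reproducible and collapses when degenerate", {
  d <- tibble::tibble(estimate = c(-0.4, -0.1, -0.3), n = c(14, 14, 10))
  a <- bootstrap_ci(d, B = 2000, seed = 77)
  b <- bootstrap_ci(d, B = 2000, seed = 77)
  expect_identical(a$ci_z, b$ci_z)
  expect_lte(a$ci_z[1], a$ci_z[2])
  # identical inputs: the interval is a point
  same <- tibble::tibble(estimate = rep(0.25, 4), n = rep(12, 4))
  ci <- bootstrap_ci(same, B = 500, seed = 1)
  expect_equal(ci$ci_z[1], ci$ci_z[2])
  expect_equal(ci$r_w, 0.25)
  g <- glance(a)
  expect_equal(g$k, 3)
  expect_equal(g$ci_r_lower, fisher_z_inv(a$ci_z[1]))
  expect_error(bootstrap_ci(d[0, ], B = 10), class = "beesem_domain_error")
})

test_that("two-species bootstrap matches the exact 3-point distribution", {
  d <- tibble::tibble(estimate = c(0.6, -0.2), n = c(14, 8))
  z <- fisher_z(d$estimate); w <- d$n - 3
  # resamples: (1,1) -> z1, (2,2) -> z2, mixed -> weighted mean
  support <- sort(c(z[1], z[2], sum(w * z) / sum(w)))
  B <- 1e4
  ci <- bootstrap_ci(d, B = B, seed = 3)
  # 2.5% quantile lies in the lowest atom (prob .25), 97.5% in the highest
  expect_lt(abs(ci$ci_z[1] - support[1]), 1 / sqrt(B))
  expect_lt(abs(ci$ci_z[2] - support[3]), 1 / sqrt(B))
})

test_that("wider B does not move the CI beyond Monte-Carlo noise", {
  d <- tibble::tibble(estimate = c(-0.5, -0.2, -0.35, 0.1), n = rep(14, 4))
  cis <- lapply(c(1e3, 1e4, 1e5), function(B) {
    bootstrap_ci(d, B = B, seed = 11)$ci_z
  })
  expect_lt(abs(cis[[3]][1] - cis[[2]][1]), 0.05)
  expect_lt(abs(cis[[3]][2] - cis[[2]][2]), 0.05)
  expect_lt(abs(cis[[2]][1] - cis[[1]][1]), 0.1)
})

test_that("Spearman correlation hits the rank closed forms", {
  expect_equal(spearman_correlation(1:7, (1:7)^3)$estimate, 1)
  expect_equal(spearman_correlation(1:7, -(1:7))$estimate, -1)
  expect_error(spearman_correlation(1:2, 2:1),
               class = "beesem_insufficient_data_error")
  expect_error(spearman_correlation(rep(2, 5), 1:5),
               class = "beesem_degenerate_error")
})

test_that("Spearman rho equals the rank-then-Pearson oracle", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(4:9, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_correlation(x, y)
    expect_equal(got$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(got$estimate, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p agrees with the reference implementation", {
  set.seed(62)
  for (rep in 1:15) {
    n <- sample(5:7, 1)
    x <- sample(n); y <- sample(n)
    got <- spearman_correlation(x, y, method = "exact")
    want <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = TRUE))
    expect_equal(got$estimate, unname(want$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-9)
  }
  # ties fall back to the t approximation
  tied <- spearman_correlation(c(1, 1, 2, 3, 4), c(2, 1, 3, 5, 4))
  expect_equal(tied$method, "t-approximation")
  expect_error(
    spearman_correlation(c(1, 1, 2), c(1, 2, 3), method = "exact"),
    class = "beesem_domain_error"
  )
})
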