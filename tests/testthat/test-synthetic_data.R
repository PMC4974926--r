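test_that("the implied covariance of a chain multiplies coefficients", {
  edges <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                          coef = c(0.6, 0.5))
  S <- implied_covariance(edges)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_equal(S["A", "C"], 0.3)
  # over-determined system is rejected
  expect_error(
    implied_covariance(tibble::tibble(from = c("A", "B"), to = c("C", "C"),
                                      coef = c(0.9, 0.9))),
    class = "beesem_config_error"
  )
})

test_that("simulate_sem draws from the implied distribution", {
  edges <- simplified_system_edges("y")
  d1 <- simulate_sem(edges, 500, seed = 9)
  d2 <- simulate_sem(edges, 500, seed = 9)
  expect_identical(d1, d2)
  big <- simulate_sem(edges, 20000, seed = 10)
  S <- implied_covariance(edges)
  emp <- cor(as.matrix(big))[rownames(S), colnames(S)]
  expect_lt(max(abs(emp - S)), 0.03)
  # deterministic limit: unit coefficient leaves no noise
  det <- simulate_sem(tibble::tibble(from = "A", to = "B", coef = 1),
                      50, seed = 11)
  expect_equal(cor(det$A, det$B), 1)
})

test_that("generated sites are deterministic and within configuration", {
  cfg <- generator_config()
  a <- generate_sites(cfg, seed = 20)
  b <- generate_sites(cfg, seed = 20)
  expect_identical(a, b)
  s <- a$sites
  expect_equal(nrow(s), 14)
  expect_true(all(s$elevation >= 1100 & s$elevation <= 1500))
  expect_true(all(s$stability > 0))
  expect_s3_class(validate_bee_table(s, "sites"), "bee_sites_tbl")
  # weekly totals add back to the seasonal abundance
  wk <- a$weekly |>
    dplyr::group_by(site) |>
    dplyr::summarise(total = sum(count))
  expect_equal(wk$total[match(s$site, wk$site)], s$flower_abundance)
  # an infeasible stability target errors
  low <- generator_config(stability_scale = c(mean = 0.2, sd = 0.01))
  expect_error(generate_sites(low, seed = 21),
               class = "beesem_config_error")
})

test_that("zero-noise unit effect makes richness track elevation exactly", {
  cfg <- generator_config(site_model = tibble::tibble(
    from = c("elevation", "flower_richness_rarefied"),
    to = c("flower_richness_rarefied", "stability"),
    coef = c(1, 0.3)
  ))
  s <- generate_sites(cfg, seed = 22)$sites
  expect_equal(cor(s$elevation, s$flower_richness_rarefied,
                   method = "spearman"), 1)
})

test_that("generated nests conserve totals and honour zero intensity", {
  cfg <- generator_config()
  sites <- generate_sites(cfg, seed = 23)$sites
  nn <- generate_nests(cfg, sites, seed = 24)
  expect_equal(sum(nn$nests$total_nests), nrow(nn$records))
  expect_equal(sum(nn$nests$total_cells), sum(nn$records$cells))
  expect_s3_class(nn$nests, "bee_nests_tbl")
  # round-trip through reproduction_summaries is consistent
  again <- reproduction_summaries(nn$records, sites = sites$site)
  expect_equal(as.data.frame(again), as.data.frame(nn$nests))

  none <- generate_nests(generator_config(base_nests = 0), sites, seed = 25)
  expect_equal(nrow(none$records), 0)
})

test_that("a negative elevation effect is recovered in sign", {
  set.seed(26)
  cfg <- generator_config(
    n_sites = 100,
    nest_coefs = c(elevation = -0.4, flower_richness_rarefied = 0,
                   stability = 0)
  )
  m <- causal_model("elevation -> total_nests")
  hits <- vapply(1:200, function(i) {
    s <- generate_sites(cfg, weekly = FALSE)$sites
    nn <- generate_nests(cfg, s)
    d <- nn$nests |>
      dplyr::group_by(site) |>
      dplyr::summarise(total_nests = sum(total_nests)) |>
      dplyr::left_join(s, by = "site")
    path_coefficients(m, d)$estimate < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("meta-analytic limits cover a common generating effect", {
  # percentile bootstrap at k = 7 species undercovers the nominal 95%
  # somewhat; coverage should sit in the high-80s to mid-90s, not collapse
  set.seed(81)
  edges <- tibble::tibble(from = "x", to = "y", coef = 0.3)
  m <- causal_model(edges[c("from", "to")])
  true_z <- fisher_z(0.3)
  cover <- vapply(1:150, function(i) {
    coefs <- vapply(1:7, function(s) {
      path_coefficients(m, simulate_sem(edges, 30))$estimate
    }, numeric(1))
    ci <- bootstrap_ci(tibble::tibble(estimate = coefs, n = 30),
                       B = 400)$ci_z
    ci[1] <= true_z && true_z <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 0.99)
})

test_that("pollen loads validate and encode the diet-breadth gradient", {
  cfg <- generator_config()
  sites <- generate_sites(cfg, seed = 27)$sites
  nn <- generate_nests(cfg, sites, seed = 28)
  pol <- generate_pollen(cfg, nn$records, seed = 29)
  expect_s3_class(pol, "bee_pollen_tbl")
  gen <- generalization_indices(pol, reps = 200, seed = 30)
  # configured breadth gradient shows up as a strong monotone trend
  breadth <- cfg$diet_breadth[as.integer(sub("bee_", "", gen$bee_species))]
  expect_gt(cor(breadth, gen$rarefied_degree, method = "spearman"), 0.7)

  # monolectic limit: a single plant species, degree 1 at any depth
  mono <- generator_config(diet_breadth = rep(1e-3, 7))
  pol1 <- generate_pollen(mono, nn$records[1:20, ], seed = 31)
  gen1 <- generalization_indices(pol1, reps = 50, seed = 32)
  expect_equal(gen1$rarefied_degree, rep(1, nrow(gen1)))
  expect_equal(gen1$rarefied_simpson, rep(1, nrow(gen1)))

  # polylectic limit: near-uniform use of the whole pool
  poly <- generator_config(diet_breadth = rep(1e6, 7), grains_mean = 2000)
  pol2 <- generate_pollen(poly, nn$records[1:20, ], seed = 33)
  gen2 <- generalization_indices(pol2, reps = 100, seed = 34)
  expect_gt(min(gen2$rarefied_simpson), 0.75 * cfg$n_plant_species)
})
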