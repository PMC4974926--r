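test_that("reproduction summaries aggregate nests and encode absence", {
  records <- tibble::tibble(
    bee_species = c("sp1", "sp1", "sp1", "sp2"),
    site = c("A", "A", "B", "A"),
    cells = c(4, 2, 5, 7)
  )
  out <- reproduction_summaries(records, sites = c("A", "B", "C"))
  a <- out[out$bee_species == "sp1" & out$site == "A", ]
  expect_equal(a$mean_cells_per_nest, 3)
  expect_equal(a$total_cells, 6)
  expect_equal(a$total_nests, 2L)
  # absent species-site: totals zero, mean undefined
  absent <- out[out$bee_species == "sp2" & out$site == "B", ]
  expect_equal(absent$total_cells, 0)
  expect_equal(absent$total_nests, 0L)
  expect_true(is.na(absent$mean_cells_per_nest))
  expect_equal(nrow(out), 6)  # 2 species x 3 sites

  # single nest of 4 cells
  one <- reproduction_summaries(tibble::tibble(
    bee_species = "sp", site = "s", cells = 4))
  expect_equal(one$mean_cells_per_nest, 4)
  expect_equal(one$total_cells, 4)
  expect_equal(one$total_nests, 1L)
})

test_that("reproduction summaries conserve raw counts", {
  set.seed(21)
  for (rep in 1:5) {
    records <- tibble::tibble(
      bee_species = sample(paste0("sp", 1:4), 60, replace = TRUE),
      site = sample(paste0("s", 1:5), 60, replace = TRUE),
      cells = rpois(60, 3) + 1
    )
    out <- reproduction_summaries(records)
    expect_equal(sum(out$total_cells), sum(records$cells))
    expect_equal(sum(out$total_nests), nrow(records))
    per_sp <- tapply(records$cells, records$bee_species, sum)
    agg <- tapply(out$total_cells, out$bee_species, sum)
    expect_equal(agg[names(per_sp)], per_sp)
  }
})

test_that("the pollen-length proxy is a plain, guarded division", {
  expect_equal(pollen_length_proxy(30, 10), 3)
  expect_equal(pollen_length_proxy(0, 5), 0)
  expect_equal(pollen_length_proxy(2 * 17, 4), 2 * pollen_length_proxy(17, 4))
  expect_error(pollen_length_proxy(10, 0), class = "beesem_domain_error")
  expect_error(pollen_length_proxy(-1, 1), class = "beesem_domain_error")
})

test_that("the focal-species filter reproduces the survey's seven species", {
  census <- monte_nest_census()
  focal <- filter_focal_species(census)
  expect_length(focal, 7)
  expect_setequal(focal, c(
    "Anthidium decaspilum", "Anthidium rubripes",
    "Anthidium vigintipunctatum", "Megachile leucographa",
    "Megachile ctenophora", "Trichothurgus laticeps",
    "Xylocopa atamisquensis"
  ))
  # stable input order
  expect_equal(focal, census$bee_species[census$total_nests >= 30])
  expect_length(filter_focal_species(census, min_nests = 0), 11)
  expect_length(filter_focal_species(census, min_nests = 1000), 0)
  # named-vector interface agrees
  expect_equal(
    filter_focal_species(setNames(census$total_nests, census$bee_species)),
    focal
  )
})

test_that("rarefied degree shares the richness contract", {
  expect_equal(rarefied_degree(c(2, 2), 2), 5 / 3, tolerance = 1e-10)
  expect_equal(rarefied_degree(c(4, 3, 2), 9), 3)   # full sample
  expect_equal(rarefied_degree(42, 10), 1)          # single-plant diet
})

test_that("rarefied Simpson hits closed forms at full depth", {
  # proportions (0.5, 0.25, 0.25): inverse Simpson = 1/0.375
  x <- rarefied_simpson(c(10, 5, 5), 20, reps = 5)
  expect_equal(as.numeric(x), 1 / 0.375)
  expect_equal(attr(x, "se"), 0)
  expect_equal(as.numeric(rarefied_simpson(rep(6, 4), 24, reps = 5)), 4)
  expect_equal(as.numeric(rarefied_simpson(50, 13, reps = 5)), 1)
  expect_error(rarefied_simpson(c(2, 2), 10), class = "beesem_domain_error")
  expect_error(rarefied_simpson(c(2, 2), 2, reps = 0),
               class = "beesem_domain_error")
})

test_that("rarefied Simpson is seed-reproducible and converges", {
  counts <- c(40, 25, 20, 10, 5)
  a <- rarefied_simpson(counts, 30, reps = 200, seed = 5)
  b <- rarefied_simpson(counts, 30, reps = 200, seed = 5)
  expect_identical(a, b)
  # Monte-Carlo se shrinks roughly as 1/sqrt(reps) and brackets the truth
  big <- rarefied_simpson(counts, 30, reps = 4000, seed = 6)
  expect_lt(attr(big, "se"), attr(a, "se"))
  expect_lt(attr(big, "se"), 0.05)
  expect_lt(abs(as.numeric(big) - as.numeric(a)),
            5 * (attr(a, "se") + attr(big, "se")))
})

test_that("generalization indices respect their ordering invariants", {
  set.seed(31)
  pollen <- random_pollen_table(n_ind = 6, n_plants = 5)
  gen <- generalization_indices(pollen, reps = 300, seed = 9)
  expect_true(all(gen$rarefied_degree >= 1))
  # inverse Simpson of any subsample cannot exceed its richness
  expect_true(all(gen$rarefied_simpson <=
                    gen$rarefied_degree + 3 * gen$rarefied_simpson_se + 1e-9))
  observed_degree <- pollen |>
    dplyr::group_by(bee_species) |>
    dplyr::summarise(k = dplyr::n_distinct(plant_species))
  expect_true(all(gen$rarefied_degree <=
                    observed_degree$k[match(gen$bee_species,
                                            observed_degree$bee_species)]))
})
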