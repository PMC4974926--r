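# Small in-code fixtures and CSV writers for the io tests.

nests_csv_lines <- c(
  "codigo.i,sitio,mean.no.celd,celd.tot,nidos.tot",
  "sp1,A,2.5,5,2",
  "sp1,B,3,3,1",
  "sp2,A,4,4,1"
)

sites_csv_lines <- c(
  "sitio,abund.flores,raref,altitud,anio.q,notes",
  "A,1200,8.2,1150,12,dry",
  "B,900,6.1,1480,3,wet"
)

pollen_csv_lines <- c(
  "id.trampa,codigo.i,site,codigo.p,sum.sp,sum.tot,prop",
  "t1,sp1,A,p1,30,40,0.75",
  "t1,sp1,A,p2,10,40,0.25",
  "t2,sp2,B,p1,20,20,1"
)

write_fixture <- function(lines, dir = withr_like_tempdir()) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

withr_like_tempdir <- function() tempdir()

# random valid tables for round-trip property tests
random_nest_table <- function(n_species = 3, n_sites = 4) {
  grid <- expand.grid(bee_species = paste0("sp", seq_len(n_species)),
                      site = paste0("s", seq_len(n_sites)),
                      stringsAsFactors = FALSE)
  nests <- rpois(nrow(grid), 3)
  cells <- ifelse(nests > 0, nests * (1 + rpois(nrow(grid), 2)), 0)
  tibble::tibble(
    bee_species = grid$bee_species, site = grid$site,
    mean_cells_per_nest = ifelse(nests > 0, cells / nests, NA_real_),
    total_cells = as.numeric(cells), total_nests = as.integer(nests)
  )
}

random_site_table <- function(n_sites = 5) {
  tibble::tibble(
    site = paste0("s", seq_len(n_sites)),
    flower_abundance = round(runif(n_sites, 100, 5000), 1),
    flower_richness_rarefied = round(runif(n_sites, 2, 15), 3),
    elevation = round(runif(n_sites, 1100, 1500), 1),
    years_since_fire = round(runif(n_sites, 0, 40), 1)
  )
}

random_pollen_table <- function(n_ind = 4, n_plants = 3) {
  rows <- lapply(seq_len(n_ind), function(i) {
    cnt <- rpois(n_plants, 5) + c(1, rep(0, n_plants - 1))
    keep <- cnt > 0
    tibble::tibble(
      bee_individual = paste0("t", i),
      bee_species = paste0("sp", 1 + i %% 2),
      site = "A",
      plant_species = paste0("p", seq_len(n_plants))[keep],
      grains_of_species = cnt[keep],
      grains_total = sum(cnt),
      proportion = cnt[keep] / sum(cnt)
    )
  })
  dplyr::bind_rows(rows)
}

# a complete-structure generating system with realistic coefficients,
# used for calibration experiments (type-I error, recovery)
complete_system_edges <- function(response = "total_cells") {
  tibble::tibble(
    from = c("elevation", "elevation", "flower_richness_rarefied",
             "elevation", "flower_abundance", "flower_richness_rarefied",
             "stability", "years_since_fire"),
    to = c("flower_richness_rarefied", "flower_abundance", "stability",
           response, response, response, response, response),
    coef = c(0.39, -0.51, -0.54, -0.45, 0.2, 0.2, 0.25, 0.25)
  )
}

simplified_system_edges <- function(response = "total_cells") {
  tibble::tibble(
    from = c("elevation", "flower_richness_rarefied",
             "elevation", "flower_richness_rarefied", "stability"),
    to = c("flower_richness_rarefied", "stability",
           response, response, response),
    coef = c(0.39, -0.54, -0.5, 0.25, -0.25)
  )
}
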