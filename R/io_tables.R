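#' Schema registry for the three survey tables
#'
#' The field data circulate as three CSV files whose headers use the original
#' Spanish column names of the supplementary material of trap-nest studies in
#' the Monte desert. The registry maps those on-disk names to the canonical
#' column names used throughout this package. Users working with differently
#' named files can supply a modified registry to [read_bee_table()] /
#' [write_bee_table()].
#'
#' Schemas:
#' \describe{
#'   \item{nests}{per bee species and site reproduction summary:
#'     `codigo.i` -> `bee_species`, `sitio` -> `site`,
#'     `mean.no.celd` -> `mean_cells_per_nest`, `celd.tot` -> `total_cells`,
#'     `nidos.tot` -> `total_nests`.}
#'   \item{sites}{per-site environment: `sitio` -> `site`,
#'     `abund.flores` -> `flower_abundance`, `raref` -> `flower_richness_rarefied`,
#'     `altitud` -> `elevation`, `anio.q` -> `years_since_fire`.}
#'   \item{pollen}{per bee individual pollen load: `id.trampa` -> `bee_individual`,
#'     `codigo.i` -> `bee_species`, `site` -> `site`, `codigo.p` -> `plant_species`,
#'     `sum.sp` -> `grains_of_species`, `sum.tot` -> `grains_total`,
#'     `prop` -> `proportion`.}
#' }
#'
#' @return A named list of named character vectors; names are on-disk column
#'   names, values are canonical names. List order is the documented column
#'   order of each file.
#' @export
#' @examples
#' bee_schema_registry()$nests
bee_schema_registry <- function() {
  list(
    nests = c(
      codigo.i = "bee_species",
      sitio = "site",
      mean.no.celd = "mean_cells_per_nest",
      celd.tot = "total_cells",
      nidos.tot = "total_nests"
    ),
    sites = c(
      sitio = "site",
      abund.flores = "flower_abundance",
      raref = "flower_richness_rarefied",
      altitud = "elevation",
      anio.q = "years_since_fire"
    ),
    pollen = c(
      id.trampa = "bee_individual",
      codigo.i = "bee_species",
      site = "site",
      codigo.p = "plant_species",
      sum.sp = "grains_of_species",
      sum.tot = "grains_total",
      prop = "proportion"
    )
  )
}

# canonical columns that must parse as numbers, per schema
.numeric_cols <- list(
  nests = c("mean_cells_per_nest", "total_cells", "total_nests"),
  sites = c("flower_abundance", "flower_richness_rarefied", "elevation",
            "years_since_fire"),
  pollen = c("grains_of_species", "grains_total", "proportion")
)

#' Read one of the three survey CSV schemas into a validated tibble
#'
#' Reads a CSV with the on-disk header named in the schema registry, renames
#' columns to canonical names, coerces numeric columns, and validates the
#' schema's invariants. Extra columns are preserved untouched (they are simply
#' carried along and ignored by the analysis).
#'
#' @param path Path to a CSV file (comma separated, UTF-8, `.` decimal).
#' @param schema One of `"nests"`, `"sites"`, `"pollen"`.
#' @param registry Schema registry, see [bee_schema_registry()].
#' @param validate Run invariant validation (default `TRUE`).
#' @param ... Passed on to the validator (e.g. `elevation_range` for the
#'   sites schema, `tol` for consistency tolerances).
#' @return A tibble with canonical column names, classed
#'   `"bee_<schema>_tbl"` in addition to `tbl_df`.
#' @seealso [write_bee_table()], [validate_bee_table()]
#' @export
read_bee_table <- function(path, schema = c("nests", "sites", "pollen"),
                           registry = bee_schema_registry(),
                           validate = TRUE, ...) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "beesem_io_error")
  }
  map <- registry[[schema]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(names(map), names(raw))
  if (length(missing)) {
    abort(
      paste0("schema '", schema, "': missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      class = "beesem_schema_error"
    )
  }
  out <- dplyr::rename(raw, !!!setNames(rlang::syms(names(map)), unname(map)))
  for (col in intersect(.numeric_cols[[schema]], names(out))) {
    vals <- out[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "NA" & vals != "" & is.na(num))
    if (length(bad)) {
      abort(
        paste0("schema '", schema, "': non-numeric value '", vals[bad[1]],
               "' in column '", col, "' at data row ", bad[1]),
        class = "beesem_parse_error"
      )
    }
    out[[col]] <- num
  }
  # extra columns: guess their type (they are carried along untouched)
  for (col in setdiff(names(out), unname(map))) {
    out[[col]] <- readr::parse_guess(out[[col]], guess_integer = FALSE)
  }
  out <- new_bee_table(out, schema)
  if (validate) validate_bee_table(out, schema, ...) else out
}

new_bee_table <- function(x, schema) {
  x <- as_tibble(x)
  class(x) <- c(paste0("bee_", schema, "_tbl"), class(x))
  attr(x, "bee_schema") <- schema
  x
}

#' Validate a survey table against its schema invariants
#'
#' @param x A tibble with canonical column names.
#' @param schema One of `"nests"`, `"sites"`, `"pollen"`; defaults to the
#'   schema recorded on `x`.
#' @param elevation_range Plausible elevation bounds in metres for the sites
#'   schema (validated, configurable).
#' @param tol Relative tolerance for "approximately equal" checks
#'   (mean-cells consistency, pollen proportions).
#' @return `x` invisibly reclassed, or an error of class
#'   `"beesem_validation_error"` naming the offending field.
#' @export
validate_bee_table <- function(x, schema = attr(x, "bee_schema"),
                               elevation_range = c(0, 6000), tol = 0.01) {
  stopifnot(!is.null(schema))
  fail <- function(msg) abort(paste0("schema '", schema, "': ", msg),
                              class = "beesem_validation_error")
  switch(schema,
    nests = {
      if (anyDuplicated(x[c("bee_species", "site")]))
        fail("duplicate (bee_species, site) pair")
      if (any(x$total_cells < 0, na.rm = TRUE) ||
          any(x$total_nests < 0, na.rm = TRUE) ||
          any(x$mean_cells_per_nest < 0, na.rm = TRUE))
        fail("negative count in total_cells/total_nests/mean_cells_per_nest")
      zero <- !is.na(x$total_nests) & x$total_nests == 0
      if (any(zero & x$total_cells != 0))
        fail("total_nests = 0 but total_cells > 0")
      if (any(zero & !is.na(x$mean_cells_per_nest)))
        fail("total_nests = 0 but mean_cells_per_nest present")
      pos <- !is.na(x$total_nests) & x$total_nests > 0 &
        !is.na(x$mean_cells_per_nest)
      expect <- x$total_cells[pos] / x$total_nests[pos]
      off <- abs(x$mean_cells_per_nest[pos] - expect) >
        pmax(tol * pmax(expect, 1), 0.5 / pmax(x$total_nests[pos], 1))
      if (any(off))
        fail(paste0("mean_cells_per_nest inconsistent with ",
                    "total_cells/total_nests at row ", which(pos)[off][1]))
    },
    sites = {
      if (anyDuplicated(x$site)) fail("duplicate site label")
      bad <- which(x$elevation < elevation_range[1] |
                     x$elevation > elevation_range[2])
      if (length(bad))
        fail(paste0("elevation ", x$elevation[bad[1]],
                    " outside plausible range [", elevation_range[1], ", ",
                    elevation_range[2], "] at row ", bad[1]))
      if (any(x$years_since_fire < 0, na.rm = TRUE))
        fail("negative years_since_fire")
      if (any(x$flower_richness_rarefied < 0, na.rm = TRUE))
        fail("negative flower_richness_rarefied")
    },
    pollen = {
      if (any(x$grains_of_species < 0 | x$grains_total < 0))
        fail("negative grain count")
      if (any(x$proportion < 0 | x$proportion > 1))
        fail("proportion outside [0, 1]")
      chk <- x |>
        dplyr::group_by(.data$bee_individual) |>
        dplyr::summarise(
          sum_sp = sum(.data$grains_of_species),
          tot = .data$grains_total[1],
          one_tot = dplyr::n_distinct(.data$grains_total) == 1L,
          psum = sum(.data$proportion),
          .groups = "drop"
        )
      if (any(!chk$one_tot))
        fail(paste0("grains_total differs within individual '",
                    chk$bee_individual[!chk$one_tot][1], "'"))
      off <- abs(chk$sum_sp - chk$tot) > 0
      if (any(off))
        fail(paste0("grain counts of individual '",
                    chk$bee_individual[off][1], "' do not sum to grains_total"))
      offp <- abs(chk$psum - 1) > tol
      if (any(offp))
        fail(paste0("proportions of individual '",
                    chk$bee_individual[offp][1], "' sum to ",
                    signif(chk$psum[offp][1], 4), ", not 1"))
      offr <- abs(x$proportion - x$grains_of_species / x$grains_total) > tol
      if (any(offr, na.rm = TRUE))
        fail(paste0("proportion inconsistent with grain counts at row ",
                    which(offr)[1]))
    },
    fail("unknown schema")
  )
  invisible(new_bee_table(x, schema))
}

#' Write a survey table back to its on-disk CSV schema
#'
#' Inverse of [read_bee_table()]: canonical columns are renamed to the on-disk
#' names of the registry, written first and in the documented order; any extra
#' columns follow. `read_bee_table(write_bee_table(x))` round-trips.
#'
#' @inheritParams read_bee_table
#' @param x Validated table as returned by [read_bee_table()] (or any tibble
#'   with the canonical columns).
#' @return `path`, invisibly.
#' @export
write_bee_table <- function(x, path, schema = attr(x, "bee_schema"),
                            registry = bee_schema_registry()) {
  if (is.null(schema)) {
    abort("schema not recorded on table; pass `schema` explicitly",
          class = "beesem_io_error")
  }
  map <- registry[[schema]]
  missing <- setdiff(unname(map), names(x))
  if (length(missing)) {
    abort(paste0("cannot write schema '", schema, "': missing column(s) ",
                 paste(missing, collapse = ", ")),
          class = "beesem_schema_error")
  }
  out <- dplyr::relocate(x, dplyr::all_of(unname(map)))
  names(out)[seq_along(map)] <- names(map)
  ok <- tryCatch({ readr::write_csv(out, path, progress = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write '", path, "': ", conditionMessage(ok)),
          class = "beesem_io_error")
  }
  invisible(path)
}

#' Nest census of the Monte desert trap-nest survey
#'
#' Occupied trap-nest totals for the 11 cavity-nesting bee species recorded
#' over one flowering season at the 14 Monte desert study sites (598 nests in
#' total). Shipped as a plain-text fixture; used for the focal-species filter
#' and census arithmetic.
#'
#' @return Tibble with columns `bee_species` (character) and `total_nests`
#'   (integer), one row per recorded species, in the published order.
#' @export
#' @examples
#' census <- monte_nest_census()
#' sum(census$total_nests)  # 598
monte_nest_census <- function() {
  path <- system.file("extdata", "monte_nest_census.csv", package = "beesem",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "ci", progress = FALSE,
                  show_col_types = FALSE)
}
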