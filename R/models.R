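#' Candidate causal models of bee reproduction
#'
#' Constructors for the two candidate structures evaluated in the Monte
#' desert analysis, parameterised by the reproductive response variable
#' (estimation is piecewise, one model per response).
#'
#' The complete model lets elevation drive rarefied flower richness and
#' flower abundance, richness drive temporal stability, and all of
#' elevation, abundance, richness, stability and time since fire act
#' directly on the response. The simplified (nested) model drops flower
#' abundance and fire, keeping richness, stability and elevation as direct
#' causes; richness and elevation edges are on the keep-list so pruning
#' retains them even when non-significant, as their trends are of central
#' scientific interest.
#'
#' @param response Name of the response column (e.g. `"total_cells"`,
#'   `"total_nests"`, `"mean_cells_per_nest"`).
#' @param name Model label.
#' @return A [causal_model()].
#' @export
#' @examples
#' model_complete("total_cells")
model_complete <- function(response, name = "complete") {
  causal_model(
    c(
      "elevation -> flower_richness_rarefied",
      "elevation -> flower_abundance",
      "flower_richness_rarefied -> stability",
      paste("elevation ->", response),
      paste("flower_abundance ->", response),
      paste("flower_richness_rarefied ->", response),
      paste("stability ->", response),
      paste("years_since_fire ->", response)
    ),
    name = name
  )
}

#' @rdname model_complete
#' @export
model_simplified <- function(response, name = "simplified") {
  causal_model(
    c(
      "elevation -> flower_richness_rarefied",
      "flower_richness_rarefied -> stability",
      paste("elevation ->", response),
      paste("flower_richness_rarefied ->", response),
      paste("stability ->", response)
    ),
    name = name,
    keep = c(paste("flower_richness_rarefied ->", response),
             paste("elevation ->", response))
  )
}

#' Read / write causal model definitions as YAML
#'
#' A model definition file holds `name`, `edges` (list of `"X -> Y"`
#' strings), optional `variables`, `keep` and `response`. Ships the model
#' structures as editable data rather than hard-coded constants.
#'
#' @param path YAML file path.
#' @return For `read_model()`, a [causal_model()] (the `response` field, if
#'   present, is attached as attribute `"response"`).
#' @export
read_model <- function(path) {
  spec <- yaml::read_yaml(path)
  model_from_list(spec)
}

#' @rdname read_model
#' @param spec A list with the fields documented above.
#' @export
model_from_list <- function(spec) {
  m <- causal_model(
    unlist(spec$edges),
    variables = spec$variables %||% NULL,
    name = spec$name %||% "model",
    keep = unlist(spec$keep %||% character())
  )
  attr(m, "response") <- spec$response %||% NULL
  m
}

#' @rdname read_model
#' @param model A [causal_model()].
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(
    list(
      name = model$name,
      variables = model$variables,
      edges = paste(model$edges$from, "->", model$edges$to),
      keep = if (nrow(model$keep)) {
        paste(model$keep$from, "->", model$keep$to)
      },
      response = attr(model, "response")
    ),
    path
  )
  invisible(path)
}
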