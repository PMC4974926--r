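#' Define a causal model as a directed acyclic graph
#'
#' A causal model is a DAG over named (observed) variables; each directed
#' edge `cause -> effect` is a hypothesised direct effect. Candidate models
#' are compared by testing the conditional independencies the DAG implies
#' ([dsep_test()]) and by AIC ([rank_models()]).
#'
#' @param edges Either a character vector of `"X -> Y"` strings or a data
#'   frame with columns `from`, `to`.
#' @param variables Optional character vector of variables; defaults to the
#'   union of edge endpoints. Isolated variables may be added here.
#' @param name Model label used in reports (e.g. `"complete"`).
#' @param keep Optional character vector of `"X -> Y"` edges protected from
#'   [prune_model()].
#' @return An object of class `causal_model`: list with `name`, `variables`,
#'   `edges` (tibble `from`, `to`), `keep`.
#' @export
#' @examples
#' m <- causal_model(c("A -> B", "B -> C"), name = "chain")
#' basis_set(m)
causal_model <- function(edges, variables = NULL, name = "model",
                         keep = character()) {
  edges <- parse_edges(edges)
  variables <- variables %||% unique(c(edges$from, edges$to))
  bad <- setdiff(c(edges$from, edges$to), variables)
  if (length(bad)) {
    abort(paste0("causal_model: edge endpoint(s) not in variables: ",
                 paste(unique(bad), collapse = ", ")),
          class = "beesem_model_error")
  }
  if (any(edges$from == edges$to)) {
    abort("causal_model: self-loop not allowed",
          class = "beesem_model_error")
  }
  if (anyDuplicated(edges[c("from", "to")])) {
    abort("causal_model: duplicate edge", class = "beesem_model_error")
  }
  m <- structure(
    list(name = name, variables = variables, edges = edges,
         keep = parse_edges(keep)),
    class = "causal_model"
  )
  if (is.null(topological_order(m))) {
    abort("causal_model: graph is cyclic", class = "beesem_model_error")
  }
  m
}

parse_edges <- function(edges) {
  if (is.data.frame(edges)) {
    return(tibble(from = as.character(edges$from),
                  to = as.character(edges$to)))
  }
  if (length(edges) == 0) return(tibble(from = character(), to = character()))
  parts <- strsplit(edges, "->", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort("edges must be 'X -> Y' strings or a from/to data frame",
          class = "beesem_model_error")
  }
  tibble(from = trimws(vapply(parts, `[[`, "", 1)),
         to = trimws(vapply(parts, `[[`, "", 2)))
}

#' @export
print.causal_model <- function(x, ...) {
  cat("<causal_model> ", x$name, ": ", length(x$variables), " variables, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to), sep = "\n")
  }
  invisible(x)
}

#' Parents of a variable in a causal model
#' @param model A [causal_model()].
#' @param v Variable name.
#' @return Character vector of direct causes of `v`.
#' @export
model_parents <- function(model, v) {
  model$edges$from[model$edges$to == v]
}

# Kahn's algorithm; NULL if cyclic
topological_order <- function(model) {
  vars <- model$variables
  indeg <- setNames(integer(length(vars)), vars)
  for (v in model$edges$to) indeg[v] <- indeg[v] + 1L
  order <- character(0)
  queue <- vars[indeg == 0]
  indeg_left <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    kids <- model$edges$to[model$edges$from == v]
    for (k in kids) {
      indeg_left[k] <- indeg_left[k] - 1L
      if (indeg_left[k] == 0) queue <- c(queue, k)
    }
  }
  if (length(order) < length(vars)) NULL else order
}

adjacent <- function(model, a, b) {
  any((model$edges$from == a & model$edges$to == b) |
        (model$edges$from == b & model$edges$to == a))
}

#' D-separation basis set of a causal model
#'
#' The basis set contains one conditional-independence claim per pair of
#' non-adjacent variables: the pair is claimed independent given the union of
#' the parents of both variables. Testing exactly these claims suffices to
#' test the DAG. Claims are returned in a deterministic canonical order
#' (lexicographic by the sorted pair).
#'
#' @param model A [causal_model()].
#' @return Tibble with columns `x`, `y` (the non-adjacent pair, `x < y`
#'   lexicographically) and `z` (list column: the conditioning set).
#' @export
#' @examples
#' basis_set(causal_model(c("A -> B", "B -> C")))  # A _||_ C | {B}
basis_set <- function(model) {
  vars <- sort(model$variables)
  pairs <- if (length(vars) < 2) {
    tibble(x = character(), y = character())
  } else {
    as_tibble(t(utils::combn(vars, 2)), .name_repair = ~ c("x", "y"))
  }
  pairs <- dplyr::filter(pairs,
                         !purrr::map2_lgl(.data$x, .data$y,
                                          ~ adjacent(model, .x, .y)))
  pairs$z <- purrr::map2(pairs$x, pairs$y, function(a, b) {
    sort(setdiff(union(model_parents(model, a), model_parents(model, b)),
                 c(a, b)))
  })
  dplyr::arrange(pairs, .data$x, .data$y)
}

#' Count the free parameters of a causal model
#'
#' Default counting rule: one parameter per edge (a path coefficient) plus
#' one variance per variable. Used as `K` in [model_aic()].
#'
#' @param model A [causal_model()].
#' @param rule `"edges_plus_variances"` (default) or `"edges"`.
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(model,
                                  rule = c("edges_plus_variances", "edges")) {
  rule <- match.arg(rule)
  nrow(model$edges) +
    if (rule == "edges_plus_variances") length(model$variables) else 0L
}

#' Drop weak, non-significant edges from a model
#'
#' Produces the nested, simplified model by removing every edge whose
#' estimated path coefficient is both non-significant (`p_value >= alpha`)
#' and small (`|estimate| < min_abs_r`). Edges on the model's keep-list (or
#' in `keep`) are never removed, so scientifically central variables can be
#' retained despite non-significant trends.
#'
#' @param model A [causal_model()].
#' @param estimates Path estimates for the model's edges, as returned by
#'   [path_coefficients()] (columns `from`, `to`, `estimate`, `p_value`).
#' @param alpha Significance threshold (default 0.05).
#' @param min_abs_r Coefficient-magnitude threshold; the default `Inf` prunes
#'   purely by significance.
#' @param keep Additional protected edges (`"X -> Y"` strings or data frame).
#' @param name Name for the pruned model.
#' @return A new, nested [causal_model()]. Variables left without any edge
#'   are dropped from the variable set; pruning away every edge warns.
#' @export
prune_model <- function(model, estimates, alpha = 0.05, min_abs_r = Inf,
                        keep = NULL, name = paste0(model$name, "_pruned")) {
  est <- dplyr::inner_join(model$edges, estimates, by = c("from", "to"))
  if (nrow(est) != nrow(model$edges)) {
    abort("prune_model: estimates do not cover every model edge",
          class = "beesem_model_error")
  }
  protected <- dplyr::bind_rows(model$keep, parse_edges(keep %||%
                                                          character()))
  est$protected <- paste(est$from, est$to) %in%
    paste(protected$from, protected$to)
  drop <- !est$protected & est$p_value >= alpha & abs(est$estimate) < min_abs_r
  kept <- est[!drop, c("from", "to")]
  if (nrow(kept) == 0) {
    warn("prune_model: pruning removed every edge")
  }
  causal_model(kept,
               variables = intersect(model$variables,
                                     unique(c(kept$from, kept$to))),
               name = name, keep = protected)
}
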