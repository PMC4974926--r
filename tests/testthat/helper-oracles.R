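# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Expected rarefied species count by full enumeration of all size-n
# subsamples of the individual pool (feasible for total counts <= ~10).
enum_rarefied_richness <- function(counts, n) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), n)
  mean(apply(subs, 2, function(idx) length(unique(pool[idx]))))
}

# Partial correlation by explicit residual regression with lm(), the
# textbook definition; p from the t distribution on n - 2 - |Z| df.
lm_partial_correlation <- function(x, y, z = NULL) {
  if (is.null(z) || NCOL(z) == 0) {
    r <- cor(x, y)
    k <- 0
  } else {
    z <- as.data.frame(z)
    rx <- resid(lm(x ~ ., data = z))
    ry <- resid(lm(y ~ ., data = z))
    r <- cor(rx, ry)
    k <- ncol(z)
  }
  df <- length(x) - 2 - k
  stat <- r * sqrt(df / (1 - r^2))
  list(estimate = r, p_value = 2 * pt(-abs(stat), df))
}

# --- brute-force d-separation by path blocking ------------------------

# descendants of v (inclusive) in a DAG given as a from/to data frame
dag_descendants <- function(edges, v) {
  out <- v
  frontier <- v
  while (length(frontier)) {
    nxt <- setdiff(edges$to[edges$from %in% frontier], out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# all simple undirected paths from a to b over the skeleton
dag_paths <- function(edges, vars, a, b) {
  nbr <- lapply(setNames(vars, vars), function(v) {
    union(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  paths <- list()
  walk <- function(path) {
    tail <- path[length(path)]
    if (tail == b) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (nx in setdiff(nbr[[tail]], path)) walk(c(path, nx))
  }
  walk(a)
  paths
}

# is the path v1..vk blocked by conditioning set z?
path_blocked <- function(edges, path, z) {
  if (length(path) <= 2) return(FALSE)
  has_edge <- function(a, b) any(edges$from == a & edges$to == b)
  for (i in 2:(length(path) - 1)) {
    v <- path[i]
    collider <- has_edge(path[i - 1], v) && has_edge(path[i + 1], v)
    if (collider) {
      if (!any(dag_descendants(edges, v) %in% z)) return(TRUE)
    } else {
      if (v %in% z) return(TRUE)
    }
  }
  FALSE
}

dsep_oracle <- function(edges, vars, x, y, z) {
  paths <- dag_paths(edges, vars, x, y)
  all(vapply(paths, function(p) path_blocked(edges, p, z), logical(1)))
}

# every DAG on `n` labelled vertices consistent with the order 1..n:
# one per subset of the upper-triangular ordered pairs. Covers every DAG
# up to vertex relabelling, to which basis_set and the oracle are blind.
upper_triangular_dags <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0
    if (!any(sel)) {
      return(data.frame(from = character(0), to = character(0)))
    }
    data.frame(from = paste0("v", pairs[sel, 1]),
               to = paste0("v", pairs[sel, 2]),
               stringsAsFactors = FALSE)
  })
}

# random DAG over n vertices with edge probability p
random_dag <- function(n, p = 0.4) {
  ord <- sample(paste0("v", seq_len(n)))
  edges <- data.frame(from = character(), to = character())
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) {
        edges <- rbind(edges, data.frame(from = ord[i], to = ord[j]))
      }
    }
  }
  list(edges = edges, vars = ord)
}
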