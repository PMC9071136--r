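#' @useDynLib pairtarget, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

graph_to_mcs_input <- function(g) {
  elem <- match(g$elem, names(ATOMIC_MASS), nomatch = 0L)
  bonds <- cbind(g$bonds[, 1:2, drop = FALSE], order = g$border)
  storage.mode(bonds) <- "integer"
  list(elem = as.integer(elem), bonds = bonds)
}

#' Maximum common substructure statistics for a molecule pair
#'
#' Finds the maximum common connected induced subgraph of the two molecular
#' graphs under element and bond-order compatibility (aromatic bonds match
#' only aromatic bonds) and reports its atom count together with the two
#' derived similarity scores:
#' \describe{
#'   \item{mcs_size}{atoms in the maximum common substructure}
#'   \item{ts_mcs}{`mcs_size / (n_a + n_b - mcs_size)`, an MCS Tanimoto}
#'   \item{oc}{`mcs_size / min(n_a, n_b)`, the overlap coefficient}
#' }
#' `ts_mcs <= oc` always holds. Pairs that exhaust the time budget are
#' flagged `timed_out` so callers can exclude them with an audit trail.
#'
#' @param a,b single-compound rows of a `compound_set`, or pre-built
#'   internal graphs.
#' @param time_budget seconds allowed for the search (default 5).
#' @return list with `mcs_size`, `ts_mcs`, `oc`, `timed_out`.
#' @export
mcs_stats <- function(a, b, time_budget = 5) {
  ga <- if (is.list(a) && !is.null(a$adj)) a else mol_graphs(a)[[1]]
  gb <- if (is.list(b) && !is.null(b$adj)) b else mol_graphs(b)[[1]]
  ia <- graph_to_mcs_input(ga)
  ib <- graph_to_mcs_input(gb)
  res <- mcs_size_cpp(ia$elem, ia$bonds, ib$elem, ib$bonds,
                      budget_ms = time_budget * 1000)
  size <- res$size
  na <- ga$n; nb <- gb$n
  list(
    mcs_size = size,
    ts_mcs = if (na + nb - size > 0) size / (na + nb - size) else 0,
    oc = if (min(na, nb) > 0) size / min(na, nb) else 0,
    timed_out = isTRUE(res$timed_out)
  )
}

# Vectorized MCS over a pair table; returns a data frame aligned with pairs.
mcs_stats_pairs <- function(graphs, pairs, time_budget = 5) {
  inputs <- lapply(graphs, graph_to_mcs_input)
  n <- nrow(pairs)
  out <- data.frame(mcs_size = integer(n), ts_mcs = numeric(n),
                    oc = numeric(n), mcs_timeout = logical(n))
  for (r in seq_len(n)) {
    ga <- graphs[[pairs$id_a[r]]]; gb <- graphs[[pairs$id_b[r]]]
    ia <- inputs[[pairs$id_a[r]]]; ib <- inputs[[pairs$id_b[r]]]
    res <- mcs_size_cpp(ia$elem, ia$bonds, ib$elem, ib$bonds,
                        budget_ms = time_budget * 1000)
    size <- res$size
    out$mcs_size[r] <- size
    out$ts_mcs[r] <- if (ga$n + gb$n - size > 0) size / (ga$n + gb$n - size) else 0
    out$oc[r] <- if (min(ga$n, gb$n) > 0) size / min(ga$n, gb$n) else 0
    out$mcs_timeout[r] <- isTRUE(res$timed_out)
  }
  out
}
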