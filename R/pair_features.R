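ts_cols <- function() paste0("ts_", FP_KINDS)
mcs_cols <- function() c("mcs_size", "ts_mcs", "oc")

canonical_pair_order <- function(id_a, id_b) {
  swap <- id_a > id_b
  list(id_a = ifelse(swap, id_b, id_a), id_b = ifelse(swap, id_a, id_b))
}

#' Assemble the feature vector of one compound pair
#'
#' Ordered concatenation of the seven fingerprint Tanimoto scores, the
#' three MCS statistics, and the two descriptor vectors of the pair, with
#' the descriptor blocks placed in canonical (lexicographic) id order so
#' the vector is invariant to argument order. Total length is `7 + 3 + 2d`
#' (460 for the classical `d = 225` registry).
#'
#' @param id_a,id_b compound ids.
#' @param bundle an `fp_bundle` from [compute_fingerprints()].
#' @param descriptors descriptor matrix from [compute_descriptors()], or
#'   `NULL` for the similarity-only 10-feature mode.
#' @param mcs optional precomputed list from [mcs_stats()] (computed on the
#'   fly from `compounds` otherwise).
#' @param compounds the `compound_set` (needed only when `mcs` is missing).
#' @param mcs_time_budget seconds per MCS search.
#' @return named numeric vector of length `7 + 3 + 2d`.
#' @export
build_pair_vector <- function(id_a, id_b, bundle, descriptors = NULL,
                              mcs = NULL, compounds = NULL,
                              mcs_time_budget = 5) {
  ord <- canonical_pair_order(id_a, id_b)
  id_a <- ord$id_a; id_b <- ord$id_b
  ts <- vapply(FP_KINDS, function(k) {
    fa <- bundle[[k]][[id_a]]; fb <- bundle[[k]][[id_b]]
    if (is.null(fa) || is.null(fb)) {
      stop("fingerprint block missing for pair (", id_a, ", ", id_b,
           "), kind ", k)
    }
    tanimoto(fa, fb)
  }, numeric(1))
  names(ts) <- ts_cols()
  if (is.null(mcs)) {
    if (is.null(compounds)) stop("MCS block missing: supply mcs= or compounds=")
    graphs <- mol_graphs(compounds[compounds$id %in% c(id_a, id_b), ])
    mcs <- mcs_stats(graphs[[id_a]], graphs[[id_b]],
                     time_budget = mcs_time_budget)
  }
  m <- c(mcs_size = mcs$mcs_size, ts_mcs = mcs$ts_mcs, oc = mcs$oc)
  if (is.null(descriptors)) return(c(ts, m))
  da <- descriptors[id_a, ]; db <- descriptors[id_b, ]
  if (anyNA(match(c(id_a, id_b), rownames(descriptors)))) {
    stop("descriptor block missing for pair (", id_a, ", ", id_b, ")")
  }
  names(da) <- paste0("a_", colnames(descriptors))
  names(db) <- paste0("b_", colnames(descriptors))
  c(ts, m, da, db)
}

#' Build the pairwise feature table for a set of pairs
#'
#' Computes, for every pair, the seven fingerprint Tanimoto similarities,
#' the three MCS statistics, and the concatenated descriptor blocks in
#' canonical id order; optionally attaches the Match/Nomatch label from a
#' target map. Pairs whose MCS search times out are excluded and counted.
#'
#' @param compounds a `compound_set` covering every id in `pairs`.
#' @param pairs data frame with columns `id_a`, `id_b` (see
#'   [enumerate_pairs()]); order within a pair is canonicalized.
#' @param bundle optional precomputed `fp_bundle`.
#' @param descriptors optional precomputed descriptor matrix; `NULL`
#'   computes the default registry, `NA` omits the descriptor blocks.
#' @param targets optional `target_map` for labelling.
#' @param mcs_time_budget seconds per MCS search (default 5).
#' @return data frame: `id_a`, `id_b`, predictors, and `label` when
#'   `targets` is given; `attr(, "n_mcs_timeout")` counts excluded pairs.
#' @export
pair_feature_table <- function(compounds, pairs, bundle = NULL,
                               descriptors = NULL, targets = NULL,
                               mcs_time_budget = 5) {
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  ord <- canonical_pair_order(pairs$id_a, pairs$id_b)
  pairs <- data.frame(id_a = ord$id_a, id_b = ord$id_b,
                      stringsAsFactors = FALSE)
  sdfset <- as_sdfset(compounds)
  bundle <- bundle %||% compute_fingerprints(compounds, sdfset)
  if (is.null(descriptors)) {
    descriptors <- compute_descriptors(compounds, sdfset = sdfset)
  } else if (length(descriptors) == 1 && is.na(descriptors[[1]])) {
    descriptors <- NULL
  }
  graphs <- mol_graphs(compounds, sdfset)

  ids <- unique(c(pairs$id_a, pairs$id_b))
  ts_mats <- lapply(FP_KINDS, function(k) tanimoto_matrix(bundle, k, ids))
  names(ts_mats) <- FP_KINDS
  out <- pairs
  for (k in FP_KINDS) {
    out[[paste0("ts_", k)]] <-
      ts_mats[[k]][cbind(match(pairs$id_a, ids), match(pairs$id_b, ids))]
  }
  mcs <- mcs_stats_pairs(graphs, pairs, time_budget = mcs_time_budget)
  out$mcs_size <- mcs$mcs_size
  out$ts_mcs <- mcs$ts_mcs
  out$oc <- mcs$oc

  if (!is.null(descriptors)) {
    da <- descriptors[pairs$id_a, , drop = FALSE]
    db <- descriptors[pairs$id_b, , drop = FALSE]
    colnames(da) <- paste0("a_", colnames(descriptors))
    colnames(db) <- paste0("b_", colnames(descriptors))
    out <- cbind(out, as.data.frame(da, optional = TRUE),
                 as.data.frame(db, optional = TRUE))
    rownames(out) <- NULL
  }

  if (!is.null(targets)) {
    out$label <- mapply(function(a, b) label_pair(targets[[a]], targets[[b]]),
                        pairs$id_a, pairs$id_b, USE.NAMES = FALSE)
  }

  n_to <- sum(mcs$mcs_timeout)
  if (n_to > 0) {
    message(n_to, " pair(s) excluded: MCS search timed out")
    out <- out[!mcs$mcs_timeout, , drop = FALSE]
  }
  structure(out, n_mcs_timeout = n_to,
            d = if (is.null(descriptors)) 0L else ncol(descriptors))
}

predictor_columns <- function(tab) {
  setdiff(names(tab), c("id_a", "id_b", "id_ref", "id_query", "label"))
}

#' Remove constant predictor columns
#'
#' Drops rows containing missing predictor values (counted, not silent),
#' then removes columns with a single distinct value across rows (e.g. all
#' zeros or all ones). The returned mask is the ordered list of retained
#' column names and can be re-applied to project any future matrix, such
#' as a test or screening matrix, onto exactly the training schema.
#'
#' @param x numeric matrix or a data frame of predictors (a
#'   `pair_feature_table` may be passed; id/label columns are ignored).
#' @return list with `matrix` (filtered), `mask` (retained column names),
#'   and `report` (removed columns, dropped row count).
#' @export
filter_constant_columns <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, predictor_columns(x), drop = FALSE])
  }
  if (!nrow(x) || !ncol(x)) stop("empty feature matrix")
  bad_row <- !stats::complete.cases(x) | rowSums(!is.finite(x)) > 0
  if (any(bad_row)) {
    message(sum(bad_row), " row(s) with missing predictors dropped")
  }
  x <- x[!bad_row, , drop = FALSE]
  if (!nrow(x)) stop("no rows left after dropping missing values")
  n_distinct <- apply(x, 2, function(col) length(unique(col)))
  constant <- n_distinct <= 1
  if (all(constant)) stop("all predictor columns are constant")
  mask <- colnames(x)[!constant]
  list(
    matrix = x[, mask, drop = FALSE],
    mask = mask,
    report = list(n_removed = sum(constant),
                  removed = colnames(x)[constant],
                  n_rows_dropped = sum(bad_row))
  )
}

#' Project a matrix through a stored column mask
#'
#' Applies a train-derived mask so the projected matrix has exactly the
#' training schema (same columns, same order). Rows with missing predictor
#' values are dropped and counted, mirroring the training-side filter.
#'
#' @param x matrix or `pair_feature_table`.
#' @param mask character vector of retained columns from
#'   [filter_constant_columns()].
#' @return numeric matrix with `colnames(x) == mask`.
#' @export
apply_column_mask <- function(x, mask) {
  if (is.data.frame(x)) x <- as.matrix(x[, predictor_columns(x), drop = FALSE])
  missing_cols <- setdiff(mask, colnames(x))
  if (length(missing_cols)) {
    stop("schema mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[, mask, drop = FALSE]
  bad_row <- !stats::complete.cases(x) | rowSums(!is.finite(x)) > 0
  if (any(bad_row)) {
    message(sum(bad_row), " row(s) with missing predictors dropped")
    x <- x[!bad_row, , drop = FALSE]
  }
  x
}

#' Concordance-at-top of two rankings
#'
#' For each depth `i`, the fraction of items shared by the top-`i` heads of
#' two duplicate-free ranked lists: `|top_i(1) n top_i(2)| / i`. Used to
#' compare how differently two similarity measures rank the same pairs.
#'
#' @param ranked_list_1,ranked_list_2 character vectors, most similar first,
#'   no duplicates.
#' @param depths integer depths at which to evaluate.
#' @return data frame with columns `depth`, `concordance`.
#' @export
cat_concordance <- function(ranked_list_1, ranked_list_2, depths) {
  if (anyDuplicated(ranked_list_1) || anyDuplicated(ranked_list_2)) {
    stop("ranked lists must be duplicate-free")
  }
  depths <- as.integer(depths)
  if (any(depths < 1) ||
      any(depths > min(length(ranked_list_1), length(ranked_list_2)))) {
    stop("depth exceeds ranked list length")
  }
  conc <- vapply(depths, function(i) {
    length(intersect(ranked_list_1[seq_len(i)], ranked_list_2[seq_len(i)])) / i
  }, numeric(1))
  data.frame(depth = depths, concordance = conc)
}
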