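#' Build the reference x query screening pair table
#'
#' Computes the full cartesian pairing of a reference (drug) library with
#' a query (natural-compound) library using exactly the training-time
#' predictors: seven fingerprint similarities, MCS statistics, and the
#' descriptor blocks in canonical id order. Near-duplicate removal happens
#' later ([dedup_near_identical()]); a query identical to a reference
#' compound still produces a record here.
#'
#' @param reference,query `compound_set`s with disjoint id spaces.
#' @param targets optional `target_map` (reference side) kept for
#'   annotation joins.
#' @param mcs_time_budget seconds per MCS search.
#' @return a pair table with columns `id_ref`, `id_query` and the full
#'   predictor set.
#' @export
build_screen_pairs <- function(reference, query, targets = NULL,
                               mcs_time_budget = 5) {
  overlap <- intersect(reference$id, query$id)
  if (length(overlap)) {
    stop("reference and query libraries share ids: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  all_cs <- new_compound_set(
    merge_compound_frames(reference, query),
    empty_rejects()
  )
  pairs <- expand.grid(id_ref = reference$id, id_query = query$id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  feat <- pair_feature_table(
    all_cs,
    data.frame(id_a = pairs$id_ref, id_b = pairs$id_query,
               stringsAsFactors = FALSE),
    mcs_time_budget = mcs_time_budget
  )
  # recover ref/query orientation after canonical ordering
  is_ref_a <- feat$id_a %in% reference$id
  out <- feat
  out$id_ref <- ifelse(is_ref_a, feat$id_a, feat$id_b)
  out$id_query <- ifelse(is_ref_a, feat$id_b, feat$id_a)
  out$id_a <- NULL; out$id_b <- NULL
  front <- c("id_ref", "id_query")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  out <- out[order(out$id_ref, out$id_query), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "d") <- attr(feat, "d")
  out
}

merge_compound_frames <- function(a, b) {
  cols <- union(names(a), names(b))
  fill <- function(df) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
    df[, cols, drop = FALSE]
  }
  rbind(fill(as.data.frame(a)), fill(as.data.frame(b)))
}

#' Flag near-identical screening pairs
#'
#' Pairs whose chosen fingerprint Tanimoto score is strictly greater than
#' the threshold are treated as the same compound appearing in both
#' libraries and are excluded from hit calling (the classical rule removes
#' pairs with score > 0.9). The comparison is strict: a pair at exactly
#' the threshold is kept.
#'
#' @param pairs a screening pair table with `ts_<fingerprint>` columns.
#' @param ts_threshold similarity threshold (default 0.9).
#' @param fingerprint which fingerprint backs the rule (default the
#'   circular `"morgan"`, the most identity-specific of the seven).
#' @return list with `kept`, `removed` (row subsets) and `n_removed`.
#' @export
dedup_near_identical <- function(pairs, ts_threshold = 0.9,
                                 fingerprint = "morgan") {
  col <- paste0("ts_", fingerprint)
  if (!col %in% names(pairs)) stop("no similarity column ", col)
  flag <- pairs[[col]] > ts_threshold
  list(kept = pairs[!flag, , drop = FALSE],
       removed = pairs[flag, , drop = FALSE],
       n_removed = sum(flag))
}

#' Consensus screen across split models
#'
#' Scores every pair with each of the `K` trained models, counts votes
#' (probability strictly above the threshold), and calls a hit when at
#' least `min_votes` models agree and the pair is not flagged as a
#' near-duplicate. Results are returned in a stable `(id_ref, id_query)`
#' order.
#'
#' @param models list of `pt_model` bundles sharing one predictor schema.
#' @param pairs screening pair table from [build_screen_pairs()].
#' @param mask train-time column mask ([filter_constant_columns()]).
#' @param prob_threshold per-model probability threshold (default 0.5).
#' @param min_votes minimum agreeing models for a hit (default 3).
#' @param ts_dedup_threshold,dedup_fingerprint near-duplicate rule
#'   parameters (see [dedup_near_identical()]).
#' @return a `screen_result` data frame: ids, per-model probabilities,
#'   `mean_prob`, `votes`, `dedup_flag`, `is_hit`, plus the similarity
#'   columns of the input pairs.
#' @export
consensus_screen <- function(models, pairs, mask,
                             prob_threshold = 0.5, min_votes = 3,
                             ts_dedup_threshold = 0.9,
                             dedup_fingerprint = "morgan") {
  K <- length(models)
  if (K < min_votes) stop("min_votes (", min_votes, ") exceeds model count (", K, ")")
  schemas <- lapply(models, `[[`, "schema")
  if (length(unique(vapply(schemas, paste, character(1), collapse = "|"))) != 1) {
    stop("models do not share one predictor schema")
  }
  X <- apply_column_mask(pairs, mask)
  if (nrow(X) != nrow(pairs)) {
    stop("screening rows with missing predictors; filter pairs first")
  }
  probs <- vapply(models, function(m) predict_proba(m, X), numeric(nrow(X)))
  colnames(probs) <- paste0("prob_", seq_len(K))
  votes <- rowSums(probs > prob_threshold)
  dedup_flag <- pairs[[paste0("ts_", dedup_fingerprint)]] > ts_dedup_threshold

  keep_cols <- intersect(c("id_ref", "id_query", "id_a", "id_b",
                           ts_cols(), mcs_cols()), names(pairs))
  out <- cbind(pairs[, keep_cols, drop = FALSE], probs)
  out$mean_prob <- rowMeans(probs)
  out$votes <- as.integer(votes)
  out$dedup_flag <- dedup_flag
  out$is_hit <- votes >= min_votes & !dedup_flag
  ord <- if (all(c("id_ref", "id_query") %in% names(out))) {
    order(out$id_ref, out$id_query)
  } else {
    order(out$id_a, out$id_b)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("screen_result", "data.frame"),
            prob_threshold = prob_threshold, min_votes = min_votes,
            n_dedup_removed = sum(dedup_flag))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x), " pairs, ", sum(x$is_hit), " hits (",
      attr(x, "n_dedup_removed"), " near-duplicates excluded)\n", sep = "")
  print(utils::head(as.data.frame(x)[, intersect(
    c("id_ref", "id_query", "mean_prob", "votes", "is_hit"), names(x))], 5))
  invisible(x)
}

#' Consensus ranking versus a single fingerprint
#'
#' Contrasts the consensus model ranking (by mean probability) with the
#' ranking induced by one fingerprint's Tanimoto score, and counts
#' single-fingerprint hits at the 0.5 / 0.6 / 0.7 score thresholds. Pairs
#' called by the models but ranked low by the fingerprint are the
#' "model-only" pattern that motivates similarity fusion.
#'
#' @param results a `screen_result`.
#' @param fingerprint fingerprint backing the single-score ranking
#'   (default `"featmorgan"`).
#' @param ts_thresholds score thresholds for the hit counts.
#' @return data frame with per-pair consensus and fingerprint ranks;
#'   `attr(, "ts_hit_counts")` holds the threshold table.
#' @export
rank_vs_single_fingerprint <- function(results, fingerprint = "featmorgan",
                                       ts_thresholds = c(0.5, 0.6, 0.7)) {
  col <- paste0("ts_", fingerprint)
  if (!col %in% names(results)) stop("no similarity column ", col)
  ts <- results[[col]]
  tab <- data.frame(
    results[, intersect(c("id_ref", "id_query", "id_a", "id_b"), names(results)),
            drop = FALSE],
    mean_prob = results$mean_prob,
    ts = ts,
    consensus_rank = rank(-results$mean_prob, ties.method = "first"),
    fingerprint_rank = rank(-ts, ties.method = "first"),
    is_hit = results$is_hit
  )
  counts <- vapply(ts_thresholds, function(th) sum(ts > th), integer(1))
  structure(tab, ts_hit_counts = data.frame(threshold = ts_thresholds,
                                            n_above = counts),
            fingerprint = fingerprint)
}
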