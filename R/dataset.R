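#' Label a compound pair by shared targets
#'
#' `"Match"` iff the two target sets intersect; compounds without targets
#' must be excluded upstream, so an empty set is an error.
#'
#' @param targets_a,targets_b nonempty character vectors of target ids.
#' @return `"Match"` or `"Nomatch"`.
#' @export
label_pair <- function(targets_a, targets_b) {
  if (is.null(targets_a) || is.null(targets_b) ||
      !length(targets_a) || !length(targets_b)) {
    stop("empty target set: compound should have been excluded upstream")
  }
  if (length(intersect(targets_a, targets_b))) "Match" else "Nomatch"
}

#' Enumerate all unordered pairs of compound ids
#'
#' Produces exactly `n(n-1)/2` distinct unordered pairs (no self-pairs),
#' each in canonical lexicographic order.
#'
#' @param ids character vector of at least two unique compound ids.
#' @return data frame with columns `id_a`, `id_b`.
#' @export
enumerate_pairs <- function(ids) {
  ids <- unique(as.character(ids))
  n <- length(ids)
  if (n < 2) stop("need at least 2 ids to enumerate pairs")
  ids <- sort(ids)
  i <- rep.int(seq_len(n - 1), (n - 1):1)
  j <- sequence((n - 1):1) + i
  data.frame(id_a = ids[i], id_b = ids[j], stringsAsFactors = FALSE)
}

# Largest-remainder allocation of per-stratum test counts so the global
# test size equals round(frac * N).
allocate_test_counts <- function(sizes, frac) {
  total <- round(frac * sum(sizes))
  raw <- frac * sizes
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(raw - base)
    take <- ord[base[ord] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  base
}

#' Compound-disjoint stratified train/test split
#'
#' Splits at the compound level (never at the pair level) so that, after
#' pairing within each side, no compound contributes pairs to both train
#' and test: this prevents leakage of per-molecule features across the
#' split. Allocation is random within each stratum of the chosen
#' annotation (structural superclass by default), with largest-remainder
#' rounding so the overall test share equals `round(test_frac * N)`.
#' Strata with fewer than 2 compounds go wholly to train with a warning.
#'
#' @param compounds a `compound_set`.
#' @param test_frac test fraction (paper-style default 0.2).
#' @param stratum_key annotation column to stratify on; missing column
#'   falls back to a single stratum.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param split_index bookkeeping index for repeated splits.
#' @return a `split_set`: list with `train_ids`, `test_ids`, `seed`,
#'   `split_index`, and a per-stratum `strat_report`.
#' @export
drug_disjoint_split <- function(compounds, test_frac = 0.2,
                                stratum_key = "superclass", seed = 1,
                                split_index = 1L) {
  ids <- compounds$id
  strata <- if (stratum_key %in% names(compounds)) {
    as.character(compounds[[stratum_key]])
  } else {
    rep("all", length(ids))
  }
  strata[is.na(strata) | !nzchar(strata)] <- "unannotated"
  groups <- split(ids, strata)
  sizes <- lengths(groups)
  small <- sizes < 2
  if (any(small)) {
    warning(sum(small), " stratum(s) with <2 compounds allocated wholly to train")
  }
  counts <- allocate_test_counts(sizes, test_frac)
  counts[small] <- 0
  test_ids <- with_seed(seed, {
    unlist(lapply(seq_along(groups), function(s) {
      if (counts[s] == 0) return(character(0))
      sample(groups[[s]], counts[s])
    }), use.names = FALSE)
  })
  train_ids <- setdiff(ids, test_ids)
  report <- data.frame(
    stratum = names(groups),
    n = as.integer(sizes),
    n_test = as.integer(counts),
    n_train = as.integer(sizes - counts),
    row.names = NULL
  )
  structure(list(split_index = as.integer(split_index),
                 train_ids = sort(train_ids), test_ids = sort(test_ids),
                 seed = as.integer(seed), strat_report = report),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat("<split_set #", x$split_index, "> train ", length(x$train_ids),
      " / test ", length(x$test_ids), " compounds (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Repeated compound-disjoint splits
#'
#' Generates `K` independent splits with seeds `base_seed .. base_seed+K-1`
#' (the paper-style protocol uses `K = 5`).
#'
#' @inheritParams drug_disjoint_split
#' @param K number of repetitions.
#' @param base_seed seed of the first split.
#' @return list of `K` `split_set`s.
#' @export
make_split_sets <- function(compounds, test_frac = 0.2, K = 5,
                            base_seed = 1, stratum_key = "superclass") {
  stopifnot(K >= 1)
  lapply(seq_len(K), function(k) {
    drug_disjoint_split(compounds, test_frac = test_frac,
                        stratum_key = stratum_key,
                        seed = base_seed + k - 1, split_index = k)
  })
}

#' Split a labelled pair table along a compound split
#'
#' Keeps only pairs whose two compounds fall on the same side; pairs that
#' straddle the split (one compound in train, one in test) are discarded,
#' which is what makes the train/test pair sets compound-disjoint.
#'
#' @param pair_tab a labelled `pair_feature_table`.
#' @param split a `split_set`.
#' @return list with `train`, `test` (pair-table subsets) and
#'   `n_cross_discarded`.
#' @export
split_pair_table <- function(pair_tab, split) {
  a_tr <- pair_tab$id_a %in% split$train_ids
  b_tr <- pair_tab$id_b %in% split$train_ids
  a_te <- pair_tab$id_a %in% split$test_ids
  b_te <- pair_tab$id_b %in% split$test_ids
  train <- pair_tab[a_tr & b_tr, , drop = FALSE]
  test <- pair_tab[a_te & b_te, , drop = FALSE]
  list(train = train, test = test,
       n_cross_discarded = nrow(pair_tab) - nrow(train) - nrow(test))
}
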