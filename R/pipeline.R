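#' Train and evaluate all classifiers across repeated splits
#'
#' End-to-end convenience wrapper over the module functions: features are
#' computed once for all pairs of the library, then for each of the `K`
#' compound-disjoint splits the constant-column filter is fitted on the
#' training side, the four classifiers (L1R, L2R, naive Bayes, tuned
#' random forest) are trained, and each is evaluated on the held-out
#' pairs.
#'
#' @param compounds a `compound_set`.
#' @param targets a `target_map` covering the compounds.
#' @param K number of repeated splits.
#' @param test_frac held-out compound fraction.
#' @param base_seed seed of the first split (also seeds tuning).
#' @param space RF search space, see [rf_search_space()].
#' @param algorithms subset of `c("L1R", "L2R", "NB", "RF")`.
#' @param pair_tab optional precomputed labelled pair table.
#' @return list with `pair_tab`, `splits`, and per-split results
#'   (`mask`, `models`, `metrics`, RF `tuning`).
#' @export
run_split_models <- function(compounds, targets, K = 5, test_frac = 0.2,
                             base_seed = 1, space = rf_search_space(),
                             algorithms = c("L1R", "L2R", "NB", "RF"),
                             pair_tab = NULL) {
  usable <- compounds[compounds$id %in% names(targets), , drop = FALSE]
  if (is.null(pair_tab)) {
    pairs <- enumerate_pairs(usable$id)
    pair_tab <- pair_feature_table(usable, pairs, targets = targets)
  }
  splits <- make_split_sets(usable, test_frac = test_frac, K = K,
                            base_seed = base_seed)
  results <- lapply(splits, function(sp) {
    sides <- split_pair_table(pair_tab, sp)
    flt <- filter_constant_columns(sides$train)
    y_tr <- as_label_factor(sides$train$label)
    X_tr <- flt$matrix
    X_te <- apply_column_mask(sides$test, flt$mask)
    y_te <- as_label_factor(sides$test$label)

    models <- list(); metrics <- list(); tuning <- NULL
    if ("L1R" %in% algorithms) {
      models$L1R <- train_logistic(X_tr, y_tr, "L1", seed = sp$seed)
    }
    if ("L2R" %in% algorithms) {
      models$L2R <- train_logistic(X_tr, y_tr, "L2", seed = sp$seed)
    }
    if ("NB" %in% algorithms) {
      models$NB <- train_naive_bayes(X_tr, y_tr)
    }
    if ("RF" %in% algorithms) {
      sp_space <- space
      sp_space$mtry_range <- pmin(sp_space$mtry_range, ncol(X_tr))
      tuning <- tune_random_forest(X_tr, y_tr, sp_space, seed = sp$seed)
      models$RF <- train_random_forest(X_tr, y_tr, tuning$best_params,
                                       seed = sp$seed)
    }
    for (nm in names(models)) {
      metrics[[nm]] <- compute_metrics(y_te, predict_proba(models[[nm]], X_te))
    }
    list(split = sp, mask = flt$mask, filter_report = flt$report,
         models = models, metrics = metrics, tuning = tuning,
         n_train_pairs = nrow(sides$train), n_test_pairs = nrow(sides$test),
         n_cross_discarded = sides$n_cross_discarded)
  })
  list(pair_tab = pair_tab, splits = splits, results = results)
}
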