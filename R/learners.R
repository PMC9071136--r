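as_label_factor <- function(y) {
  y <- normalize_labels(y)
  factor(y, levels = c("Nomatch", "Match"))
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) stop("both classes must be present")
}

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Prevalence-derived class weights
#'
#' The positive (Match) class receives weight `1 - p` and the negative
#' class `p`, where `p` is the Match prevalence of the training labels —
#' at the classical 0.03 class ratio this gives the 0.97/0.03 weighting.
#'
#' @param y label vector.
#' @return named numeric vector `c(Match = , Nomatch = )`.
#' @export
prevalence_weights <- function(y) {
  y <- as_label_factor(y)
  p <- mean(y == "Match")
  c(Match = 1 - p, Nomatch = p)
}

#' Heuristic regularization cost
#'
#' Standardizes the training matrix, draws a class-balanced subsample
#' (all minority rows plus an equal-size majority sample), and returns
#' the inverse mean squared row norm `1 / mean(||z_i||^2)` of the
#' subsample as the logistic cost `C` — the classical scale-based cost
#' heuristic for linear classifiers. Deterministic given the seed.
#'
#' @param X numeric predictor matrix.
#' @param y label vector (both classes required).
#' @param seed integer seed for the balanced subsample.
#' @return positive scalar cost.
#' @export
heuristic_cost <- function(X, y, seed = 1) {
  y <- as_label_factor(y)
  check_two_classes(y)
  n_min <- min(table(y))
  idx <- with_seed(seed, {
    unlist(lapply(levels(y), function(lv) {
      rows <- which(y == lv)
      if (length(rows) > n_min) sample(rows, n_min) else rows
    }))
  })
  Z <- standardize_apply(X, standardize_fit(X))
  msq <- mean(rowSums(Z[idx, , drop = FALSE]^2))
  if (!is.finite(msq) || msq <= 0) return(1)
  1 / msq
}

new_model_bundle <- function(algorithm, fit, schema, extra = list()) {
  structure(c(list(algorithm = algorithm, fit = fit, schema = schema), extra),
            class = "pt_model")
}

#' @export
print.pt_model <- function(x, ...) {
  cat("<pt_model ", x$algorithm, "> ", length(x$schema), " predictors\n",
      sep = "")
  invisible(x)
}

#' Train a class-weighted regularized logistic regression
#'
#' L1 (lasso) or L2 (ridge) penalized logistic regression on standardized
#' predictors, with per-observation class weights and a single penalty
#' derived from the cost `C` as `lambda = 1/(n C)`. Standardization
#' parameters are learned on the training matrix only and stored in the
#' bundle.
#'
#' @param X numeric predictor matrix (rows = pairs).
#' @param y label vector.
#' @param reg `"L1"` or `"L2"`.
#' @param C positive cost; defaults to [heuristic_cost()].
#' @param class_weights named weights for Match/Nomatch; defaults to
#'   [prevalence_weights()].
#' @param seed seed for the cost heuristic subsample.
#' @return a `pt_model` bundle.
#' @export
train_logistic <- function(X, y, reg = c("L1", "L2"), C = NULL,
                           class_weights = NULL, seed = 1) {
  reg <- match.arg(reg)
  y <- as_label_factor(y)
  check_two_classes(y)
  if (any(!is.finite(X))) stop("non-finite predictor values")
  if (is.null(C)) C <- heuristic_cost(X, y, seed = seed)
  if (is.null(class_weights)) class_weights <- prevalence_weights(y)
  std <- standardize_fit(X)
  Z <- standardize_apply(X, std)
  w <- unname(class_weights[as.character(y)])
  fit <- glmnet::glmnet(Z, y, family = "binomial",
                        alpha = if (reg == "L1") 1 else 0,
                        lambda = 1 / (nrow(Z) * C),
                        weights = w, standardize = FALSE)
  new_model_bundle(paste0(reg, "R"), fit, colnames(X),
                   list(std = std, C = C, class_weights = class_weights))
}

#' Train a naive Bayes classifier
#'
#' Gaussian naive Bayes on the raw predictors. Class-conditional standard
#' deviations of (near-)constant features are floored at a small epsilon
#' so degenerate densities cannot poison the posterior.
#'
#' @inheritParams train_logistic
#' @return a `pt_model` bundle.
#' @export
train_naive_bayes <- function(X, y) {
  y <- as_label_factor(y)
  check_two_classes(y)
  if (any(!is.finite(X))) stop("non-finite predictor values")
  fit <- e1071::naiveBayes(as.data.frame(X), y)
  eps <- 1e-6
  fit$tables <- lapply(fit$tables, function(tb) {
    tb[, 2] <- pmax(tb[, 2], eps)
    tb
  })
  new_model_bundle("NB", fit, colnames(X))
}

#' Random forest hyperparameter search space
#'
#' The classical tuning box: trees capped at 300, terminal node size
#' 20-50, variables per split 15-30, positive-class weight 300-3000,
#' explored by 10 random draws each scored by stratified 5-fold CV MCC.
#'
#' @param ntree_max maximum trees.
#' @param nodesize_range,mtry_range,classwt_range integer/numeric intervals.
#' @param n_iter random search iterations.
#' @param cv_folds cross-validation folds.
#' @return an `rf_search_space` list.
#' @export
rf_search_space <- function(ntree_max = 300, nodesize_range = c(20, 50),
                            mtry_range = c(15, 30),
                            classwt_range = c(300, 3000),
                            n_iter = 10, cv_folds = 5) {
  stopifnot(ntree_max >= 50, diff(nodesize_range) >= 0,
            diff(mtry_range) >= 0, diff(classwt_range) >= 0,
            n_iter >= 1, cv_folds >= 2)
  structure(list(ntree_max = ntree_max, nodesize_range = nodesize_range,
                 mtry_range = mtry_range, classwt_range = classwt_range,
                 n_iter = n_iter, cv_folds = cv_folds),
            class = "rf_search_space")
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      rows <- which(y == lv)
      if (length(rows) < k) {
        stop("class ", lv, " has fewer members (", length(rows),
             ") than folds (", k, ")")
      }
      fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
    fold
  })
}

draw_rf_params <- function(space, seed) {
  with_seed(seed, {
    list(
      ntree = sample(seq(50, space$ntree_max, by = 50), 1),
      nodesize = sample(space$nodesize_range[1]:space$nodesize_range[2], 1),
      mtry = sample(space$mtry_range[1]:space$mtry_range[2], 1),
      classwt = stats::runif(1, space$classwt_range[1], space$classwt_range[2])
    )
  })
}

#' Random search with cross-validation for random forest
#'
#' Draws `n_iter` hyperparameter combinations from the space, scores each
#' by mean MCC over stratified `cv_folds`-fold cross-validation, and
#' returns the best combination with the full trial table. Ties on CV MCC
#' resolve to the less complex trial (fewer trees, then larger nodesize).
#' Fully reproducible given the seed.
#'
#' @inheritParams train_logistic
#' @param space an [rf_search_space()].
#' @param seed integer seed.
#' @return list with `best_params` and `trials` (one row per iteration).
#' @export
tune_random_forest <- function(X, y, space = rf_search_space(), seed = 1) {
  y <- as_label_factor(y)
  check_two_classes(y)
  folds <- stratified_folds(y, space$cv_folds, seed = seed)
  trials <- vector("list", space$n_iter)
  for (it in seq_len(space$n_iter)) {
    params <- draw_rf_params(space, seed = seed * 1000L + it)
    fold_mcc <- numeric(space$cv_folds)
    for (f in seq_len(space$cv_folds)) {
      tr <- folds != f
      model <- train_random_forest(X[tr, , drop = FALSE], y[tr], params,
                                   seed = seed * 1000L + it * 10L + f)
      prob <- predict_proba(model, X[!tr, , drop = FALSE])
      fold_mcc[f] <- compute_metrics(y[!tr], prob)$mcc
    }
    trials[[it]] <- data.frame(
      iter = it, ntree = params$ntree, nodesize = params$nodesize,
      mtry = params$mtry, classwt = params$classwt,
      mean_cv_mcc = mean(fold_mcc),
      t(stats::setNames(fold_mcc, paste0("mcc_fold", seq_len(space$cv_folds))))
    )
  }
  trials <- do.call(rbind, trials)
  ord <- order(-trials$mean_cv_mcc, trials$ntree, -trials$nodesize)
  best <- trials[ord[1], ]
  list(
    best_params = list(ntree = best$ntree, nodesize = best$nodesize,
                       mtry = best$mtry, classwt = best$classwt),
    trials = trials
  )
}

#' Train a random forest with given hyperparameters
#'
#' Classic bootstrap probability forest with the positive-class weight
#' applied to the splitting rule; out-of-bag probability predictions and
#' the native (sd-normalized) permutation importances are retained in the
#' bundle.
#'
#' @inheritParams train_logistic
#' @param params list with `ntree`, `nodesize`, `mtry`, `classwt`
#'   (positive-class weight; the negative class has weight 1).
#' @param seed seed controlling bootstrap and split sampling.
#' @return a `pt_model` bundle.
#' @export
train_random_forest <- function(X, y, params, seed = 1) {
  y <- as_label_factor(y)
  check_two_classes(y)
  if (params$mtry > ncol(X)) {
    stop("mtry (", params$mtry, ") exceeds predictor count (", ncol(X), ")")
  }
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = params$ntree, min.node.size = params$nodesize,
    mtry = params$mtry,
    class.weights = c(Nomatch = 1, Match = params$classwt),
    probability = TRUE, importance = "permutation",
    scale.permutation.importance = TRUE,
    num.threads = 1, seed = seed
  )
  new_model_bundle("RF", fit, colnames(X),
                   list(params = params, seed = seed,
                        importances = fit$variable.importance,
                        oob_votes = fit$predictions))
}

#' Predict Match probabilities
#'
#' Returns the probability of the Match class for each row; the matrix
#' must carry exactly the schema the model was trained on (missing or
#' extra columns are a hard error naming the offenders).
#'
#' @param model a `pt_model`.
#' @param X numeric matrix with the model's predictor columns.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) {
  missing_cols <- setdiff(model$schema, colnames(X))
  extra <- setdiff(colnames(X), model$schema)
  if (length(missing_cols)) {
    stop("schema mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(extra)) {
    stop("schema mismatch; unexpected columns: ",
         paste(extra, collapse = ", "))
  }
  X <- X[, model$schema, drop = FALSE]
  switch(model$algorithm,
    L1R = ,
    L2R = {
      Z <- standardize_apply(X, model$std)
      as.numeric(stats::predict(model$fit, Z, type = "response"))
    },
    NB = {
      p <- stats::predict(model$fit, as.data.frame(X), type = "raw")
      as.numeric(p[, "Match"])
    },
    RF = {
      p <- stats::predict(model$fit, X, num.threads = 1)$predictions
      as.numeric(p[, "Match"])
    },
    stop("unknown algorithm: ", model$algorithm)
  )
}

#' Permutation feature importance
#'
#' For each predictor: permute the column, re-predict, and record the
#' increase in classification error over the baseline; repeated
#' `n_repeats` times. The importance is the mean error increase divided by
#' the standard deviation of the per-repeat differences; when that
#' standard deviation is zero the unnormalized mean is reported (it is
#' then almost always zero, e.g. for a constant column).
#'
#' @param model a `pt_model`.
#' @param X predictor matrix (out-of-bag or held-out rows).
#' @param y labels for `X`.
#' @param n_repeats permutations per feature (>= 1).
#' @param seed integer seed.
#' @param threshold decision threshold for the error rate.
#' @return named numeric importance vector (one entry per predictor).
#' @export
permutation_importance <- function(model, X, y, n_repeats = 5, seed = 1,
                                   threshold = 0.5) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  y <- as_label_factor(y)
  base_err <- compute_metrics(y, predict_proba(model, X), threshold)$mmce
  p <- ncol(X)
  diffs <- matrix(0, n_repeats, p, dimnames = list(NULL, colnames(X)))
  for (j in seq_len(p)) {
    for (r in seq_len(n_repeats)) {
      Xp <- X
      perm <- with_seed(seed * 10000L + j * 100L + r,
                        sample(nrow(X)))
      Xp[, j] <- X[perm, j]
      err <- compute_metrics(y, predict_proba(model, Xp), threshold)$mmce
      diffs[r, j] <- err - base_err
    }
  }
  mu <- colMeans(diffs)
  sdv <- apply(diffs, 2, stats::sd)
  if (n_repeats == 1) sdv[] <- 0
  imp <- ifelse(sdv > 0, mu / sdv, mu)
  stats::setNames(imp, colnames(X))
}
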