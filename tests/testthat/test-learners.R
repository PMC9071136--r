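test_that("heuristic cost is positive, deterministic and balance-based", {
  pm <- planted_matrix()
  c1 <- heuristic_cost(pm$X, pm$y, seed = 3)
  c2 <- heuristic_cost(pm$X, pm$y, seed = 3)
  expect_gt(c1, 0)
  expect_identical(c1, c2)
  # a different subsample seed moves the estimate (balanced subsampling
  # is really happening)
  c3 <- heuristic_cost(pm$X, pm$y, seed = 4)
  expect_false(identical(c1, c3))
  expect_error(heuristic_cost(pm$X, rep("Match", nrow(pm$X))),
               "both classes")
})

test_that("prevalence-derived class weights follow the 1-p / p rule", {
  y <- c(rep("Match", 3), rep("Nomatch", 97))
  w <- prevalence_weights(y)
  expect_equal(unname(w["Match"]), 0.97)
  expect_equal(unname(w["Nomatch"]), 0.03)
})

test_that("logistic regression recovers a linearly separable signal", {
  set.seed(21)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(X[, 1] > 0, "Match", "Nomatch")
  for (reg in c("L1", "L2")) {
    fit <- train_logistic(X, y, reg)
    m <- compute_metrics(y, predict_proba(fit, X))
    expect_gt(m$mcc, 0.9, label = reg)
  }
})

test_that("logistic regression on permuted labels scores near zero", {
  pm <- planted_matrix(n = 500)
  set.seed(99)
  y_perm <- sample(pm$y)
  fit <- train_logistic(pm$X, y_perm, "L2")
  m <- compute_metrics(y_perm, predict_proba(fit, pm$X))
  expect_lt(abs(m$mcc), 0.15)
})

test_that("class-weighted LR has higher minority recall than unweighted LR", {
  set.seed(77)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- ifelse(runif(n) < plogis(2 * X[, 1] - 3), "Match", "Nomatch")
  w_flat <- c(Match = 0.5, Nomatch = 0.5)
  fit_w <- train_logistic(X, y, "L2")             # prevalence weights
  fit_u <- train_logistic(X, y, "L2", class_weights = w_flat)
  rec_w <- compute_metrics(y, predict_proba(fit_w, X))$tpr
  rec_u <- compute_metrics(y, predict_proba(fit_u, X))$tpr
  expect_gt(rec_w, rec_u)
})

test_that("naive Bayes separates two Gaussian classes and degrades to priors", {
  set.seed(31)
  n <- 400
  y <- rep(c("Match", "Nomatch"), each = n / 2)
  X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f1"))
  X[y == "Match", 1] <- X[y == "Match", 1] + 6
  fit <- train_naive_bayes(X, y)
  m <- compute_metrics(y, predict_proba(fit, X))
  expect_gt(m$acc, 0.99)

  # identical class-conditional distributions: probabilities near prior
  X0 <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "f1"))
  y0 <- ifelse(seq_len(n) <= 0.3 * n, "Match", "Nomatch")
  fit0 <- train_naive_bayes(X0, y0)
  p0 <- predict_proba(fit0, X0)
  expect_lt(abs(mean(p0) - 0.3), 0.1)
  expect_identical(predict_proba(fit0, X0), p0) # deterministic
})

test_that("random-forest search space validates and draws inside ranges", {
  sp <- rf_search_space()
  expect_equal(sp$ntree_max, 300)
  expect_equal(sp$nodesize_range, c(20, 50))
  expect_equal(sp$mtry_range, c(15, 30))
  expect_equal(sp$classwt_range, c(300, 3000))
  expect_equal(sp$n_iter, 10)
  expect_equal(sp$cv_folds, 5)
  for (i in 1:20) {
    pr <- pairtarget:::draw_rf_params(sp, seed = i)
    expect_lte(pr$ntree, 300); expect_gte(pr$ntree, 50)
    expect_true(pr$nodesize >= 20 && pr$nodesize <= 50)
    expect_true(pr$mtry >= 15 && pr$mtry <= 30)
    expect_true(pr$classwt >= 300 && pr$classwt <= 3000)
  }
})

test_that("random search records n_iter x cv_folds fold fits reproducibly", {
  pm <- planted_matrix(n = 250, p = 16, prevalence = 0.25)
  sp <- rf_search_space(ntree_max = 100, nodesize_range = c(5, 15),
                        mtry_range = c(2, 5), classwt_range = c(1, 10),
                        n_iter = 3, cv_folds = 3)
  t1 <- tune_random_forest(pm$X, pm$y, sp, seed = 12)
  t2 <- tune_random_forest(pm$X, pm$y, sp, seed = 12)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$trials), 3)
  expect_length(grep("^mcc_fold", names(t1$trials)), 3)
  expect_equal(t1$best_params$ntree,
               t1$trials$ntree[which.max(t1$trials$mean_cv_mcc)])
})

test_that("random forest learns planted signal and ignores pure noise", {
  pm <- planted_matrix(n = 700, p = 6, beta = 4, seed = 13)
  params <- list(ntree = 150, nodesize = 5, mtry = 3, classwt = 2)
  idx <- seq_len(400)
  fit <- train_random_forest(pm$X[idx, ], pm$y[idx], params, seed = 5)
  m <- compute_metrics(pm$y[-idx], predict_proba(fit, pm$X[-idx, ]))
  expect_gt(m$auc_roc, 0.8)

  set.seed(14)
  y_noise <- sample(c("Match", "Nomatch"), 700, replace = TRUE, prob = c(.3, .7))
  fit0 <- train_random_forest(pm$X[idx, ], y_noise[idx], params, seed = 5)
  m0 <- compute_metrics(y_noise[-idx], predict_proba(fit0, pm$X[-idx, ]))
  # null band: AUC ~ 0.5 within ~3 sd for a 300-row held-out set
  expect_lt(abs(m0$auc_roc - 0.5), 0.12)

  fit_b <- train_random_forest(pm$X[idx, ], pm$y[idx], params, seed = 5)
  expect_identical(predict_proba(fit, pm$X[-idx, ]),
                   predict_proba(fit_b, pm$X[-idx, ]))
  expect_error(
    train_random_forest(pm$X, pm$y,
                        list(ntree = 10, nodesize = 5, mtry = 99, classwt = 1)),
    "mtry")
})

test_that("probabilities are complementary, schema-checked and reproducible", {
  pm <- planted_matrix()
  fit <- train_logistic(pm$X, pm$y, "L1")
  p <- predict_proba(fit, pm$X)
  expect_true(all(p >= 0 & p <= 1))
  # schema errors name the offending columns
  expect_error(predict_proba(fit, pm$X[, 1:3]), "missing columns.*f4")
  Xx <- cbind(pm$X, junk = 1)
  expect_error(predict_proba(fit, Xx), "unexpected columns.*junk")
  # NB invariant to feature order at predict time
  nb <- train_naive_bayes(pm$X, pm$y)
  expect_equal(predict_proba(nb, pm$X),
               predict_proba(nb, pm$X[, rev(colnames(pm$X))]))
})

test_that("permutation importance finds the planted feature and zeroes
           constants", {
  pm <- planted_matrix(n = 500, p = 5, beta = 4, seed = 17)
  X <- cbind(pm$X, konst = 1)
  params <- list(ntree = 100, nodesize = 5, mtry = 2, classwt = 2)
  fit <- train_random_forest(X, pm$y, params, seed = 3)
  imp <- permutation_importance(fit, X, pm$y, n_repeats = 5, seed = 8)
  expect_equal(names(which.max(imp)), "f1")
  expect_identical(unname(imp["konst"]), 0)
  # independent feature scores near zero
  expect_lt(abs(imp["f3"]), abs(imp["f1"]))
  expect_error(permutation_importance(fit, X, pm$y, n_repeats = 0), "n_repeats")
})
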