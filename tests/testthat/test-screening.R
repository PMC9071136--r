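screen_fixture <- function() {
  fixture("screen_fixture", function() {
    cfg <- synth_config(n_families = 6, compounds_per_family = 3,
                        cross_family_target_prob = 0, seed = 77)
    ref <- suppressMessages(generate_library(cfg))
    qry <- suppressMessages(generate_screen_library(
      cfg, ref, n_query = 8, positive_fraction = 0.5, n_exact_copies = 2))
    pairs <- suppressMessages(build_screen_pairs(ref$compounds, qry$compounds))
    list(cfg = cfg, ref = ref, qry = qry, pairs = pairs)
  })
}

test_that("screen pairing is the full cartesian product with predictors", {
  fx <- screen_fixture()
  n_ref <- nrow(fx$ref$compounds)
  n_qry <- nrow(fx$qry$compounds)
  expect_equal(nrow(fx$pairs), n_ref * n_qry)
  expect_true(all(c("id_ref", "id_query", paste0("ts_", FP_KINDS),
                    "mcs_size", "ts_mcs", "oc") %in% names(fx$pairs)))
  # exact copies still produce records at this stage
  copies <- fx$qry$truth$id[fx$qry$truth$is_copy]
  expect_true(all(copies %in% fx$pairs$id_query))
})

test_that("near-duplicate rule is strict at the boundary", {
  tab <- data.frame(id_ref = c("r1", "r2", "r3"),
                    id_query = c("q1", "q2", "q3"),
                    ts_morgan = c(0.95, 0.9, 0.2))
  dd <- dedup_near_identical(tab, ts_threshold = 0.9)
  expect_equal(dd$n_removed, 1)
  expect_equal(dd$removed$id_query, "q1")
  expect_true("q2" %in% dd$kept$id_query)  # exactly 0.9 kept
  dd_all_low <- dedup_near_identical(tab[3, , drop = FALSE])
  expect_equal(dd_all_low$n_removed, 0)
})

test_that("injected exact copies are caught by the >0.9 rule", {
  fx <- screen_fixture()
  copies <- fx$qry$truth$id[fx$qry$truth$is_copy]
  dd <- dedup_near_identical(fx$pairs)
  caught <- unique(dd$removed$id_query)
  expect_true(all(copies %in% caught))
})

test_that("consensus voting uses strict thresholds and min_votes", {
  # direct arithmetic on the voting rule
  votes <- function(p, thr = 0.5) sum(p > thr)
  expect_gte(votes(c(0.6, 0.6, 0.6, 0.2, 0.2)), 3)   # hit
  expect_lt(votes(c(0.6, 0.6, 0.4, 0.4, 0.4)), 3)    # 2 votes: no hit
  expect_equal(votes(rep(0.5, 5)), 0)                # strict >
})

test_that("consensus screen scores pairs, votes and flags hits end to end", {
  fx <- screen_fixture()
  lib <- fx$ref
  pt <- suppressMessages(pair_feature_table(
    lib$compounds, enumerate_pairs(lib$compounds$id), targets = lib$targets))
  res <- suppressMessages(run_split_models(
    lib$compounds, lib$targets, K = 3, base_seed = 5, pair_tab = pt,
    algorithms = "RF",
    space = rf_search_space(ntree_max = 100, nodesize_range = c(5, 10),
                            mtry_range = c(3, 6), classwt_range = c(5, 50),
                            n_iter = 2, cv_folds = 2)))
  models <- lapply(res$results, function(r) r$models$RF)
  # project screening pairs through the first split's mask
  mask <- res$results[[1]]$mask
  # models were trained per-split with their own masks; rebuild on a
  # common mask for the consensus call
  common <- Reduce(intersect, lapply(res$results, `[[`, "mask"))
  models <- lapply(res$results, function(r) {
    sides <- split_pair_table(pt, r$split)
    X <- apply_column_mask(sides$train, common)
    train_random_forest(X, sides$train$label,
                        r$tuning$best_params, seed = r$split$seed)
  })
  scr <- consensus_screen(models, fx$pairs, common,
                          prob_threshold = 0.5, min_votes = 2)
  expect_s3_class(scr, "screen_result")
  expect_equal(nrow(scr), nrow(fx$pairs))
  expect_true(all(scr$votes <= 3))
  expect_true(all(scr$votes[scr$is_hit] >= 2))
  expect_true(all(!scr$dedup_flag[scr$is_hit]))

  # monotonicity: raising threshold or votes never grows the hit set
  scr_hi <- consensus_screen(models, fx$pairs, common,
                             prob_threshold = 0.7, min_votes = 2)
  scr_votes <- consensus_screen(models, fx$pairs, common,
                                prob_threshold = 0.5, min_votes = 3)
  key <- function(s) paste(s$id_ref, s$id_query)[s$is_hit]
  expect_true(all(key(scr_hi) %in% key(scr)))
  expect_true(all(key(scr_votes) %in% key(scr)))

  # hit set invariant to input pair order
  perm <- sample(nrow(fx$pairs))
  scr_perm <- consensus_screen(models, fx$pairs[perm, ], common,
                               prob_threshold = 0.5, min_votes = 2)
  expect_setequal(key(scr_perm), key(scr))

  # error paths
  expect_error(consensus_screen(models[1:2], fx$pairs, common, min_votes = 3),
               "min_votes")

  # single-fingerprint comparison table
  cmp <- rank_vs_single_fingerprint(scr)
  counts <- attr(cmp, "ts_hit_counts")
  expect_true(all(diff(counts$n_above) <= 0))
  expect_equal(nrow(cmp), nrow(scr))
  expect_setequal(cmp$consensus_rank, seq_len(nrow(scr)))
})
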