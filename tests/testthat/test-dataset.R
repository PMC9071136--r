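test_that("pair labelling follows shared-target set semantics", {
  expect_equal(label_pair("T1", c("T1", "T2")), "Match")
  expect_equal(label_pair("T1", "T2"), "Nomatch")
  expect_equal(label_pair(c("T1", "T2", "T3"), "T3"), "Match")
  expect_equal(label_pair(c("T1", "T2"), c("T2", "T1")),
               label_pair(c("T2", "T1"), c("T1", "T2")))
  expect_error(label_pair(character(0), "T1"), "empty")
})

test_that("pair enumeration yields exactly n(n-1)/2 canonical pairs", {
  p <- enumerate_pairs(c("b", "a"))
  expect_equal(nrow(p), 1)
  expect_equal(p$id_a, "a")
  p5 <- enumerate_pairs(letters[1:5])
  expect_equal(nrow(p5), 10)
  expect_true(all(p5$id_a < p5$id_b))
  expect_false(any(duplicated(paste(p5$id_a, p5$id_b))))
  expect_error(enumerate_pairs("solo"), "at least 2")
})

test_that("the classical 1,410-drug split sizes give the printed pair counts", {
  ids <- sprintf("D%04d", 1:1410)
  cs <- structure(data.frame(id = ids, smiles = "CCO"),
                  class = c("compound_set", "data.frame"))
  sp <- drug_disjoint_split(cs, test_frac = 0.2, seed = 3)
  expect_length(sp$train_ids, 1128)
  expect_length(sp$test_ids, 282)
  expect_equal(nrow(enumerate_pairs(sp$train_ids)), 635628)
  expect_equal(nrow(enumerate_pairs(sp$test_ids)), 39621)
})

test_that("splits are deterministic, disjoint and exhaustive", {
  lib <- small_synth()$compounds
  s1 <- drug_disjoint_split(lib, 0.2, seed = 9)
  s2 <- drug_disjoint_split(lib, 0.2, seed = 9)
  expect_identical(s1, s2)
  s3 <- drug_disjoint_split(lib, 0.2, seed = 10)
  expect_false(identical(s1$test_ids, s3$test_ids))
  expect_length(intersect(s1$train_ids, s1$test_ids), 0)
  expect_setequal(c(s1$train_ids, s1$test_ids), lib$id)
  expect_equal(length(s1$test_ids), round(0.2 * nrow(lib)))
})

test_that("stratified allocation balances the annotation across sides", {
  lib <- small_synth()$compounds
  sp <- drug_disjoint_split(lib, 0.25, stratum_key = "superclass", seed = 2)
  rep <- sp$strat_report
  # largest-remainder: per-stratum test share within one compound of target
  expect_true(all(abs(rep$n_test - 0.25 * rep$n) <= 1))
  expect_equal(sum(rep$n_test), length(sp$test_ids))
})

test_that("tiny strata go wholly to train with a warning", {
  cs <- structure(
    data.frame(id = sprintf("c%02d", 1:11), smiles = "CCO",
               superclass = c(rep("big", 10), "lonely")),
    class = c("compound_set", "data.frame"))
  expect_warning(sp <- drug_disjoint_split(cs, 0.2, seed = 1), "<2 compounds")
  expect_true("c11" %in% sp$train_ids)
})

test_that("repeated splits use consecutive seeds and reproduce exactly", {
  lib <- small_synth()$compounds
  f1 <- make_split_sets(lib, 0.2, K = 5, base_seed = 31)
  f2 <- make_split_sets(lib, 0.2, K = 5, base_seed = 31)
  expect_length(f1, 5)
  expect_identical(f1, f2)
  expect_equal(vapply(f1, `[[`, integer(1), "seed"), 31:35)
  expect_length(make_split_sets(lib, 0.2, K = 1, base_seed = 1), 1)
})

test_that("no pair straddles the split and cross-pair accounting is exact", {
  lib <- small_synth()$compounds
  pt <- small_synth_pairs()
  sp <- drug_disjoint_split(lib, 0.2, seed = 4)
  sides <- split_pair_table(pt, sp)
  # leakage check: no test-pair compound appears in any train pair
  train_compounds <- unique(c(sides$train$id_a, sides$train$id_b))
  test_compounds <- unique(c(sides$test$id_a, sides$test$id_b))
  expect_length(intersect(train_compounds, test_compounds), 0)
  # |pairs(train)| + |pairs(test)| + |cross| = C(N,2), cross = |train|*|test|
  expect_equal(sides$n_cross_discarded,
               length(sp$train_ids) * length(sp$test_ids))
  expect_equal(nrow(sides$train) + nrow(sides$test) + sides$n_cross_discarded,
               choose(nrow(lib), 2))
})

test_that("synthetic prevalence matches the configured expectation", {
  lib <- small_synth()
  pt <- small_synth_pairs()
  cfg <- synth_config(n_families = 10, compounds_per_family = 4,
                      cross_family_target_prob = 0.02, seed = 42)
  expected <- expected_match_prevalence(cfg)
  n <- nrow(pt)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(pt$label == "Match") - expected), 3 * se + 1e-9)
})
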