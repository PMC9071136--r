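test_that("pair vector length is 7 + 3 + 2d and invariant to argument order", {
  lib <- tiny_library()
  b <- tiny_bundle()
  dm <- tiny_descriptors()
  v1 <- build_pair_vector("benzene", "toluene", b, dm, compounds = lib)
  v2 <- build_pair_vector("toluene", "benzene", b, dm, compounds = lib)
  expect_identical(v1, v2)
  expect_length(v1, 7 + 3 + 2 * ncol(dm))
  expect_true(all(v1[paste0("ts_", FP_KINDS)] >= 0 &
                    v1[paste0("ts_", FP_KINDS)] <= 1))

  # similarity-only mode: d = 0 gives length 10
  v0 <- build_pair_vector("benzene", "toluene", b, NULL, compounds = lib)
  expect_length(v0, 10)

  # d = 3 gives 16
  v3 <- build_pair_vector("benzene", "toluene", b,
                          dm[, 1:3, drop = FALSE], compounds = lib)
  expect_length(v3, 16)
})

test_that("classical d = 225 registry gives the 460-length pair vector", {
  lib <- tiny_library()
  b <- tiny_bundle()
  # a 225-column descriptor block (classical registry size)
  d225 <- matrix(rnorm(nrow(lib) * 225), nrow(lib), 225,
                 dimnames = list(lib$id, sprintf("desc%03d", 1:225)))
  v <- build_pair_vector("benzene", "ethanol", b, d225, compounds = lib)
  expect_length(v, 460)
})

test_that("missing feature blocks are hard errors naming the block", {
  lib <- tiny_library()
  b <- tiny_bundle()
  dm <- tiny_descriptors()
  expect_error(build_pair_vector("benzene", "toluene", b, dm),
               "MCS block")
  b_broken <- unclass(b)
  b_broken$morgan[["benzene"]] <- NULL
  expect_error(
    build_pair_vector("benzene", "toluene", b_broken, dm, compounds = lib),
    "fingerprint block")
})

test_that("constant-column filter removes exactly the constant columns", {
  set.seed(5)
  n <- 40
  X <- matrix(rnorm(n * 378), n, 378)
  C <- matrix(rep(c(0, 1), each = n, length.out = n * 82), n, 82)
  C[] <- rep(sample(c(0, 1), 82, replace = TRUE), each = n)
  M <- cbind(X, C)[, sample(460)]
  colnames(M) <- sprintf("p%03d", 1:460)
  flt <- filter_constant_columns(M)
  expect_equal(ncol(flt$matrix), 378)
  expect_equal(flt$report$n_removed, 82)
  expect_setequal(c(flt$mask, flt$report$removed), colnames(M))
})

test_that("no constant columns means identity projection", {
  set.seed(6)
  M <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, letters[1:10]))
  flt <- filter_constant_columns(M)
  expect_identical(flt$matrix, M)
  expect_identical(flt$mask, colnames(M))
})

test_that("rows with missing predictors are dropped and counted", {
  M <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, letters[1:5]))
  M[3, 2] <- NA
  M[7, 4] <- Inf
  expect_message(flt <- filter_constant_columns(M), "2 row")
  expect_equal(nrow(flt$matrix), 8)
  expect_equal(flt$report$n_rows_dropped, 2)
})

test_that("an all-constant matrix is a hard error", {
  M <- matrix(1, 5, 4, dimnames = list(NULL, letters[1:4]))
  expect_error(filter_constant_columns(M), "constant")
})

test_that("a train-derived mask projects a test matrix onto the train schema", {
  set.seed(8)
  train <- matrix(rnorm(300), 30, 10,
                  dimnames = list(NULL, sprintf("c%02d", 1:10)))
  train[, 4] <- 1  # constant in train
  flt <- filter_constant_columns(train)
  test <- matrix(rnorm(100), 10, 10,
                 dimnames = list(NULL, sprintf("c%02d", 1:10)))
  proj <- apply_column_mask(test, flt$mask)
  expect_identical(colnames(proj), flt$mask)
  expect_error(apply_column_mask(test[, 1:3], flt$mask), "missing columns")
})

test_that("concordance at top matches direct set intersection", {
  expect_equal(cat_concordance(letters[1:5], letters[1:5], 1:5)$concordance,
               rep(1, 5))
  expect_equal(cat_concordance(letters[1:5], letters[6:10], 1:5)$concordance,
               rep(0, 5))
  expect_equal(cat_concordance(c("a", "b"), c("b", "c"), 2)$concordance, 0.5)
  expect_error(cat_concordance(c("a", "a"), c("b", "c"), 1), "duplicate")
  expect_error(cat_concordance(c("a", "b"), c("b", "c"), 3), "depth")
})

test_that("pair table carries canonical id order and valid similarity ranges", {
  pt <- small_synth_pairs()
  expect_true(all(pt$id_a < pt$id_b))
  for (col in c(paste0("ts_", FP_KINDS), "ts_mcs", "oc")) {
    expect_true(all(pt[[col]] >= 0 & pt[[col]] <= 1), label = col)
  }
  expect_true(all(pt$ts_mcs <= pt$oc + 1e-12))
  expect_true(all(pt$label %in% c("Match", "Nomatch")))
})
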