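test_that("SMILES TSV loading canonicalizes and indexes compounds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles\tsuperclass",
               "b1\tC1=CC=CC=C1\tbenzenoid",
               "e1\tCCO\talcohol",
               "t1\tCc1ccccc1\tbenzenoid"), path)
  cs <- load_compounds(path, "smiles-tsv")
  expect_s3_class(cs, "compound_set")
  expect_equal(nrow(cs), 3)
  expect_setequal(cs$id, c("b1", "e1", "t1"))
  expect_equal(cs$smiles[cs$id == "b1"], "c1ccccc1")
  expect_equal(cs$superclass[cs$id == "e1"], "alcohol")
  expect_equal(nrow(compound_rejects(cs)), 0)
})

test_that("broken records are logged and counted, not silently dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles",
               "a\tCCO", "b\tCCN", "bad\tC1CC", "c\tCCC", "d\tCCCl"), path)
  expect_message(cs <- load_compounds(path, "smiles-tsv"), "rejected")
  expect_equal(nrow(cs), 4)
  rej <- compound_rejects(cs)
  expect_equal(rej$id, "bad")
  expect_equal(rej$reason, "unparseable structure")
})

test_that("zero parseable records is a hard error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles", "x\tC1CC", "y\tnot_a_smiles"), path)
  expect_error(suppressMessages(load_compounds(path, "smiles-tsv")),
               "no parseable")
})

test_that("canonicalization is idempotent and merges input encodings", {
  # kekulized vs aromatic notation of one molecule
  canon <- canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_equal(canon[1], canon[2])
  lib <- tiny_library()
  expect_identical(canonical_smiles(lib$smiles), lib$smiles)
})

test_that("InChI input converts to the same canonical structures", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tinchi",
               "eth\tInChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3",
               "bz\tInChI=1S/C6H6/c1-2-4-6-5-3-1/h1-6H"), path)
  cs <- load_compounds(path, "inchi-tsv")
  expect_equal(cs$smiles[cs$id == "eth"], canonical_smiles("CCO"))
  expect_equal(cs$smiles[cs$id == "bz"], canonical_smiles("c1ccccc1"))
})

test_that("salt records reduce to the largest organic fragment", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles", "salt\tCCO.Cl", "plain\tCCN"), path)
  expect_message(cs <- load_compounds(path, "smiles-tsv"), "multi-fragment")
  expect_equal(cs$smiles[cs$id == "salt"], canonical_smiles("CCO"))
})

test_that("write/load round-trips to an identical compound set", {
  lib <- tiny_library()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compounds(lib, path)
  back <- load_compounds(path, "smiles-tsv")
  expect_equal(as.data.frame(back), as.data.frame(lib))
})

test_that("duplicate ids are rejected at load time", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles", "a\tCCO", "a\tCCN"), path)
  expect_error(load_compounds(path, "smiles-tsv"), "duplicate")
})

test_that("target map aggregates rows with set semantics", {
  lib <- tiny_library()
  tm <- target_map(c("benzene", "benzene", "benzene", "toluene"),
                   c("T1", "T1", "T2", "T2"), lib)
  expect_equal(tm$benzene, c("T1", "T2"))
  expect_equal(tm$toluene, "T2")
})

test_that("target map supports wide fan-out (one compound, 86 targets)", {
  lib <- tiny_library()
  tm <- target_map(rep("aspirin", 86), sprintf("T%02d", 1:86), lib)
  expect_length(tm$aspirin, 86)
})

test_that("unknown compound ids in the map warn and are excluded", {
  lib <- tiny_library()
  expect_warning(
    tm <- target_map(c("benzene", "ghost"), c("T1", "T2"), lib),
    "absent from library")
  expect_named(tm, "benzene")
  expect_equal(attr(tm, "excluded"), "ghost")
  expect_error(suppressWarnings(target_map("ghost", "T1", lib)), "empty")
})

test_that("SDF loading yields the same canonical structures as SMILES", {
  lib <- tiny_library()
  sdf <- as_sdfset(lib)
  path <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, path)
  cs <- load_compounds(path, "sdf")
  expect_equal(nrow(cs), nrow(lib))
  expect_setequal(cs$smiles, lib$smiles)
})
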