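# Structure loading, canonicalization, salt stripping, InChIKeys

test_that("load_library enforces the exact header contract and keeps bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES,Sample ID", "CCO,A", "OCC,B", ",C"), f)
  lib <- load_library(f)
  expect_equal(nrow(lib), 3)
  expect_true(all(is.na(lib$user_gene_symbol)))
  expect_equal(lib$parse_ok, c(TRUE, TRUE, FALSE))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,Sample ID", "CCO,A"), f2)
  expect_error(load_library(f2), "SMILES", class = "hitdecon_schema_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES,Sample ID", "CCO,A"), f3)
  expect_error(load_library(f3, require_gene_column = TRUE), "Gene Symbol",
               class = "hitdecon_schema_error")
  expect_error(load_library(withr::local_tempfile(fileext = ".xlsx")),
               class = "hitdecon_io_error")
})

test_that("canonicalization collapses equivalent SMILES and flags bad input", {
  a <- standardize_structure("OCC")
  b <- standardize_structure("CCO")
  expect_true(a$parse_ok && b$parse_ok)
  expect_identical(a$smiles_canonical, b$smiles_canonical)
  bad <- standardize_structure("not_a_smiles")
  expect_false(bad$parse_ok)
  expect_true(is.na(bad$smiles_canonical))
})

test_that("standardization is idempotent over a generated structure panel", {
  panel <- hitdecon:::smiles_pool(60)
  panel[seq(1, 60, by = 4)] <- paste0(panel[seq(1, 60, by = 4)], ".Cl")
  for (s in panel) {
    once <- standardize_structure(s)
    expect_true(once$parse_ok, info = s)
    twice <- standardize_structure(once$smiles_canonical)
    expect_identical(twice$smiles_canonical, once$smiles_canonical, info = s)
  }
})

test_that("salt stripping keeps the largest organic fragment", {
  can <- standardize_structure("CCO.Cl")$smiles_canonical
  p <- strip_salt_parent(can)
  expect_false(p$empty_parent)
  expect_identical(p$smiles_parent, standardize_structure("CCO")$smiles_canonical)

  single <- standardize_structure("CCO")$smiles_canonical
  expect_identical(strip_salt_parent(single)$smiles_parent, single)

  inorganic <- standardize_structure("[Na+].[Cl-]")$smiles_canonical
  expect_true(strip_salt_parent(inorganic)$empty_parent)
})

test_that("charge neutralization is applied to the selected parent", {
  can <- standardize_structure("CC(=O)[O-].[Na+]")$smiles_canonical
  p <- strip_salt_parent(can, neutralize = TRUE)
  expect_identical(p$smiles_parent, standardize_structure("CC(=O)O")$smiles_canonical)
  expect_false(identical(p$smiles_parent, p$smiles_parent_preneutral))
})

test_that("InChIKeys match the reference implementation and the 14-10-1 shape", {
  keys <- make_inchikeys("CCO", "CCO")
  expect_identical(keys$inchikey_full, "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
  expect_identical(keys$inchikey_parent, keys$inchikey_full)
  expect_true(is_inchikey(keys$inchikey_full))

  # tautomer pair: same connectivity skeleton, equal first-14 block
  k1 <- make_inchikeys("Oc1ccccn1", "Oc1ccccn1")$inchikey_full
  k2 <- make_inchikeys("O=c1cccc[nH]1", "O=c1cccc[nH]1")$inchikey_full
  expect_identical(substr(k1, 1, 14), substr(k2, 1, 14))
})

test_that("library standardization conserves records and round-trips via CSV", {
  lib <- tibble::tibble(
    sample_id = c("A", "B", "C", "D"),
    smiles_raw = c("CCO", "c1ccccc1N.Cl", "??bad", "CC(=O)O"),
    user_gene_symbol = c(NA, "HRH1", NA, "")
  )
  std <- standardize_compounds(lib)
  expect_equal(nrow(std), nrow(lib))
  expect_equal(std$parse_ok, c(TRUE, TRUE, FALSE, TRUE))
  # parse failure <=> all structure fields absent
  expect_true(all(is.na(std$smiles_canonical[!std$parse_ok])))
  expect_true(all(is.na(std$inchikey_full[!std$parse_ok])))
  expect_true(all(is_inchikey(std$inchikey_full[std$parse_ok])))
  # salt: parent key differs from full key; single fragment: keys equal
  expect_false(std$inchikey_full[2] == std$inchikey_parent[2])
  expect_identical(std$inchikey_full[1], std$inchikey_parent[1])

  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(std, f, na = "")
  back <- readr::read_csv(f, col_types = readr::cols(
    parse_ok = "l", .default = "c"))
  expect_equal(as.data.frame(back), as.data.frame(std), ignore_attr = TRUE)
})
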