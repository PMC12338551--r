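# Per-source adapters: dialect parsing and the source filters

write_tmp <- function(lines, ext) {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("identifier mapping tries the full key first, then the parent", {
  cmp <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    inchikey_full = c("LFQSCWFLJHTTHZ-UHFFFAOYSA-N", "AAAAAAAAAAAAAA-BBBBBBBBBB-N",
                      "CCCCCCCCCCCCCC-DDDDDDDDDD-N"),
    inchikey_parent = c("LFQSCWFLJHTTHZ-UHFFFAOYSA-N", "PAYRUJLWNCNPSJ-UHFFFAOYSA-N",
                        "CCCCCCCCCCCCCC-DDDDDDDDDD-N"),
    parse_ok = TRUE
  )
  map <- write_tmp(c("inchikey\tsource\tsource_id",
                     "LFQSCWFLJHTTHZ-UHFFFAOYSA-N\tchembl\tCHEMBL1",
                     "PAYRUJLWNCNPSJ-UHFFFAOYSA-N\tchembl\tCHEMBL2",
                     "badkey\tchembl\tCHEMBL3",
                     "LFQSCWFLJHTTHZ-UHFFFAOYSA-N\tnotasource\tX1"), ".tsv")
  res <- suppressWarnings(map_identifiers(cmp, map))
  expect_equal(res$sample_id, c("A", "B"))
  expect_equal(res$matched_via, c("full", "parent"))
  expect_equal(attr(res, "unresolved"), "C")

  empty <- write_tmp("inchikey\tsource\tsource_id", ".tsv")
  res0 <- map_identifiers(cmp, empty)
  expect_equal(nrow(res0), 0)
  expect_setequal(attr(res0, "unresolved"), cmp$sample_id)
})

test_that("drugbank adapter filters unknown-action and non-human targets", {
  xml <- write_tmp(c(
    '<drugbank>',
    ' <drug><drugbank-id>DB1</drugbank-id><targets>',
    '  <target><known-action>yes</known-action><organism>Humans</organism>',
    '   <polypeptide><gene-name>G1</gene-name><external-identifiers>',
    '    <external-identifier><resource>UniProtKB</resource><identifier>P1</identifier></external-identifier>',
    '   </external-identifiers></polypeptide></target>',
    '  <target><known-action>unknown</known-action><organism>Humans</organism>',
    '   <polypeptide><gene-name>G2</gene-name><external-identifiers>',
    '    <external-identifier><resource>UniProtKB</resource><identifier>P2</identifier></external-identifier>',
    '   </external-identifiers></polypeptide></target>',
    '  <target><known-action>yes</known-action><organism>Rat</organism>',
    '   <polypeptide><gene-name>G3</gene-name><external-identifiers>',
    '    <external-identifier><resource>UniProtKB</resource><identifier>P3</identifier></external-identifier>',
    '   </external-identifiers></polypeptide></target>',
    ' </targets></drug></drugbank>'), ".xml")
  recs <- parse_drugbank(xml, mini_id_map(c("A", "drugbank", "DB1")))
  expect_equal(nrow(recs), 1)
  expect_equal(recs$uniprot_acc, "P1")
  expect_true(all(is.na(recs$activity_value_molar)))
})

test_that("pharmgkb adapter joins chemicals to genes through the gene map", {
  tsv <- write_tmp(c(
    "entity1_id\tentity1_name\tentity1_type\tentity2_id\tentity2_name\tentity2_type",
    "PA1\tdrug1\tChemical\tPAG1\tDRD2\tGene",
    "PA1\tdrug1\tChemical\tPAG2\tNOPE\tGene",
    "PA9\tother\tChemical\tPAG1\tDRD2\tGene"), ".tsv")
  gm <- tibble::tibble(gene_symbol = "DRD2", uniprot_acc = "P14416")
  recs <- parse_pharmgkb(tsv, mini_id_map(c("A", "pharmgkb", "PA1")), gm)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$uniprot_acc, "P14416")
  expect_equal(unname(drop_counts(recs)["unresolved_gene_symbol"]), 1L)
})

test_that("iuphar adapter applies the inclusive 10 uM cutoff on the p-scale", {
  rows <- list(
    list(ligand_id = "L1", target_species = "Human", affinity_parameter = "pKi",
         affinity_value = "8.0", action = "Antagonist", target_uniprot = "P1",
         target_gene_symbol = "G1"),
    list(ligand_id = "L1", target_species = "Human", affinity_parameter = "pKi",
         affinity_value = "4.0", action = "Antagonist", target_uniprot = "P2",
         target_gene_symbol = "G2"),
    list(ligand_id = "L1", target_species = "Human", affinity_parameter = "pKi",
         affinity_value = "5.0", action = NA, target_uniprot = "P5",
         target_gene_symbol = "G5"),
    list(ligand_id = "L1", target_species = "Mouse", affinity_parameter = "pKi",
         affinity_value = "8.0", action = NA, target_uniprot = "P3",
         target_gene_symbol = "G3"),
    list(ligand_id = "L1", target_species = "Human", affinity_parameter = "pKi",
         affinity_value = "ND", action = NA, target_uniprot = "P4",
         target_gene_symbol = "G4")
  )
  f <- write_tmp(jsonlite::toJSON(rows, auto_unbox = TRUE), ".json")
  recs <- parse_iuphar(f, mini_id_map(c("A", "iuphar", "L1")))
  # pKi 8 kept; pKi 5 is exactly 10 uM, inclusive; pKi 4, Mouse, ND dropped
  expect_setequal(recs$uniprot_acc, c("P1", "P5"))
  expect_equal(recs$activity_value_molar[recs$uniprot_acc == "P1"], 1e-8)
  expect_equal(recs$action_field[recs$uniprot_acc == "P1"], "Antagonist")
  expect_equal(unname(drop_counts(recs)["unparseable_affinity"]), 1L)
})

test_that("pubchem adapter normalizes units and keeps concentrations <= 10 uM", {
  csv <- write_tmp(c(
    "cid,target_accession,target_taxon,activity_type,activity_value,activity_unit",
    "C1,P1,Homo sapiens,IC50,500,nM",
    "C1,P2,Homo sapiens,IC50,50,uM",
    "C1,P3,Homo sapiens,IC50,10,uM",
    "C1,P4,Homo sapiens,IC50,5,ugmL",
    "C1,P5,Homo sapiens,Active,1,nM",
    "C1,P6,Rattus norvegicus,IC50,1,nM"), ".csv")
  recs <- parse_pubchem(csv, mini_id_map(c("A", "pubchem", "C1")))
  expect_setequal(recs$uniprot_acc, c("P1", "P3"))
  expect_equal(recs$activity_value_molar[recs$uniprot_acc == "P1"], 5e-7)
  d <- drop_counts(recs)
  expect_equal(unname(d["unknown_unit_or_value"]), 1L)
  expect_equal(unname(d["non_concentration_type"]), 1L)
})

test_that("chembl adapter keeps human single-protein assays at pChEMBL >= 5", {
  csv <- write_tmp(c(
    paste0("molecule_chembl_id,target_accession,target_organism,target_type,",
           "assay_type,standard_type,pchembl_value,action_type"),
    "CH1,P1,Homo sapiens,SINGLE PROTEIN,B,IC50,6.2,",
    "CH1,P2,Homo sapiens,SINGLE PROTEIN,B,IC50,4.9,",
    "CH1,P3,Homo sapiens,SINGLE PROTEIN,F,Ki,5.0,INHIBITOR",
    "CH1,P4,Homo sapiens,PROTEIN COMPLEX,B,IC50,7.0,",
    "CH1,P5,Homo sapiens,SINGLE PROTEIN,A,IC50,7.0,",
    "CH1,P6,Homo sapiens,SINGLE PROTEIN,B,IC50,,"), ".csv")
  recs <- parse_chembl(csv, mini_id_map(c("A", "chembl", "CH1")))
  expect_setequal(recs$uniprot_acc, c("P1", "P3"))
  expect_equal(recs$assay_class[recs$uniprot_acc == "P3"], "functional")
  expect_equal(recs$action_field[recs$uniprot_acc == "P3"], "INHIBITOR")
  expect_equal(unname(drop_counts(recs)["missing_pchembl"]), 1L)
})

test_that("user gene annotations resolve through the gene map and blanks are ignored", {
  gm <- tibble::tibble(gene_symbol = "HRH1", uniprot_acc = "P35367")
  cmp <- tibble::tibble(sample_id = c("A", "B", "C"),
                        user_gene_symbol = c("HRH1", "", "NOT_A_GENE"))
  recs <- attach_user_annotations(cmp, gm)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$uniprot_acc, "P35367")
  expect_equal(unname(drop_counts(recs)["unresolved_gene_symbol"]), 1L)

  blank <- attach_user_annotations(
    tibble::tibble(sample_id = "A", user_gene_symbol = NA_character_), gm)
  expect_equal(nrow(blank), 0)
})

test_that("emitted records satisfy the source filter invariants post hoc", {
  spec <- synthetic_screen_spec(n_compounds = 80, n_targets = 15, seed = 5,
                                baseline_rate = 0.08, hit_fraction = 0.1)
  b <- generate_screen(spec, dir = withr::local_tempdir())
  lib <- load_library(b$paths[["library"]])
  cmp <- standardize_compounds(lib)
  im <- map_identifiers(cmp, b$paths[["id_map"]])
  recs <- suppressWarnings(parse_all_sources(cmp, im, paths = list(
    drugbank = b$paths[["drugbank"]], pharmgkb = b$paths[["pharmgkb"]],
    iuphar = b$paths[["iuphar"]], pubchem = b$paths[["pubchem"]],
    chembl = b$paths[["chembl"]], gene_map = b$paths[["gene_map"]])))
  expect_true(all(recs$organism == "human"))
  conc <- recs$source %in% c("iuphar", "pubchem")
  expect_true(all(recs$activity_value_molar[conc] <= 1e-5))
  expect_true(all(recs$pchembl[recs$source == "chembl"] >= 5))
  curated <- recs$source %in% c("drugbank", "pharmgkb", "user")
  expect_true(all(is.na(recs$activity_value_molar[curated])))
})

test_that("tightening the activity cutoff never increases record counts", {
  spec <- synthetic_screen_spec(n_compounds = 60, n_targets = 10, seed = 9,
                                baseline_rate = 0.1, hit_fraction = 0.1)
  b <- generate_screen(spec, dir = withr::local_tempdir())
  cmp <- standardize_compounds(load_library(b$paths[["library"]]))
  im <- map_identifiers(cmp, b$paths[["id_map"]])
  for (src in c("iuphar", "pubchem")) {
    parser <- if (src == "iuphar") parse_iuphar else parse_pubchem
    n10 <- nrow(parser(b$paths[[src]], im, cutoff_molar = 1e-5))
    n1 <- nrow(parser(b$paths[[src]], im, cutoff_molar = 1e-6))
    expect_lte(n1, n10)
  }
  n5 <- nrow(parse_chembl(b$paths[["chembl"]], im, pchembl_min = 5))
  n6 <- nrow(parse_chembl(b$paths[["chembl"]], im, pchembl_min = 6))
  expect_lte(n6, n5)
})

test_that("adapters are order-independent over shuffled dump rows", {
  spec <- synthetic_screen_spec(n_compounds = 60, n_targets = 10, seed = 21,
                                baseline_rate = 0.1, hit_fraction = 0.1)
  b <- generate_screen(spec, dir = withr::local_tempdir())
  cmp <- standardize_compounds(load_library(b$paths[["library"]]))
  im <- map_identifiers(cmp, b$paths[["id_map"]])
  orig <- parse_chembl(b$paths[["chembl"]], im)
  lines <- readLines(b$paths[["chembl"]])
  set.seed(1)
  shuf <- c(lines[1], sample(lines[-1]))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuf, f)
  redo <- parse_chembl(f, im)
  key <- function(d) sort(do.call(paste, as.data.frame(d)))
  expect_identical(key(redo), key(orig))
})
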