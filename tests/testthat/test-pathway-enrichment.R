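# GMT reading and gene-set overrepresentation with the strength metric

test_that("GMT reading applies set semantics and validates line shape", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tG1\tG2\tG2\tG3", "S2\tdesc two\tG4"), f)
  gs <- read_gmt(f)
  expect_equal(nrow(gs), 2)
  expect_setequal(gs$members[[1]], c("G1", "G2", "G3"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tG1", "S2\tonlydesc"), bad)
  expect_error(read_gmt(bad), "line 2", class = "hitdecon_schema_error")

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_equal(nrow(read_gmt(empty)), 0)
})

test_that("strength reproduces its closed forms through real enrichments", {
  universe <- paste0("G", 1:100)
  # observed 5, expected 5*10/100 = 0.5 -> strength 1
  sets <- tibble::tibble(term_id = "T", term_name = "t",
                         members = list(paste0("G", 1:5)))
  r <- enrich_pathways(paste0("G", 1:10), sets, universe)
  expect_equal(r$expected, 0.5)
  expect_equal(r$strength, 1)
  # observed 3, expected 30*10/100 = 3 -> strength 0
  sets2 <- tibble::tibble(term_id = "T", term_name = "t",
                          members = list(paste0("G", c(1:3, 20:46))))
  r2 <- enrich_pathways(paste0("G", 1:10), sets2, universe)
  expect_equal(r2$observed, 3L)
  expect_equal(r2$strength, 0)
  # observed 2, expected 20*40/100 = 8 -> strength log10(0.25)
  sets3 <- tibble::tibble(term_id = "T", term_name = "t",
                          members = list(paste0("G", c(1:2, 60:77))))
  r3 <- enrich_pathways(paste0("G", 1:40), sets3, universe)
  expect_equal(r3$observed, 2L)
  expect_equal(r3$expected, 8)
  expect_equal(r3$strength, log10(0.25), tolerance = 1e-12)
  expect_equal(round(r3$strength, 3), -0.602)
})

test_that("strength is anti-symmetric and p reuses the exact Fisher tail", {
  set.seed(7)
  obs <- sample(1:50, 100, TRUE)
  expd <- runif(100, 0.1, 50)
  expect_equal(enrichment_strength(obs, expd), -enrichment_strength(expd, obs),
               tolerance = 1e-12)

  universe <- paste0("G", 1:60)
  sets <- tibble::tibble(term_id = "T", term_name = "t",
                         members = list(paste0("G", 1:12)))
  r <- enrich_pathways(paste0("G", 1:9), sets, universe)
  expect_equal(r$p_value,
               fisher_right_tail(60, 9, 12, r$observed), tolerance = 1e-12)
})

test_that("enlarging the universe never decreases strength", {
  sets <- tibble::tibble(term_id = "T", term_name = "t",
                         members = list(paste0("G", 1:8)))
  query <- paste0("G", 1:4)
  last <- -Inf
  for (n in c(20, 50, 100, 500)) {
    r <- enrich_pathways(query, sets, paste0("G", 1:n))
    expect_gte(r$strength, last - 1e-12)
    last <- r$strength
  }
})

test_that("degenerate pathway inputs error; out-of-universe genes drop with warning", {
  sets <- tibble::tibble(term_id = "T", term_name = "t", members = list("G1"))
  expect_error(enrich_pathways(character(0), sets, "G1"), class = "hitdecon_value_error")
  expect_error(enrich_pathways("G1", sets, character(0)), class = "hitdecon_value_error")
  expect_warning(r <- enrich_pathways(c("G1", "ZZZ"), sets, c("G1", "G2")),
                 "outside the universe")
  expect_equal(attr(r, "query_size"), 1L)
  # observed = 0 terms are reported untested, excluded from BH
  sets0 <- tibble::tibble(term_id = c("A", "B"), term_name = c("a", "b"),
                          members = list("G1", "G2"))
  r0 <- enrich_pathways("G1", sets0, c("G1", "G2"))
  expect_true(is.na(r0$strength[r0$term_id == "B"]))
  expect_true(is.na(r0$q_value[r0$term_id == "B"]))
})

test_that("the remote client is interface-only offline and parses canned responses", {
  expect_error(remote_enrichment_request(c("HRH1", "DRD2")),
               class = "hitdecon_remote_unavailable")
  expect_error(remote_enrichment_request(character(0)),
               class = "hitdecon_value_error")
  req <- remote_enrichment_request(c("HRH1", "DRD2"), offline = FALSE)
  expect_true(grepl("enrichment", req$url))

  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(list(
    term = "hsa04020", description = "Calcium signaling pathway",
    number_of_genes = 5, number_of_genes_in_background = 50,
    p_value = 1e-4, fdr = 1e-3)), auto_unbox = TRUE), f)
  parsed <- parse_remote_enrichment(f, universe_size = 1000, query_size = 20)
  expect_equal(parsed$observed, 5L)
  expect_equal(parsed$expected, 1)
  expect_equal(parsed$strength, log10(5))
})
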