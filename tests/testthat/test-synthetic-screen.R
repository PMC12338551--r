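# Synthetic screen generator: determinism, planted bookkeeping, null design

test_that("spec validation rejects impossible screens", {
  expect_error(synthetic_screen_spec(n_compounds = 100, seed = NULL),
               class = "hitdecon_value_error")
  expect_error(synthetic_screen_spec(n_compounds = 0, seed = 1),
               class = "hitdecon_value_error")
  expect_error(synthetic_screen_spec(n_compounds = 5, hit_fraction = 0.01, seed = 1),
               class = "hitdecon_value_error")
  expect_error(synthetic_screen_spec(baseline_rate = 1.5, seed = 1),
               class = "hitdecon_value_error")
})

test_that("bundles are byte-identical under a fixed seed", {
  spec <- synthetic_screen_spec(n_compounds = 40, n_targets = 8, seed = 7,
                                baseline_rate = 0.1, hit_fraction = 0.1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_screen(spec, dir = d1)
  b2 <- generate_screen(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  expect_identical(b1$manifest, b2$manifest)
})

test_that("the manifest books boundary records as inclusive survivors", {
  spec <- synthetic_screen_spec(n_compounds = 60, n_targets = 10, seed = 13,
                                baseline_rate = 0.05, hit_fraction = 0.1)
  b <- generate_screen(spec, chemistry = FALSE)
  m <- b$manifest
  b10 <- m[m$note %in% "boundary_10uM", ]
  expect_equal(nrow(b10), 1)
  expect_true(b10$survives)
  expect_equal(b10$activity_value * 1e-6, 1e-5)
  bp5 <- m[m$note %in% "boundary_pchembl5", ]
  expect_equal(nrow(bp5), 1)
  expect_true(bp5$survives)
  expect_equal(bp5$pchembl, 5)
})

test_that("planted targets are booked in spec and manifest exactly once", {
  spec <- synthetic_screen_spec(n_compounds = 60, n_targets = 10, seed = 2,
                                baseline_rate = 0.05, hit_fraction = 0.1,
                                planted_targets = tibble::tibble(target = 3L, fold = 5))
  core <- simulate_associations(spec)
  planted_accs <- unique(core$pairs$uniprot_acc[core$pairs$planted])
  expect_true(all(planted_accs %in% core$targets$uniprot_acc[3]))
  b <- generate_screen(spec, chemistry = FALSE)
  expect_equal(sum(grepl("^PLANTED", b$gene_sets$term_id)), 1)
  expect_true(core$targets$gene_symbol[3] %in% b$gene_sets$members[[1]])
})

test_that("decoy rows are planted to fail exactly their own filter", {
  spec <- synthetic_screen_spec(n_compounds = 80, n_targets = 12, seed = 31,
                                baseline_rate = 0.08, hit_fraction = 0.1)
  b <- generate_screen(spec, chemistry = FALSE)
  dec <- b$manifest[b$manifest$note %in% c("decoy", "decoy_nd_affinity"), ]
  expect_true(nrow(dec) >= 5)
  expect_false(any(dec$survives))
  expect_true(all(dec$reason %in% c(
    "known_action_unknown", "non_human", "above_cutoff", "unparseable_affinity",
    "unknown_unit", "below_pchembl_min", "not_single_protein",
    "missing_pchembl", "unresolved_gene_symbol")))
})

test_that("the null screen gives one uniform association per compound", {
  ns <- generate_null_screen(n_compounds = 200, n_targets = 20, hit_fraction = 0.1,
                             seed = 5)
  expect_equal(nrow(ns$pairs), 200)
  expect_equal(anyDuplicated(ns$pairs$sample_id), 0)
  expect_equal(length(ns$hit_ids), 20)
  expect_equal(nrow(ns$planted_targets), 0)
  expect_error(generate_null_screen(n_compounds = 5, hit_fraction = 0.01, seed = 1),
               class = "hitdecon_value_error")
  expect_error(generate_null_screen(seed = NULL), class = "hitdecon_value_error")
})

test_that("association rates track the spec probabilities", {
  spec <- synthetic_screen_spec(n_compounds = 1000, n_targets = 40, seed = 17,
                                baseline_rate = 0.02, hit_fraction = 0.05,
                                planted_targets = tibble::tibble(target = 1L, fold = 5))
  core <- simulate_associations(spec)
  n_cells <- 1000 * 40
  rate <- nrow(core$pairs) / n_cells
  expect_gt(rate, 0.015); expect_lt(rate, 0.025)
  planted_hit <- core$pairs[core$pairs$planted & core$pairs$is_hit, ]
  hit_rate <- nrow(planted_hit) / length(core$hit_ids)
  expect_gt(hit_rate, 0.04) # fold 5 on a 2% baseline
})
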