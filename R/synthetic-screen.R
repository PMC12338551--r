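# Synthetic screens with planted ground truth. A screen is a compound library
# (valid enumerated structures, a salt fraction, a few invalid strings), a hit
# list, evidence rows spread over the five database dialects plus optional
# user gene annotations, identifier/gene maps, gene sets, and a manifest that
# records for every emitted row whether it should survive the pipeline's
# filters. All randomness flows from the single spec seed through a
# counter-based derivation, so bundles are reproducible file by file.

derive_seed <- function(seed, counter) {
  as.integer(((as.numeric(seed) %% 94906249) * 1103 + counter * 7919 + 13) %% 2147483647)
}

#' Specify a synthetic screen
#'
#' Defaults are the package's reference study conditions: a 2,000-compound
#' library annotated against 100 targets at a 2% background association rate,
#' 5% of compounds designated hits, and one planted mechanism whose
#' association probability among hits is 5-fold the baseline.
#'
#' @param n_compounds library size.
#' @param n_targets number of protein targets.
#' @param baseline_rate probability that a (compound, target) association
#'   exists.
#' @param hit_fraction fraction of compounds designated hits.
#' @param planted_targets tibble `(target, fold)`: planted target indices and
#'   the multiplier applied to the association probability among hits
#'   (fold >= 1).
#' @param source_mix named probabilities over the five database sources used
#'   to attribute evidence rows.
#' @param activity_profile list with `log10_molar_mean` and `log10_molar_sd`:
#'   bioactivity values are drawn log-normally around ~100 nM so that a small
#'   tail straddles the 10 uM cutoff.
#' @param salt_fraction fraction of valid structures written as salts.
#' @param invalid_fraction fraction of library rows with unparseable SMILES.
#' @param user_gene_fraction fraction of compounds carrying a user
#'   `Gene Symbol` annotation.
#' @param decoy_fraction evidence rows that must fail a source filter, as a
#'   fraction of true evidence rows.
#' @param seed integer seed (mandatory).
#' @return a `synthetic_screen_spec` list.
#' @export
synthetic_screen_spec <- function(n_compounds = 2000, n_targets = 100,
                                  baseline_rate = 0.02, hit_fraction = 0.05,
                                  planted_targets = tibble(target = 1L, fold = 5),
                                  source_mix = c(drugbank = 0.10, pharmgkb = 0.10,
                                                 iuphar = 0.25, pubchem = 0.25,
                                                 chembl = 0.30),
                                  activity_profile = list(log10_molar_mean = -7,
                                                          log10_molar_sd = 1),
                                  salt_fraction = 0.15, invalid_fraction = 0.02,
                                  user_gene_fraction = 0.05, decoy_fraction = 0.15,
                                  seed) {
  if (missing(seed) || is.null(seed)) hd_stop("seed is mandatory", "hitdecon_value_error")
  probs <- c(baseline_rate, hit_fraction, salt_fraction, invalid_fraction,
             user_gene_fraction, decoy_fraction, unname(source_mix))
  if (any(probs < 0 | probs > 1)) {
    hd_stop("probabilities must lie in [0, 1]", "hitdecon_value_error")
  }
  if (n_compounds < 1 || round(hit_fraction * n_compounds) < 1) {
    hd_stop("need at least one compound and at least one hit", "hitdecon_value_error")
  }
  planted_targets <- as_tibble(planted_targets)
  if (nrow(planted_targets)) {
    stopifnot(all(planted_targets$fold >= 1),
              all(planted_targets$target >= 1 & planted_targets$target <= n_targets))
  }
  structure(list(
    n_compounds = as.integer(n_compounds), n_targets = as.integer(n_targets),
    baseline_rate = baseline_rate, hit_fraction = hit_fraction,
    planted_targets = planted_targets,
    source_mix = source_mix / sum(source_mix), activity_profile = activity_profile,
    salt_fraction = salt_fraction, invalid_fraction = invalid_fraction,
    user_gene_fraction = user_gene_fraction, decoy_fraction = decoy_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_screen_spec")
}

target_table <- function(n_targets) {
  tibble(
    uniprot_acc = sprintf("P%05d", 10000L + seq_len(n_targets)),
    gene_symbol = sprintf("SYG%03d", seq_len(n_targets))
  )
}

#' Sample the association structure of a synthetic screen
#'
#' The statistical core of [generate_screen()]: which compounds are hits and
#' which (compound, target) associations exist, with planted targets'
#' association probability among hits multiplied by their fold.
#'
#' @param spec a [synthetic_screen_spec()].
#' @return list with `library_ids`, `hit_ids`, `targets` and the association
#'   `pairs` tibble (with `planted` and `is_hit` flags).
#' @export
simulate_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_screen_spec"))
  set.seed(derive_seed(spec$seed, 1L))
  n <- spec$n_compounds; t <- spec$n_targets
  library_ids <- sprintf("CMPD%05d", seq_len(n))
  hit_idx <- sort(sample.int(n, round(spec$hit_fraction * n)))
  prob <- matrix(spec$baseline_rate, n, t)
  if (nrow(spec$planted_targets)) {
    for (k in seq_len(nrow(spec$planted_targets))) {
      j <- spec$planted_targets$target[k]
      prob[hit_idx, j] <- pmin(1, spec$baseline_rate * spec$planted_targets$fold[k])
    }
  }
  assoc <- matrix(rbinom(n * t, 1L, prob), n, t) == 1L
  idx <- which(assoc, arr.ind = TRUE)
  targets <- target_table(t)
  pairs <- tibble(
    sample_id = library_ids[idx[, 1]],
    uniprot_acc = targets$uniprot_acc[idx[, 2]],
    gene_symbol = targets$gene_symbol[idx[, 2]],
    planted = idx[, 2] %in% spec$planted_targets$target,
    is_hit = idx[, 1] %in% hit_idx
  ) |> arrange(.data$sample_id, .data$uniprot_acc)
  list(library_ids = library_ids, hit_ids = library_ids[hit_idx],
       targets = targets, pairs = pairs)
}

# deterministic pool of valid, structurally distinct small-molecule SMILES:
# scaffold + alkyl chain + terminal group enumeration
smiles_pool <- function(n) {
  scaffolds <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccc2ccccc2c1", "c1ccoc1",
                 "c1ccsc1", "C1CCNCC1", "c1cnccn1", "C1CCOC1", "c1ccc2[nH]ccc2c1")
  tails <- c("", "O", "N", "Cl", "Br", "F", "C(=O)O", "C(=O)N", "C#N",
             "N(C)C", "OC", "S(=O)(=O)N")
  grid <- expand.grid(len = 0:16, tail = tails, scaffold = scaffolds,
                      stringsAsFactors = FALSE)
  if (n > nrow(grid)) {
    hd_stop(paste0("structure pool supports at most ", nrow(grid), " compounds"),
            "hitdecon_value_error")
  }
  paste0(grid$scaffold[seq_len(n)], strrep("C", grid$len[seq_len(n)]),
         grid$tail[seq_len(n)])
}

SALT_SUFFIXES <- c(".Cl", ".O", ".[Na+].[Cl-]", ".OS(=O)(=O)O", ".CC(=O)O")

SOURCE_ID_PREFIX <- c(drugbank = "DB", pharmgkb = "PA", iuphar = "IUP",
                      pubchem = "CID", chembl = "CHEMBL")

source_id_for <- function(source, compound_index) {
  paste0(SOURCE_ID_PREFIX[source], sprintf("%05d", compound_index))
}

# evidence-value assignment for one vector of rows of a given source
draw_bioactivity <- function(n_rows, source, profile) {
  molar <- 10^rnorm(n_rows, profile$log10_molar_mean, profile$log10_molar_sd)
  out <- tibble(activity_type = NA_character_, activity_value = NA_real_,
                activity_unit = NA_character_, pchembl = NA_real_,
                action_field = NA_character_, assay = NA_character_,
                value_survives = TRUE, .rows = n_rows)
  if (source == "iuphar") {
    par <- sample(c("pKi", "pIC50", "pEC50", "pKd"), n_rows, TRUE,
                  prob = c(0.4, 0.3, 0.2, 0.1))
    p <- round(-log10(molar), 2)
    act <- sample(c(NA, "Antagonist", "Agonist"), n_rows, TRUE, prob = c(0.4, 0.4, 0.2))
    out$activity_type <- par; out$activity_value <- p; out$action_field <- act
    out$value_survives <- 10^(-p) <= ACTIVITY_CUTOFF_MOLAR
  } else if (source == "pubchem") {
    par <- sample(c("IC50", "EC50", "Ki", "Kd", "AC50"), n_rows, TRUE,
                  prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    unit <- sample(c("nM", "uM"), n_rows, TRUE, prob = c(0.7, 0.3))
    fac <- ifelse(unit == "nM", 1e-9, 1e-6)
    val <- signif(molar / fac, 6)
    out$activity_type <- par; out$activity_value <- val; out$activity_unit <- unit
    out$value_survives <- val * fac <= ACTIVITY_CUTOFF_MOLAR
  } else if (source == "chembl") {
    par <- sample(c("IC50", "EC50", "Ki", "Kd"), n_rows, TRUE,
                  prob = c(0.4, 0.25, 0.25, 0.1))
    pch <- round(-log10(molar), 2)
    act <- sample(c(NA, "INHIBITOR", "ANTAGONIST", "AGONIST", "ACTIVATOR"),
                  n_rows, TRUE, prob = c(0.55, 0.2, 0.1, 0.1, 0.05))
    out$activity_type <- par; out$pchembl <- pch; out$action_field <- act
    out$assay <- sample(c("B", "F"), n_rows, TRUE, prob = c(0.7, 0.3))
    out$value_survives <- pch >= PCHEMBL_MIN
  }
  out
}

empty_manifest <- function() {
  tibble(sample_id = character(), uniprot_acc = character(),
         gene_symbol = character(), source = character(), source_id = character(),
         organism = character(), target_type = character(), assay = character(),
         activity_type = character(), activity_value = numeric(),
         activity_unit = character(), pchembl = numeric(),
         action_field = character(), known_action = character(),
         is_true_association = logical(), survives = logical(),
         reason = character(), note = character())
}

# decoy modes: evidence rows that each violate exactly one source filter
decoy_modes <- function() {
  data.frame(
    source = c("drugbank", "drugbank", "iuphar", "iuphar", "iuphar",
               "pubchem", "pubchem", "chembl", "chembl", "chembl", "pharmgkb"),
    reason = c("known_action_unknown", "non_human", "non_human", "above_cutoff",
               "unparseable_affinity", "above_cutoff", "unknown_unit",
               "below_pchembl_min", "not_single_protein", "missing_pchembl",
               "unresolved_gene_symbol"),
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic screen with planted ground truth
#'
#' Emits the library table, hit list, all five source dumps in their fixture
#' dialects, identifier- and gene-mapping tables, a GMT file with one gene set
#' per planted mechanism, and a manifest that records every emitted evidence
#' row together with whether it survives the corresponding source filter.
#' Two boundary rows are always planted: a 10 uM concentration (inclusive
#' cutoff, survives) and a pChEMBL of exactly 5 (survives).
#'
#' @param spec a [synthetic_screen_spec()].
#' @param dir if non-NULL, write the bundle files here (see
#'   [write_screen_bundle()] for names).
#' @param chemistry compute structures' InChIKeys and the identifier map
#'   (requires OpenBabel work proportional to the library size). With
#'   `chemistry = FALSE` the id map and library SMILES are still generated but
#'   keys/ids are omitted, which is sufficient for purely statistical use of
#'   the manifest. Writing a bundle forces chemistry.
#' @return a list bundle: `spec`, `library`, `hit_ids`, `targets`, `pairs`
#'   (true associations), `manifest`, `survivor_pairs` (distinct pairs with at
#'   least one surviving evidence row), `id_map`, `gene_map`, `gene_sets`,
#'   `dumps` (per-source tibbles/xml), and `paths` when written.
#' @export
generate_screen <- function(spec, dir = NULL, chemistry = !is.null(dir)) {
  stopifnot(inherits(spec, "synthetic_screen_spec"))
  core <- simulate_associations(spec)
  n <- spec$n_compounds

  # library masks: invalid structures, salts, user annotations
  set.seed(derive_seed(spec$seed, 2L))
  invalid <- runif(n) < spec$invalid_fraction
  salted <- !invalid & runif(n) < spec$salt_fraction
  salt_idx <- sample.int(length(SALT_SUFFIXES), n, TRUE)
  user_mask <- runif(n) < spec$user_gene_fraction
  user_target_idx <- sample.int(spec$n_targets, n, TRUE)
  map_via_parent <- runif(n) < 0.5

  base_smiles <- smiles_pool(n)
  smiles <- base_smiles
  smiles[salted] <- paste0(base_smiles[salted], SALT_SUFFIXES[salt_idx[salted]])
  smiles[invalid] <- sprintf("??invalid%04d", which(invalid))

  user_gene <- rep(NA_character_, n)
  user_gene[user_mask] <- core$targets$gene_symbol[user_target_idx[user_mask]]
  # one deliberately unresolvable symbol to exercise the dropped-count path
  bad_user <- which(user_mask)[1]
  if (!is.na(bad_user)) user_gene[bad_user] <- "NOTAGENE"

  library_tbl <- tibble(
    `SMILES` = smiles, `Sample ID` = core$library_ids, `Gene Symbol` = user_gene
  )

  # true evidence rows over the five database sources
  set.seed(derive_seed(spec$seed, 3L))
  pairs <- core$pairs
  comp_index <- match(pairs$sample_id, core$library_ids)
  n_pairs <- nrow(pairs)
  reps <- 1L + rbinom(n_pairs, 1L, 0.3)
  ev <- pairs[rep(seq_len(n_pairs), reps), ]
  ev_comp <- rep(comp_index, reps)
  src <- sample(names(spec$source_mix), nrow(ev), TRUE, prob = spec$source_mix)
  rows <- list()
  for (s in unique(src)) {
    sel <- which(src == s)
    v <- draw_bioactivity(length(sel), s, spec$activity_profile)
    valid_struct <- !invalid[ev_comp[sel]]
    survives <- valid_struct & v$value_survives
    reason <- rep(NA_character_, length(sel))
    reason[!v$value_survives] <- if (s == "chembl") "below_pchembl_min" else "above_cutoff"
    reason[!valid_struct] <- "structure_unresolvable"
    rows[[s]] <- tibble(
      sample_id = ev$sample_id[sel], uniprot_acc = ev$uniprot_acc[sel],
      gene_symbol = ev$gene_symbol[sel], source = s,
      source_id = source_id_for(s, ev_comp[sel]),
      organism = "Homo sapiens",
      target_type = if (s == "chembl") "SINGLE PROTEIN" else NA_character_,
      assay = v$assay, activity_type = v$activity_type,
      activity_value = v$activity_value, activity_unit = v$activity_unit,
      pchembl = v$pchembl, action_field = v$action_field,
      known_action = if (s == "drugbank") "yes" else NA_character_,
      is_true_association = TRUE, survives = survives, reason = reason,
      note = NA_character_
    )
  }
  manifest <- bind_rows(rows)

  # user annotations are evidence too
  user_rows <- which(user_mask)
  if (length(user_rows)) {
    ok_symbol <- user_gene[user_rows] != "NOTAGENE"
    valid_user_target <- core$targets$gene_symbol[user_target_idx[user_rows]]
    manifest <- bind_rows(manifest, tibble(
      sample_id = core$library_ids[user_rows],
      uniprot_acc = core$targets$uniprot_acc[user_target_idx[user_rows]],
      gene_symbol = valid_user_target, source = "user", source_id = NA_character_,
      organism = "Homo sapiens", target_type = NA_character_, assay = NA_character_,
      activity_type = NA_character_, activity_value = NA_real_,
      activity_unit = NA_character_, pchembl = NA_real_,
      action_field = NA_character_, known_action = NA_character_,
      is_true_association = TRUE, survives = ok_symbol,
      reason = ifelse(ok_symbol, NA_character_, "unresolved_gene_symbol"),
      note = NA_character_
    ))
  }

  # boundary rows: 10 uM exactly (inclusive) and pChEMBL exactly 5
  set.seed(derive_seed(spec$seed, 4L))
  true_keys <- unique(paste(manifest$sample_id, manifest$uniprot_acc))
  free_cell <- function() {
    for (i in 1:1000) {
      ci <- sample(which(!invalid), 1); tj <- sample.int(spec$n_targets, 1)
      key <- paste(core$library_ids[ci], core$targets$uniprot_acc[tj])
      if (!key %in% true_keys) {
        true_keys <<- c(true_keys, key)
        return(c(ci, tj))
      }
    }
    NULL
  }
  b1 <- free_cell(); b2 <- free_cell()
  if (!is.null(b1)) {
    manifest <- bind_rows(manifest, tibble(
      sample_id = core$library_ids[b1[1]], uniprot_acc = core$targets$uniprot_acc[b1[2]],
      gene_symbol = core$targets$gene_symbol[b1[2]], source = "pubchem",
      source_id = source_id_for("pubchem", b1[1]), organism = "Homo sapiens",
      target_type = NA_character_, assay = NA_character_, activity_type = "IC50",
      activity_value = 10, activity_unit = "uM", pchembl = NA_real_,
      action_field = NA_character_, known_action = NA_character_,
      is_true_association = TRUE, survives = TRUE, reason = NA_character_,
      note = "boundary_10uM"
    ))
  }
  if (!is.null(b2)) {
    manifest <- bind_rows(manifest, tibble(
      sample_id = core$library_ids[b2[1]], uniprot_acc = core$targets$uniprot_acc[b2[2]],
      gene_symbol = core$targets$gene_symbol[b2[2]], source = "chembl",
      source_id = source_id_for("chembl", b2[1]), organism = "Homo sapiens",
      target_type = "SINGLE PROTEIN", assay = "B", activity_type = "Ki",
      activity_value = NA_real_, activity_unit = NA_character_, pchembl = 5,
      action_field = NA_character_, known_action = NA_character_,
      is_true_association = TRUE, survives = TRUE, reason = NA_character_,
      note = "boundary_pchembl5"
    ))
  }

  # decoys: rows that must each fail one source filter, on non-true cells
  n_decoy <- max(5L, round(spec$decoy_fraction * nrow(manifest)))
  modes <- decoy_modes()
  decoys <- list()
  for (d in seq_len(n_decoy)) {
    mode <- modes[((d - 1L) %% nrow(modes)) + 1L, ]
    cell <- free_cell()
    if (is.null(cell)) break
    ci <- cell[1]; tj <- cell[2]
    row <- tibble(
      sample_id = core$library_ids[ci], uniprot_acc = core$targets$uniprot_acc[tj],
      gene_symbol = core$targets$gene_symbol[tj], source = mode$source,
      source_id = source_id_for(mode$source, ci), organism = "Homo sapiens",
      target_type = if (mode$source == "chembl") "SINGLE PROTEIN" else NA_character_,
      assay = if (mode$source == "chembl") "B" else NA_character_,
      activity_type = NA_character_, activity_value = NA_real_,
      activity_unit = NA_character_, pchembl = NA_real_,
      action_field = NA_character_,
      known_action = if (mode$source == "drugbank") "yes" else NA_character_,
      is_true_association = FALSE, survives = FALSE, reason = mode$reason,
      note = "decoy"
    )
    row <- switch(mode$reason,
      known_action_unknown = { row$known_action <- "unknown"; row },
      non_human = { row$organism <- if (mode$source == "iuphar") "Mouse" else "Rat"
                    if (mode$source == "iuphar") { row$activity_type <- "pKi"; row$activity_value <- 8 }
                    row },
      above_cutoff = { if (mode$source == "iuphar") {
                         row$activity_type <- "pKi"; row$activity_value <- 4
                       } else {
                         row$activity_type <- "IC50"; row$activity_value <- 50
                         row$activity_unit <- "uM"
                       }
                       row },
      unparseable_affinity = { row$activity_type <- "pKi"; row$note <- "decoy_nd_affinity"; row },
      unknown_unit = { row$activity_type <- "IC50"; row$activity_value <- 5
                       row$activity_unit <- "ugmL"; row },
      below_pchembl_min = { row$activity_type <- "IC50"; row$pchembl <- 4.5; row },
      not_single_protein = { row$target_type <- "PROTEIN COMPLEX"
                             row$activity_type <- "IC50"; row$pchembl <- 6; row },
      missing_pchembl = { row$activity_type <- "IC50"; row },
      unresolved_gene_symbol = { row$gene_symbol <- "NOTAGENE"; row },
      row)
    decoys[[d]] <- row
  }
  if (length(decoys)) manifest <- bind_rows(manifest, decoys)
  manifest <- manifest |> arrange(.data$source, .data$sample_id, .data$uniprot_acc)

  survivor_pairs <- manifest |>
    filter(.data$survives) |>
    distinct(.data$sample_id, .data$uniprot_acc) |>
    arrange(.data$sample_id, .data$uniprot_acc)

  # gene map (all real targets) and gene sets (one per planted mechanism)
  gene_map <- core$targets |> select(gene_symbol = "gene_symbol", uniprot_acc = "uniprot_acc")
  set.seed(derive_seed(spec$seed, 5L))
  sets <- list()
  if (nrow(spec$planted_targets)) {
    for (k in seq_len(nrow(spec$planted_targets))) {
      j <- spec$planted_targets$target[k]
      others <- setdiff(seq_len(spec$n_targets), j)
      members <- c(core$targets$gene_symbol[j],
                   core$targets$gene_symbol[sample(others, min(7, length(others)))])
      sets[[length(sets) + 1L]] <- tibble(
        term_id = sprintf("PLANTED%02d", k),
        term_name = sprintf("planted mechanism %d", k),
        members = list(sort(members)))
    }
  }
  for (k in 1:5) {
    members <- core$targets$gene_symbol[sample.int(spec$n_targets, min(10, spec$n_targets))]
    sets[[length(sets) + 1L]] <- tibble(
      term_id = sprintf("RANDSET%02d", k),
      term_name = sprintf("random set %d", k), members = list(sort(members)))
  }
  gene_sets <- bind_rows(sets)

  # identifier map: one row per (compound, source) present in any dump row
  id_map <- NULL
  std <- NULL
  if (chemistry) {
    std <- standardize_compounds(library_tbl |>
      rename(sample_id = "Sample ID", smiles_raw = "SMILES",
             user_gene_symbol = "Gene Symbol"))
    present <- manifest |>
      filter(.data$source != "user") |>
      distinct(.data$sample_id, .data$source)
    ci <- match(present$sample_id, core$library_ids)
    key <- ifelse(map_via_parent[ci] & !invalid[ci],
                  std$inchikey_parent[ci], std$inchikey_full[ci])
    id_map <- tibble(inchikey = key, source = present$source,
                     source_id = source_id_for(present$source, ci)) |>
      filter(!is.na(.data$inchikey)) |>
      distinct() |>
      arrange(.data$source, .data$source_id)
  }

  bundle <- list(
    spec = spec, library = library_tbl, standardized = std,
    hit_ids = core$hit_ids, targets = core$targets, pairs = core$pairs,
    manifest = manifest, survivor_pairs = survivor_pairs,
    id_map = id_map, gene_map = gene_map, gene_sets = gene_sets
  )
  if (!is.null(dir)) bundle$paths <- write_screen_bundle(bundle, dir)
  bundle
}

#' Generate a null screen for type-I calibration
#'
#' Every compound carries exactly one target association drawn uniformly, and
#' hits are drawn uniformly: Fisher tables across targets are exchangeable
#' draws from the null, so the fraction of targets with small p calibrates
#' the test.
#'
#' @param n_compounds,n_targets,hit_fraction,seed as in
#'   [synthetic_screen_spec()].
#' @return list with `library_ids`, `hit_ids`, `targets`, `pairs` and an empty
#'   `planted_targets` manifest entry.
#' @export
generate_null_screen <- function(n_compounds = 500, n_targets = 50,
                                 hit_fraction = 0.1, seed) {
  if (missing(seed) || is.null(seed)) hd_stop("seed is mandatory", "hitdecon_value_error")
  if (n_compounds < 1 || round(hit_fraction * n_compounds) < 1) {
    hd_stop("need at least one compound and at least one hit", "hitdecon_value_error")
  }
  set.seed(derive_seed(as.integer(seed), 1L))
  library_ids <- sprintf("CMPD%05d", seq_len(n_compounds))
  targets <- target_table(n_targets)
  tj <- sample.int(n_targets, n_compounds, TRUE)
  hit_idx <- sort(sample.int(n_compounds, round(hit_fraction * n_compounds)))
  pairs <- tibble(
    sample_id = library_ids, uniprot_acc = targets$uniprot_acc[tj],
    gene_symbol = targets$gene_symbol[tj],
    planted = FALSE, is_hit = seq_len(n_compounds) %in% hit_idx
  )
  list(library_ids = library_ids, hit_ids = library_ids[hit_idx],
       targets = targets, pairs = pairs, planted_targets = tibble(target = integer(), fold = numeric()))
}

#' Write a generated screen bundle to disk
#'
#' Files: `library.csv`, `hits.txt`, `drugbank.xml`, `pharmgkb.tsv`,
#' `iuphar.json`, `pubchem.csv`, `chembl.csv`, `id_map.tsv`, `gene_map.tsv`,
#' `pathways.gmt`, `manifest.csv`, `manifest_summary.json`. Output is
#' deterministic byte-for-byte for a fixed spec.
#'
#' @param bundle output of [generate_screen()] (with chemistry).
#' @param dir output directory (created if missing).
#' @return named character vector of paths.
#' @export
write_screen_bundle <- function(bundle, dir) {
  if (is.null(bundle$id_map)) {
    hd_stop("bundle was generated without chemistry; regenerate with chemistry = TRUE",
            "hitdecon_value_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(bundle$library, p("library.csv"), na = "")
  writeLines(bundle$hit_ids, p("hits.txt"))
  m <- bundle$manifest

  # drugbank XML
  db <- m |> filter(.data$source == "drugbank")
  doc <- xml2::xml_new_root("drugbank")
  for (id in unique(db$source_id)) {
    drug <- xml2::xml_add_child(doc, "drug")
    xml2::xml_add_child(drug, "drugbank-id", id)
    tgts <- xml2::xml_add_child(drug, "targets")
    sub <- db[db$source_id == id, ]
    for (i in seq_len(nrow(sub))) {
      tgt <- xml2::xml_add_child(tgts, "target")
      xml2::xml_add_child(tgt, "known-action", sub$known_action[i])
      xml2::xml_add_child(tgt, "organism",
                          if (sub$organism[i] == "Homo sapiens") "Humans" else sub$organism[i])
      poly <- xml2::xml_add_child(tgt, "polypeptide")
      xml2::xml_add_child(poly, "gene-name", sub$gene_symbol[i])
      ext <- xml2::xml_add_child(poly, "external-identifiers")
      e <- xml2::xml_add_child(ext, "external-identifier")
      xml2::xml_add_child(e, "resource", "UniProtKB")
      xml2::xml_add_child(e, "identifier", sub$uniprot_acc[i])
    }
  }
  xml2::write_xml(doc, p("drugbank.xml"))

  # pharmgkb relationships TSV
  pg <- m |> filter(.data$source == "pharmgkb")
  readr::write_tsv(tibble(
    entity1_id = pg$source_id, entity1_name = pg$sample_id, entity1_type = "Chemical",
    entity2_id = paste0("PAG", pg$gene_symbol), entity2_name = pg$gene_symbol,
    entity2_type = "Gene"
  ), p("pharmgkb.tsv"), na = "")

  # iuphar interactions JSON
  iu <- m |> filter(.data$source == "iuphar")
  iu_json <- tibble(
    ligand_id = iu$source_id,
    target_species = ifelse(iu$organism == "Homo sapiens", "Human", iu$organism),
    affinity_parameter = iu$activity_type,
    affinity_value = ifelse(iu$note %in% "decoy_nd_affinity", "ND",
                            as.character(iu$activity_value)),
    action = iu$action_field,
    target_uniprot = iu$uniprot_acc, target_gene_symbol = iu$gene_symbol
  )
  writeLines(jsonlite::toJSON(iu_json, dataframe = "rows", na = "null", pretty = TRUE),
             p("iuphar.json"))

  # pubchem bioactivity CSV
  pc <- m |> filter(.data$source == "pubchem")
  readr::write_csv(tibble(
    cid = pc$source_id, target_accession = pc$uniprot_acc,
    target_taxon = pc$organism, activity_type = pc$activity_type,
    activity_value = pc$activity_value, activity_unit = pc$activity_unit,
    target_gene_symbol = pc$gene_symbol
  ), p("pubchem.csv"), na = "")

  # chembl activity CSV
  ch <- m |> filter(.data$source == "chembl")
  readr::write_csv(tibble(
    molecule_chembl_id = ch$source_id, target_accession = ch$uniprot_acc,
    target_organism = ch$organism, target_type = ch$target_type,
    assay_type = ch$assay, standard_type = ch$activity_type,
    pchembl_value = ch$pchembl, action_type = ch$action_field,
    target_gene_symbol = ch$gene_symbol
  ), p("chembl.csv"), na = "")

  readr::write_tsv(bundle$id_map, p("id_map.tsv"))
  readr::write_tsv(bundle$gene_map, p("gene_map.tsv"))
  gmt_lines <- vapply(seq_len(nrow(bundle$gene_sets)), function(i) {
    paste(c(bundle$gene_sets$term_id[i], bundle$gene_sets$term_name[i],
            bundle$gene_sets$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, p("pathways.gmt"))
  readr::write_csv(m, p("manifest.csv"), na = "")
  summary <- list(
    n_compounds = bundle$spec$n_compounds, n_targets = bundle$spec$n_targets,
    n_hits = length(bundle$hit_ids),
    n_true_pairs = nrow(dplyr::distinct(bundle$pairs, .data$sample_id, .data$uniprot_acc)),
    n_manifest_rows = nrow(m), n_surviving_rows = sum(m$survives),
    n_survivor_pairs = nrow(bundle$survivor_pairs),
    planted = as.list(setNames(bundle$spec$planted_targets$fold,
                               bundle$targets$uniprot_acc[bundle$spec$planted_targets$target]))
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE),
             p("manifest_summary.json"))
  files <- c(library = "library.csv", hits = "hits.txt", drugbank = "drugbank.xml",
             pharmgkb = "pharmgkb.tsv", iuphar = "iuphar.json", pubchem = "pubchem.csv",
             chembl = "chembl.csv", id_map = "id_map.tsv", gene_map = "gene_map.tsv",
             gmt = "pathways.gmt", manifest = "manifest.csv",
             summary = "manifest_summary.json")
  setNames(file.path(dir, files), names(files))
}
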