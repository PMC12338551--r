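# Per-source adapters: each parses an offline dump dialect into harmonized
# compound-target evidence records and applies that source's filters (human
# targets only; 10 uM inclusive potency cutoff for bioactivity sources;
# pChEMBL >= 5 for ChEMBL; DrugBank known-action != "unknown").
#
# Harmonized evidence columns:
#   sample_id, source, uniprot_acc, gene_symbol, activity_type,
#   activity_value_molar, pchembl, action_field, assay_class, organism
# Dropped-row tallies are attached as attribute "drop_counts".

empty_records <- function() {
  tibble(
    sample_id = character(), source = character(), uniprot_acc = character(),
    gene_symbol = character(), activity_type = character(),
    activity_value_molar = double(), pchembl = double(),
    action_field = character(), assay_class = character(), organism = character()
  )
}

new_records <- function(sample_id, source, uniprot_acc, gene_symbol = NA_character_,
                        activity_type = NA_character_, activity_value_molar = NA_real_,
                        pchembl = NA_real_, action_field = NA_character_,
                        assay_class = NA_character_, organism = "human") {
  tibble(
    sample_id = as.character(sample_id), source = source,
    uniprot_acc = as.character(uniprot_acc), gene_symbol = as.character(gene_symbol),
    activity_type = as.character(activity_type),
    activity_value_molar = as.numeric(activity_value_molar),
    pchembl = as.numeric(pchembl), action_field = as.character(action_field),
    assay_class = as.character(assay_class), organism = organism
  )
}

with_drops <- function(records, ...) {
  attr(records, "drop_counts") <- c(...)
  records
}

#' Drop-count tally attached by an adapter
#' @param records adapter output.
#' @return named integer vector (possibly empty).
#' @export
drop_counts <- function(records) attr(records, "drop_counts") %||% integer(0)

is_human <- function(x) {
  tolower(trimws(as.character(x))) %in%
    c("human", "humans", "homo sapiens", "9606", "h. sapiens")
}

#' Read an identifier-mapping table (InChIKey to per-source compound ids)
#'
#' @param path delimited file with columns `inchikey`, `source`, `source_id`.
#' @return tibble of well-formed rows; malformed rows are skipped with a
#'   warning and counted in attribute `"drop_counts"`.
#' @export
read_id_map <- function(path) {
  tbl <- read_delimited(path)
  for (col in c("inchikey", "source", "source_id")) {
    if (!col %in% names(tbl)) {
      hd_stop(paste0("id-mapping table is missing column '", col, "'"),
              "hitdecon_schema_error")
    }
  }
  tbl <- tbl |>
    mutate(source = tolower(trimws(.data$source)), inchikey = trimws(.data$inchikey))
  ok <- is_inchikey(tbl$inchikey) & tbl$source %in% HITDECON_SOURCES &
    !is.na(blank_to_na(tbl$source_id))
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warn(paste0("skipped ", n_bad, " malformed id-mapping row(s)"))
  }
  with_drops(tbl[ok, c("inchikey", "source", "source_id")], malformed_rows = n_bad)
}

#' Resolve library compounds to per-source compound identifiers
#'
#' Lookup tries `inchikey_full` first, then `inchikey_parent` (salt-stripped),
#' mirroring the flexible matching that salt-aware key generation enables.
#' Compounds whose keys match no source at all form the unresolved set.
#'
#' @param compounds standardized library from [standardize_compounds()].
#' @param mapping either a path to the mapping table or a tibble from
#'   [read_id_map()].
#' @return tibble `(sample_id, source, source_id, matched_via)` restricted to
#'   library compounds, with attribute `"unresolved"` listing sample ids that
#'   resolved in no source (structure-valid compounds only; parse failures are
#'   reported separately).
#' @export
map_identifiers <- function(compounds, mapping) {
  idmap <- if (is.character(mapping)) read_id_map(mapping) else as_tibble(mapping)
  valid <- compounds |> filter(.data$parse_ok)
  by_full <- valid |>
    select("sample_id", inchikey = "inchikey_full") |>
    inner_join(idmap, by = "inchikey") |>
    mutate(matched_via = "full")
  rest <- valid |> anti_join(by_full, by = "sample_id")
  by_parent <- rest |>
    select("sample_id", inchikey = "inchikey_parent") |>
    inner_join(idmap, by = "inchikey") |>
    mutate(matched_via = "parent")
  res <- bind_rows(by_full, by_parent) |>
    select("sample_id", "source", "source_id", "matched_via") |>
    distinct() |>
    arrange(.data$sample_id, .data$source, .data$source_id)
  unresolved <- setdiff(valid$sample_id, res$sample_id)
  attr(res, "unresolved") <- unresolved
  res
}

sample_ids_for <- function(id_map, src) {
  id_map |>
    filter(.data$source == src) |>
    select("sample_id", "source_id") |>
    distinct()
}

#' Read a gene-symbol to UniProt accession table
#'
#' @param path delimited file with columns `gene_symbol`, `uniprot_acc`.
#' @return tibble with one row per gene symbol (first accession wins on
#'   duplicates).
#' @export
read_gene_map <- function(path) {
  tbl <- read_delimited(path)
  for (col in c("gene_symbol", "uniprot_acc")) {
    if (!col %in% names(tbl)) {
      hd_stop(paste0("gene-map table is missing column '", col, "'"),
              "hitdecon_schema_error")
    }
  }
  tbl |>
    select("gene_symbol", "uniprot_acc") |>
    filter(!is.na(blank_to_na(.data$gene_symbol)), !is.na(blank_to_na(.data$uniprot_acc))) |>
    distinct(.data$gene_symbol, .keep_all = TRUE)
}

#' Parse a DrugBank-style XML dump
#'
#' Emits one curated record per (mapped drug, target) whose `known-action`
#' attribute is not "unknown" and whose organism is human; the UniProt
#' accession is read from the target polypeptide's external identifiers.
#'
#' @param xml_path path to the XML dump.
#' @param id_map identifier map from [map_identifiers()].
#' @return harmonized evidence tibble (curated: no activity fields).
#' @export
parse_drugbank <- function(xml_path, id_map) {
  ids <- sample_ids_for(id_map, "drugbank")
  doc <- xml2::read_xml(xml_path)
  drugs <- xml2::xml_find_all(doc, ".//drug")
  out <- list()
  n_noacc <- 0L
  for (drug in drugs) {
    db_id <- xml2::xml_text(xml2::xml_find_first(drug, "./drugbank-id"))
    samples <- ids$sample_id[ids$source_id == db_id]
    if (!length(samples)) next
    for (tgt in xml2::xml_find_all(drug, "./targets/target")) {
      ka <- xml2::xml_text(xml2::xml_find_first(tgt, "./known-action"))
      if (is.na(ka) || tolower(trimws(ka)) == "unknown") next
      org <- xml2::xml_text(xml2::xml_find_first(tgt, "./organism"))
      if (!is_human(org)) next
      acc <- xml2::xml_text(xml2::xml_find_first(
        tgt, "./polypeptide/external-identifiers/external-identifier[resource='UniProtKB']/identifier"))
      if (is.na(acc) || !nzchar(acc)) {
        n_noacc <- n_noacc + 1L
        warn(paste0("drugbank target without UniProt identifier skipped (drug ", db_id, ")"))
        next
      }
      gene <- xml2::xml_text(xml2::xml_find_first(tgt, "./polypeptide/gene-name"))
      out[[length(out) + 1L]] <- new_records(
        sample_id = samples, source = "drugbank", uniprot_acc = acc,
        gene_symbol = if (is.na(gene) || !nzchar(gene)) NA_character_ else gene
      )
    }
  }
  res <- if (length(out)) bind_rows(out) else empty_records()
  with_drops(res, missing_uniprot = n_noacc)
}

#' Parse a PharmGKB-style relationships TSV
#'
#' Chemical-gene relationship rows whose chemical id maps to a library
#' compound yield curated records; gene symbols are resolved to UniProt
#' accessions through the gene map. Unresolvable symbols are dropped and
#' counted.
#'
#' @param tsv_path relationships TSV with columns `entity1_id`,
#'   `entity1_name`, `entity1_type`, `entity2_id`, `entity2_name`,
#'   `entity2_type`.
#' @param id_map identifier map from [map_identifiers()].
#' @param gene_map path or tibble from [read_gene_map()].
#' @return harmonized evidence tibble.
#' @export
parse_pharmgkb <- function(tsv_path, id_map, gene_map) {
  gm <- if (is.character(gene_map)) read_gene_map(gene_map) else as_tibble(gene_map)
  ids <- sample_ids_for(id_map, "pharmgkb")
  tbl <- read_delimited(tsv_path)
  need <- c("entity1_id", "entity1_type", "entity2_name", "entity2_type")
  for (col in need) {
    if (!col %in% names(tbl)) {
      hd_stop(paste0("pharmgkb relationships table is missing column '", col, "'"),
              "hitdecon_schema_error")
    }
  }
  rel <- tbl |>
    filter(tolower(.data$entity1_type) == "chemical",
           tolower(.data$entity2_type) == "gene") |>
    inner_join(ids, by = c(entity1_id = "source_id"))
  joined <- rel |> inner_join(gm, by = c(entity2_name = "gene_symbol"))
  n_dropped <- nrow(rel) - nrow(joined)
  res <- if (nrow(joined)) {
    new_records(sample_id = joined$sample_id, source = "pharmgkb",
                uniprot_acc = joined$uniprot_acc, gene_symbol = joined$entity2_name)
  } else empty_records()
  with_drops(res, unresolved_gene_symbol = n_dropped)
}

#' Parse an IUPHAR-style interactions JSON
#'
#' Human interactions with a numeric affinity on the p-scale (pKi and kin) are
#' converted to mol/L as `10^(-p)` and kept when at or below the 10 uM cutoff
#' (inclusive). The curated `Action` string is carried into `action_field` for
#' the mechanism classifier. Rows without a parseable affinity are dropped and
#' counted.
#'
#' @param json_path interactions JSON: array of objects with fields
#'   `ligand_id`, `target_species`, `affinity_parameter`, `affinity_value`,
#'   `action`, `target_uniprot`, `target_gene_symbol`.
#' @param id_map identifier map from [map_identifiers()].
#' @param cutoff_molar inclusive molar activity cutoff (default 10 uM).
#' @return harmonized evidence tibble.
#' @export
parse_iuphar <- function(json_path, id_map, cutoff_molar = ACTIVITY_CUTOFF_MOLAR) {
  ids <- sample_ids_for(id_map, "iuphar")
  rows <- jsonlite::fromJSON(json_path, simplifyDataFrame = TRUE)
  if (!length(rows) || !NROW(rows)) return(with_drops(empty_records(), unparseable_affinity = 0L))
  rows <- as_tibble(rows)
  rows <- rows |> inner_join(ids, by = c(ligand_id = "source_id"))
  keep_human <- is_human(rows$target_species)
  rows <- rows[keep_human, , drop = FALSE]
  pval <- suppressWarnings(as.numeric(rows$affinity_value))
  unparseable <- is.na(pval)
  n_unparseable <- sum(unparseable)
  rows <- rows[!unparseable, , drop = FALSE]
  molar <- 10^(-pval[!unparseable])
  keep <- molar <= cutoff_molar
  rows <- rows[keep, , drop = FALSE]
  molar <- molar[keep]
  res <- if (nrow(rows)) {
    new_records(
      sample_id = rows$sample_id, source = "iuphar", uniprot_acc = rows$target_uniprot,
      gene_symbol = rows$target_gene_symbol, activity_type = rows$affinity_parameter,
      activity_value_molar = molar, action_field = blank_to_na(rows$action)
    )
  } else empty_records()
  with_drops(res, unparseable_affinity = n_unparseable)
}

# unit tokens accepted for concentration activities, as multipliers to mol/L
MOLAR_UNIT_FACTORS <- c("m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6,
                        "nm" = 1e-9, "pm" = 1e-12)

# concentration-typed potency fields; a molar cutoff is undefined for anything else
CONCENTRATION_TYPE_PATTERN <- "^(IC[0-9]+|EC[0-9]+|AC[0-9]+|XC50|GI50|KI|KD|POTENCY)$"

#' Parse a PubChem-style bioactivity table
#'
#' Human rows with a concentration-typed potency (IC/EC/AC/XC50/Ki/Kd/Potency)
#' are unit-normalized to mol/L and kept when at or below the 10 uM cutoff
#' (inclusive). Rows with an unknown unit token are dropped and counted;
#' non-concentration outcomes are not usable under a molar cutoff and are
#' likewise counted.
#'
#' @param table_path bioactivity table with columns `cid`,
#'   `target_accession`, `target_taxon`, `activity_type`, `activity_value`,
#'   `activity_unit`, optional `target_gene_symbol`.
#' @param id_map identifier map from [map_identifiers()].
#' @param cutoff_molar inclusive molar activity cutoff (default 10 uM).
#' @return harmonized evidence tibble.
#' @export
parse_pubchem <- function(table_path, id_map, cutoff_molar = ACTIVITY_CUTOFF_MOLAR) {
  ids <- sample_ids_for(id_map, "pubchem")
  tbl <- read_delimited(table_path)
  need <- c("cid", "target_accession", "target_taxon", "activity_type",
            "activity_value", "activity_unit")
  for (col in need) {
    if (!col %in% names(tbl)) {
      hd_stop(paste0("pubchem bioactivity table is missing column '", col, "'"),
              "hitdecon_schema_error")
    }
  }
  rows <- tbl |> inner_join(ids, by = c(cid = "source_id"))
  rows <- rows[is_human(rows$target_taxon), , drop = FALSE]
  type_norm <- toupper(trimws(rows$activity_type))
  conc <- grepl(CONCENTRATION_TYPE_PATTERN, type_norm)
  n_nonconc <- sum(!conc)
  rows <- rows[conc, , drop = FALSE]
  unit <- tolower(trimws(rows$activity_unit))
  factor <- unname(MOLAR_UNIT_FACTORS[unit])
  value <- suppressWarnings(as.numeric(rows$activity_value))
  bad <- is.na(factor) | is.na(value)
  n_badunit <- sum(bad)
  rows <- rows[!bad, , drop = FALSE]
  molar <- value[!bad] * factor[!bad]
  keep <- molar <= cutoff_molar
  rows <- rows[keep, , drop = FALSE]
  molar <- molar[keep]
  res <- if (nrow(rows)) {
    new_records(
      sample_id = rows$sample_id, source = "pubchem",
      uniprot_acc = rows$target_accession,
      gene_symbol = if ("target_gene_symbol" %in% names(rows)) rows$target_gene_symbol else NA_character_,
      activity_type = rows$activity_type, activity_value_molar = molar
    )
  } else empty_records()
  with_drops(res, unknown_unit_or_value = n_badunit, non_concentration_type = n_nonconc)
}

#' Parse a ChEMBL-style activity extract
#'
#' Retains human, single-protein rows from binding or functional assays with
#' a pChEMBL value of 5 or above (pChEMBL = -log10 molar IC50/XC50/EC50/AC50/
#' Ki/Kd/Potency, so pChEMBL 5 is the 10 uM cutoff). `action_type` is carried
#' into `action_field`; the underlying standard type token is kept for the
#' mechanism classifier.
#'
#' @param extract_path activity extract with columns `molecule_chembl_id`,
#'   `target_accession`, `target_organism`, `target_type`, `assay_type`,
#'   `standard_type`, `pchembl_value`, `action_type`, optional
#'   `target_gene_symbol`.
#' @param id_map identifier map from [map_identifiers()].
#' @param pchembl_min inclusive minimum pChEMBL (default 5).
#' @return harmonized evidence tibble.
#' @export
parse_chembl <- function(extract_path, id_map, pchembl_min = PCHEMBL_MIN) {
  ids <- sample_ids_for(id_map, "chembl")
  tbl <- read_delimited(extract_path)
  need <- c("molecule_chembl_id", "target_accession", "target_organism",
            "target_type", "assay_type", "standard_type", "pchembl_value")
  for (col in need) {
    if (!col %in% names(tbl)) {
      hd_stop(paste0("chembl activity extract is missing column '", col, "'"),
              "hitdecon_schema_error")
    }
  }
  rows <- tbl |> inner_join(ids, by = c(molecule_chembl_id = "source_id"))
  rows <- rows[is_human(rows$target_organism), , drop = FALSE]
  rows <- rows[toupper(trimws(rows$target_type)) == "SINGLE PROTEIN", , drop = FALSE]
  assay <- toupper(trimws(rows$assay_type))
  rows <- rows[assay %in% c("B", "F", "BINDING", "FUNCTIONAL"), , drop = FALSE]
  pch <- suppressWarnings(as.numeric(rows$pchembl_value))
  n_nopchembl <- sum(is.na(pch))
  rows <- rows[!is.na(pch), , drop = FALSE]
  pch <- pch[!is.na(pch)]
  keep <- pch >= pchembl_min
  rows <- rows[keep, , drop = FALSE]
  pch <- pch[keep]
  res <- if (nrow(rows)) {
    assay_class <- ifelse(toupper(trimws(rows$assay_type)) %in% c("B", "BINDING"),
                          "binding", "functional")
    act <- if ("action_type" %in% names(rows)) blank_to_na(rows$action_type) else NA_character_
    new_records(
      sample_id = rows$sample_id, source = "chembl",
      uniprot_acc = rows$target_accession,
      gene_symbol = if ("target_gene_symbol" %in% names(rows)) rows$target_gene_symbol else NA_character_,
      activity_type = rows$standard_type, activity_value_molar = 10^(-pch),
      pchembl = pch, action_field = act, assay_class = assay_class
    )
  } else empty_records()
  with_drops(res, missing_pchembl = n_nopchembl)
}

#' Turn user-supplied gene symbols into curated evidence records
#'
#' Each compound with a non-blank `Gene Symbol` resolvable in the gene map
#' yields one record with source `user`. An all-blank column yields no records
#' and no error.
#'
#' @param compounds standardized library (needs `sample_id`,
#'   `user_gene_symbol`).
#' @param gene_map path or tibble from [read_gene_map()].
#' @return harmonized evidence tibble.
#' @export
attach_user_annotations <- function(compounds, gene_map) {
  gm <- if (is.character(gene_map)) read_gene_map(gene_map) else as_tibble(gene_map)
  with_symbol <- compounds |>
    filter(!is.na(blank_to_na(.data$user_gene_symbol)))
  joined <- with_symbol |> inner_join(gm, by = c(user_gene_symbol = "gene_symbol"))
  n_dropped <- nrow(with_symbol) - nrow(joined)
  res <- if (nrow(joined)) {
    new_records(sample_id = joined$sample_id, source = "user",
                uniprot_acc = joined$uniprot_acc, gene_symbol = joined$user_gene_symbol)
  } else empty_records()
  with_drops(res, unresolved_gene_symbol = n_dropped)
}

#' Run every annotation adapter over a bundle of source dumps
#'
#' @param compounds standardized library.
#' @param id_map identifier map from [map_identifiers()].
#' @param paths named list with any of `drugbank`, `pharmgkb`, `iuphar`,
#'   `pubchem`, `chembl`, `gene_map`. Missing entries skip that source.
#' @param cutoff_molar,pchembl_min potency filters passed to the bioactivity
#'   adapters.
#' @return harmonized evidence tibble across all sources, with per-source
#'   drop counts merged into attribute `"drop_counts"`.
#' @export
parse_all_sources <- function(compounds, id_map, paths,
                              cutoff_molar = ACTIVITY_CUTOFF_MOLAR,
                              pchembl_min = PCHEMBL_MIN) {
  out <- list(); drops <- integer(0)
  add <- function(rec, src) {
    d <- drop_counts(rec)
    if (length(d)) names(d) <- paste0(src, ".", names(d))
    drops <<- c(drops, d)
    out[[length(out) + 1L]] <<- rec
  }
  if (!is.null(paths$drugbank)) add(parse_drugbank(paths$drugbank, id_map), "drugbank")
  if (!is.null(paths$pharmgkb)) add(parse_pharmgkb(paths$pharmgkb, id_map, paths$gene_map), "pharmgkb")
  if (!is.null(paths$iuphar)) add(parse_iuphar(paths$iuphar, id_map, cutoff_molar), "iuphar")
  if (!is.null(paths$pubchem)) add(parse_pubchem(paths$pubchem, id_map, cutoff_molar), "pubchem")
  if (!is.null(paths$chembl)) add(parse_chembl(paths$chembl, id_map, pchembl_min), "chembl")
  if (!is.null(paths$gene_map)) add(attach_user_annotations(compounds, paths$gene_map), "user")
  res <- if (length(out)) bind_rows(out) else empty_records()
  with_drops(res, drops)
}
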