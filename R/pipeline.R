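# One-shot pipeline driver: standardize -> map -> parse all sources ->
# collate -> target enrichment -> action classification (enriched targets
# only) -> pathway enrichment, with a machine-readable run report and the
# full CSV output bundle. Offline-first: no stage touches the network.

#' Assemble a pipeline run configuration
#'
#' @param library path to the screening-library table (`SMILES`, `Sample ID`,
#'   optional `Gene Symbol`).
#' @param hits path to the hit-list file.
#' @param id_map path to the InChIKey-to-source identifier map.
#' @param gene_map path to the gene-symbol-to-UniProt table.
#' @param drugbank,pharmgkb,iuphar,pubchem,chembl paths to the per-source
#'   dumps; NULL skips a source.
#' @param gmt path to pathway gene sets (GMT); NULL skips the pathway stage.
#' @param out_dir output directory for the CSV bundle.
#' @param activity_cutoff_molar inclusive molar potency cutoff (default 10 uM).
#' @param pchembl_min inclusive minimum pChEMBL (default 5).
#' @param fdr_level,p_level enrichment thresholds (defaults 0.05).
#' @param pathway_universe `"background"` (all targets mapped for the
#'   screening collection, the default) or `"gmt"` (union of gene-set
#'   members).
#' @param pathway_query `"fdr"` (genes of FDR-enriched targets, default) or
#'   `"p"` (genes of raw-p-enriched targets) or `"all"` (all hit-associated
#'   targets).
#' @param offline forbid any network operation (must stay TRUE; the remote
#'   enrichment client is interface-only).
#' @return a `run_config` list.
#' @export
run_config <- function(library, hits, id_map, gene_map,
                       drugbank = NULL, pharmgkb = NULL, iuphar = NULL,
                       pubchem = NULL, chembl = NULL, gmt = NULL,
                       out_dir = NULL,
                       activity_cutoff_molar = 1e-5, pchembl_min = 5,
                       fdr_level = 0.05, p_level = 0.05,
                       pathway_universe = c("background", "gmt"),
                       pathway_query = c("fdr", "p", "all"),
                       offline = TRUE) {
  stopifnot(activity_cutoff_molar > 0, pchembl_min > 0,
            fdr_level > 0, p_level > 0)
  cfg <- list(
    library = library, hits = hits, id_map = id_map, gene_map = gene_map,
    drugbank = drugbank, pharmgkb = pharmgkb, iuphar = iuphar,
    pubchem = pubchem, chembl = chembl, gmt = gmt, out_dir = out_dir,
    activity_cutoff_molar = activity_cutoff_molar, pchembl_min = pchembl_min,
    fdr_level = fdr_level, p_level = p_level,
    pathway_universe = match.arg(pathway_universe),
    pathway_query = match.arg(pathway_query),
    offline = isTRUE(offline)
  )
  structure(cfg, class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  flat <- unclass(config)
  flat$out_dir <- NULL # identical analyses written elsewhere share a hash
  writeLines(paste(names(flat), vapply(flat, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

# every output CSV carries a provenance header comment (config hash + version)
write_output_csv <- function(df, path, hash) {
  header <- c(
    paste0("# hitdecon ", as.character(utils::packageVersion("hitdecon"))),
    paste0("# config_hash ", hash)
  )
  con <- file(path, "wb")
  writeLines(header, con)
  close(con)
  readr::write_csv(df, path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a pipeline output CSV (skipping provenance comments)
#'
#' @param path CSV written by [run_pipeline()].
#' @return tibble.
#' @export
read_output_csv <- function(path) {
  # skip only the leading provenance lines; "#" may occur inside SMILES fields
  head <- readLines(path, n = 10)
  k <- match(FALSE, startsWith(head, "#")) - 1L
  readr::read_csv(path, skip = k, show_col_types = FALSE, progress = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    hd_stop(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            "hitdecon_stage_error")
  })
}

#' Run the full deconvolution pipeline
#'
#' Executes standardize, map, parse (all configured sources), collate,
#' target enrichment, action classification restricted to enriched targets,
#' and pathway enrichment, writing the CSV output bundle to
#' `config$out_dir` and returning all intermediate tables plus a
#' machine-readable run report of per-stage counts.
#'
#' @param config a [run_config()].
#' @return (invisibly printed) list with elements `compounds`, `id_map`,
#'   `records`, `pairs`, `targets_by_source`, `compound_source_counts`,
#'   `unresolved`, `upset_targets`, `upset_compounds`, `enrichment`, `calls`,
#'   `action_matrix`, `pathways`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("library", "hits", "id_map", "gene_map", "drugbank", "pharmgkb",
              "iuphar", "pubchem", "chembl", "gmt")) {
    pth <- config[[f]]
    if (!is.null(pth) && !file.exists(pth)) {
      hd_stop(paste0("pipeline stage '", f, "' input missing: ", pth),
              "hitdecon_stage_error")
    }
  }
  hash <- config_hash(config)
  report <- list(config_hash = hash,
                 package_version = as.character(utils::packageVersion("hitdecon")))

  lib <- stage("load_library", load_library(config$library))
  hit_ids <- stage("load_hits", load_hits(config$hits))
  if (!length(hit_ids)) {
    hd_stop("pipeline stage 'load_hits' failed: hit list is empty", "hitdecon_stage_error")
  }
  compounds <- stage("standardize", standardize_compounds(lib))
  report$compounds_in <- nrow(compounds)
  report$compounds_parse_failed <- sum(!compounds$parse_ok)

  id_map <- stage("map_identifiers", map_identifiers(compounds, config$id_map))
  report$compounds_id_mapped <- length(unique(id_map$sample_id))

  records <- stage("annotate", parse_all_sources(
    compounds, id_map,
    paths = config[c("drugbank", "pharmgkb", "iuphar", "pubchem", "chembl", "gene_map")],
    cutoff_molar = config$activity_cutoff_molar, pchembl_min = config$pchembl_min))
  report$evidence_records <- nrow(records)
  report$evidence_by_source <- as.list(table(records$source))
  report$dropped_records <- as.list(drop_counts(records))

  pairs <- stage("collate", collate_pairs(records))
  report$pairs_after_dedup <- nrow(pairs)
  report$compounds_resolved <- length(unique(pairs$sample_id))
  report$unique_targets <- length(unique(pairs$uniprot_acc))

  tgt_tbl <- stage("collate", summarize_targets(pairs))
  cmp_tbl <- stage("collate", summarize_compounds(pairs, compounds))
  unresolved <- attr(cmp_tbl, "unresolved")
  report$compounds_unresolved <- nrow(unresolved)
  up_t <- upset_counts(pairs |> distinct(.data$uniprot_acc, .keep_all = TRUE) |>
                         select("sources"))
  up_c <- upset_counts(pairs |> group_by(.data$sample_id) |>
                         summarise(sources = paste(sort(unique(unlist(
                           strsplit(.data$sources, "+", fixed = TRUE)))), collapse = "+"),
                           .groups = "drop") |> select("sources"))

  enr <- stage("enrich_targets", enrich_targets(
    pairs, hit_ids, fdr_level = config$fdr_level, p_level = config$p_level,
    library_ids = unique(compounds$sample_id)))
  report$hit_compounds <- length(hit_ids)
  report$hit_compounds_with_pairs <- length(unique(pairs$sample_id[pairs$sample_id %in% hit_ids]))
  report$hit_pairs <- attr(enr, "nhl")
  report$targets_tested <- attr(enr, "m_tested")
  report$enriched_fdr <- sum(enr$enriched_fdr)
  report$enriched_p <- sum(enr$enriched_p)

  enriched_accs <- enr$uniprot_acc[enr$enriched_fdr]
  evidence <- attr(pairs, "evidence")
  calls <- stage("classify_actions",
                 classify_actions(evidence, hit_ids, enriched_accs))
  report$action_calls <- as.list(table(calls$call))
  amat <- stage("classify_actions", build_action_matrix(calls, enriched_accs))

  pathways <- NULL
  if (!is.null(config$gmt)) {
    gene_sets <- stage("pathways", read_gmt(config$gmt))
    acc2gene <- pairs |>
      distinct(.data$uniprot_acc, .keep_all = TRUE) |>
      select("uniprot_acc", "gene_symbol")
    universe <- if (config$pathway_universe == "background") {
      stats::na.omit(unique(acc2gene$gene_symbol))
    } else {
      unique(unlist(gene_sets$members))
    }
    query_accs <- switch(config$pathway_query,
                         fdr = enr$uniprot_acc[enr$enriched_fdr],
                         p = enr$uniprot_acc[enr$enriched_p],
                         all = enr$uniprot_acc)
    query <- stats::na.omit(unique(acc2gene$gene_symbol[acc2gene$uniprot_acc %in% query_accs]))
    pathways <- if (length(query) && length(universe)) {
      stage("pathways", enrich_pathways(query, gene_sets, universe,
                                        fdr_level = config$fdr_level))
    } else NULL
    report$pathway_query_genes <- length(query)
    report$pathways_tested <- if (is.null(pathways)) 0L else sum(!is.na(pathways$p_value))
    report$pathways_enriched_fdr <- if (is.null(pathways)) 0L else sum(pathways$enriched_fdr)
  }

  out <- list(compounds = compounds, id_map = id_map, records = records,
              pairs = pairs, targets_by_source = tgt_tbl,
              compound_source_counts = cmp_tbl, unresolved = unresolved,
              upset_targets = up_t, upset_compounds = up_c,
              enrichment = enr, calls = calls, action_matrix = amat,
              pathways = pathways, report = report)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) write_output_csv(df, file.path(config$out_dir, f), hash)
    w(compounds, "standardized_compounds.csv")
    w(pairs, "pairs.csv")
    w(evidence |> select(-dplyr::any_of("pair_id")), "evidence.csv")
    w(tgt_tbl, "targets_by_source.csv")
    w(cmp_tbl, "compound_source_counts.csv")
    w(unresolved, "unresolved_compounds.csv")
    w(up_t, "upset_counts_targets.csv")
    w(up_c, "upset_counts_compounds.csv")
    w(tidy(enr), "target_enrichment.csv")
    w(calls, "action_calls.csv")
    w(amat, "action_matrix.csv")
    if (!is.null(pathways)) w(tidy(pathways), "pathway_enrichment.csv")
    # timestamps are confined to the run report
    report$written_at <- format(Sys.time(), tz = "UTC")
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$out_dir, "run_report.json"))
    out$report <- report
  }
  out
}
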