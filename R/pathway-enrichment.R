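# Gene-set (pathway) overrepresentation for a target list. The ranking
# statistic is the enrichment strength log10(observed/expected), with the
# exact hypergeometric right-tail p reused from the target-enrichment module
# and BH adjustment across tested (observed >= 1) terms.

#' Read gene sets from a GMT file
#'
#' One set per line: term id, description, then member genes, tab-separated.
#' Duplicate member tokens collapse (set semantics).
#'
#' @param path GMT file path.
#' @return tibble `(term_id, term_name, members)` where `members` is a
#'   list-column of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    hd_stop(paste0("GMT file not found: ", path), "hitdecon_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(term_id = character(), term_name = character(), members = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    hd_stop(paste0("GMT line ", short[1], " has fewer than 3 fields"),
            "hitdecon_schema_error")
  }
  tibble(
    term_id = vapply(fields, `[[`, character(1), 1),
    term_name = vapply(fields, `[[`, character(1), 2),
    members = lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  )
}

#' Enrichment strength: log10 of observed over expected counts
#'
#' The magnitude-of-enrichment metric used to rank pathway results. Undefined
#' (NA) when `observed` is zero; anti-symmetric under swapping observed and
#' expected.
#'
#' @param observed observed member count (vectorized).
#' @param expected expected count under the universe (vectorized, > 0).
#' @return numeric vector.
#' @export
enrichment_strength <- function(observed, expected) {
  ifelse(observed > 0 & expected > 0, log10(observed / expected), NA_real_)
}

#' Gene-set overrepresentation with the enrichment-strength metric
#'
#' For each term: `observed` is the query overlap within the universe,
#' `expected = |members in universe| * |query| / |universe|`, the strength is
#' `log10(observed/expected)` (defined only when observed >= 1), the p-value
#' is the exact hypergeometric right tail (via [fisher_right_tail()] with
#' `nb = |universe|`, `nhl = |query|`, `tic = |members in universe|`,
#' `tihlc = observed`), and q-values are BH across tested terms. Results sort
#' by descending strength.
#'
#' @param query character vector of query genes; genes outside the universe
#'   are dropped with a warning.
#' @param gene_sets tibble from [read_gmt()].
#' @param universe character vector defining the background gene universe
#'   (typically all targets mapped for the screening collection).
#' @param fdr_level FDR threshold for the `enriched_fdr` flag.
#' @return a `pathway_enrichment` tibble: `term_id`, `term_name`, `set_size`,
#'   `observed`, `expected`, `strength`, `p_value`, `q_value`, `enriched_fdr`.
#' @export
enrich_pathways <- function(query, gene_sets, universe, fdr_level = 0.05) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) hd_stop("universe is empty", "hitdecon_value_error")
  if (!length(query)) hd_stop("query gene set is empty", "hitdecon_value_error")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(paste0(length(outside), " query gene(s) outside the universe dropped"))
    query <- intersect(query, universe)
    if (!length(query)) hd_stop("no query gene lies in the universe", "hitdecon_value_error")
  }
  res <- gene_sets |>
    mutate(
      set_size = vapply(.data$members, function(m) length(intersect(m, universe)), integer(1)),
      observed = vapply(.data$members, function(m) length(intersect(intersect(m, universe), query)), integer(1)),
      expected = .data$set_size * length(query) / length(universe),
      strength = enrichment_strength(.data$observed, .data$expected)
    ) |>
    select("term_id", "term_name", "set_size", "observed", "expected", "strength")
  tested <- res$observed >= 1 & res$set_size > 0
  res$p_value <- NA_real_
  res$p_value[tested] <- fisher_right_tail(
    nb = length(universe), nhl = length(query),
    tic = res$set_size[tested], tihlc = res$observed[tested])
  res$q_value <- NA_real_
  res$q_value[tested] <- bh_adjust(res$p_value[tested])
  res$enriched_fdr <- !is.na(res$q_value) & res$q_value <= fdr_level
  res <- res |> arrange(dplyr::desc(.data$strength), .data$term_id)
  structure(res, class = c("pathway_enrichment", class(res)),
            universe_size = length(universe), query_size = length(query),
            fdr_level = fdr_level)
}

#' @export
print.pathway_enrichment <- function(x, ...) {
  cat(sprintf("Pathway overrepresentation: %d terms (%d tested), universe %d genes, query %d genes\n",
              nrow(x), sum(!is.na(x$p_value)), attr(x, "universe_size"), attr(x, "query_size")))
  NextMethod()
}

#' @rdname enrich_pathways
#' @param x,object a `pathway_enrichment` object.
#' @param ... unused.
#' @export
tidy.pathway_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pathway_enrichment")
  as_tibble(out)
}

#' @rdname enrich_pathways
#' @export
glance.pathway_enrichment <- function(x, ...) {
  tibble(universe_size = attr(x, "universe_size"), query_size = attr(x, "query_size"),
         n_terms = nrow(x), n_tested = sum(!is.na(x$p_value)),
         n_enriched_fdr = sum(x$enriched_fdr))
}

#' @rdname enrich_pathways
#' @param top_n number of top-strength terms to draw.
#' @export
autoplot.pathway_enrichment <- function(object, top_n = 15, ...) {
  df <- tidy(object) |>
    filter(!is.na(.data$strength)) |>
    utils::head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strength,
                                   y = stats::reorder(.data$term_name, .data$strength),
                                   fill = -log10(.data$p_value))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "enrichment strength log10(obs/exp)", y = NULL,
                  fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Build (but do not send) a remote functional-enrichment request
#'
#' Interface to a networked functional-enrichment service returning the same
#' result shape as [enrich_pathways()]. This package is offline-first: with
#' `offline = TRUE` (the default and the only tested mode) the function raises
#' a remote-unavailable error rather than silently falling back to local
#' enrichment.
#'
#' @param genes character vector of query gene identifiers.
#' @param species NCBI taxon id (default human, 9606).
#' @param offline must be set to FALSE to permit network use.
#' @return request descriptor list `(url, method, params)` when
#'   `offline = FALSE`; never sends it.
#' @export
remote_enrichment_request <- function(genes, species = 9606, offline = TRUE) {
  genes <- unique(as.character(genes))
  if (!length(genes)) {
    hd_stop("refusing to build a remote enrichment request for an empty gene list",
            "hitdecon_value_error")
  }
  if (isTRUE(offline)) {
    hd_stop("remote enrichment service unavailable in offline mode",
            "hitdecon_remote_unavailable")
  }
  list(
    url = "https://string-db.org/api/json/enrichment",
    method = "POST",
    params = list(identifiers = paste(genes, collapse = "%0d"), species = species)
  )
}

#' Parse a canned remote functional-enrichment response
#'
#' Converts a saved JSON response (array of objects with `term`,
#' `description`, `number_of_genes`, `number_of_genes_in_background`,
#' `p_value`, `fdr`, plus the universe/query sizes implied by the request)
#' into the [enrich_pathways()] result shape.
#'
#' @param json_path path to the saved JSON response.
#' @param universe_size,query_size the background and query sizes of the
#'   original request, needed to reconstruct expected counts.
#' @return a `pathway_enrichment`-shaped tibble.
#' @export
parse_remote_enrichment <- function(json_path, universe_size, query_size) {
  rows <- as_tibble(jsonlite::fromJSON(json_path, simplifyDataFrame = TRUE))
  need <- c("term", "description", "number_of_genes",
            "number_of_genes_in_background", "p_value", "fdr")
  for (col in need) {
    if (!col %in% names(rows)) {
      hd_stop(paste0("remote response is missing field '", col, "'"),
              "hitdecon_schema_error")
    }
  }
  tibble(
    term_id = rows$term, term_name = rows$description,
    set_size = as.integer(rows$number_of_genes_in_background),
    observed = as.integer(rows$number_of_genes),
    expected = as.integer(rows$number_of_genes_in_background) * query_size / universe_size
  ) |>
    mutate(strength = ifelse(.data$observed >= 1,
                             log10(.data$observed / .data$expected), NA_real_),
           p_value = rows$p_value, q_value = rows$fdr,
           enriched_fdr = .data$q_value <= 0.05)
}
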