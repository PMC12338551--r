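# Collation: merge per-source evidence into deduplicated compound-target
# pairs with provenance, plus the summary tables (unique targets by source,
# per-compound source counts + unresolved list, upset intersection counts).

#' Collate evidence records into deduplicated compound-target pairs
#'
#' One pair per distinct `(sample_id, uniprot_acc)`; `sources` is the
#' `+`-joined sorted set of contributing sources and `n_evidence` the number
#' of underlying records. The full evidence tibble is attached as attribute
#' `"evidence"` (with a `pair_id` key) so the action classifier can re-inspect
#' activity fields after enrichment.
#'
#' @param records harmonized evidence tibble (adapter output).
#' @return tibble `(sample_id, uniprot_acc, gene_symbol, sources, n_sources,
#'   n_evidence)`.
#' @export
collate_pairs <- function(records) {
  records <- as_tibble(records)
  if (!nrow(records)) {
    out <- tibble(sample_id = character(), uniprot_acc = character(),
                  gene_symbol = character(), sources = character(),
                  n_sources = integer(), n_evidence = integer())
    attr(out, "evidence") <- records
    return(out)
  }
  records <- records |> mutate(pair_id = paste(.data$sample_id, .data$uniprot_acc, sep = "\r"))
  out <- records |>
    group_by(.data$pair_id, .data$sample_id, .data$uniprot_acc) |>
    summarise(
      gene_symbol = first(stats::na.omit(.data$gene_symbol)) %|NA|% NA_character_,
      sources = paste(sort(unique(.data$source)), collapse = "+"),
      n_sources = length(unique(.data$source)),
      n_evidence = n(),
      .groups = "drop"
    ) |>
    arrange(.data$sample_id, .data$uniprot_acc) |>
    select(-"pair_id")
  attr(out, "evidence") <- records
  out
}

`%|NA|%` <- function(x, y) if (length(x)) x else y

pair_sources_list <- function(pairs) strsplit(pairs$sources, "+", fixed = TRUE)

#' Unique-target table with one boolean column per source
#'
#' @param pairs output of [collate_pairs()].
#' @return tibble with one row per distinct target; a source flag is TRUE iff
#'   any pair for that target carries that source.
#' @export
summarize_targets <- function(pairs) {
  base <- tibble(uniprot_acc = character(), gene_symbol = character())
  for (s in HITDECON_SOURCES) base[[s]] <- logical()
  if (!nrow(pairs)) return(base)
  long <- tibble(
    uniprot_acc = rep(pairs$uniprot_acc, lengths(pair_sources_list(pairs))),
    gene_symbol = rep(pairs$gene_symbol, lengths(pair_sources_list(pairs))),
    source = unlist(pair_sources_list(pairs))
  )
  out <- long |>
    group_by(.data$uniprot_acc) |>
    summarise(gene_symbol = first(stats::na.omit(.data$gene_symbol)) %|NA|% NA_character_,
              .groups = "drop")
  for (s in HITDECON_SOURCES) {
    with_s <- unique(long$uniprot_acc[long$source == s])
    out[[s]] <- out$uniprot_acc %in% with_s
  }
  arrange(out, .data$uniprot_acc)
}

#' Per-compound target counts by source, plus the unresolved list
#'
#' Every library entry lands in exactly one of the two outputs: compounds with
#' at least one collated pair get a row of per-source distinct-target counts;
#' the rest (no pairs, including structure parse failures) form the unresolved
#' list.
#'
#' @param pairs output of [collate_pairs()].
#' @param library library tibble (needs `sample_id`; `parse_ok` used for the
#'   unresolved reason when present).
#' @return tibble of per-compound counts with attribute `"unresolved"`
#'   (tibble `sample_id`, `reason`).
#' @export
summarize_compounds <- function(pairs, library) {
  lib_ids <- unique(as.character(library$sample_id))
  counts <- tibble(sample_id = intersect(lib_ids, unique(pairs$sample_id)))
  if (nrow(pairs)) {
    srcs <- pair_sources_list(pairs)
    long <- tibble(
      sample_id = rep(pairs$sample_id, lengths(srcs)),
      uniprot_acc = rep(pairs$uniprot_acc, lengths(srcs)),
      source = unlist(srcs)
    )
    for (s in HITDECON_SOURCES) {
      per <- long |>
        filter(.data$source == s) |>
        group_by(.data$sample_id) |>
        summarise(nt = length(unique(.data$uniprot_acc)), .groups = "drop")
      counts[[s]] <- per$nt[match(counts$sample_id, per$sample_id)]
      counts[[s]][is.na(counts[[s]])] <- 0L
    }
    tot <- pairs |> count(.data$sample_id, name = "n_targets")
    counts$n_targets <- tot$n_targets[match(counts$sample_id, tot$sample_id)]
  } else {
    for (s in HITDECON_SOURCES) counts[[s]] <- integer(0)
    counts$n_targets <- integer(0)
  }
  unresolved_ids <- setdiff(lib_ids, counts$sample_id)
  reason <- rep("no_target_annotation", length(unresolved_ids))
  if ("parse_ok" %in% names(library)) {
    bad <- unique(as.character(library$sample_id[!library$parse_ok]))
    reason[unresolved_ids %in% bad] <- "structure_invalid"
  }
  attr(counts, "unresolved") <- tibble(sample_id = unresolved_ids, reason = reason)
  arrange(counts, .data$sample_id)
}

#' Exact source-combination counts (upset-plot data)
#'
#' @param source_sets either a pairs/targets tibble with a `sources` column of
#'   `+`-joined combinations, or a list of character vectors.
#' @return tibble `(combination, degree, count)` whose counts sum to the item
#'   count; combinations are sorted source names joined by `+`.
#' @export
upset_counts <- function(source_sets) {
  sets <- if (is.data.frame(source_sets)) {
    pair_sources_list(source_sets)
  } else {
    source_sets
  }
  if (!length(sets)) {
    return(tibble(combination = character(), degree = integer(), count = integer()))
  }
  combo <- vapply(sets, function(s) paste(sort(unique(s)), collapse = "+"), character(1))
  tibble(combination = combo) |>
    count(.data$combination, name = "count") |>
    mutate(degree = lengths(strsplit(.data$combination, "+", fixed = TRUE))) |>
    select("combination", "degree", "count") |>
    arrange(dplyr::desc(.data$count), .data$combination)
}

#' Bar chart of source-combination counts
#'
#' @param counts output of [upset_counts()].
#' @return a ggplot object.
#' @export
plot_upset_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$combination, -.data$count), y = .data$count)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "source combination", y = "items") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
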