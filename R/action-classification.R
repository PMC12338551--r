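# Rule-based mechanism-of-action classification of (hit, enriched target)
# pairs. Per evidence record: the activity parameter gives a preliminary
# direction (Ki/pKi/INH/IC* inhibitor; EC* activator; Kd/Kb/Km/Ka
# inconclusive; curated record without a parameter unknown), which a curated
# action annotation (IUPHAR "Action" / ChEMBL "Action Type") overrides when it
# maps to a direction — Ki-type parameters do not always reflect inhibition.
# Per pair: both directions present -> mixed; one -> that direction; a
# definite direction beats inconclusive/unknown; only inconclusive ->
# inconclusive; only unknown -> unknown.

#' Default curated-action vocabulary
#'
#' Maps normalized action strings (IUPHAR `Action`, ChEMBL `Action Type`) to a
#' direction. Strings not in the table apply no override.
#'
#' @return tibble `(action, direction)`.
#' @export
default_action_vocab <- function() {
  tibble(
    action = c("agonist", "partial agonist", "full agonist", "activator",
               "positive modulator", "positive allosteric modulator", "opener",
               "antagonist", "inhibitor", "inverse agonist", "blocker",
               "negative modulator", "negative allosteric modulator", "channel blocker"),
    direction = c(rep("activator", 7), rep("inhibitor", 7))
  )
}

norm_token <- function(x) toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))

param_direction <- function(activity_type, source) {
  tok <- norm_token(activity_type)
  # a leading P marks the -log10 scale of the same parameter (pKi, pIC50)
  base <- ifelse(grepl("^P(IC|EC|KI$|KD$|KB$|KM$|KA$|XC)", tok), sub("^P", "", tok), tok)
  out <- rep(NA_character_, length(tok))
  out[grepl("^IC[0-9]+$", base) | base %in% c("KI", "INH")] <- "inhibitor"
  out[grepl("^EC[0-9]+$", base)] <- "activator"
  out[base %in% c("KD", "KB", "KM", "KA")] <- "inconclusive"
  no_param <- is.na(activity_type) | !nzchar(trimws(ifelse(is.na(activity_type), "", activity_type)))
  curated <- source %in% CURATED_SOURCES
  out[no_param & curated] <- "unknown"
  # a bioactivity parameter outside the rule table is not directional
  out[is.na(out) & !no_param] <- "inconclusive"
  # bioactivity record with no parameter at all: nothing to interpret
  out[is.na(out)] <- "inconclusive"
  out
}

#' Label each evidence record with a preliminary action
#'
#' @param records harmonized evidence tibble.
#' @param action_vocab override table, see [default_action_vocab()].
#' @return `records` with added columns `prelim_label` (parameter-based),
#'   `label` (after curated-action override) and `override_applied`.
#' @export
label_evidence <- function(records, action_vocab = default_action_vocab()) {
  records <- as_tibble(records)
  prelim <- param_direction(records$activity_type, records$source)
  act <- tolower(trimws(as.character(records$action_field)))
  ov <- action_vocab$direction[match(act, action_vocab$action)]
  applied <- !is.na(ov)
  records$prelim_label <- prelim
  records$label <- ifelse(applied, ov, prelim)
  records$override_applied <- applied
  unknown_tokens <- setdiff(unique(records$activity_type[records$label == "inconclusive"]), NA)
  attr(records, "unrecognized_tokens") <-
    unknown_tokens[!norm_token(unknown_tokens) %in% c("KD", "KB", "KM", "KA")]
  records
}

aggregate_labels <- function(labels) {
  if (!length(labels)) {
    hd_stop("cannot classify a pair with no evidence", "hitdecon_value_error")
  }
  has_inh <- "inhibitor" %in% labels
  has_act <- "activator" %in% labels
  if (has_inh && has_act) return("mixed")
  if (has_inh) return("inhibitor")
  if (has_act) return("activator")
  if ("inconclusive" %in% labels) return("inconclusive")
  "unknown"
}

#' Classify one compound-target pair from its evidence
#'
#' @param evidence evidence records all sharing one `(sample_id,
#'   uniprot_acc)`; may be pre-labelled by [label_evidence()].
#' @param action_vocab override table.
#' @return a one-row tibble `(sample_id, uniprot_acc, call, n_evidence,
#'   n_overrides)` with the per-evidence basis attached as attribute
#'   `"basis"`.
#' @export
classify_pair <- function(evidence, action_vocab = default_action_vocab()) {
  if (!nrow(evidence)) {
    hd_stop("cannot classify a pair with no evidence", "hitdecon_value_error")
  }
  key <- unique(paste(evidence$sample_id, evidence$uniprot_acc))
  if (length(key) != 1) {
    hd_stop("classify_pair expects evidence for exactly one compound-target pair",
            "hitdecon_value_error")
  }
  if (!"label" %in% names(evidence)) {
    evidence <- label_evidence(evidence, action_vocab)
  }
  out <- tibble(
    sample_id = evidence$sample_id[1], uniprot_acc = evidence$uniprot_acc[1],
    call = aggregate_labels(evidence$label),
    n_evidence = nrow(evidence), n_overrides = sum(evidence$override_applied)
  )
  attr(out, "basis") <- evidence |>
    select("source", "activity_type", "action_field",
           "prelim_label", "label", "override_applied")
  out
}

#' Classify every (hit, enriched target) pair
#'
#' @param records harmonized evidence tibble (all sources).
#' @param hit_ids hit Sample IDs.
#' @param enriched_targets UniProt accessions of enriched targets.
#' @param action_vocab override table.
#' @return tibble of action calls, one row per (hit, enriched target) pair
#'   with evidence, sorted by sample id then accession.
#' @export
classify_actions <- function(records, hit_ids, enriched_targets,
                             action_vocab = default_action_vocab()) {
  lab <- label_evidence(records, action_vocab) |>
    filter(.data$sample_id %in% hit_ids, .data$uniprot_acc %in% enriched_targets)
  if (!nrow(lab)) {
    return(tibble(sample_id = character(), uniprot_acc = character(),
                  call = character(), n_evidence = integer(), n_overrides = integer()))
  }
  lab |>
    group_by(.data$sample_id, .data$uniprot_acc) |>
    summarise(call = aggregate_labels(.data$label), n_evidence = n(),
              n_overrides = sum(.data$override_applied), .groups = "drop") |>
    arrange(.data$sample_id, .data$uniprot_acc)
}

#' Hit-by-enriched-target action matrix
#'
#' @param calls output of [classify_actions()].
#' @param enriched_targets accessions defining the columns.
#' @return wide tibble, one row per hit with at least one call; empty cells
#'   are `NA`.
#' @export
build_action_matrix <- function(calls, enriched_targets) {
  cols <- sort(unique(as.character(enriched_targets)))
  if (!nrow(calls)) {
    out <- tibble(sample_id = character())
    for (col in cols) out[[col]] <- character()
    return(out)
  }
  wide <- calls |>
    filter(.data$uniprot_acc %in% cols) |>
    select("sample_id", "uniprot_acc", "call") |>
    tidyr::pivot_wider(names_from = "uniprot_acc", values_from = "call")
  for (col in setdiff(cols, names(wide))) wide[[col]] <- NA_character_
  wide[, c("sample_id", cols)] |> arrange(.data$sample_id)
}

#' Tile plot of the action matrix
#'
#' @param calls output of [classify_actions()].
#' @return a ggplot object.
#' @export
plot_action_matrix <- function(calls) {
  pal <- c(inhibitor = "#d62728", activator = "#2ca02c", mixed = "#9467bd",
           inconclusive = "grey70", unknown = "grey90")
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$uniprot_acc, y = .data$sample_id,
                                      fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = "enriched target", y = "hit compound", fill = "action") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
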