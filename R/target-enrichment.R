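# Per-target overrepresentation among hit compounds versus the screening
# background. For target i, with NB total background compound-target
# associations, Nhl of them from hit compounds, Tic associations for the
# target in the background and Tihlc of those in the hit list, the 2x2 table
#
#              in hit list      not in hit list    total
#   target i   Tihlc            Tic - Tihlc        Tic
#   others     Nhl - Tihlc      NB - Tic - Nhl     NB - Tic
#                               + Tihlc
#   total      Nhl              NB - Nhl           NB
#
# is tested with the exact right-tail (overrepresentation) Fisher test and
# p-values are Benjamini-Hochberg adjusted across tested targets.

#' Build the contingency counts for one target
#'
#' Counts are computed on deduplicated pairs; `nb` and `nhl` are
#' target-independent constants of the run.
#'
#' @param pairs deduplicated pairs tibble (`sample_id`, `uniprot_acc`).
#' @param hit_ids character vector of hit Sample IDs.
#' @param target one UniProt accession.
#' @param library_ids Sample IDs of the full library (defaults to the
#'   compounds seen in `pairs`); every hit must belong to it.
#' @return list `(nb, nhl, tic, tihlc)`.
#' @export
build_contingency <- function(pairs, hit_ids, target,
                              library_ids = unique(pairs$sample_id)) {
  check_hits(hit_ids, library_ids)
  is_hit <- pairs$sample_id %in% hit_ids
  is_t <- pairs$uniprot_acc == target
  tab <- list(nb = nrow(pairs), nhl = sum(is_hit),
              tic = sum(is_t), tihlc = sum(is_t & is_hit))
  validate_contingency(tab)
  tab
}

check_hits <- function(hit_ids, library_ids) {
  if (!length(hit_ids)) {
    hd_stop("hit list is empty; enrichment is undefined", "hitdecon_value_error")
  }
  missing <- setdiff(hit_ids, library_ids)
  if (length(missing)) {
    hd_stop(paste0("hit id(s) not in the screening library: ",
                   paste(utils::head(missing, 5), collapse = ", ")),
            "hitdecon_value_error")
  }
  invisible(TRUE)
}

validate_contingency <- function(tab) {
  with(tab, {
    ok <- is.finite(nb) && is.finite(nhl) && is.finite(tic) && is.finite(tihlc) &&
      tihlc >= 0 && tihlc <= min(tic, nhl) && tic <= nb && nhl <= nb &&
      (nb - tic - nhl + tihlc) >= 0
    if (!ok) {
      hd_stop(sprintf(
        "invalid contingency table (nb=%s, nhl=%s, tic=%s, tihlc=%s)",
        nb, nhl, tic, tihlc), "hitdecon_value_error")
    }
  })
  invisible(TRUE)
}

#' Exact right-tail Fisher probability of a contingency table
#'
#' `P(X >= tihlc)` for X hypergeometric with population `nb`, `tic` successes
#' and `nhl` draws — the exact one-sided overrepresentation p-value. All four
#' arguments are vectorized.
#'
#' @param nb,nhl,tic,tihlc the four table quantities (see
#'   [build_contingency()]); alternatively pass a single list/table as `nb`.
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"` (sum of outcome probabilities no larger than the observed
#'   one, as in `fisher.test`).
#' @return numeric vector of p-values in \[0, 1\].
#' @export
fisher_right_tail <- function(nb, nhl = NULL, tic = NULL, tihlc = NULL,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.list(nb)) {
    tab <- nb; nb <- tab$nb; nhl <- tab$nhl; tic <- tab$tic; tihlc <- tab$tihlc
  }
  n <- max(length(nb), length(nhl), length(tic), length(tihlc))
  nb <- rep_len(nb, n); nhl <- rep_len(nhl, n)
  tic <- rep_len(tic, n); tihlc <- rep_len(tihlc, n)
  bad <- tihlc < 0 | tihlc > pmin(tic, nhl) | tic > nb | nhl > nb |
    (nb - tic - nhl + tihlc) < 0
  if (any(bad)) {
    hd_stop("invalid contingency table passed to fisher_right_tail",
            "hitdecon_value_error")
  }
  if (alternative == "greater") {
    pmin(1, phyper(tihlc - 1, tic, nb - tic, nhl, lower.tail = FALSE))
  } else {
    vapply(seq_len(n), function(i) {
      support <- max(0, nhl[i] + tic[i] - nb[i]):min(tic[i], nhl[i])
      d <- stats::dhyper(support, tic[i], nb[i] - tic[i], nhl[i])
      obs <- stats::dhyper(tihlc[i], tic[i], nb[i] - tic[i], nhl[i])
      min(1, sum(d[d <= obs * (1 + 1e-7)]))
    }, numeric(1))
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: on ascending p, `q(i) = min over j >= i of m*p(j)/j`, capped at
#' 1, mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    hd_stop("p-values must lie in [0, 1]", "hitdecon_value_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Test every hit-associated target for overrepresentation
#'
#' Targets with at least one hit association are tested (`tihlc >= 1`;
#' never-hit targets cannot be overrepresented and would only inflate the BH
#' denominator). Results are sorted by ascending p, ties broken by accession.
#'
#' @param pairs deduplicated pairs tibble (from [collate_pairs()] or any tibble
#'   with `sample_id`, `uniprot_acc`, optionally `gene_symbol`).
#' @param hit_ids character vector of hit Sample IDs (must map to at least one
#'   pair).
#' @param fdr_level FDR threshold for the `enriched_fdr` flag (default 0.05).
#' @param p_level raw-p threshold for the `enriched_p` flag (default 0.05).
#' @param library_ids Sample IDs of the full library (defaults to compounds in
#'   `pairs`).
#' @param alternative sidedness passed to [fisher_right_tail()].
#' @return a `target_enrichment` tibble: `uniprot_acc`, `gene_symbol`,
#'   `tihlc`, `tic`, `nhl`, `nb`, `odds_ratio`, `p_value`, `q_value`,
#'   `enriched_fdr`, `enriched_p`; run constants are in attributes
#'   `nb`, `nhl`, `m_tested`, `fdr_level`, `p_level`.
#' @export
enrich_targets <- function(pairs, hit_ids, fdr_level = 0.05, p_level = 0.05,
                           library_ids = unique(pairs$sample_id),
                           alternative = "greater") {
  check_hits(hit_ids, library_ids)
  is_hit <- pairs$sample_id %in% hit_ids
  nb <- nrow(pairs); nhl <- sum(is_hit)
  if (nhl == 0) {
    hd_stop("no hit compound has a mapped compound-target pair; enrichment is undefined",
            "hitdecon_value_error")
  }
  per_target <- pairs |>
    group_by(.data$uniprot_acc) |>
    summarise(
      gene_symbol = if ("gene_symbol" %in% names(pairs)) {
        first(stats::na.omit(.data$gene_symbol)) %|NA|% NA_character_
      } else NA_character_,
      tic = n(), tihlc = sum(.data$sample_id %in% hit_ids),
      .groups = "drop") |>
    filter(.data$tihlc >= 1)
  res <- per_target |>
    mutate(
      nhl = nhl, nb = nb,
      odds_ratio = (.data$tihlc * (nb - .data$tic - nhl + .data$tihlc)) /
        ((.data$tic - .data$tihlc) * (nhl - .data$tihlc)),
      p_value = fisher_right_tail(nb, nhl, .data$tic, .data$tihlc,
                                  alternative = alternative),
      q_value = bh_adjust(.data$p_value),
      enriched_fdr = .data$q_value <= fdr_level,
      enriched_p = .data$p_value <= p_level
    ) |>
    arrange(.data$p_value, .data$uniprot_acc) |>
    select("uniprot_acc", "gene_symbol", "tihlc", "tic", "nhl", "nb",
           "odds_ratio", "p_value", "q_value", "enriched_fdr", "enriched_p")
  structure(res,
            class = c("target_enrichment", class(res)),
            nb = nb, nhl = nhl, m_tested = nrow(res),
            fdr_level = fdr_level, p_level = p_level, alternative = alternative)
}

#' @export
print.target_enrichment <- function(x, ...) {
  cat(sprintf(
    "Target overrepresentation: %d tested targets (NB=%d background, Nhl=%d hit associations)\n",
    attr(x, "m_tested"), attr(x, "nb"), attr(x, "nhl")))
  cat(sprintf("  enriched at FDR %g: %d; at p %g: %d\n",
              attr(x, "fdr_level"), sum(x$enriched_fdr),
              attr(x, "p_level"), sum(x$enriched_p)))
  NextMethod()
}

#' @rdname enrich_targets
#' @param x a `target_enrichment` object.
#' @param ... unused.
#' @export
tidy.target_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "target_enrichment")
  as_tibble(out)
}

#' @rdname enrich_targets
#' @export
glance.target_enrichment <- function(x, ...) {
  tibble(
    nb = attr(x, "nb"), nhl = attr(x, "nhl"), m_tested = attr(x, "m_tested"),
    fdr_level = attr(x, "fdr_level"), p_level = attr(x, "p_level"),
    n_enriched_fdr = sum(x$enriched_fdr), n_enriched_p = sum(x$enriched_p)
  )
}

#' @rdname enrich_targets
#' @param object a `target_enrichment` object.
#' @param max_or cap for plotting infinite/huge odds ratios.
#' @export
autoplot.target_enrichment <- function(object, max_or = 64, ...) {
  df <- tidy(object) |>
    mutate(or_capped = pmin(pmax(.data$odds_ratio, 1 / max_or), max_or),
           status = ifelse(.data$enriched_fdr, "FDR", ifelse(.data$enriched_p, "p", "ns")))
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$or_capped),
                                   y = -log10(.data$p_value), colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(FDR = "#d62728", p = "#ff9896", ns = "grey60")) +
    ggplot2::labs(x = "log2 odds ratio (capped)", y = "-log10 p",
                  colour = "enriched") +
    ggplot2::theme_minimal()
}
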