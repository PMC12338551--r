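# shared fixtures built in code

toy_dir <- function() system.file("extdata", "toy", package = "hitdecon")

toy_config <- function(out_dir = NULL, gmt = file.path(toy_dir(), "pathways.gmt")) {
  d <- toy_dir()
  run_config(
    library = file.path(d, "library.csv"), hits = file.path(d, "hits.txt"),
    id_map = file.path(d, "id_map.tsv"), gene_map = file.path(d, "gene_map.tsv"),
    drugbank = file.path(d, "drugbank.xml"), pharmgkb = file.path(d, "pharmgkb.tsv"),
    iuphar = file.path(d, "iuphar.json"), pubchem = file.path(d, "pubchem.csv"),
    chembl = file.path(d, "chembl.csv"), gmt = gmt, out_dir = out_dir
  )
}

# minimal evidence record for classifier tests
ev_record <- function(sample_id = "C1", acc = "P1", source = "chembl",
                      activity_type = NA, action_field = NA) {
  tibble::tibble(
    sample_id = sample_id, source = source, uniprot_acc = acc,
    gene_symbol = NA_character_, activity_type = as.character(activity_type),
    activity_value_molar = NA_real_, pchembl = NA_real_,
    action_field = as.character(action_field), assay_class = NA_character_,
    organism = "human"
  )
}

# the six-pair background used throughout the contingency examples
example_pairs <- function() {
  tibble::tibble(
    sample_id = c("c1", "c2", "c3", "c1", "c4", "c5"),
    uniprot_acc = c("A", "A", "A", "B", "B", "C")
  )
}

# id map tibble for adapter tests, bypassing chemistry
mini_id_map <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(sample_id = r[1], source = r[2], source_id = r[3],
                   matched_via = "full")
  }))
}

# brute-force hypergeometric right tail from first principles (binomial
# coefficients only) — the oracle for the exact Fisher test
hyper_tail_oracle <- function(nb, nhl, tic, tihlc) {
  ks <- max(0, tic + nhl - nb):min(tic, nhl)
  ks <- ks[ks >= tihlc]
  if (!length(ks)) return(0)
  sum(exp(lchoose(tic, ks) + lchoose(nb - tic, nhl - ks) - lchoose(nb, nhl)))
}

# independently coded BH step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  run <- Inf
  for (j in m:1) {
    run <- min(run, m * ps[j] / j)
    q[j] <- min(1, run)
  }
  q[order(o)]
}

# aggregation oracle for action calls, coded as the plain rule table
aggregate_oracle <- function(labels) {
  if ("inhibitor" %in% labels && "activator" %in% labels) return("mixed")
  if ("inhibitor" %in% labels) return("inhibitor")
  if ("activator" %in% labels) return("activator")
  if ("inconclusive" %in% labels) return("inconclusive")
  "unknown"
}
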