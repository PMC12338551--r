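# Structure standardization: canonical SMILES, salt stripping, InChIKeys.
# All chemistry goes through OpenBabel (ChemmineOB); conversions are done one
# molecule at a time because OpenBabel aborts a batch at the first bad SMILES.

#' Read a screening-library table
#'
#' The library is a delimited table (CSV or TSV) with exact column headers
#' `SMILES` and `Sample ID`, and an optional `Gene Symbol` column holding a
#' single primary-annotation gene per compound. Rows with a blank SMILES or
#' blank Sample ID are retained and flagged `parse_ok = FALSE`, never dropped,
#' so downstream counts always partition the input.
#'
#' @param path path to a `.csv`, `.tsv` or `.txt` file.
#' @param require_gene_column error if the optional `Gene Symbol` header is
#'   absent.
#' @return a tibble with one row per library entry: `sample_id`, `smiles_raw`,
#'   `user_gene_symbol` (NA when the column is absent or blank) and `parse_ok`.
#' @export
load_library <- function(path, require_gene_column = FALSE) {
  if (!file.exists(path)) {
    hd_stop(paste0("library file not found: ", path), "hitdecon_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xls", "xlsx")) {
    hd_stop(
      "spreadsheet input is not supported; export the library as CSV with columns 'SMILES' and 'Sample ID'",
      "hitdecon_io_error"
    )
  }
  tbl <- read_delimited(path)
  for (col in c("SMILES", "Sample ID")) {
    if (!col %in% names(tbl)) {
      hd_stop(paste0("library table is missing required column '", col, "'"),
              "hitdecon_schema_error")
    }
  }
  if (require_gene_column && !"Gene Symbol" %in% names(tbl)) {
    hd_stop("library table is missing required column 'Gene Symbol'",
            "hitdecon_schema_error")
  }
  gene <- if ("Gene Symbol" %in% names(tbl)) blank_to_na(tbl[["Gene Symbol"]]) else NA_character_
  out <- tibble(
    sample_id = as.character(tbl[["Sample ID"]]),
    smiles_raw = as.character(tbl[["SMILES"]]),
    user_gene_symbol = as.character(gene)
  )
  out$parse_ok <- !is.na(blank_to_na(out$sample_id)) & !is.na(blank_to_na(out$smiles_raw))
  out
}

#' Read a hit list (one Sample ID per line, or a one-column table)
#'
#' @param path path to a text/CSV file of Sample IDs.
#' @return character vector of unique hit Sample IDs.
#' @export
load_hits <- function(path) {
  if (!file.exists(path)) {
    hd_stop(paste0("hit-list file not found: ", path), "hitdecon_io_error")
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x)]
  # tolerate a header line naming the column
  if (length(x) && x[1] %in% c("Sample ID", "sample_id")) x <- x[-1]
  unique(x)
}

read_delimited <- function(path) {
  ext <- tolower(tools::file_ext(path))
  delim <- if (ext %in% c("tsv", "txt")) "\t" else ","
  # no comment character: "#" is meaningful inside SMILES (triple bonds)
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, trim_ws = TRUE)
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  x
}

ob_convert <- function(from, to, value, neutralize = FALSE) {
  out <- tryCatch(
    suppressWarnings(if (neutralize) {
      ChemmineOB::convertFormat(
        from, to, value,
        options = data.frame(names = "neutralize", args = "", stringsAsFactors = FALSE))
    } else {
      ChemmineOB::convertFormat(from, to, value)
    }),
    error = function(e) ""
  )
  out <- sub("\t.*$", "", sub("\n$", "", out))
  trimws(out)
}

#' Canonicalize a single SMILES string
#'
#' Normalizes the structure (implicit hydrogens, aromatic perception) and
#' returns its canonical SMILES. Canonicalization is idempotent; equivalent
#' SMILES of the same structure collapse to one form. Invalidity is signalled
#' through `parse_ok`, never as an error.
#'
#' @param smiles_raw one SMILES string.
#' @param neutralize also neutralize simple protonation states.
#' @return list with `smiles_canonical` (NA if unparseable) and `parse_ok`.
#' @export
standardize_structure <- function(smiles_raw, neutralize = FALSE) {
  if (is.na(smiles_raw) || !nzchar(trimws(smiles_raw))) {
    return(list(smiles_canonical = NA_character_, parse_ok = FALSE))
  }
  can <- ob_convert("SMI", "CAN", smiles_raw, neutralize = neutralize)
  if (!nzchar(can)) {
    return(list(smiles_canonical = NA_character_, parse_ok = FALSE))
  }
  list(smiles_canonical = can, parse_ok = TRUE)
}

# SMILES fragment statistics used by the salt-stripping rule. Heavy atoms are
# all non-hydrogen atoms; carbon presence decides "organic". Two-letter organic
# subset symbols (Cl, Br) are matched before their one-letter prefixes.
fragment_stats <- function(frag) {
  brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1]]
  heavy <- 0L
  carbon <- FALSE
  for (b in brackets) {
    inner <- sub("^\\[", "", sub("\\]$", "", b))
    elem <- regmatches(inner, regexpr("^[0-9]*([A-Z][a-z]?|[a-z]{1,2})", inner))
    elem <- sub("^[0-9]*", "", elem)
    if (!length(elem) || elem %in% c("H", "D", "T")) next
    heavy <- heavy + 1L
    if (elem %in% c("C", "c")) carbon <- TRUE
  }
  bare <- gsub("\\[[^]]*\\]", "", frag)
  toks <- regmatches(bare, gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", bare))[[1]]
  heavy <- heavy + length(toks)
  carbon <- carbon || any(toks %in% c("C", "c"))
  list(heavy = heavy, carbon = carbon)
}

#' Strip salt/solvent fragments, keeping the largest organic parent
#'
#' Multi-fragment structures are split at dots; the retained parent is the
#' fragment with the most heavy atoms among fragments containing at least one
#' carbon, ties broken by canonical-SMILES lexicographic order. Single-fragment
#' input is returned unchanged. When no organic fragment remains (a pure
#' inorganic salt) the parent is NA and `empty_parent = TRUE`.
#'
#' @param smiles_canonical canonical SMILES of a parsed structure.
#' @param neutralize neutralize the selected parent's simple protonation
#'   states (applied after fragment selection).
#' @return list with `smiles_parent` (canonical, NA when empty),
#'   `smiles_parent_preneutral` and `empty_parent`.
#' @export
strip_salt_parent <- function(smiles_canonical, neutralize = TRUE) {
  stopifnot(length(smiles_canonical) == 1L)
  if (is.na(smiles_canonical)) {
    return(list(smiles_parent = NA_character_,
                smiles_parent_preneutral = NA_character_, empty_parent = TRUE))
  }
  frags <- strsplit(smiles_canonical, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) {
    pre <- smiles_canonical
  } else {
    stats <- lapply(frags, fragment_stats)
    organic <- vapply(stats, `[[`, logical(1), "carbon")
    if (!any(organic)) {
      return(list(smiles_parent = NA_character_,
                  smiles_parent_preneutral = NA_character_, empty_parent = TRUE))
    }
    cand <- frags[organic]
    heavy <- vapply(stats[organic], `[[`, integer(1), "heavy")
    best <- cand[heavy == max(heavy)]
    pre <- sort(best)[1]
  }
  post <- ob_convert("SMI", "CAN", pre, neutralize = neutralize)
  if (!nzchar(post)) post <- pre
  list(smiles_parent = post, smiles_parent_preneutral = pre, empty_parent = FALSE)
}

#' Generate full and parent InChIKeys for one standardized structure
#'
#' The full key describes the structure as supplied (salt included); the
#' parent key describes the salt-stripped, neutralized parent. For
#' single-fragment structures the two keys are computed from the same parent
#' and therefore equal.
#'
#' @param smiles_canonical canonical SMILES of the full structure.
#' @param smiles_parent canonical SMILES of the parent (NA when no organic
#'   parent exists; the full key alone is kept).
#' @return list with `inchikey_full` and `inchikey_parent` (NA on failure).
#' @export
make_inchikeys <- function(smiles_canonical, smiles_parent) {
  key_of <- function(s) {
    if (is.na(s)) return(NA_character_)
    k <- ob_convert("SMI", "INCHIKEY", s)
    if (is_inchikey(k)) k else NA_character_
  }
  full <- key_of(smiles_canonical)
  parent <- if (!is.na(smiles_parent) && identical(smiles_parent, smiles_canonical)) {
    full
  } else {
    key_of(smiles_parent)
  }
  if (is.na(parent)) parent <- full
  list(inchikey_full = full, inchikey_parent = parent)
}

#' Test for syntactically valid standard InChIKeys
#'
#' @param x character vector.
#' @return logical vector; TRUE where `x` matches the hyphenated 14-10-1
#'   uppercase pattern (27 characters).
#' @export
is_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' Standardize a whole library
#'
#' Runs [standardize_structure()], [strip_salt_parent()] and
#' [make_inchikeys()] on every record. Record count is conserved: structures
#' that fail to parse keep `parse_ok = FALSE` with absent canonical fields.
#' A log of parent-fragment neutralizations (pre vs post canonical SMILES)
#' is attached as attribute `"neutralization_log"`.
#'
#' @param library a tibble from [load_library()] (columns `sample_id`,
#'   `smiles_raw`, optionally `user_gene_symbol`).
#' @param neutralize neutralize the parent after salt stripping.
#' @return tibble with columns `sample_id`, `smiles_raw`, `smiles_canonical`,
#'   `smiles_parent`, `inchikey_full`, `inchikey_parent`, `user_gene_symbol`,
#'   `parse_ok`.
#' @export
standardize_compounds <- function(library, neutralize = TRUE) {
  stopifnot(is.data.frame(library), all(c("sample_id", "smiles_raw") %in% names(library)))
  n <- nrow(library)
  res <- tibble(
    sample_id = as.character(library$sample_id),
    smiles_raw = as.character(library$smiles_raw),
    smiles_canonical = NA_character_,
    smiles_parent = NA_character_,
    inchikey_full = NA_character_,
    inchikey_parent = NA_character_,
    user_gene_symbol = if ("user_gene_symbol" %in% names(library)) {
      blank_to_na(library$user_gene_symbol)
    } else NA_character_,
    parse_ok = FALSE
  )
  log_pre <- character(0); log_post <- character(0); log_id <- character(0)
  # cache repeated structures: screening libraries repeat compounds across plates
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    raw <- res$smiles_raw[i]
    if (is.na(blank_to_na(raw)) || is.na(blank_to_na(res$sample_id[i]))) next
    hit <- if (!is.na(raw)) get0(raw, envir = cache) else NULL
    if (is.null(hit)) {
      std <- standardize_structure(raw)
      if (!std$parse_ok) {
        hit <- list(ok = FALSE)
      } else {
        par <- strip_salt_parent(std$smiles_canonical, neutralize = neutralize)
        keys <- make_inchikeys(std$smiles_canonical, par$smiles_parent)
        hit <- list(ok = TRUE, can = std$smiles_canonical, parent = par$smiles_parent,
                    pre = par$smiles_parent_preneutral,
                    full = keys$inchikey_full, pkey = keys$inchikey_parent)
      }
      assign(raw, hit, envir = cache)
    }
    if (!isTRUE(hit$ok)) next
    res$smiles_canonical[i] <- hit$can
    res$smiles_parent[i] <- hit$parent
    res$inchikey_full[i] <- hit$full
    res$inchikey_parent[i] <- hit$pkey
    res$parse_ok[i] <- !is.na(hit$full)
    if (!is.na(hit$pre) && !identical(hit$pre, hit$parent)) {
      log_id <- c(log_id, res$sample_id[i])
      log_pre <- c(log_pre, hit$pre); log_post <- c(log_post, hit$parent)
    }
  }
  # parse_ok = FALSE <=> canonical and keys absent
  bad <- !res$parse_ok
  res$smiles_canonical[bad] <- NA_character_
  res$smiles_parent[bad] <- NA_character_
  res$inchikey_full[bad] <- NA_character_
  res$inchikey_parent[bad] <- NA_character_
  attr(res, "neutralization_log") <-
    tibble(sample_id = log_id, smiles_preneutral = log_pre, smiles_postneutral = log_post)
  res
}
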