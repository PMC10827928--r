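#' Normalize a protein identifier pair
#'
#' Harmonizes a (UniProt accession, gene symbol) pair for cross-dataset
#' matching: the accession is trimmed and stripped of any isoform suffix
#' (`"-<digits>"`), the gene symbol is trimmed and upper-cased. Blank or
#' missing inputs become empty strings; a pair where both fields end up
#' empty is invalid.
#'
#' @param uniprot Character vector of raw UniProt accessions (may be blank).
#' @param gene Character vector of raw gene symbols (may be blank).
#' @return A tibble with columns `uniprot` and `gene`, one row per input pair.
#' @examples
#' normalize_key("P12345-2", "mapt")
#' @export
normalize_key <- function(uniprot, gene) {
  n <- max(length(uniprot), length(gene))
  uniprot <- rep_len(as.character(uniprot), n)
  gene <- rep_len(as.character(gene), n)
  uniprot[is.na(uniprot)] <- ""
  gene[is.na(gene)] <- ""
  uniprot <- sub("-[0-9]+$", "", trimws(uniprot))
  gene <- toupper(trimws(gene))
  bad <- uniprot == "" & gene == ""
  if (any(bad)) {
    abort_validation(sprintf(
      "row(s) %s have neither a UniProt accession nor a gene symbol",
      paste(which(bad), collapse = ", ")
    ))
  }
  tibble::tibble(uniprot = uniprot, gene = gene)
}

#' Test whether two protein keys match
#'
#' Two keys match if their accessions are non-empty and identical, or their
#' gene symbols are non-empty and identical. Empty fields never match: a
#' record known only by gene symbol cannot match a record known only by
#' accession. The relation is symmetric and reflexive but deliberately not
#' transitive, so cross-table matching always pairs records directly and
#' never chains through intermediates.
#'
#' @param a,b Single-row key tibbles from [normalize_key()], or lists with
#'   `uniprot` and `gene` elements.
#' @return Logical scalar.
#' @export
keys_match <- function(a, b) {
  (nzchar(a$uniprot) && nzchar(b$uniprot) && a$uniprot == b$uniprot) ||
    (nzchar(a$gene) && nzchar(b$gene) && a$gene == b$gene)
}

# Vectorized matcher: for each row of `a`, the index of its match in `b`
# (NA if none). Accession matches take priority over gene matches; within
# a priority level the first occurrence in `b` wins.
match_key_indices <- function(a, b) {
  # empty fields never match, and NA must not match NA
  ui <- match(ifelse(nzchar(a$uniprot), a$uniprot, NA_character_),
              ifelse(nzchar(b$uniprot), b$uniprot, NA_character_),
              incomparables = NA)
  gi <- match(ifelse(nzchar(a$gene), a$gene, NA_character_),
              ifelse(nzchar(b$gene), b$gene, NA_character_),
              incomparables = NA)
  ifelse(!is.na(ui), ui, gi)
}

read_delim_or_xlsx <- function(path, sheet = NULL) {
  if (!file.exists(path)) abort_param(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort_param("reading .xlsx requires the 'readxl' package")
    }
    if (is.null(sheet)) abort_param("an explicit `sheet` name is required for .xlsx input")
    tibble::as_tibble(readxl::read_excel(path, sheet = sheet))
  } else if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(unlist(cols), names(df))
  if (length(missing)) {
    abort_param(sprintf(
      "column(s) %s not found in %s (available: %s)",
      paste(sQuote(missing), collapse = ", "), path,
      paste(sQuote(names(df)), collapse = ", ")
    ))
  }
}

#' Read and validate a differential-protein table
#'
#' Reads a delimited file (TSV/CSV) or an XLSX sheet, maps its columns to the
#' canonical schema, normalizes identifiers, drops rows lacking both
#' identifiers, and collapses duplicate keys keeping the most significant
#' record (smallest significance value, ties broken by largest |log2fc|,
#' then first occurrence). Direction is taken from the mapped direction
#' column if present, otherwise from the sign of log2fc.
#'
#' @param path Input file. XLSX requires an explicit `sheet`.
#' @param column_map Named list mapping canonical names (`uniprot`, `gene`,
#'   and at least one of `log2fc`/`direction`; optionally `significance`)
#'   to column names in the file.
#' @param label Dataset label stored with the table.
#' @param sheet Sheet name for XLSX input.
#' @return A tibble with columns `uniprot`, `gene`, `log2fc`, `direction`
#'   (`"up"`/`"down"`), `significant`, carrying attributes `label`,
#'   `provenance` and `load_report` (rows read / dropped / duplicates
#'   collapsed).
#' @export
read_diff_table <- function(path, column_map, label, sheet = NULL) {
  raw <- read_delim_or_xlsx(path, sheet)
  require_columns(raw, column_map[intersect(names(column_map),
                                            c("uniprot", "gene", "log2fc",
                                              "direction", "significance"))],
                  path)
  if (is.null(column_map$log2fc) && is.null(column_map$direction)) {
    abort_param("column_map must name at least one of 'log2fc' or 'direction'")
  }
  get_col <- function(nm) if (is.null(column_map[[nm]])) NULL else raw[[column_map[[nm]]]]

  up_raw <- as.character(if (is.null(get_col("uniprot"))) "" else get_col("uniprot"))
  gn_raw <- as.character(if (is.null(get_col("gene"))) "" else get_col("gene"))
  up_raw[is.na(up_raw)] <- ""
  gn_raw[is.na(gn_raw)] <- ""
  keep <- trimws(up_raw) != "" | trimws(gn_raw) != ""
  n_dropped <- sum(!keep)

  keys <- normalize_key(up_raw[keep], gn_raw[keep])
  lfc <- get_col("log2fc")
  if (!is.null(lfc)) {
    lfc <- suppressWarnings(as.numeric(lfc))
    bad <- which(!is.na(get_col("log2fc")) & is.na(lfc) &
                   trimws(as.character(get_col("log2fc"))) != "")
    if (length(bad)) {
      abort_validation(sprintf("unparseable log2fc at row(s) %s of %s",
                               paste(utils::head(bad, 5), collapse = ", "), path))
    }
    lfc <- lfc[keep]
  } else {
    lfc <- rep(NA_real_, sum(keep))
  }
  dir_col <- get_col("direction")
  if (!is.null(dir_col)) {
    direction <- tolower(trimws(as.character(dir_col)))[keep]
    direction[direction %in% c("increased", "increase", "+1", "1", "pos", "positive")] <- "up"
    direction[direction %in% c("decreased", "decrease", "-1", "neg", "negative")] <- "down"
    bad <- !direction %in% c("up", "down")
    if (any(bad)) {
      abort_validation(sprintf("unrecognized direction value(s): %s",
                               paste(unique(direction[bad]), collapse = ", ")))
    }
  } else {
    direction <- ifelse(lfc >= 0, "up", "down")
  }
  sig <- get_col("significance")
  sig <- if (is.null(sig)) rep(NA_real_, sum(keep)) else suppressWarnings(as.numeric(sig))[keep]

  tbl <- tibble::tibble(
    uniprot = keys$uniprot, gene = keys$gene,
    log2fc = lfc, direction = direction,
    significance = sig, significant = TRUE
  )
  # deduplicate keeping the strongest evidence, then restore file order
  orig <- seq_len(nrow(tbl))
  ord <- order(ifelse(is.na(tbl$significance), Inf, tbl$significance),
               -abs(ifelse(is.na(tbl$log2fc), 0, tbl$log2fc)),
               orig)
  tbl <- tbl[ord, ]
  dup_key <- paste(tbl$uniprot, tbl$gene, sep = "\r")
  dup <- duplicated(dup_key)
  n_dup <- sum(dup)
  tbl <- tbl[!dup, ]
  tbl <- tbl[order(orig[ord][!dup]), ]

  report <- list(rows_read = nrow(raw), rows_dropped = n_dropped,
                 duplicates_collapsed = n_dup)
  message(sprintf("[%s] %d rows read, %d dropped (no identifier), %d duplicate(s) collapsed",
                  label, report$rows_read, report$rows_dropped, report$duplicates_collapsed))
  attr(tbl, "label") <- label
  attr(tbl, "provenance") <- paste0(path, if (!is.null(sheet)) paste0("#", sheet))
  attr(tbl, "load_report") <- report
  tbl
}

#' Write a differential table in the canonical TSV layout
#'
#' @param tbl A table from [read_diff_table()] or [gen_disease_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(tbl, path) {
  out <- tbl[, c("uniprot", "gene", "log2fc", "direction", "significant")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a curated reference protein set
#'
#' Loads a protein list (e.g. lesion-enriched proteins, tau interactors,
#' causative genes), normalizes identifiers and deduplicates.
#'
#' @inheritParams read_diff_table
#' @param name Set name used in annotation columns and summaries.
#' @return A tibble with columns `uniprot`, `gene`, attribute `name`.
#' @export
read_reference_set <- function(path, column_map, name, sheet = NULL) {
  raw <- read_delim_or_xlsx(path, sheet)
  if (nrow(raw) == 0) abort_param(sprintf("empty reference set: %s", path))
  require_columns(raw, column_map[intersect(names(column_map), c("uniprot", "gene"))], path)
  up <- if (is.null(column_map$uniprot)) "" else as.character(raw[[column_map$uniprot]])
  gn <- if (is.null(column_map$gene)) "" else as.character(raw[[column_map$gene]])
  up[is.na(up)] <- ""; gn[is.na(gn)] <- ""
  keep <- trimws(up) != "" | trimws(gn) != ""
  keys <- normalize_key(up[keep], gn[keep])
  keys <- keys[!duplicated(paste(keys$uniprot, keys$gene, sep = "\r")), ]
  if (nrow(keys) == 0) abort_param(sprintf("empty reference set: %s", path))
  attr(keys, "name") <- name
  keys
}
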