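# Multi-source drug-status tables -> standardized, label-harmonized
# databases. A drug is labelled withdrawn (1) if ANY source claims a
# withdrawal for its structure; structure identity is the canonical SMILES
# key. Standardization removes structureless records, collapses duplicates,
# drops single-element substances and over-long SMILES.

#' Read a drug-status table from one source
#'
#' Accepts comma- or tab-delimited text with a header naming at least the
#' `id`, `smiles` and `status` columns (a `name` column is optional), or a
#' `.smi` file (SMILES, whitespace, id) for structure-only lists, in which
#' case every record receives status `"unknown"` which the status map must
#' handle.
#'
#' @param path file path.
#' @param source_name name of the source database the file belongs to.
#' @param status_map named character vector mapping each raw status value to
#'   one of `"withdrawn"`, `"approved"`, `"ignore"`.
#' @return data.frame of drug records: `drug_id`, `name`, `smiles`, `status`
#'   (raw), `mapped_status`, `source`, `structure_less` (flag for empty
#'   SMILES cells). Rows whose mapped status is `"ignore"` are dropped; row
#'   order is preserved.
#' @export
parse_drug_table <- function(path, source_name, status_map) {
  if (!file.exists(path)) {
    stop(sprintf("source file not found: '%s'", path))
  }
  stopifnot(is.character(status_map), !is.null(names(status_map)))
  bad_target <- setdiff(unique(status_map), c("withdrawn", "approved", "ignore"))
  if (length(bad_target)) {
    stop(sprintf("status_map targets must be withdrawn/approved/ignore; got: %s",
                 paste(bad_target, collapse = ", ")))
  }
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    df <- data.frame(
      id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
      name = NA_character_,
      smiles = vapply(parts, `[[`, "", 1),
      status = "unknown",
      stringsAsFactors = FALSE
    )
  } else {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            stringsAsFactors = FALSE, comment.char = "",
                            colClasses = "character")
  }
  names(df) <- tolower(names(df))
  for (col in c("id", "smiles", "status")) {
    if (!col %in% names(df)) {
      stop(sprintf("source '%s' (%s): missing required column '%s'",
                   source_name, path, col))
    }
  }
  if (!"name" %in% names(df)) df$name <- NA_character_

  unmapped <- setdiff(unique(df$status), names(status_map))
  if (length(unmapped)) {
    stop(sprintf("source '%s': status value(s) not in status_map: %s",
                 source_name, paste(sQuote(unmapped), collapse = ", ")))
  }
  mapped <- unname(status_map[df$status])
  keep <- mapped != "ignore"
  data.frame(
    drug_id = df$id[keep],
    name = df$name[keep],
    smiles = trimws(df$smiles[keep]),
    status = df$status[keep],
    mapped_status = mapped[keep],
    source = source_name,
    structure_less = !nzchar(trimws(df$smiles[keep])),
    stringsAsFactors = FALSE
  )
}

#' Harmonize the records sharing one structure key into a labeled drug
#'
#' The withdrawal label follows the any-source rule: one withdrawal claim by
#' any source (or by any record within a source, e.g. two salt forms) makes
#' the drug withdrawn.
#'
#' @param records data.frame of drug records (as from [parse_drug_table()])
#'   that all share one canonical key.
#' @return one-row data.frame: `key`, `smiles` (canonical), `label` (1 =
#'   withdrawn), `sources` (semicolon-joined source names).
#' @export
assign_label <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("assign_label: empty record group")
  }
  keys <- canonical_key(records$smiles)
  if (length(unique(keys)) != 1L) {
    stop("assign_label: records do not share one canonical key")
  }
  data.frame(
    key = keys[1],
    smiles = keys[1],
    label = as.integer(any(records$mapped_status == "withdrawn")),
    sources = paste(sort(unique(records$source)), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

.new_drug_database <- function(name, drugs) {
  drugs <- drugs[order(drugs$key), , drop = FALSE]
  rownames(drugs) <- NULL
  structure(list(name = name, drugs = drugs), class = "withdrawr_database")
}

#' @export
print.withdrawr_database <- function(x, ...) {
  cat(sprintf("<withdrawr_database> '%s': %d drugs (%d withdrawn)\n",
              x$name, nrow(x$drugs), sum(x$drugs$label)))
  invisible(x)
}

#' Standardize the records of one source into a drug database
#'
#' Filters, in order: structureless/unparseable records removed; duplicate
#' records collapsed by canonical key (labels merged under the any-withdrawn
#' rule); single-element substances (e.g. `[Fe]`, `OO`) removed; raw SMILES
#' longer than `max_len` characters removed. The exclusion report accounts
#' for every input record: `duplicate + no_structure + single_element +
#' over_length + retained = input`.
#'
#' @param records data.frame of drug records from [parse_drug_table()].
#' @param source_name database name; defaults to the records' single source.
#' @param max_len maximum raw SMILES length kept (inclusive), default 300.
#' @return list with `database` (a `withdrawr_database`) and `report`
#'   (exclusion counts).
#' @export
standardize_database <- function(records, source_name = NULL, max_len = 300L) {
  stopifnot(max_len > 0L)
  if (is.null(source_name)) {
    source_name <- if (nrow(records)) records$source[1] else "unnamed"
  }
  n_input <- nrow(records)
  report <- list(input = n_input, duplicate = 0L, no_structure = 0L,
                 single_element = 0L, over_length = 0L, retained = 0L)

  if (n_input == 0L) {
    db <- .new_drug_database(source_name, data.frame(
      key = character(0), smiles = character(0), label = integer(0),
      sources = character(0), stringsAsFactors = FALSE))
    return(list(database = db, report = report))
  }

  # structure-required: empty cells and unparseable SMILES
  parseable <- !records$structure_less
  keys <- rep(NA_character_, n_input)
  for (i in which(parseable)) {
    keys[i] <- tryCatch(canonical_key(records$smiles[i]),
                        error = function(e) NA_character_)
  }
  has_structure <- !is.na(keys)
  report$no_structure <- sum(!has_structure)

  rec <- records[has_structure, , drop = FALSE]
  key <- keys[has_structure]

  # duplicate collapse by canonical key (first-seen record is representative)
  groups <- split(seq_len(nrow(rec)), key)
  report$duplicate <- nrow(rec) - length(groups)

  keep_key <- character(0); keep_label <- integer(0)
  keep_sources <- character(0)
  for (k in sort(names(groups))) {
    idx <- groups[[k]]
    raw_smiles <- rec$smiles[idx[1]] # first-seen raw writing anchors filters
    if (length(smiles_elements(raw_smiles)) < 2L) {
      report$single_element <- report$single_element + 1L
      next
    }
    if (nchar(raw_smiles) > max_len) {
      report$over_length <- report$over_length + 1L
      next
    }
    keep_key <- c(keep_key, k)
    keep_label <- c(keep_label,
                    as.integer(any(rec$mapped_status[idx] == "withdrawn")))
    keep_sources <- c(keep_sources,
                      paste(sort(unique(rec$source[idx])), collapse = ";"))
  }
  report$retained <- length(keep_key)
  if (report$retained == 0L) {
    warning(sprintf("standardize_database('%s'): all %d records excluded",
                    source_name, n_input))
  }
  db <- .new_drug_database(source_name, data.frame(
    key = keep_key, smiles = keep_key, label = keep_label,
    sources = keep_sources, stringsAsFactors = FALSE))
  list(database = db, report = report)
}

#' Write / read a standardized database as CSV
#'
#' Columns: `key`, `smiles`, `label`, `sources` (semicolon-joined).
#'
#' @param db a `withdrawr_database`.
#' @param path output CSV path.
#' @return `path`, invisibly (`write_database`); a `withdrawr_database`
#'   (`read_database`).
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "withdrawr_database"))
  utils::write.csv(db$drugs, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_database
#' @param name database name to attach on read (default: file stem).
#' @export
read_database <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  drugs <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(key = "character",
                                          smiles = "character",
                                          label = "integer",
                                          sources = "character"))
  .new_drug_database(name, drugs)
}

#' Serialize an exclusion report to JSON
#'
#' @param report exclusion report from [standardize_database()].
#' @param path output path for the JSON file.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
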