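#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that first
#' validates the file so that malformed input is reported with a line
#' number, and that truncates headers at the first whitespace to obtain
#' record ids.  Record order is preserved; sequence lines belonging to
#' one record (including runs interrupted by blank lines) are
#' concatenated.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id` and `sequence`, one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_content)) stop("FASTA parse error: file is empty: ", path)
  if (!startsWith(trimws(lines[first_content]), ">")) {
    stop(sprintf("FASTA parse error at line %d: expected a '>' header",
                 first_content))
  }
  # Biostrings tolerates blank lines inside records but we keep the scan
  # above so that files that start mid-record fail with a line number.
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids, sequence = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids character vector of record ids.
#' @param sequences character vector of sequences, same length as `ids`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  set <- Biostrings::AAStringSet(setNames(sequences, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Default column mapping for QSbio-style annotation tables
#'
#' Maps the internal field names to the column names used by QSbio
#' exports.  Override individual entries to read tables with different
#' headers.
#'
#' @param id,sequence,nsub,corrected_nsub,best_bu,err_prob,is_homomer,family_id
#'   column names in the file for each field.  `family_id` and
#'   `is_homomer` are optional in the file; when `is_homomer` is absent
#'   every row is assumed homomeric.
#' @return named character vector suitable for the `schema` argument of
#'   [read_label_table()].
#' @export
qsbio_schema <- function(id = "code", sequence = "sequence", nsub = "nsub",
                         corrected_nsub = "corrected_nsub",
                         best_bu = "Best_BU", err_prob = "QSBIO_err_prob",
                         is_homomer = "homomer", family_id = "f_id") {
  c(id = id, sequence = sequence, nsub = nsub,
    corrected_nsub = corrected_nsub, best_bu = best_bu,
    err_prob = err_prob, is_homomer = is_homomer, family_id = family_id)
}

#' Read a QSbio-style annotation table
#'
#' Reads a delimited text file (CSV or TSV, auto-detected) with one row
#' per annotated protein and returns the standardized entry table used
#' by [filter_qsbio()] and [deduplicate()].  Required fields are `id`,
#' `sequence`, `nsub`, `corrected_nsub`, `best_bu` and `err_prob`;
#' `is_homomer` and `family_id` are optional (a missing `is_homomer`
#' column marks all rows as homomers, matching tables that were exported
#' for homomers only).
#'
#' @param path path to the delimited file; must have a header row.
#' @param schema named character vector mapping internal field names to
#'   file column names, see [qsbio_schema()].
#' @return a `data.frame` with columns `id`, `sequence`, `nsub`,
#'   `corrected_nsub`, `best_bu`, `err_prob`, `is_homomer`, `family_id`.
#' @export
read_label_table <- function(path, schema = qsbio_schema()) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  required <- c("id", "sequence", "nsub", "corrected_nsub", "best_bu",
                "err_prob")
  missing_cols <- setdiff(schema[required], names(tab))
  if (length(missing_cols) > 0) {
    stop("label table schema error; missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    id = as.character(tab[[schema[["id"]]]]),
    sequence = as.character(tab[[schema[["sequence"]]]]),
    nsub = as.integer(tab[[schema[["nsub"]]]]),
    corrected_nsub = as.integer(tab[[schema[["corrected_nsub"]]]]),
    best_bu = as.integer(tab[[schema[["best_bu"]]]]),
    err_prob = as.numeric(tab[[schema[["err_prob"]]]]),
    stringsAsFactors = FALSE
  )
  out$is_homomer <- if (schema[["is_homomer"]] %in% names(tab)) {
    as.logical(tab[[schema[["is_homomer"]]]])
  } else TRUE
  out$family_id <- if (schema[["family_id"]] %in% names(tab)) {
    as.character(tab[[schema[["family_id"]]]])
  } else NA_character_
  if (any(out$nsub < 1, na.rm = TRUE)) stop("nsub must be >= 1")
  if (any(out$err_prob < 0, na.rm = TRUE)) stop("err_prob must be >= 0")
  out
}

#' Filter annotation entries to high-confidence homomers
#'
#' Retains entries that are homomeric, whose annotation survived
#' internal validation (`corrected_nsub == nsub`), whose biological unit
#' is the top-ranked one (`best_bu == 1`), and whose error probability
#' is strictly below `max_err`.
#'
#' @param entries entry table as returned by [read_label_table()].
#' @param max_err strict upper bound on the annotation error
#'   probability; the default 15 keeps `err_prob < 15`.
#' @return the retained subset of `entries` (possibly empty).
#' @export
filter_qsbio <- function(entries, max_err = 15) {
  stopifnot(is.data.frame(entries))
  keep <- entries$is_homomer &
    entries$corrected_nsub == entries$nsub &
    entries$best_bu == 1 &
    entries$err_prob < max_err
  keep[is.na(keep)] <- FALSE
  entries[keep, , drop = FALSE]
}

#' Collapse duplicate sequences, keeping the most confident annotation
#'
#' Among entries sharing an identical sequence string, the entry with
#' the lowest `err_prob` is kept (ties broken by input order).  The
#' result is a labeled dataset whose qs label is the annotated number of
#' subunits.  Non-standard residues are mapped to `X` via
#' [clean_sequences()].
#'
#' @param entries filtered entry table, see [filter_qsbio()].
#' @return a `qs_dataset`: list with `records` (data.frame `id`,
#'   `sequence`, `qs_label`, `family_id`, `cluster_id`) and `label_set`
#'   (sorted distinct qs labels).
#' @export
deduplicate <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) > 0)
  entries$sequence <- clean_sequences(entries$sequence)
  ord <- order(entries$err_prob)        # stable: ties keep input order
  ordered <- entries[ord, , drop = FALSE]
  first <- !duplicated(ordered$sequence)
  kept <- ordered[first, , drop = FALSE]
  kept <- kept[order(match(kept$id, entries$id)), , drop = FALSE]  # input order
  records <- data.frame(
    id = kept$id,
    sequence = kept$sequence,
    qs_label = as.integer(kept$nsub),
    family_id = if ("family_id" %in% names(kept)) kept$family_id else NA_character_,
    cluster_id = NA_character_,
    stringsAsFactors = FALSE
  )
  qs_dataset(records)
}

#' Construct a labeled quaternary-state dataset
#'
#' @param records data.frame with columns `id`, `sequence`, `qs_label`
#'   and optionally `family_id`, `cluster_id`.
#' @return an object of class `qs_dataset`.
#' @export
qs_dataset <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence", "qs_label") %in% names(records)))
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  if (anyDuplicated(records$sequence)) stop("duplicate sequences; run deduplicate() first")
  if (any(!nzchar(records$sequence))) stop("empty sequence in records")
  if (any(records$qs_label < 1)) stop("qs labels must be positive integers")
  if (!"family_id" %in% names(records)) records$family_id <- NA_character_
  if (!"cluster_id" %in% names(records)) records$cluster_id <- NA_character_
  records$qs_label <- as.integer(records$qs_label)
  structure(list(records = records,
                 label_set = sort(unique(records$qs_label))),
            class = "qs_dataset")
}

#' @export
print.qs_dataset <- function(x, ...) {
  cat(sprintf("qs_dataset: %d records, %d qs labels (%s)\n",
              nrow(x$records), length(x$label_set),
              paste(x$label_set, collapse = ",")))
  invisible(x)
}

#' Write a labeled dataset as a TSV truth table
#'
#' @param dataset a `qs_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "qs_dataset"))
  data.table::fwrite(dataset$records, path, sep = "\t")
  invisible(path)
}
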