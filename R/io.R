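#' Read a reader-annotation table
#'
#' Annotation tables are delimited text with a header row and one row per
#' (reader, case, session) label entry. CSV or TSV is autodetected from the
#' file extension. Column names can be remapped through `schema` when the
#' table comes from another system.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param schema Named character vector mapping the canonical column names
#'   (`reader_id`, `case_id`, `session`, `label`, `entry_time_s`) to the names
#'   used in the file. Defaults to the identity mapping.
#' @return A data frame of annotations with the canonical columns:
#'   `reader_id` and `case_id` (character), `session`
#'   (`"unaugmented"`/`"augmented"`), `label` (integer 0/1) and `entry_time_s`
#'   (seconds since session start; `NA` allowed when timing was not logged).
#' @details Duplicate (reader, case, session) keys, labels outside \{0, 1\}
#'   and unknown session levels are errors, never silently coerced: the study
#'   design guarantees exactly one label per reader-case-session.
#' @export
read_annotations <- function(path, schema = NULL) {
  tab <- read_delimited(path)
  required <- c("reader_id", "case_id", "session", "label", "entry_time_s")
  if (!is.null(schema)) {
    if (is.null(names(schema)) || !all(names(schema) %in% required)) {
      stop("`schema` must be named by canonical columns: ",
           paste(required, collapse = ", "), call. = FALSE)
    }
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(tab)) {
        stop("schema error: column '", schema[[canon]],
             "' (mapped to '", canon, "') not found in ", path, call. = FALSE)
      }
      names(tab)[names(tab) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ",
         paste(sQuote(missing_cols), collapse = ", "), " in ", path,
         call. = FALSE)
  }
  ann <- data.frame(
    reader_id = as.character(tab$reader_id),
    case_id = as.character(tab$case_id),
    session = as.character(tab$session),
    label = tab$label,
    entry_time_s = as.numeric(tab$entry_time_s),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
}

# Shared row-level validation for annotation tables, whether read from disk
# or built in memory.
validate_annotations <- function(ann) {
  bad_session <- !ann$session %in% SESSIONS
  if (any(bad_session)) {
    stop("value error: unknown session ",
         paste(sQuote(unique(ann$session[bad_session])), collapse = ", "),
         " at row(s) ", paste(utils::head(which(bad_session), 5), collapse = ", "),
         call. = FALSE)
  }
  lab <- suppressWarnings(as.numeric(ann$label))
  bad_label <- is.na(lab) | !lab %in% c(0, 1)
  if (any(bad_label)) {
    stop("value error: non-binary label at row(s) ",
         paste(utils::head(which(bad_label), 5), collapse = ", "),
         " (labels must be 0 or 1)", call. = FALSE)
  }
  ann$label <- as.integer(lab)
  key <- paste(ann$reader_id, ann$case_id, ann$session, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    shown <- utils::head(unique(key[dup]), 5)
    stop("integrity error: duplicated (reader_id, case_id, session) key(s): ",
         paste(gsub("\r", " / ", shown), collapse = "; "), call. = FALSE)
  }
  if (any(!is.na(ann$entry_time_s) & ann$entry_time_s < 0)) {
    stop("value error: negative entry_time_s", call. = FALSE)
  }
  ann
}

#' Write an annotation table
#'
#' @param annotations Data frame as returned by [read_annotations()] or
#'   [simulate_annotations()].
#' @param path Output `.csv` or `.tsv` path; format follows the extension.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  write_delimited(annotations, path)
}

#' Read or write a case truth table
#'
#' The truth table has one row per case: `case_id`, `truth` (0/1),
#' `n_lesions`, and for simulated positive cases `max_diameter_mm` (largest
#' lesion diameter; clinical significance requires > 3 mm).
#'
#' @param path CSV (or TSV) path.
#' @return `read_truth()`: a validated data frame of case records.
#' @export
read_truth <- function(path) {
  tab <- read_delimited(path)
  required <- c("case_id", "truth")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ",
         paste(sQuote(missing_cols), collapse = ", "), " in ", path,
         call. = FALSE)
  }
  cases <- data.frame(
    case_id = as.character(tab$case_id),
    truth = as.integer(tab$truth),
    n_lesions = if ("n_lesions" %in% names(tab)) as.integer(tab$n_lesions)
                else NA_integer_,
    max_diameter_mm = if ("max_diameter_mm" %in% names(tab))
                        as.numeric(tab$max_diameter_mm) else NA_real_,
    stringsAsFactors = FALSE
  )
  validate_truth(cases)
}

validate_truth <- function(cases) {
  if (nrow(cases) == 0) stop("empty case list", call. = FALSE)
  if (anyDuplicated(cases$case_id)) {
    stop("integrity error: duplicated case_id in truth table", call. = FALSE)
  }
  if (!all(cases$truth %in% c(0L, 1L))) {
    stop("value error: `truth` must be 0 or 1", call. = FALSE)
  }
  known_lesions <- !is.na(cases$n_lesions)
  if (any(known_lesions & (cases$truth == 1L) != (cases$n_lesions >= 1L))) {
    stop("integrity error: truth = 1 iff n_lesions >= 1 violated", call. = FALSE)
  }
  known_diam <- !is.na(cases$max_diameter_mm)
  if (any(known_diam & cases$truth == 1L & cases$max_diameter_mm <= 3.0)) {
    stop("integrity error: positive cases must have max_diameter_mm > 3",
         call. = FALSE)
  }
  cases
}

#' @rdname read_truth
#' @param cases Case-record data frame.
#' @export
write_truth <- function(cases, path) {
  validate_truth(cases)
  write_delimited(cases, path)
}

#' Assemble the cases-by-readers label matrix for one session
#'
#' The agreement statistics operate on a complete binary matrix with one row
#' per case (in truth-table order) and one column per reader (in roster
#' order). Completeness is enforced: a missing (reader, case) pair for the
#' session is an error, never imputed.
#'
#' @param annotations Annotation data frame (both sessions may be present).
#' @param session `"unaugmented"` or `"augmented"`.
#' @param roster Reader roster data frame (column `reader_id`); column order
#'   of the result follows it.
#' @param cases Case-record data frame (column `case_id`); row order of the
#'   result follows it.
#' @return An integer matrix `length(cases) x length(readers)` of 0/1 labels
#'   with case ids as row names and reader ids as column names.
#' @export
build_matrix <- function(annotations, session, roster, cases) {
  check_session(session)
  annotations <- validate_annotations(annotations)
  ann <- annotations[annotations$session == session, , drop = FALSE]
  readers <- roster$reader_id
  case_ids <- cases$case_id
  mat <- matrix(NA_integer_, nrow = length(case_ids), ncol = length(readers),
                dimnames = list(case_ids, readers))
  idx_case <- match(ann$case_id, case_ids)
  idx_reader <- match(ann$reader_id, readers)
  keep <- !is.na(idx_case) & !is.na(idx_reader)
  mat[cbind(idx_case[keep], idx_reader[keep])] <- ann$label[keep]
  if (anyNA(mat)) {
    miss <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("completeness error: no ", session, " annotation for reader '",
         readers[miss[["col"]]], "' on case '", case_ids[miss[["row"]]], "'",
         call. = FALSE)
  }
  mat
}

# -- delimited-file helpers ---------------------------------------------------

delim_for <- function(path) {
  switch(tolower(tools::file_ext(path)),
    csv = ",",
    tsv = ,
    txt = "\t",
    stop("unsupported table extension for ", path, " (use .csv or .tsv)",
         call. = FALSE)
  )
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = delim_for(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_delimited <- function(x, path) {
  utils::write.table(x, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
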