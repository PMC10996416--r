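#' Construct a paired-reader study dataset
#'
#' A `study_dataset` holds one row per (case, finding) pair in long format:
#' the reference-standard label (`truth`), one call column per reader coded
#' `0`/`1`/`NA` (`NA` means the reader produced no output for that case, e.g.
#' an algorithm that failed to process the image), and optional
#' `<reader>_score` columns holding continuous suspicion scores in `[0, 1]`.
#'
#' @param records data frame with columns `case_id`, `finding`, `truth`, one
#'   integer column per reader and optional `<reader>_score` columns.
#' @param readers character vector of reader column names; by default every
#'   column that is not `case_id`, `finding`, `truth` or a score column.
#'
#' @details Invariants enforced: `truth` is always 0/1 and never missing
#'   (every included case carries a reference-standard label); `(case_id,
#'   finding)` pairs are unique; reader cells are 0, 1 or `NA`; every finding
#'   covers the same number of cases (long format of a rectangular cohort).
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `records` (tibble), `readers` and `findings` (character vectors).
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   case_id = c("c1", "c2", "c3"),
#'   finding = "pneumothorax",
#'   truth = c(1L, 0L, 1L),
#'   radiologist = c(1L, 0L, 0L),
#'   ai = c(1L, 0L, NA)
#' )
#' ds <- study_dataset(rec)
#' ds$readers
study_dataset <- function(records, readers = NULL) {
  records <- tibble::as_tibble(records)
  required <- c("case_id", "finding", "truth")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  score_cols <- grep("_score$", names(records), value = TRUE)
  if (is.null(readers)) {
    readers <- setdiff(names(records), c(required, score_cols))
  }
  if (length(readers) < 1) {
    stop("dataset needs at least one reader column", call. = FALSE)
  }
  bad_scores <- setdiff(score_cols, paste0(readers, "_score"))
  if (length(bad_scores) > 0) {
    stop("score column(s) without a matching reader: ",
         paste(bad_scores, collapse = ", "), call. = FALSE)
  }

  records$case_id <- as.character(records$case_id)
  records$finding <- as.character(records$finding)
  records$truth <- .check_binary(records$truth, "truth", allow_na = FALSE)
  for (r in readers) {
    records[[r]] <- .check_binary(records[[r]], r, allow_na = TRUE)
  }
  for (s in score_cols) {
    sc <- as.numeric(records[[s]])
    if (any(!is.na(sc) & (sc < 0 | sc > 1))) {
      stop("scores in '", s, "' must lie in [0, 1]", call. = FALSE)
    }
    records[[s]] <- sc
  }

  key <- paste(records$case_id, records$finding, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (case_id, finding) pair: ",
         gsub("\r", " / ", dup), call. = FALSE)
  }
  findings <- unique(records$finding)
  per_finding <- table(records$finding)
  if (length(unique(as.integer(per_finding))) > 1) {
    stop("case count differs across findings; the cohort must be rectangular",
         call. = FALSE)
  }

  structure(
    list(records = records, readers = readers, findings = findings),
    class = "study_dataset"
  )
}

.check_binary <- function(x, name, allow_na) {
  if (is.logical(x)) x <- as.integer(x)
  if (is.character(x)) {
    x <- tolower(trimws(x))
    x[x %in% c("na", "")] <- NA
    map <- c("0" = 0L, "1" = 1L, "true" = 1L, "false" = 0L)
    bad <- !is.na(x) & !(x %in% names(map))
    if (any(bad)) {
      stop("column '", name, "' has non-binary value(s): ",
           paste(unique(x[bad]), collapse = ", "),
           " (rows ", paste(which(bad), collapse = ", "), ")", call. = FALSE)
    }
    x <- unname(map[x])
  }
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% c(0L, 1L))
  if (any(bad)) {
    stop("column '", name, "' must be coded 0/1",
         if (allow_na) "/NA" else "",
         " (rows ", paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop("column '", name, "' may not contain missing values (rows ",
         paste(which(is.na(x)), collapse = ", "), ")", call. = FALSE)
  }
  x
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", nrow(x$records), " records | ",
      length(x$findings), " finding(s) | readers: ",
      paste(x$readers, collapse = ", "), "\n", sep = "")
  print(utils::head(x$records, 5))
  invisible(x)
}

#' Read a paired-reader dataset from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `case_id,finding,truth,<reader>[,<reader>...][,<reader>_score...]`.
#' `truth` cells are coerced from `{0, 1, true, false}`; reader cells from
#' `{0, 1, NA}` where `NA` marks an unavailable call. Malformed cells raise
#' an error naming the offending CSV line; duplicated `(case_id, finding)`
#' pairs and missing `truth` values are rejected.
#'
#' @param path path to a CSV file.
#' @return A [study_dataset].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed CSV at line ", prob$row[1] + 1L, ": ",
         prob$expected[1], call. = FALSE)
  }
  # report validation errors in CSV line numbers (header is line 1)
  out <- tryCatch(
    study_dataset(raw),
    error = function(e) {
      msg <- conditionMessage(e)
      m <- regmatches(msg, gregexpr("rows? [0-9, ]+", msg))[[1]]
      if (length(m) > 0) {
        rows <- as.integer(strsplit(gsub("rows? ", "", m[1]), ", ")[[1]])
        msg <- paste0(msg, " [CSV line(s) ",
                      paste(rows + 1L, collapse = ", "), "]")
      }
      stop(msg, call. = FALSE)
    }
  )
  out
}

#' Write a paired-reader dataset to CSV
#'
#' Inverse of [read_dataset()]: unavailable reader calls are written as
#' literal `NA` cells and survive a round-trip.
#'
#' @param ds a [study_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "study_dataset"))
  readr::write_csv(ds$records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Build a 2x2 confusion table
#'
#' Counts of a binary reader against the reference standard: `tp` and `fn`
#' partition the truth-positive cases, `tn` and `fp` the truth-negatives.
#'
#' @param tp,fp,fn,tn non-negative integer counts; their sum must be >= 1.
#' @return An object of class `confusion_table`.
#' @export
#' @examples
#' ct <- confusion_table(tp = 57, fp = 8, fn = 115, tn = 1224)
#' sensitivity(ct)
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fp, fn, tn must be non-negative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)),
                            c("tp", "fp", "fn", "tn"))
  if (sum(counts) < 1) {
    stop("confusion table must contain at least one case", call. = FALSE)
  }
  structure(as.list(counts), n = sum(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(reader = c("positive", "negative"),
                              truth = c("positive", "negative")))
  cat("<confusion_table> n =", attr(x, "n"), "\n")
  print(m)
  invisible(x)
}

#' Tabulate one reader against the reference standard
#'
#' Crosses a reader's calls with `truth` for one finding. Cases where the
#' reader produced no output are either excluded from the denominator
#' (`"drop"`, the default, mirroring a study that reports the algorithm on
#' the subset of images it could process) or scored as negative calls
#' (`"count_negative"`, the operational view that a failed triage output
#' is a non-detection).
#'
#' @param ds a [study_dataset].
#' @param reader reader name (one of `ds$readers`).
#' @param finding finding name (one of `ds$findings`).
#' @param unavailable_policy `"drop"` or `"count_negative"`.
#' @return A [confusion_table] whose `n` equals the number of contributing
#'   cases.
#' @export
confusion_from_calls <- function(ds, reader, finding,
                                 unavailable_policy = c("drop", "count_negative")) {
  stopifnot(inherits(ds, "study_dataset"))
  unavailable_policy <- match.arg(unavailable_policy)
  if (!reader %in% ds$readers) {
    stop("unknown reader: ", reader, call. = FALSE)
  }
  if (!finding %in% ds$findings) {
    stop("unknown finding: ", finding, call. = FALSE)
  }
  rec <- ds$records[ds$records$finding == finding, ]
  call <- rec[[reader]]
  truth <- rec$truth
  if (unavailable_policy == "count_negative") {
    call[is.na(call)] <- 0L
  } else {
    keep <- !is.na(call)
    call <- call[keep]
    truth <- truth[keep]
  }
  if (length(call) == 0) {
    stop("no contributing cases for reader '", reader, "', finding '",
         finding, "' under policy '", unavailable_policy, "'", call. = FALSE)
  }
  confusion_table(
    tp = sum(call == 1L & truth == 1L),
    fp = sum(call == 1L & truth == 0L),
    fn = sum(call == 0L & truth == 1L),
    tn = sum(call == 0L & truth == 0L)
  )
}
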