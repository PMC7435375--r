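# Canonical data model and I/O for per-frame facial-state time series.

.stream_numeric_cols <- c("t", "left_gap", "right_gap", "mar")
.stream_logical_cols <- c("left_closed", "right_closed", "mouth_open")
.stream_cols <- c(.stream_numeric_cols, .stream_logical_cols, "label")

#' Construct a facial-state stream
#'
#' A `state_stream` holds one record per video frame: a timestamp `t` (seconds
#' from stream start) plus any of the continuous measurements `left_gap`,
#' `right_gap` (eyelid opening distance, image-relative units) and `mar`
#' (mouth aspect ratio), and/or the pre-binarized states `left_closed`,
#' `right_closed`, `mouth_open`. An optional `label` column carries
#' ground-truth drowsiness states for evaluation.
#'
#' Timestamps are seconds as floats with `t = 0` at stream start; the frame
#' index is derived, never stored, so dropped frames are tolerated.
#'
#' @param records data.frame with column `t` and any subset of the measurement
#'   columns above. Unknown columns are preserved.
#' @param nominal_fps nominal frame rate; inferred from the median inter-frame
#'   interval when `NULL`.
#' @param meta free-form provenance list.
#' @param validate run [validate_stream()] (default `TRUE`).
#' @return object of class `state_stream`: a list with elements `records`,
#'   `nominal_fps`, `meta`.
#' @export
state_stream <- function(records, nominal_fps = NULL, meta = list(), validate = TRUE) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) .stopf("empty stream: no records")
  if (!"t" %in% names(records)) .stopf("stream records must have a 't' column")
  for (col in .stream_numeric_cols) {
    if (col %in% names(records)) records[[col]] <- as.numeric(records[[col]])
  }
  for (col in .stream_logical_cols) {
    if (col %in% names(records)) records[[col]] <- as.logical(records[[col]])
  }
  if (is.null(nominal_fps)) {
    nominal_fps <- if (nrow(records) >= 2L) {
      round(1 / median(diff(records$t)))
    } else {
      30
    }
  }
  x <- structure(
    list(records = records, nominal_fps = nominal_fps, meta = meta),
    class = "state_stream"
  )
  if (validate) validate_stream(x)
  x
}

#' Validate a facial-state stream
#'
#' Enforces the stream invariants: timestamps non-negative, finite and strictly
#' increasing; gaps and mar non-negative; at least one measurement column
#' present. Records in which every measurement is absent (e.g. frames where no
#' face was detected) are allowed but counted with a warning, as is a median
#' inter-frame interval deviating more than 20% from `1/nominal_fps`.
#'
#' @param stream a `state_stream`.
#' @return the stream, invisibly; errors/warnings otherwise.
#' @export
validate_stream <- function(stream) {
  stopifnot(inherits(stream, "state_stream"))
  rec <- stream$records
  t <- rec$t
  if (anyNA(t) || any(!is.finite(t))) {
    .stopf("invalid timestamp at row %d", which(is.na(t) | !is.finite(t))[1])
  }
  if (any(t < 0)) .stopf("negative timestamp at row %d", which(t < 0)[1])
  if (nrow(rec) >= 2L) {
    bad <- which(diff(t) <= 0)
    if (length(bad)) {
      .stopf("timestamps not strictly increasing at row %d", bad[1] + 1L)
    }
  }
  for (col in c("left_gap", "right_gap", "mar")) {
    v <- rec[[col]]
    if (!is.null(v) && any(v < 0, na.rm = TRUE)) {
      .stopf("negative %s at row %d", col, which(v < 0)[1])
    }
  }
  meas <- intersect(c(.stream_numeric_cols[-1], .stream_logical_cols), names(rec))
  if (length(meas) == 0L) {
    .stopf("stream has neither continuous measurements nor binary states")
  }
  present <- Reduce(`|`, lapply(rec[meas], function(v) !is.na(v)))
  if (!all(present)) {
    warning(sprintf("%d record(s) carry no measurement (e.g. no face detected)",
                    sum(!present)), call. = FALSE)
  }
  if (nrow(rec) >= 2L && !is.null(stream$nominal_fps)) {
    dt <- median(diff(t))
    if (abs(dt - 1 / stream$nominal_fps) > 0.2 / stream$nominal_fps) {
      warning(sprintf(
        "median inter-frame interval %.4fs deviates >20%% from 1/%g fps",
        dt, stream$nominal_fps), call. = FALSE)
    }
  }
  invisible(stream)
}

#' Does every record carry binary eye/mouth states?
#'
#' @param stream a `state_stream`.
#' @return `TRUE` when `left_closed`, `right_closed` and `mouth_open` are all
#'   present and non-missing on every record.
#' @export
is_binarized <- function(stream) {
  rec <- stream$records
  all(.stream_logical_cols %in% names(rec)) &&
    !anyNA(rec[.stream_logical_cols])
}

#' @export
print.state_stream <- function(x, ...) {
  rec <- x$records
  dur <- if (nrow(rec)) rec$t[nrow(rec)] - rec$t[1] + 1 / x$nominal_fps else 0
  cat(sprintf("<state_stream> %d frames, %.1f s @ %g fps (nominal)\n",
              nrow(rec), dur, x$nominal_fps))
  cols <- setdiff(names(rec), "t")
  cat("  columns:", paste(cols, collapse = ", "), "\n")
  if (is_binarized(x)) cat("  binarized: yes\n")
  invisible(x)
}

#' @export
summary.state_stream <- function(object, ...) {
  print(object)
  rec <- object$records
  if (!is.null(rec$left_closed)) {
    cat(sprintf("  eyes closed (both): %.1f%% of frames\n",
                100 * mean(rec$left_closed & rec$right_closed, na.rm = TRUE)))
  }
  if (!is.null(rec$mouth_open)) {
    cat(sprintf("  mouth open: %.1f%% of frames\n",
                100 * mean(rec$mouth_open, na.rm = TRUE)))
  }
  invisible(object)
}

.stream_dialect <- function(path, dialect) {
  dialect <- match.arg(dialect, c("auto", "csv", "jsonl"))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  dialect
}

#' Read a facial-state stream from CSV or JSONL
#'
#' CSV dialect: mandatory header row, comma separated, UTF-8, missing values as
#' empty cells. JSONL dialect: one JSON object per line, absent keys meaning
#' absent fields, `null` allowed.
#'
#' @param path file path.
#' @param dialect `"csv"`, `"jsonl"` or `"auto"` (by extension; default).
#' @param nominal_fps override the inferred nominal frame rate.
#' @return a validated [state_stream()].
#' @export
read_stream <- function(path, dialect = "auto", nominal_fps = NULL) {
  if (!file.exists(path)) .stopf("stream file not found: %s", path)
  dialect <- .stream_dialect(path, dialect)
  if (dialect == "csv") {
    if (file.size(path) == 0) .stopf("empty stream: %s", path)
    rec <- tryCatch(
      read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
      error = function(e) .stopf("failed to parse %s: %s", path, conditionMessage(e))
    )
    if (nrow(rec) == 0L) .stopf("empty stream: %s", path)
    if (!"t" %in% names(rec)) .stopf("missing 't' column in %s", path)
    tnum <- suppressWarnings(as.numeric(rec$t))
    if (anyNA(tnum)) {
      .stopf("malformed row: non-numeric 't' at data row %d of %s",
             which(is.na(tnum))[1], path)
    }
    rec$t <- tnum
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) .stopf("empty stream: %s", path)
    parsed <- lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[i]),
               error = function(e) .stopf("malformed JSONL at line %d of %s", i, path))
    })
    keys <- unique(unlist(lapply(parsed, names)))
    rec <- as.data.frame(lapply(keys, function(k) {
      vals <- lapply(parsed, function(p) {
        v <- p[[k]]
        if (is.null(v)) NA else v
      })
      unlist(vals)
    }), stringsAsFactors = FALSE)
    names(rec) <- keys
    if (!"t" %in% names(rec)) .stopf("missing 't' key in %s", path)
  }
  state_stream(rec, nominal_fps = nominal_fps)
}

#' Write a facial-state stream to CSV or JSONL
#'
#' Columns that are entirely absent (all `NA`) are dropped; partially absent
#' values are written as empty cells (CSV) or explicit `null` (JSONL).
#' Round-trip property: `read_stream(write_stream(s))` reproduces the records
#' field by field up to floating-point text representation.
#'
#' @param stream a validated `state_stream`.
#' @param path output path.
#' @param dialect `"csv"`, `"jsonl"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, dialect = "auto") {
  stopifnot(inherits(stream, "state_stream"))
  dialect <- .stream_dialect(path, dialect)
  rec <- stream$records
  keep <- vapply(rec, function(v) !all(is.na(v)), logical(1))
  keep["t"] <- TRUE
  rec <- rec[keep]
  if (dialect == "csv") {
    ok <- tryCatch({
      write.csv(rec, path, row.names = FALSE, na = "")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) .stopf("cannot write stream to %s", path)
  } else {
    con <- tryCatch(file(path, "w"), error = function(e) .stopf("cannot write stream to %s", path))
    on.exit(close(con))
    for (i in seq_len(nrow(rec))) {
      row <- as.list(rec[i, , drop = FALSE])
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null", digits = NA), con)
    }
  }
  invisible(path)
}
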