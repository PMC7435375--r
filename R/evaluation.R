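# Segment-level scoring of per-second drowsiness output against ground truth.

#' Split a per-second truth track into evaluation segments
#'
#' Contiguous runs of the same label are split into consecutive segments of
#' approximately `segment_s` seconds (the last piece of a run keeps the
#' remainder), matching the protocol of scoring scripted sessions in
#' roughly one-minute segments.
#'
#' @param truth data.frame with columns `t` (end of each one-second tick) and
#'   `label`.
#' @param segment_s nominal segment duration in seconds (default 60); `NULL`
#'   keeps each run as a single segment.
#' @return data.frame with columns `segment`, `label`, `start_s`, `end_s`
#'   (spans are half-open `(start_s, end_s]`).
#' @export
truth_segments <- function(truth, segment_s = 60) {
  stopifnot(all(c("t", "label") %in% names(truth)))
  truth <- truth[order(truth$t), , drop = FALSE]
  r <- rle(as.character(truth$label))
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths
  starts <- numeric(0); ends <- numeric(0); labs <- character(0)
  for (i in seq_along(r$lengths)) {
    s0 <- truth$t[run_start[i] + 1L] - 1
    e0 <- truth$t[run_end[i]]
    if (is.null(segment_s)) {
      cuts <- c(s0, e0)
    } else {
      n_seg <- max(1L, round((e0 - s0) / segment_s))
      cuts <- seq(s0, e0, length.out = n_seg + 1L)
    }
    starts <- c(starts, cuts[-length(cuts)])
    ends <- c(ends, cuts[-1])
    labs <- c(labs, rep(r$values[i], length(cuts) - 1L))
  }
  data.frame(segment = seq_along(labs), label = labs,
             start_s = starts, end_s = ends, stringsAsFactors = FALSE)
}

#' Per-segment predicted labels from a per-second level series
#'
#' Each segment's prediction is the majority vote of the per-second labels
#' whose emission time falls in the segment span `(start_s, end_s]`; ties go
#' to the more severe label (fail-safe direction: late alarms are worse than
#' early ones).
#'
#' @param levels a `level_series` (from [infer_series()]) or data.frame with
#'   columns `t` and `label`.
#' @param segments data.frame from [truth_segments()] (columns `segment`,
#'   `label`, `start_s`, `end_s`). Segments that end before the first emission
#'   (inside the warm-up window) are skipped with a message; a later segment
#'   with no emissions is a coverage error.
#' @return data.frame of class `segment_results`: `segment`, `truth`,
#'   `predicted`, `start_s`, `end_s`, `n_levels`.
#' @export
segment_predictions <- function(levels, segments) {
  stopifnot(all(c("t", "label") %in% names(levels)))
  pred_lv <- as_level(levels$label)
  truth_lv <- as_level(segments$label)
  eps <- 1e-9
  t_min <- min(levels$t)
  out <- segments
  out$truth <- as.character(truth_lv)
  out$predicted <- NA_character_
  out$n_levels <- 0L
  skip <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    sel <- levels$t > segments$start_s[i] + eps & levels$t <= segments$end_s[i] + eps
    if (!any(sel)) {
      if (segments$end_s[i] < t_min - eps) {  # warm-up: no full window yet
        skip[i] <- TRUE
        next
      }
      .stopf("segment %d (%g, %g] not covered by any emitted level",
             segments$segment[i], segments$start_s[i], segments$end_s[i])
    }
    votes <- table(pred_lv[sel])
    winners <- names(votes)[votes == max(votes)]
    out$predicted[i] <- winners[which.max(match(winners, .levels))]  # tie -> severe
    out$n_levels[i] <- sum(sel)
  }
  if (any(skip)) {
    message(sprintf("skipping %d warm-up segment(s) before the first emission", sum(skip)))
    out <- out[!skip, , drop = FALSE]
  }
  out <- out[, c("segment", "truth", "predicted", "start_s", "end_s", "n_levels")]
  class(out) <- c("segment_results", "data.frame")
  out
}

#' Confusion matrix over segment results
#'
#' @param results a [segment_predictions()] data.frame (columns `truth`,
#'   `predicted`).
#' @return object of class `confusion_summary`: list with `matrix` (3x3 counts,
#'   rows = truth, columns = predicted), `per_class_accuracy`,
#'   `total_accuracy` (trace over total) and `n_segments`.
#' @export
confusion <- function(results) {
  if (NROW(results) == 0L) .stopf("empty segment results")
  truth <- as_level(results$truth)
  pred <- as_level(results$predicted)
  m <- table(truth = truth, predicted = pred)
  m <- unclass(m)[.levels, .levels]
  state <- unname(.state_names)
  dimnames(m) <- list(truth = state, predicted = state)
  per_class <- ifelse(rowSums(m) > 0, diag(m) / rowSums(m), NA_real_)
  names(per_class) <- rownames(m)
  structure(list(matrix = m,
                 per_class_accuracy = per_class,
                 total_accuracy = sum(diag(m)) / sum(m),
                 n_segments = sum(m)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> %d segments, total accuracy %.1f%%\n",
              x$n_segments, 100 * x$total_accuracy))
  print(x$matrix)
  pc <- x$per_class_accuracy
  pc <- pc[!is.na(pc)]
  cat("per-class accuracy:",
      paste(sprintf("%s %.1f%%", names(pc), 100 * pc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.confusion_summary <- function(x, ...) {
  as.data.frame.table(as.table(x$matrix), responseName = "count")
}
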