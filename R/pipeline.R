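# End-to-end chain: stream -> (calibration) -> binarization -> sliding
# indicators -> fuzzy inference -> per-second levels and alarm events.

#' Run the full drowsiness-estimation pipeline
#'
#' Routes the input through the stages it needs: already-binarized streams skip
#' the frontend and calibration; continuous streams are binarized against the
#' supplied profile, or against a profile calibrated on the first
#' `calibration_s` seconds when requested. Indicators are computed each
#' `stride_s` seconds over the sliding window and mapped through the fuzzy
#' inference system; the first emission occurs at `t = window_s` (no
#' partial-window outputs). Deterministic: the same inputs yield identical
#' outputs.
#'
#' @param input a `state_stream`, a `labeled_stream`, or a path readable by
#'   [read_stream()].
#' @param fis a [fis_config()] (default [default_fis_config()]).
#' @param profile optional [calibrate()] profile for continuous input.
#' @param window a [window_config()].
#' @param calibration_s when given and `profile` is `NULL`, calibrate on the
#'   first `calibration_s` seconds of the stream (those frames stay in the
#'   analysis).
#' @param eye_combine `"all"` or `"any"` per-eye combination rule.
#' @param alarm_min_level lowest level that raises an alarm event
#'   (default `"Medium"`).
#' @param debounce_s a label must persist this many consecutive seconds before
#'   an alarm event opens (default 0 = off; the estimator itself is stateless).
#' @return object of class `pipeline_result`: list with `levels`
#'   (per-second [infer_series()] output), `indicators`, `profile` (if any),
#'   `alarms` (data.frame `t_start`, `t_end`, `level`), and `log`
#'   (stage notes, e.g. dropped/faceless frame counts).
#' @export
run_pipeline <- function(input, fis = default_fis_config(), profile = NULL,
                         window = window_config(), calibration_s = NULL,
                         eye_combine = c("all", "any"),
                         alarm_min_level = "Medium", debounce_s = 0) {
  eye_combine <- match.arg(eye_combine)
  stream <- if (inherits(input, "labeled_stream")) {
    input$stream
  } else if (inherits(input, "state_stream")) {
    input
  } else if (is.character(input) && length(input) == 1L) {
    read_stream(input)
  } else {
    .stopf("input must be a state_stream, labeled_stream or file path")
  }
  log <- list()
  rec <- stream$records
  meas <- intersect(c("left_gap", "right_gap", "mar",
                      "left_closed", "right_closed", "mouth_open"), names(rec))
  present <- Reduce(`|`, lapply(rec[meas], function(v) !is.na(v)))
  log$n_frames <- nrow(rec)
  log$n_faceless <- sum(!present)

  if (is_binarized(stream)) {
    log$route <- "binarized input: frontend and calibration skipped"
    bin <- stream
  } else {
    if (is.null(profile)) {
      if (is.null(calibration_s)) {
        .stopf(paste0("continuous input without a calibration profile; run ",
                      "calibrate() first or pass calibration_s"))
      }
      profile <- calibrate(stream, duration_s = calibration_s,
                           eye_combine = eye_combine)
      log$route <- sprintf("calibrated on first %g s, then binarized", calibration_s)
    } else {
      log$route <- "binarized against supplied profile"
    }
    bin <- binarize_stream(stream, profile)
  }
  ind <- sliding_indicators(bin, window, eye_combine = eye_combine)
  lev <- infer_series(ind, fis)
  alarms <- alarm_events(lev, min_level = alarm_min_level, debounce_s = debounce_s,
                         stride_s = window$stride_s)
  structure(list(levels = lev, indicators = ind, profile = profile,
                 alarms = alarms, window = window, log = log),
            class = "pipeline_result")
}

#' Alarm events from a level series
#'
#' Collapses consecutive emissions at or above `min_level` into labelled alarm
#' events (severity = most severe label within the run). Runs shorter than
#' `debounce_s` are suppressed.
#'
#' @param levels a `level_series` (columns `t`, `label`).
#' @param min_level lowest alarming level (default `"Medium"`).
#' @param debounce_s minimum persistence in seconds (default 0).
#' @param stride_s emission period of the series (default 1).
#' @return data.frame with columns `t_start`, `t_end`, `level`.
#' @export
alarm_events <- function(levels, min_level = "Medium", debounce_s = 0, stride_s = 1) {
  lv <- as_level(levels$label)
  hot <- lv >= as_level(min_level)[1]
  r <- rle(as.vector(hot))
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  keep <- which(r$values & r$lengths * stride_s >= debounce_s)
  if (!length(keep)) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      level = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    t_start = levels$t[s[keep]],
    t_end = levels$t[e[keep]],
    level = vapply(keep, function(k) {
      as.character(max(lv[s[k]:e[k]]))
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %s\n", x$log$route))
  cat(sprintf("  %d frames in (%d without measurements), %d per-second levels out\n",
              x$log$n_frames, x$log$n_faceless, nrow(x$levels)))
  tab <- table(factor(x$levels$label, levels = .levels))
  cat("  levels:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  alarms: %d event(s)\n", nrow(x$alarms)))
  invisible(x)
}
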