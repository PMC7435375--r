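# Sliding-window drowsiness indicators over a binarized stream:
#   PERCLOS  - fraction of eyes-closed frames in the window
#   ECD      - mean duration of eyes-closed intervals in the window
#   AOT      - mean yawn duration (mouth-open runs past the 3 s floor)

#' Sliding-window configuration
#'
#' @param window_s window length in seconds (default 60).
#' @param stride_s emission period in seconds (default 1).
#' @param yawn_min_s minimum mouth-open time before a yawn starts counting
#'   (default 3); a run of length L seconds yields a yawn of duration
#'   `L - yawn_min_s` only when `L > yawn_min_s`.
#' @param duration_mode `"frames"` (default) measures interval durations as
#'   run length times the nominal frame period, matching fixed-fps frame-count
#'   arithmetic; `"timestamps"` sums the observed inter-frame intervals, for
#'   irregular streams.
#' @return object of class `window_config`.
#' @export
window_config <- function(window_s = 60, stride_s = 1, yawn_min_s = 3,
                          duration_mode = c("frames", "timestamps")) {
  duration_mode <- match.arg(duration_mode)
  if (window_s <= 0) .stopf("window_s must be positive")
  if (stride_s <= 0 || stride_s > window_s) .stopf("stride_s must be in (0, window_s]")
  if (yawn_min_s < 0) .stopf("yawn_min_s must be non-negative")
  structure(list(window_s = window_s, stride_s = stride_s,
                 yawn_min_s = yawn_min_s, duration_mode = duration_mode),
            class = "window_config")
}

#' PERCLOS of a window
#'
#' Percentage of eyelid closure: the number of eyes-closed frames divided by
#' the number of frames in the window. Missing flags count as open.
#'
#' @param flags logical vector of per-frame eyes-closed states.
#' @param n frame count (defaults to `length(flags)`).
#' @return fraction in `[0, 1]`.
#' @export
perclos <- function(flags, n = length(flags)) {
  if (n < 1L) .stopf("undefined window: no frames")
  sum(flags, na.rm = TRUE) / n
}

# run-length scan shared by closed_intervals / detect_yawns:
# maximal TRUE runs, durations = run length * frame_period (runs truncated at
# the window edges are thereby clipped to their in-window portion).
.run_durations <- function(flags, frame_period) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  r$lengths[r$values] * frame_period
}

#' Eyes-closed intervals of a window
#'
#' Maximal runs of eyes-closed frames, each converted to a duration (run
#' length times the frame period). Runs straddling the window boundary are
#' clipped to their in-window portion, so every duration is at most the window
#' length.
#'
#' @param flags logical vector of per-frame eyes-closed states.
#' @param frame_period seconds per frame (`1 / fps`).
#' @return numeric vector of durations in seconds (possibly empty).
#' @export
closed_intervals <- function(flags, frame_period) {
  .run_durations(flags, frame_period)
}

#' Eye closing duration (ECD) of a window
#'
#' Mean duration of the eyes-closed intervals in the window; 0 when there are
#' none (no closures map to the least-drowsy value).
#'
#' @inheritParams closed_intervals
#' @return seconds (>= 0).
#' @export
ecd <- function(flags, frame_period) {
  d <- closed_intervals(flags, frame_period)
  if (length(d) == 0L) 0 else mean(d)
}

#' Detect yawns in a window
#'
#' A yawn is a maximal mouth-open run longer than `yawn_min_s` seconds; its
#' duration is counted only past those first `yawn_min_s` seconds. Shorter
#' runs emit nothing.
#'
#' @param flags logical vector of per-frame mouth-open states.
#' @param frame_period seconds per frame.
#' @param yawn_min_s qualification floor in seconds (default 3).
#' @return numeric vector of yawn durations in seconds (possibly empty).
#' @export
detect_yawns <- function(flags, frame_period, yawn_min_s = 3) {
  d <- .run_durations(flags, frame_period)
  d <- d[d > yawn_min_s + 1e-12]
  d - yawn_min_s
}

#' Average mouth opening time (AOT) of a window
#'
#' Mean of the yawn durations in the window; 0 when no yawn qualifies.
#'
#' @inheritParams detect_yawns
#' @return seconds (>= 0).
#' @export
aot <- function(flags, frame_period, yawn_min_s = 3) {
  d <- detect_yawns(flags, frame_period, yawn_min_s)
  if (length(d) == 0L) 0 else mean(d)
}

# clip run [s, e] (frame indices) to window [i1, i2]; returns lengths of
# intersections for all runs overlapping the window
.clipped_run_lengths <- function(starts, ends, i1, i2) {
  keep <- starts <= i2 & ends >= i1
  if (!any(keep)) return(integer(0))
  pmin(ends[keep], i2) - pmax(starts[keep], i1) + 1L
}

#' Sliding-window indicator series
#'
#' Emits one indicator sample per stride point `t = window_s, window_s +
#' stride_s, ...` up to the stream duration, computed over the frames whose
#' timestamps fall in the half-open window `[t - window_s, t)` (a frame is
#' stamped at the start of the period it samples, so a frame stamped exactly
#' at an emission instant belongs to the next window and stride concatenation
#' partitions time exactly; a full one-minute window at 30 fps holds exactly
#' 1800 frames). Each sample
#' carries PERCLOS, ECD and AOT plus the frame, closed-interval and yawn
#' counts, and equals a from-scratch recomputation of the single-window
#' operations on that slice.
#'
#' @param stream a binarized `state_stream` (see [binarize_stream()]).
#' @param cfg a [window_config()].
#' @param eye_combine `"all"` (default) or `"any"`: how the per-eye closed
#'   flags combine into the eyes-closed state.
#' @return data.frame of class `indicator_series` with columns `t`, `perclos`,
#'   `ecd`, `aot`, `n_frames`, `p_intervals`, `n_yawns`.
#' @export
sliding_indicators <- function(stream, cfg = window_config(),
                               eye_combine = c("all", "any")) {
  stopifnot(inherits(stream, "state_stream"))
  eye_combine <- match.arg(eye_combine)
  if (!is_binarized(stream)) {
    # tolerate NA flags (frames without a face): they count as open / not yawning
    if (!all(.stream_logical_cols %in% names(stream$records))) {
      .stopf("stream is not binarized; run binarize_stream() first")
    }
  }
  rec <- stream$records
  fps <- stream$nominal_fps
  t <- rec$t - rec$t[1]
  duration <- t[length(t)] + 1 / fps
  if (duration < cfg$window_s - 1e-9) {
    .stopf("insufficient data: stream spans %.2f s, window is %g s", duration, cfg$window_s)
  }
  closed <- .combine_eyes(rec$left_closed, rec$right_closed, eye_combine)
  closed[is.na(closed)] <- FALSE
  mouth <- rec$mouth_open
  mouth[is.na(mouth)] <- FALSE

  # global runs, clipped per window
  run_idx <- function(flags) {
    r <- rle(flags)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    list(s = s[r$values], e = e[r$values])
  }
  cruns <- run_idx(closed)
  mruns <- run_idx(mouth)
  ccum <- c(0, cumsum(closed))
  fp <- 1 / fps
  frames_mode <- cfg$duration_mode == "frames"
  dtcum <- if (frames_mode) NULL else c(0, cumsum(c(diff(t), 1 / fps)))
  run_dur <- function(runs, i1, i2) {
    keep <- which(runs$s <= i2 & runs$e >= i1)
    if (!length(keep)) return(numeric(0))
    s <- pmax(runs$s[keep], i1)
    e <- pmin(runs$e[keep], i2)
    if (frames_mode) (e - s + 1L) * fp else dtcum[e + 1L] - dtcum[s]
  }

  eps <- 1e-9
  t_emit <- seq(cfg$window_s, duration + eps, by = cfg$stride_s)
  t_emit <- t_emit[t_emit <= duration + eps]
  out <- data.frame(t = t_emit + rec$t[1], perclos = NA_real_, ecd = NA_real_,
                    aot = NA_real_, n_frames = NA_integer_,
                    p_intervals = NA_integer_, n_yawns = NA_integer_)
  for (k in seq_along(t_emit)) {
    lo <- t_emit[k] - cfg$window_s
    hi <- t_emit[k]
    i1 <- findInterval(lo - eps, t) + 1L
    i2 <- findInterval(hi - eps, t)
    n <- i2 - i1 + 1L
    if (n < 1L) next
    cd <- run_dur(cruns, i1, i2)
    yd <- run_dur(mruns, i1, i2)
    yd <- yd[yd > cfg$yawn_min_s + 1e-12] - cfg$yawn_min_s
    out$perclos[k] <- (ccum[i2 + 1L] - ccum[i1]) / n
    out$ecd[k] <- if (length(cd)) mean(cd) else 0
    out$aot[k] <- if (length(yd)) mean(yd) else 0
    out$n_frames[k] <- n
    out$p_intervals[k] <- length(cd)
    out$n_yawns[k] <- length(yd)
  }
  out <- out[!is.na(out$n_frames), , drop = FALSE]
  class(out) <- c("indicator_series", "data.frame")
  attr(out, "window_config") <- cfg
  out
}

#' @export
as.data.frame.indicator_series <- function(x, ...) {
  attr(x, "window_config") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.indicator_series <- function(x, ...) {
  cfg <- attr(x, "window_config")
  cat(sprintf("<indicator_series> %d samples (window %g s, stride %g s)\n",
              nrow(x), cfg$window_s, cfg$stride_s))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}
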