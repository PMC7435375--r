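# Personalized setup: open-eye / open-mouth references and the per-frame
# eye/mouth state classifier.

#' Calibrate personalized open-eye / open-mouth references
#'
#' Implements the one-minute personalized setup: over the first `duration_s`
#' seconds of the stream, the eyelid gaps and mouth aspect ratio are collected
#' (at 30 fps and 60 s that is 1800 values per eye and for mar), each signal is
#' sorted in descending order and the mean of the top `ceiling(top_fraction *
#' N)` values -- the most significant distances, indicating opened eyes and
#' mouth -- becomes that signal's open reference. Frames with an absent
#' measurement are skipped and do not count towards N for that signal.
#'
#' @param stream a `state_stream` with continuous measurements spanning at
#'   least `duration_s` seconds.
#' @param duration_s calibration window length in seconds (default 60).
#' @param top_fraction fraction of largest values averaged (default 0.05).
#' @param eye_closed_ratio fraction of the open reference below which an eye
#'   counts as closed (default 0.2).
#' @param mar_open_threshold absolute mar threshold for "mouth open"
#'   (default 0.7).
#' @param mar_mode `"fixed"` uses `mar_open_threshold` as-is (default);
#'   `"calibrated"` replaces it by `mar_ratio * open_mar_ref` when the
#'   calibration window captured mouth openings.
#' @param mar_ratio ratio applied to `open_mar_ref` in `"calibrated"` mode.
#' @param eye_combine `"all"` (both eyes below threshold count as eyes-closed,
#'   default; suppresses single-eye glitches and winks) or `"any"`.
#' @return object of class `calibration_profile`.
#' @export
calibrate <- function(stream, duration_s = 60, top_fraction = 0.05,
                      eye_closed_ratio = 0.2, mar_open_threshold = 0.7,
                      mar_mode = c("fixed", "calibrated"), mar_ratio = 0.7,
                      eye_combine = c("all", "any")) {
  stopifnot(inherits(stream, "state_stream"))
  mar_mode <- match.arg(mar_mode)
  eye_combine <- match.arg(eye_combine)
  if (!(top_fraction > 0 && top_fraction <= 1)) .stopf("top_fraction must be in (0, 1]")
  if (!(eye_closed_ratio > 0 && eye_closed_ratio < 1)) .stopf("eye_closed_ratio must be in (0, 1)")
  rec <- stream$records
  t0 <- rec$t[1]
  span <- rec$t[nrow(rec)] - t0 + 1 / stream$nominal_fps
  if (span < duration_s - 1e-9) {
    .stopf("insufficient data: stream spans %.2f s, calibration needs %g s", span, duration_s)
  }
  win <- rec[rec$t - t0 < duration_s - 1e-9, , drop = FALSE]
  if (is.null(win$left_gap) && is.null(win$right_gap)) {
    .stopf("calibration impossible: stream has no continuous eyelid-gap measurements")
  }
  top_mean <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) return(list(ref = NA_real_, n = 0L, k = 0L))
    k <- as.integer(ceiling(top_fraction * n))
    list(ref = mean(sort(v, decreasing = TRUE)[seq_len(k)]), n = n, k = k)
  }
  left <- top_mean(win$left_gap)
  right <- top_mean(win$right_gap)
  marr <- top_mean(win$mar)
  if (left$n == 0L && right$n == 0L) {
    .stopf("calibration impossible: no usable eyelid-gap values in the window")
  }
  thr <- mar_open_threshold
  if (mar_mode == "calibrated") {
    if (is.na(marr$ref)) .stopf("calibrated mar mode requested but no mar values in window")
    thr <- mar_ratio * marr$ref
  }
  structure(list(
    open_gap_ref_left = left$ref,
    open_gap_ref_right = right$ref,
    open_mar_ref = marr$ref,
    eye_closed_ratio = eye_closed_ratio,
    mar_open_threshold = thr,
    mar_mode = mar_mode,
    eye_combine = eye_combine,
    calibration_duration_s = duration_s,
    top_fraction = top_fraction,
    n_values = c(left_gap = left$n, right_gap = right$n, mar = marr$n),
    k_top = c(left_gap = left$k, right_gap = right$k, mar = marr$k)
  ), class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile>\n")
  cat(sprintf("  open gap refs: left %.4g, right %.4g (closed below %.0f%%)\n",
              x$open_gap_ref_left, x$open_gap_ref_right, 100 * x$eye_closed_ratio))
  cat(sprintf("  mar threshold: %.3g (%s mode)\n", x$mar_open_threshold, x$mar_mode))
  cat(sprintf("  calibrated on %d/%d/%d values (left/right/mar), top %g%% averaged\n",
              x$n_values[1], x$n_values[2], x$n_values[3], 100 * x$top_fraction))
  invisible(x)
}

.combine_eyes <- function(left_closed, right_closed, combine = "all") {
  if (combine == "all") left_closed & right_closed else left_closed | right_closed
}

#' Classify one frame's eye and mouth state
#'
#' Applies the personalized thresholds: a single eye counts as closed when its
#' gap falls below `eye_closed_ratio` times that eye's open reference (the 20%
#' rule by default); `eyes_closed` combines the two per-eye flags (`"all"` =
#' both closed, the default). The mouth counts as open when `mar` is strictly
#' greater than the mar threshold (0.7 by default). Records that already carry
#' binary states are passed through unchanged.
#'
#' @param rec a single frame: a list or one-row data.frame with the
#'   `state_stream` record fields.
#' @param profile a [calibrate()] profile (required for continuous records).
#' @return named logical vector `c(eyes_closed =, mouth_open =)`; elements may
#'   be `NA` when the underlying measurement is absent.
#' @export
classify_frame <- function(rec, profile = NULL) {
  rec <- as.list(rec)
  has_bin <- !is.null(rec$left_closed) && !is.null(rec$right_closed) &&
    !is.na(rec$left_closed) && !is.na(rec$right_closed)
  if (has_bin) {
    combine <- if (!is.null(profile)) profile$eye_combine else "all"
    mo <- if (is.null(rec$mouth_open)) NA else rec$mouth_open
    return(c(eyes_closed = .combine_eyes(rec$left_closed, rec$right_closed, combine),
             mouth_open = as.logical(mo)))
  }
  if (is.null(profile)) {
    .stopf("missing calibration: continuous record but no profile; run calibrate() first")
  }
  lc <- if (is.null(rec$left_gap) || is.na(rec$left_gap)) NA else
    rec$left_gap < profile$eye_closed_ratio * profile$open_gap_ref_left
  rc <- if (is.null(rec$right_gap) || is.na(rec$right_gap)) NA else
    rec$right_gap < profile$eye_closed_ratio * profile$open_gap_ref_right
  mo <- if (is.null(rec$mar) || is.na(rec$mar)) NA else
    rec$mar > profile$mar_open_threshold
  c(eyes_closed = .combine_eyes(lc, rc, profile$eye_combine), mouth_open = mo)
}

#' Binarize a facial-state stream
#'
#' Vectorized [classify_frame()]: fills `left_closed`, `right_closed` and
#' `mouth_open` on every record from the continuous measurements and the
#' profile. Idempotent on already-binarized streams.
#'
#' @param stream a `state_stream`.
#' @param profile a [calibrate()] profile; may be `NULL` for already-binarized
#'   streams.
#' @return a binarized `state_stream`.
#' @export
binarize_stream <- function(stream, profile = NULL) {
  stopifnot(inherits(stream, "state_stream"))
  if (is_binarized(stream)) return(stream)
  if (is.null(profile)) {
    .stopf("missing calibration: continuous stream but no profile; run calibrate() first")
  }
  rec <- stream$records
  lc <- if (is.null(rec$left_gap)) rep(NA, nrow(rec)) else
    rec$left_gap < profile$eye_closed_ratio * profile$open_gap_ref_left
  rc <- if (is.null(rec$right_gap)) rep(NA, nrow(rec)) else
    rec$right_gap < profile$eye_closed_ratio * profile$open_gap_ref_right
  mo <- if (is.null(rec$mar)) rep(NA, nrow(rec)) else
    rec$mar > profile$mar_open_threshold
  # already-binary cells (mixed streams) win over recomputation
  if (!is.null(rec$left_closed)) lc <- ifelse(is.na(rec$left_closed), lc, rec$left_closed)
  if (!is.null(rec$right_closed)) rc <- ifelse(is.na(rec$right_closed), rc, rec$right_closed)
  if (!is.null(rec$mouth_open)) mo <- ifelse(is.na(rec$mouth_open), mo, rec$mouth_open)
  rec$left_closed <- as.logical(lc)
  rec$right_closed <- as.logical(rc)
  rec$mouth_open <- as.logical(mo)
  out <- stream
  out$records <- rec
  out
}

#' Write / read a calibration profile
#'
#' Profiles are serialized as human-readable YAML key-value files.
#'
#' @param profile a `calibration_profile`.
#' @param path file path.
#' @return `write_profile`: `path` invisibly; `read_profile`: the profile.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  yaml::write_yaml(lapply(unclass(profile), function(v) {
    if (is.numeric(v) || is.integer(v)) as.list(unname(v)) else v
  })[c("open_gap_ref_left", "open_gap_ref_right", "open_mar_ref",
       "eye_closed_ratio", "mar_open_threshold", "mar_mode", "eye_combine",
       "calibration_duration_s", "top_fraction")], path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  y <- yaml::read_yaml(path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v[[1]] %||% v)
  structure(list(
    open_gap_ref_left = num(y$open_gap_ref_left),
    open_gap_ref_right = num(y$open_gap_ref_right),
    open_mar_ref = num(y$open_mar_ref),
    eye_closed_ratio = num(y$eye_closed_ratio),
    mar_open_threshold = num(y$mar_open_threshold),
    mar_mode = y$mar_mode %||% "fixed",
    eye_combine = y$eye_combine %||% "all",
    calibration_duration_s = num(y$calibration_duration_s),
    top_fraction = num(y$top_fraction),
    n_values = NULL, k_top = NULL
  ), class = "calibration_profile")
}
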