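# Synthetic facial-state stream generator with ground-truth labels.
#
# Eye closures and yawns are generated as independent alternating renewal
# (on/off) processes started in equilibrium: an event regime with rate r
# events/min and mean event duration m seconds has cycle length 60/r s, so the
# expected on-time fraction is exactly r * m / 60. Blink and sustained-closure
# processes are OR-ed, giving a closed-time fraction of
# 1 - (1 - f_blink)(1 - f_sustained).

#' Per-regime event process parameters
#'
#' @param blink_rate blinks per minute (short closures).
#' @param blink_duration_mean_s mean blink closure duration (s, exponential).
#' @param sustained_rate sustained (drowsy) eye closures per minute.
#' @param sustained_duration_mean_s mean sustained-closure duration (s,
#'   exponential).
#' @param yawn_rate yawns per minute.
#' @param yawn_duration_mean_s mean yawn (mouth-open) duration in seconds;
#'   drawn from a shape-4 gamma, since yawns are stereotyped events rather
#'   than memoryless ones.
#' @return object of class `regime_params`.
#' @export
regime_params <- function(blink_rate = 15, blink_duration_mean_s = 0.2,
                          sustained_rate = 0, sustained_duration_mean_s = 0,
                          yawn_rate = 0, yawn_duration_mean_s = 0) {
  p <- list(blink_rate = blink_rate,
            blink_duration_mean_s = blink_duration_mean_s,
            sustained_rate = sustained_rate,
            sustained_duration_mean_s = sustained_duration_mean_s,
            yawn_rate = yawn_rate,
            yawn_duration_mean_s = yawn_duration_mean_s)
  rates <- unlist(p[c(1, 3, 5)])
  if (any(rates < 0)) .stopf("event rates must be non-negative")
  if (any(unlist(p[c(2, 4, 6)]) < 0)) .stopf("mean durations must be non-negative")
  structure(p, class = "regime_params")
}

#' Default regime presets
#'
#' Presets for the three scripted drowsiness regimes, calibrated at design time
#' so that each regime's expected indicator triple falls inside the intended
#' terms of [default_fis_config()]:
#' * `Normal`: 15 blinks/min of 0.2 s; no sustained closures, no yawns
#'   (PERCLOS ~ 0.05, ECD ~ 0.2 s).
#' * `Drowsy`: slowed blinking (6/min of 0.3 s) plus 4 sustained closures/min
#'   of mean 3.5 s and 0.5 yawns/min of mean 6 s (PERCLOS ~ 0.26, ECD ~ 1.6 s).
#' * `Severe`: 2 blinks/min of 0.3 s plus 3 long closures/min of mean 18 s and
#'   2 yawns/min of mean 12 s (PERCLOS ~ 0.9, ECD ~ 10 s, AOT ~ 9 s).
#'
#' @return named list of [regime_params()].
#' @export
regime_presets <- function() {
  list(
    Normal = regime_params(blink_rate = 15, blink_duration_mean_s = 0.2),
    Drowsy = regime_params(blink_rate = 6, blink_duration_mean_s = 0.3,
                           sustained_rate = 4, sustained_duration_mean_s = 3.5,
                           yawn_rate = 0.5, yawn_duration_mean_s = 6),
    Severe = regime_params(blink_rate = 2, blink_duration_mean_s = 0.3,
                           sustained_rate = 3, sustained_duration_mean_s = 18,
                           yawn_rate = 2, yawn_duration_mean_s = 12)
  )
}

#' Default segment plan
#'
#' Contiguous blocks of approximately one-minute segments in the proportions
#' 100 Normal / 60 Drowsy / 40 Severe, emulating a scripted session in which
#' fatigue accumulates over the drive.
#'
#' @param normal,drowsy,severe segment counts per regime.
#' @param segment_s segment duration in seconds (default 60).
#' @return data.frame with columns `label`, `duration_s`.
#' @export
default_plan <- function(normal = 100, drowsy = 60, severe = 40, segment_s = 60) {
  data.frame(
    label = rep(c("Normal", "Drowsy", "Severe"), times = c(normal, drowsy, severe)),
    duration_s = segment_s,
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters
#'
#' @param plan ordered data.frame of segments with columns `label` (a regime
#'   name) and `duration_s`.
#' @param fps frames per second (default 30).
#' @param seed integer seed; all stochastic draws come from one seeded
#'   generator in a fixed order, so runs are reproducible.
#' @param regimes named list of [regime_params()], one per label used in the
#'   plan (default [regime_presets()]).
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(plan = default_plan(), fps = 30, seed = NULL,
                              regimes = regime_presets()) {
  plan <- as.data.frame(plan)
  if (!all(c("label", "duration_s") %in% names(plan))) {
    .stopf("plan needs columns 'label' and 'duration_s'")
  }
  if (nrow(plan) == 0L) .stopf("empty segment plan")
  if (any(plan$duration_s <= 0)) .stopf("segment durations must be positive")
  missing <- setdiff(unique(plan$label), names(regimes))
  if (length(missing)) {
    .stopf("plan labels without a regime definition: %s", paste(missing, collapse = ", "))
  }
  if (fps <= 0) .stopf("fps must be positive")
  structure(list(plan = plan, fps = fps, seed = seed, regimes = regimes),
            class = "simulation_params")
}

# One equilibrium alternating on/off process over [0, duration_s).
# rate is events per minute, mean_s the mean on-duration; rdur draws on-times.
# Returns a matrix of on-intervals (start, end), clipped to the segment.
.sample_onoff <- function(duration_s, rate, mean_s, rdur = NULL) {
  if (rate <= 0 || mean_s <= 0) return(cbind(start = numeric(0), end = numeric(0)))
  cycle <- 60 / rate
  mean_off <- cycle - mean_s
  if (mean_off <= 0) {  # saturated regime: permanently on
    return(cbind(start = 0, end = duration_s))
  }
  if (is.null(rdur)) rdur <- function(n) rexp(n, rate = 1 / mean_s)
  f <- mean_s / cycle
  starts <- numeric(0); ends <- numeric(0)
  t <- 0
  on <- runif(1) < f  # equilibrium initial state
  repeat {
    if (on) {
      d <- rdur(1)
      starts <- c(starts, t)
      ends <- c(ends, min(t + d, duration_s))
      t <- t + d
      on <- FALSE
    } else {
      t <- t + rexp(1, rate = 1 / mean_off)
      on <- TRUE
    }
    if (t >= duration_s) break
  }
  cbind(start = starts, end = ends)
}

# merge overlapping intervals; ints is a (start, end) matrix
.merge_intervals <- function(ints) {
  if (nrow(ints) <= 1L) return(ints)
  o <- order(ints[, 1])
  s <- ints[o, 1]; e <- ints[o, 2]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# TRUE for frame times covered by any interval
.cover <- function(tf, ints) {
  if (nrow(ints) == 0L) return(rep(FALSE, length(tf)))
  ints <- .merge_intervals(ints)
  idx <- findInterval(tf, ints[, 1])
  idx > 0 & tf < ints[cbind(pmax(idx, 1L), 2L)] + 1e-12
}

#' Simulate a labelled facial-state stream
#'
#' Renders the segment plan to a per-frame binarized stream: per segment, eye
#' closures arise from a blink process and a sustained-closure process (both
#' equilibrium alternating renewal with exponential closure lengths, OR-ed
#' together) and yawns from an independent renewal process with gamma
#' durations. Both eyes close together. Ground truth is a per-second label
#' track covering the full stream duration.
#'
#' @param params a [simulation_params()].
#' @return object of class `labeled_stream`: list with `stream` (a binarized
#'   [state_stream()]) and `truth` (data.frame `t`, `label`; `t` is the end of
#'   each one-second tick).
#' @export
simulate_stream <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  plan <- params$plan
  fps <- params$fps
  offsets <- cumsum(c(0, plan$duration_s))
  total <- offsets[length(offsets)]
  closed_ints <- list(); yawn_ints <- list()
  for (i in seq_len(nrow(plan))) {
    rg <- params$regimes[[plan$label[i]]]
    d <- plan$duration_s[i]
    blink <- .sample_onoff(d, rg$blink_rate, rg$blink_duration_mean_s)
    sust <- .sample_onoff(d, rg$sustained_rate, rg$sustained_duration_mean_s)
    yd <- rg$yawn_duration_mean_s
    yawn <- .sample_onoff(d, rg$yawn_rate, yd,
                          rdur = function(n) rgamma(n, shape = 4, scale = yd / 4))
    closed_ints[[i]] <- rbind(blink, sust) + offsets[i]
    yawn_ints[[i]] <- yawn + offsets[i]
  }
  closed_ints <- do.call(rbind, closed_ints)
  yawn_ints <- do.call(rbind, yawn_ints)
  n <- round(total * fps)
  tf <- (seq_len(n) - 1L) / fps
  closed <- .cover(tf, closed_ints)
  mouth <- .cover(tf, yawn_ints)
  seg_of <- findInterval(seq_len(floor(total)) - 0.5, offsets)
  truth <- data.frame(t = seq_len(floor(total)),
                      label = plan$label[seg_of],
                      stringsAsFactors = FALSE)
  stream <- state_stream(
    data.frame(t = tf, left_closed = closed, right_closed = closed,
               mouth_open = mouth),
    nominal_fps = fps,
    meta = list(source = "simulate_stream", seed = params$seed)
  )
  structure(list(stream = stream, truth = truth, params = params),
            class = "labeled_stream")
}

#' @export
print.labeled_stream <- function(x, ...) {
  cat("<labeled_stream>\n")
  print(x$stream)
  tab <- table(x$truth$label)
  cat("  truth seconds:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Expected stationary PERCLOS of a regime
#'
#' Analytic closed-time fraction of the generating process: the blink and
#' sustained-closure components each occupy an expected fraction
#' `rate * mean_duration / 60` of the time (saturating at 1 when the mean
#' duration fills the whole cycle); since the two processes are independent
#' and OR-ed, the expected PERCLOS is `1 - (1 - f_blink)(1 - f_sustained)`.
#'
#' @param regime a [regime_params()].
#' @return expected PERCLOS fraction in `[0, 1]`.
#' @export
expected_perclos <- function(regime) {
  stopifnot(inherits(regime, "regime_params"))
  frac <- function(rate, mean_s) {
    if (rate <= 0 || mean_s <= 0) return(0)
    min(1, rate * mean_s / 60)
  }
  fb <- frac(regime$blink_rate, regime$blink_duration_mean_s)
  fs <- frac(regime$sustained_rate, regime$sustained_duration_mean_s)
  1 - (1 - fb) * (1 - fs)
}

#' Render continuous gap/mar signals onto a binary stream
#'
#' Turns a binarized stream into continuous eyelid-gap and mouth-aspect-ratio
#' measurements so the calibration path can be exercised end to end: open
#' frames get a gap around the open reference, closed frames a gap around
#' `closed_gap_frac` of it, the mouth sits above/below the mar threshold, all
#' with optional Gaussian noise. With `noise_frac = 0` the generating binary
#' track is exactly recoverable by [classify_frame()] with the corresponding
#' profile.
#'
#' @param stream a binarized `state_stream`.
#' @param open_gap_left,open_gap_right open-eye reference gaps (image units).
#' @param closed_gap_frac closed-frame gap as a fraction of the reference
#'   (default 0.1, inside the 5-15% band of visibly shut lids).
#' @param mar_open,mar_closed mar values rendered for open / closed mouth.
#' @param noise_frac Gaussian noise s.d. as a fraction of each signal's
#'   reference (default 0).
#' @param seed optional seed for the noise draws.
#' @param keep_states keep the binary columns alongside the continuous ones
#'   (default `FALSE`: the result is a purely continuous stream).
#' @return a `state_stream` with `left_gap`, `right_gap`, `mar`.
#' @export
render_continuous <- function(stream, open_gap_left = 12, open_gap_right = 12,
                              closed_gap_frac = 0.1, mar_open = 1.0,
                              mar_closed = 0.25, noise_frac = 0, seed = NULL,
                              keep_states = FALSE) {
  stopifnot(inherits(stream, "state_stream"))
  if (!is_binarized(stream)) .stopf("render_continuous needs a binarized stream")
  if (!is.null(seed)) set.seed(seed)
  rec <- stream$records
  n <- nrow(rec)
  noise <- function(ref) if (noise_frac > 0) rnorm(n, 0, noise_frac * ref) else 0
  lg <- ifelse(rec$left_closed, closed_gap_frac * open_gap_left, open_gap_left)
  rg <- ifelse(rec$right_closed, closed_gap_frac * open_gap_right, open_gap_right)
  mr <- ifelse(rec$mouth_open, mar_open, mar_closed)
  rec$left_gap <- pmax(0, lg + noise(open_gap_left))
  rec$right_gap <- pmax(0, rg + noise(open_gap_right))
  rec$mar <- pmax(0, mr + noise(mar_open))
  if (!keep_states) {
    rec$left_closed <- NULL; rec$right_closed <- NULL; rec$mouth_open <- NULL
  }
  out <- stream
  out$records <- rec
  out
}
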