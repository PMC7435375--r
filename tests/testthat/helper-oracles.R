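.levels_test <- c("Low", "Medium", "High")

# Independent brute-force oracles used to cross-check the indicator stage.
# Deliberately written as explicit per-frame scans: they share no code with
# the package implementation.

oracle_run_durations <- function(flags, frame_period) {
  flags[is.na(flags)] <- FALSE
  durations <- numeric(0)
  count <- 0L
  for (f in flags) {
    if (f) {
      count <- count + 1L
    } else if (count > 0L) {
      durations <- c(durations, count * frame_period)
      count <- 0L
    }
  }
  if (count > 0L) durations <- c(durations, count * frame_period)
  durations
}

oracle_perclos <- function(flags) {
  n <- 0L; closed <- 0L
  for (f in flags) {
    n <- n + 1L
    if (isTRUE(f)) closed <- closed + 1L
  }
  closed / n
}

oracle_ecd <- function(flags, frame_period) {
  d <- oracle_run_durations(flags, frame_period)
  if (length(d) == 0L) 0 else mean(d)
}

oracle_yawns <- function(flags, frame_period, yawn_min_s = 3) {
  d <- oracle_run_durations(flags, frame_period)
  d <- d[d > yawn_min_s + 1e-12]
  d - yawn_min_s
}

oracle_aot <- function(flags, frame_period, yawn_min_s = 3) {
  d <- oracle_yawns(flags, frame_period, yawn_min_s)
  if (length(d) == 0L) 0 else mean(d)
}

# naive per-window recomputation of the sliding indicator series
oracle_sliding <- function(stream, cfg = window_config(), eye_combine = "all") {
  rec <- stream$records
  fps <- stream$nominal_fps
  t <- rec$t - rec$t[1]
  fp <- 1 / fps
  duration <- t[length(t)] + fp
  closed <- if (eye_combine == "all") {
    rec$left_closed & rec$right_closed
  } else {
    rec$left_closed | rec$right_closed
  }
  closed[is.na(closed)] <- FALSE
  mouth <- rec$mouth_open
  mouth[is.na(mouth)] <- FALSE
  eps <- 1e-9
  t_emit <- seq(cfg$window_s, duration + eps, by = cfg$stride_s)
  t_emit <- t_emit[t_emit <= duration + eps]
  rows <- lapply(t_emit, function(te) {
    sel <- t > te - cfg$window_s - eps & t < te - eps
    cw <- closed[sel]; mw <- mouth[sel]
    cd <- oracle_run_durations(cw, fp)
    yd <- oracle_yawns(mw, fp, cfg$yawn_min_s)
    data.frame(t = te + rec$t[1], perclos = oracle_perclos(cw),
               ecd = if (length(cd)) mean(cd) else 0,
               aot = if (length(yd)) mean(yd) else 0,
               n_frames = sum(sel), p_intervals = length(cd),
               n_yawns = length(yd))
  })
  do.call(rbind, rows)
}

# quick binarized stream from flag vectors
make_binary_stream <- function(closed, mouth = rep(FALSE, length(closed)), fps = 30) {
  state_stream(
    data.frame(t = (seq_along(closed) - 1) / fps,
               left_closed = closed, right_closed = closed, mouth_open = mouth),
    nominal_fps = fps
  )
}

# landmark template used by the geometry tests: upright schematic layout
make_landmarks <- function(gap_right = 6, gap_left = 6, mouth_h = 7, mouth_w = 10) {
  pts <- matrix(0, 68, 2)
  pts[, 1] <- rep(seq(10, 77, length.out = 68))  # arbitrary distinct finite coords
  pts[, 2] <- 50
  set_pair <- function(pts, iu, il, x, y, gap) {
    pts[iu, ] <- c(x, y - gap / 2)
    pts[il, ] <- c(x, y + gap / 2)
    pts
  }
  # right eye pairs (38,42), (39,41) at x = 30, 34; left eye at x = 60, 64
  pts <- set_pair(pts, 38, 42, 30, 40, gap_right)
  pts <- set_pair(pts, 39, 41, 34, 40, gap_right)
  pts[37, ] <- c(27, 40); pts[40, ] <- c(37, 40)
  pts <- set_pair(pts, 44, 48, 60, 40, gap_left)
  pts <- set_pair(pts, 45, 47, 64, 40, gap_left)
  pts[43, ] <- c(57, 40); pts[46, ] <- c(67, 40)
  # inner lip: corners 61/65, height pairs (62,68), (63,67), (64,66)
  pts[61, ] <- c(45 - mouth_w / 2, 70); pts[65, ] <- c(45 + mouth_w / 2, 70)
  pts <- set_pair(pts, 62, 68, 42, 70, mouth_h)
  pts <- set_pair(pts, 63, 67, 45, 70, mouth_h)
  pts <- set_pair(pts, 64, 66, 48, 70, mouth_h)
  landmark_set(pts)
}
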