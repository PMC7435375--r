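# 68-point facial-landmark frontend: geometric eyelid-gap / mouth-aspect-ratio
# extraction, a schematic-face detector for synthetic frames, and conversion of
# frame sequences to state streams.
#
# Landmark indexing follows the 1-based iBUG 300-W convention: 1-17 jaw,
# 18-27 brows, 28-36 nose, 37-42 right eye, 43-48 left eye, 49-60 outer lip,
# 61-68 inner lip ("right"/"left" are the subject's, i.e. right eye appears on
# the image's left for a frontal face).

.right_eye_pairs <- rbind(c(38L, 42L), c(39L, 41L))
.left_eye_pairs  <- rbind(c(44L, 48L), c(45L, 47L))
.mouth_height_pairs <- rbind(c(62L, 68L), c(63L, 67L), c(64L, 66L))
.mouth_width_idx <- c(61L, 65L)

#' Construct a 68-point landmark set
#'
#' @param points 68 x 2 numeric matrix of (x, y) pixel coordinates in iBUG
#'   order; y grows downward (image rows).
#' @return object of class `landmark_set` (the matrix, with columns `x`, `y`).
#' @export
landmark_set <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L) {
    .stopf("a landmark set is a 68 x 2 numeric matrix, got %s x %s",
           nrow(points), ncol(points))
  }
  if (any(!is.finite(points))) .stopf("landmark coordinates must be finite")
  colnames(points) <- c("x", "y")
  structure(points, class = c("landmark_set", class(points)))
}

.pair_dist <- function(lm, pairs) {
  d <- sqrt((lm[pairs[, 1], 1] - lm[pairs[, 2], 1])^2 +
            (lm[pairs[, 1], 2] - lm[pairs[, 2], 2])^2)
  mean(d)
}

#' Eyelid gap from landmarks
#'
#' The space between eyelids: the mean of the two upper/lower lid landmark-pair
#' distances. The right eye uses pairs (38,42) and (39,41), the left eye
#' (44,48) and (45,47). For an upright face these pairs are vertically aligned,
#' so the value equals the mean vertical lid distance; the Euclidean form is
#' additionally invariant under in-plane rotation.
#'
#' @param lm a [landmark_set()].
#' @param side `"left"` or `"right"` (the subject's side).
#' @return gap in pixels (>= 0).
#' @export
eyelid_gap <- function(lm, side = c("left", "right")) {
  stopifnot(inherits(lm, "landmark_set"))
  side <- match.arg(side)
  pairs <- if (side == "right") .right_eye_pairs else .left_eye_pairs
  .pair_dist(lm, pairs)
}

#' Mouth aspect ratio from landmarks
#'
#' `mar = Height / Width`: Height is the mean distance of the inner-lip pairs
#' (62,68), (63,67), (64,66); Width is the distance between the inner mouth
#' corners 61 and 65. Dimensionless, hence invariant under uniform scaling.
#'
#' @param lm a [landmark_set()].
#' @return mar (>= 0).
#' @export
mouth_aspect_ratio <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  w <- sqrt(sum((lm[.mouth_width_idx[1], ] - lm[.mouth_width_idx[2], ])^2))
  if (w <= .Machine$double.eps^0.5) .stopf("degenerate landmarks: mouth width is zero")
  .pair_dist(lm, .mouth_height_pairs) / w
}

#' Render a schematic face frame
#'
#' Draws the synthetic grayscale face the `schematic` backend of
#' [detect_landmarks()] understands: a bright face ellipse on a dark
#' background, with dark eye and mouth ellipses whose vertical extent encodes
#' eye openness and mouth opening. Used to exercise the image-to-landmarks
#' path without a camera.
#'
#' @param eye_openness openness in `[0, 1]`; length 1 (both eyes) or 2
#'   (right, left). 0 renders closed eyes.
#' @param mouth_openness opening in `[0, 1]`; 0 renders a closed mouth.
#' @param width,height frame size in pixels.
#' @param center face centre `(x, y)`; defaults to the frame centre.
#' @return `height` x `width` numeric matrix with values in `[0, 1]`.
#' @export
render_face_frame <- function(eye_openness = 1, mouth_openness = 0,
                              width = 160L, height = 120L, center = NULL) {
  if (length(eye_openness) == 1L) eye_openness <- rep(eye_openness, 2L)
  center <- center %||% c(width / 2, height / 2)
  rx <- 0.28 * width
  ry <- 0.44 * height
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  img <- matrix(0.05, height, width)
  inside <- function(cx, cy, ax, ay) {
    ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
  }
  img[inside(center[1], center[2], rx, ry)] <- 0.85
  eye_cx <- center[1] + c(-0.45, 0.45) * rx  # right eye on image left
  eye_cy <- center[2] - 0.30 * ry
  for (k in 1:2) {
    hh <- eye_openness[k] * 0.12 * ry
    if (hh >= 0.5) img[inside(eye_cx[k], eye_cy, 0.20 * rx, hh)] <- 0.10
  }
  mh <- mouth_openness * 0.24 * ry
  if (mh >= 0.5) {
    img[inside(center[1], center[2] + 0.45 * ry, 0.28 * rx, mh)] <- 0.10
  }
  img
}

# Extract upper/lower lid (or lip) sample points from a dark feature region.
# cols_frac: fractions of the feature width at which to sample columns.
.feature_points <- function(dark, x0, y0, x1, y1, cols_frac, fallback_y, fallback_xs) {
  sub <- dark[y0:y1, x0:x1, drop = FALSE]
  if (!any(sub)) {
    return(list(found = FALSE,
                xs = fallback_xs, upper = rep(fallback_y, length(cols_frac)),
                lower = rep(fallback_y, length(cols_frac)),
                corners = cbind(range(fallback_xs), c(fallback_y, fallback_y))))
  }
  cs <- which(colSums(sub) > 0)
  rs <- which(rowSums(sub) > 0)
  cl <- min(cs); cr <- max(cs)
  xs <- round(cl + cols_frac * (cr - cl))
  upper <- numeric(length(xs)); lower <- numeric(length(xs))
  for (i in seq_along(xs)) {
    col <- sub[, xs[i]]
    if (!any(col)) {  # nearest non-empty column
      xs[i] <- cs[which.min(abs(cs - xs[i]))]
      col <- sub[, xs[i]]
    }
    upper[i] <- min(which(col))
    lower[i] <- max(which(col))
  }
  mid <- (min(rs) + max(rs)) / 2
  list(found = TRUE,
       xs = xs + x0 - 1,
       upper = upper + y0 - 1, lower = lower + y0 - 1,
       corners = cbind(c(cl, cr) + x0 - 1, c(mid, mid) + y0 - 1))
}

.schematic_landmarks <- function(image, min_face_px = 100L) {
  mask <- image > 0.5
  if (sum(mask) < min_face_px) return(NULL)
  rs <- which(rowSums(mask) > 0)
  cs <- which(colSums(mask) > 0)
  top <- min(rs); bottom <- max(rs); left <- min(cs); right <- max(cs)
  h <- bottom - top; w <- right - left
  cx <- (left + right) / 2; cy <- (top + bottom) / 2
  # features are dark holes inside the face ellipse (not the bbox corners,
  # which are background)
  xs <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  ys <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  inface <- ((xs - cx) / (0.95 * w / 2))^2 + ((ys - cy) / (0.95 * h / 2))^2 <= 1
  dark <- image < 0.3 & inface

  eye_band_y <- c(top, round(top + 0.5 * h))
  eyeline <- round(top + 0.31 * h)
  r_eye <- .feature_points(dark, left, eye_band_y[1], round(cx), eye_band_y[2],
                           c(0.35, 0.65), eyeline,
                           round(cx - c(0.55, 0.35) * w / 2))
  l_eye <- .feature_points(dark, round(cx), eye_band_y[1], right, eye_band_y[2],
                           c(0.35, 0.65), eyeline,
                           round(cx + c(0.35, 0.55) * w / 2))
  mouthline <- round(top + 0.80 * h)
  mouth <- .feature_points(dark, round(cx - 0.35 * w), round(top + 0.55 * h),
                           round(cx + 0.35 * w), bottom,
                           c(0.25, 0.5, 0.75), mouthline,
                           round(cx + c(-0.2, 0, 0.2) * w / 2))

  pts <- matrix(NA_real_, 68, 2)
  # jaw 1-17: lower face ellipse arc, subject-right to subject-left
  ang <- seq(0, pi, length.out = 17)
  pts[1:17, 1] <- cx - (w / 2 - 1) * cos(ang)
  pts[1:17, 2] <- pmin(cy + (h / 2 - 1) * sin(ang), bottom)
  # brows 18-22 / 23-27: above each eye
  brow_y <- top + 0.18 * h
  pts[18:22, ] <- cbind(seq(left + 0.12 * w, cx - 0.08 * w, length.out = 5), brow_y)
  pts[23:27, ] <- cbind(seq(cx + 0.08 * w, right - 0.12 * w, length.out = 5), brow_y)
  # nose 28-36
  pts[28:31, ] <- cbind(cx, seq(top + 0.35 * h, top + 0.55 * h, length.out = 4))
  pts[32:36, ] <- cbind(seq(cx - 0.08 * w, cx + 0.08 * w, length.out = 5), top + 0.58 * h)
  # right eye 37-42: corners 37/40, upper lid 38/39, lower lid 41/42
  pts[37, ] <- r_eye$corners[1, ]; pts[40, ] <- r_eye$corners[2, ]
  pts[38, ] <- c(r_eye$xs[1], r_eye$upper[1]); pts[39, ] <- c(r_eye$xs[2], r_eye$upper[2])
  pts[41, ] <- c(r_eye$xs[2], r_eye$lower[2]); pts[42, ] <- c(r_eye$xs[1], r_eye$lower[1])
  # left eye 43-48
  pts[43, ] <- l_eye$corners[1, ]; pts[46, ] <- l_eye$corners[2, ]
  pts[44, ] <- c(l_eye$xs[1], l_eye$upper[1]); pts[45, ] <- c(l_eye$xs[2], l_eye$upper[2])
  pts[47, ] <- c(l_eye$xs[2], l_eye$lower[2]); pts[48, ] <- c(l_eye$xs[1], l_eye$lower[1])
  # outer lip 49-60: rectangle-ish ring around the mouth region
  mx <- mouth$corners[, 1]; myc <- mean(c(mouth$upper, mouth$lower))
  mw2 <- max((mx[2] - mx[1]) / 2 + 2, 0.12 * w)
  mh2 <- max((max(mouth$lower) - min(mouth$upper)) / 2 + 2, 0.03 * h)
  mcx <- mean(mx)
  thm <- seq(0, 2 * pi, length.out = 13)[-13]
  pts[49:60, ] <- cbind(mcx - mw2 * cos(thm), myc + mh2 * sin(thm))
  # inner lip 61-68: corners 61/65, upper 62-64 (l->r), lower 66-68 (r->l)
  pts[61, ] <- c(mx[1], myc); pts[65, ] <- c(mx[2], myc)
  pts[62, ] <- c(mouth$xs[1], mouth$upper[1])
  pts[63, ] <- c(mouth$xs[2], mouth$upper[2])
  pts[64, ] <- c(mouth$xs[3], mouth$upper[3])
  pts[66, ] <- c(mouth$xs[3], mouth$lower[3])
  pts[67, ] <- c(mouth$xs[2], mouth$lower[2])
  pts[68, ] <- c(mouth$xs[1], mouth$lower[1])
  landmark_set(pts)
}

#' Detect facial landmarks in a frame
#'
#' Locates the largest face in a grayscale frame and returns its 68 landmarks,
#' or `NULL` when no face is found.
#'
#' Backends: `"schematic"` (implemented here) detects the bright face ellipse
#' of frames produced by [render_face_frame()] by intensity thresholding and
#' reads lid and lip positions from the dark feature regions. The `"haar"`
#' (cascade classifier on Haar-like features) and `"hog"` (linear SVM on HOG
#' features) backends consume pretrained detector and landmark-regressor model
#' assets that are not distributed with this package; calling them without a
#' valid `model_path` raises a configuration error naming the expected asset.
#'
#' @param image grayscale numeric matrix, values in `[0, 1]` (rows = y).
#' @param backend `"schematic"`, `"haar"` or `"hog"`.
#' @param model_path path to pretrained model assets (haar/hog only).
#' @param min_face_px minimum number of face pixels for a detection.
#' @return a [landmark_set()] or `NULL`.
#' @export
detect_landmarks <- function(image, backend = c("schematic", "haar", "hog"),
                             model_path = NULL, min_face_px = 100L) {
  backend <- match.arg(backend)
  if (backend != "schematic") {
    asset <- c(haar = "haarcascade_frontalface_default.xml (pretrained Haar cascade)",
               hog = "dlib HOG face detector + 68-point shape predictor (.dat)")[[backend]]
    if (is.null(model_path) || !file.exists(model_path)) {
      .stopf(paste0("configuration error: backend '%s' requires a pretrained ",
                    "model asset (%s); expected at model_path = %s"),
             backend, asset, model_path %||% "<unset>")
    }
    .stopf("backend '%s' has no runtime binding in this build; use 'schematic'",
           backend)
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    .stopf("image must be a numeric matrix (grayscale)")
  }
  .schematic_landmarks(image, min_face_px = min_face_px)
}

.read_frame <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.character(x)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      .stopf("reading PNG frames requires the 'png' package")
    }
    a <- png::readPNG(x)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
    return(a)
  }
  .stopf("frames must be numeric matrices or PNG file paths")
}

#' Convert a frame sequence to a facial-state stream
#'
#' Runs [detect_landmarks()] on each frame and extracts per-frame eyelid gaps
#' and mouth aspect ratio. Frames in which no face is detected yield records
#' with absent measurements. Video-container decoding is outside this package;
#' supply the frames as a list of grayscale matrices or PNG file paths.
#'
#' @param frames list of grayscale matrices, or character vector of PNG paths.
#' @param fps native frame rate of the sequence.
#' @param backend landmark backend, see [detect_landmarks()].
#' @param sample_fps optional processing rate; frames are subsampled by
#'   `round(fps / sample_fps)`.
#' @param rescale optional detection-stage reduction factor in `(0, 1]`
#'   (speed strategy): detection runs on the reduced image and coordinates are
#'   rescaled back to the original resolution. Default 1 (off).
#' @return a [state_stream()] with `left_gap`, `right_gap`, `mar`.
#' @export
video_to_stream <- function(frames, fps = 30, backend = "schematic",
                            sample_fps = NULL, rescale = 1) {
  if (is.character(frames)) frames <- as.list(frames)
  n <- length(frames)
  if (n == 0L) .stopf("empty stream: no frames")
  step <- if (is.null(sample_fps)) 1L else max(1L, round(fps / sample_fps))
  idx <- seq(1L, n, by = step)
  recs <- data.frame(t = (idx - 1L) / fps,
                     left_gap = NA_real_, right_gap = NA_real_, mar = NA_real_)
  for (k in seq_along(idx)) {
    img <- .read_frame(frames[[idx[k]]])
    if (rescale < 1) {
      small <- img[seq(1, nrow(img), by = round(1 / rescale)),
                   seq(1, ncol(img), by = round(1 / rescale)), drop = FALSE]
      lm <- detect_landmarks(small, backend)
      if (!is.null(lm)) {
        sc <- c(ncol(img) / ncol(small), nrow(img) / nrow(small))
        lm <- landmark_set(sweep(unclass(lm), 2, sc, `*`))
      }
    } else {
      lm <- detect_landmarks(img, backend)
    }
    if (is.null(lm)) next
    recs$left_gap[k] <- eyelid_gap(lm, "left")
    recs$right_gap[k] <- eyelid_gap(lm, "right")
    recs$mar[k] <- tryCatch(mouth_aspect_ratio(lm), error = function(e) NA_real_)
  }
  suppressWarnings(state_stream(recs, nominal_fps = fps / step,
                                meta = list(source = "video_to_stream", backend = backend)))
}
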