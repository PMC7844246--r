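# Background subtraction to 1-bit silhouette masks and extraction of the six
# fall parameters H_i, W_i, theta_i, V_i, a_i, Delta-T from a tracked subject.

#' Background subtraction to 1-bit silhouette masks
#'
#' Estimates a static background as the per-pixel temporal median of the
#' background window, thresholds the absolute difference of every frame
#' against it, and cleans the binary masks with a 3x3 morphological open
#' followed by close. This reduces the pixel depth from 24-bit grayscale to
#' the 1-bit silhouettes from which all fall parameters are measured.
#'
#' @param frames list of grayscale matrices in \[0, 1\] (all same size).
#' @param background_window indices of frames to build the background model
#'   from (default: the first frame; for synthetic clips, any frames of the
#'   background section).
#' @param threshold absolute intensity difference above which a pixel is
#'   foreground; default 25/255.
#' @param cleanup apply the 3x3 open/close cleanup?
#' @return list of 0/1 integer matrices (class `silhouette_masks`, with the
#'   background model as attribute `background`).
#' @export
subtract_background <- function(frames, background_window = 1L,
                                threshold = 25 / 255, cleanup = TRUE) {
  if (length(frames) == 0) stop("empty frame sequence")
  stopifnot(all(vapply(frames, is.matrix, TRUE)))
  bgf <- frames[background_window]
  if (length(bgf) == 0) stop("background window selects no frames")
  bg <- if (length(bgf) == 1) bgf[[1]] else {
    arr <- array(unlist(bgf), dim = c(dim(bgf[[1]]), length(bgf)))
    apply(arr, c(1, 2), median)
  }
  kern <- matrix(1, 3, 3)
  masks <- lapply(frames, function(f) {
    m <- (abs(f - bg) > threshold) * 1
    if (cleanup && any(m > 0)) {
      m <- EBImage::closing(EBImage::opening(m, kern), kern)
      m <- (m > 0.5) * 1
    }
    storage.mode(m) <- "integer"
    m
  })
  structure(masks, class = "silhouette_masks", background = bg)
}

#' Apparent height and width of a silhouette within a box
#'
#' `H_i` is the vertical extent (pixels) of foreground inside the box —
#' from the ground contact to the vertex of the head — and `W_i` the
#' horizontal extent.
#'
#' @param mask a 0/1 matrix.
#' @param box `c(x0, y0, x1, y1)` half-open pixel box; `NULL` = whole mask.
#' @return `c(H = , W = )`, or `NULL` if the box holds no foreground (the
#'   caller interpolates or drops the frame).
#' @export
measure_silhouette <- function(mask, box = NULL) {
  h <- nrow(mask); w <- ncol(mask)
  if (is.null(box)) box <- c(0, 0, w, h)
  if (box[1] < 0 || box[2] < 0 || box[3] > w || box[4] > h)
    stop("box outside mask bounds")
  ii <- (floor(box[2]) + 1):max(floor(box[2]) + 1, ceiling(box[4]))
  jj <- (floor(box[1]) + 1):max(floor(box[1]) + 1, ceiling(box[3]))
  sub <- mask[ii, jj, drop = FALSE]
  rows <- which(rowSums(sub) > 0)
  if (length(rows) == 0) return(NULL)
  cols <- which(colSums(sub) > 0)
  out <- c(H = max(rows) - min(rows) + 1, W = max(cols) - min(cols) + 1)
  # tight silhouette box in absolute frame coordinates (half-open)
  attr(out, "box") <- c(x0 = jj[min(cols)] - 1, y0 = ii[min(rows)] - 1,
                        x1 = jj[max(cols)], y1 = ii[max(rows)])
  out
}

#' Tilt angle from the apparent-height ratio
#'
#' The body is modeled as a rigid rod of reference length `H_0`; at tilt
#' `theta` above the ground its apparent height is `H_0 * sin(theta)`, so
#' `theta_i = asin(H_i / H_0)`: 90 degrees upright, 0 flat on the ground.
#'
#' @param H_i apparent height (pixels, >= 0); values above `H_0` are clipped.
#' @param H_0 reference upright height (> 0).
#' @return tilt angle in degrees.
#' @examples
#' tilt_angle(90, 180)  # 30
#' @export
tilt_angle <- function(H_i, H_0) {
  if (!is.numeric(H_0) || any(H_0 <= 0)) stop("H_0 must be > 0")
  asin(pmin(1, pmax(0, H_i / H_0))) * 180 / pi
}

#' Normalized descent velocity between two frames
#'
#' `V_i = (H_{i-1} - H_i) / (H_0 * (T_i - T_{i-1}))`, in 1/seconds; positive
#' while the apparent height is falling. Dividing by `H_0` normalizes away
#' the camera-to-subject distance.
#'
#' @param H_prev,H_curr apparent heights at the previous / current frame.
#' @param T_prev,T_curr timestamps in seconds, `T_curr > T_prev`.
#' @param H_0 reference upright height (> 0).
#' @return velocity in 1/s.
#' @examples
#' fall_velocity(180, 162, 0, 0.1, 180)  # 1
#' @export
fall_velocity <- function(H_prev, H_curr, T_prev, T_curr, H_0) {
  if (any(H_0 <= 0)) stop("H_0 must be > 0")
  if (any(T_curr <= T_prev)) stop("timestamps must be strictly increasing")
  (H_prev - H_curr) / (H_0 * (T_curr - T_prev))
}

#' Normalized descent acceleration over three frames
#'
#' The general form divides the velocity change by the centered interval
#' `(T_i - T_{i-2}) / 2`:
#' \deqn{a_i = (V_i - V_{i-1}) / ((T_i - T_{i-2})/2).}
#' With uniform frame spacing `dT` this reduces algebraically to
#' `(2 H_{i-1} - (H_i + H_{i-2})) / (dT^2 * H_0)`, which
#' [fall_acceleration_uniform()] computes directly.
#'
#' @param H_pp,H_p,H_c heights at frames i-2, i-1, i.
#' @param T_pp,T_p,T_c strictly increasing timestamps (s).
#' @param H_0 reference upright height (> 0).
#' @return acceleration in 1/s^2.
#' @examples
#' fall_acceleration(100, 90, 70, 0, 0.1, 0.2, 100)  # 10
#' @export
fall_acceleration <- function(H_pp, H_p, H_c, T_pp, T_p, T_c, H_0) {
  if (any(H_0 <= 0)) stop("H_0 must be > 0")
  if (any(T_c <= T_p) || any(T_p <= T_pp))
    stop("timestamps must be strictly increasing")
  v_i <- (H_p - H_c) / (H_0 * (T_c - T_p))
  v_im1 <- (H_pp - H_p) / (H_0 * (T_p - T_pp))
  (v_i - v_im1) / ((T_c - T_pp) / 2)
}

#' @rdname fall_acceleration
#' @param dT the constant inter-frame interval in seconds.
#' @export
fall_acceleration_uniform <- function(H_pp, H_p, H_c, dT, H_0) {
  if (any(H_0 <= 0)) stop("H_0 must be > 0")
  if (any(dT <= 0)) stop("dT must be > 0")
  (2 * H_p - (H_c + H_pp)) / (dT^2 * H_0)
}

# centered 3-point rolling median (ends passed through)
.smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- vapply(2:(n - 1), function(i) median(x[(i - 1):(i + 1)]),
                           0)
  out
}

#' Extract the fall-parameter series for a tracked subject
#'
#' Measures `H_i`, `W_i` inside each path box on the corresponding mask,
#' fills gaps of up to `max_gap` frames by linear interpolation, smooths the
#' height series with a 3-point rolling median, estimates the reference
#' height `H_0` as the maximum smoothed height over the subject's history
#' (the subject observed upright), and derives `theta_i`, `V_i`, `a_i` and
#' the nominal inter-frame interval `dT`.
#'
#' @param masks output of [subtract_background()] (or list of 0/1 matrices).
#' @param path a `track_path` (see [viterbi_paths()]) or a data frame with
#'   columns `frame, x0, y0, x1, y1` aligned with `masks` indices.
#' @param timestamps per-mask timestamps in seconds.
#' @param max_gap largest run of empty-silhouette frames to interpolate.
#' @param smooth apply the 3-point median smoothing before differentiating?
#' @return an object of class `fall_feature_series`: data frame with columns
#'   `frame, T, H, W, theta, V, a` and the tight silhouette box
#'   `bx0, by0, bx1, by1` (absolute pixels), plus attributes `H_0`, `dT` and
#'   `H_0_reliable` (`FALSE` when the subject was never observed upright —
#'   a flat, short height series).
#' @export
extract_series <- function(masks, path, timestamps, max_gap = 2,
                           smooth = TRUE) {
  boxes <- if (inherits(path, "track_path")) path$boxes else path
  stopifnot(is.data.frame(boxes),
            all(c("frame", "x0", "y0", "x1", "y1") %in% names(boxes)))
  n <- nrow(boxes)
  if (n == 0) stop("empty path")
  H <- W <- bx0 <- by0 <- bx1 <- by1 <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    m <- masks[[boxes$frame[k]]]
    hw <- measure_silhouette(m, c(boxes$x0[k], boxes$y0[k],
                                  boxes$x1[k], boxes$y1[k]))
    if (!is.null(hw)) {
      H[k] <- hw[["H"]]; W[k] <- hw[["W"]]
      bb <- attr(hw, "box")
      bx0[k] <- bb[["x0"]]; by0[k] <- bb[["y0"]]
      bx1[k] <- bb[["x1"]]; by1[k] <- bb[["y1"]]
    }
  }
  # interpolate missing measurements over short gaps, drop longer runs
  fill <- function(x) {
    miss <- is.na(x)
    if (!any(miss) || all(miss)) return(x)
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    ok <- which(!is.na(x))
    for (g in which(r$values)) {
      if (r$lengths[g] <= max_gap) {
        idx <- starts[g]:ends[g]
        x[idx] <- stats::approx(ok, x[ok], xout = idx, rule = 2)$y
      }
    }
    x
  }
  H <- fill(H); W <- fill(W)
  bx0 <- fill(bx0); by0 <- fill(by0); bx1 <- fill(bx1); by1 <- fill(by1)
  keep <- !is.na(H)
  H <- H[keep]; W <- W[keep]
  bx0 <- bx0[keep]; by0 <- by0[keep]; bx1 <- bx1[keep]; by1 <- by1[keep]
  tt <- timestamps[boxes$frame][keep]
  fr <- boxes$frame[keep]
  if (length(H) == 0) stop("no usable silhouette measurements along the path")
  Hs <- if (smooth) .smooth3(H) else H
  H_0 <- max(Hs)
  reliable <- H_0 > 0 && length(Hs) >= 3 && (max(Hs) - min(Hs)) / H_0 > 0.05
  if (H_0 <= 0) H_0 <- 1
  nn <- length(Hs)
  V <- rep(NA_real_, nn); a <- rep(NA_real_, nn)
  if (nn >= 2)
    V[2:nn] <- fall_velocity(Hs[1:(nn - 1)], Hs[2:nn],
                             tt[1:(nn - 1)], tt[2:nn], H_0)
  if (nn >= 3)
    a[3:nn] <- fall_acceleration(Hs[1:(nn - 2)], Hs[2:(nn - 1)], Hs[3:nn],
                                 tt[1:(nn - 2)], tt[2:(nn - 1)], tt[3:nn], H_0)
  dT <- if (nn >= 2) median(diff(tt)) else NA_real_
  out <- data.frame(frame = fr, T = tt, H = Hs, W = W,
                    theta = tilt_angle(Hs, H_0), V = V, a = a,
                    bx0 = bx0, by0 = by0, bx1 = bx1, by1 = by1)
  structure(out, class = c("fall_feature_series", "data.frame"),
            H_0 = H_0, dT = dT, H_0_reliable = reliable, H_raw = H)
}

#' Export a fall-feature series as CSV
#' @param series a [extract_series()] result.
#' @param file path to write.
#' @return `file`, invisibly.
#' @export
write_series_csv <- function(series, file) {
  utils::write.csv(as.data.frame(series), file, row.names = FALSE)
  invisible(file)
}
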