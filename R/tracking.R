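# Sliding-window human detection restricted to motion regions, Viterbi
# association of detections into human-presence paths, and clip cropping.

# intersection-over-union of two half-open boxes c(x0,y0,x1,y1)
.box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

# greedy non-maximum suppression; df has x0,y0,x1,y1,p_human
.nms <- function(df, iou = 0.5) {
  if (nrow(df) <= 1) return(df)
  ord <- order(-df$p_human)
  keep <- logical(nrow(df))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (.box_iou(as.numeric(df[i, c("x0", "y0", "x1", "y1")]),
                   as.numeric(df[j, c("x0", "y0", "x1", "y1")])) > iou) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  df[keep, , drop = FALSE]
}

# bounding boxes of connected foreground components above a minimum area
.motion_blobs <- function(mask, min_area = 25) {
  if (sum(mask) < min_area) return(list())
  lab <- EBImage::bwlabel(mask)
  labs <- sort(unique(as.integer(lab)))
  labs <- labs[labs > 0]
  out <- list()
  for (l in labs) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    out[[length(out) + 1]] <- c(x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
                                x1 = max(idx[, 2]), y1 = max(idx[, 1]))
  }
  out
}

#' Detect humans in one frame by sliding-window HOG + RVM
#'
#' Windows are evaluated only where the silhouette mask indicates motion
#' (foreground density above `min_density`); window sizes are chosen around
#' each motion blob (optionally modulated by `scales`), each window is
#' resampled to the detector's canonical size, scored by the RVM human
#' detector, thresholded and reduced by greedy non-maximum suppression at
#' IoU 0.5.
#'
#' @param frame grayscale matrix in \[0, 1\].
#' @param mask matching 0/1 silhouette mask.
#' @param model a `human_detector` (see [train_human_detector()]) or an
#'   [rvm()] together with `desc`.
#' @param scales numeric vector of window-size multipliers around the
#'   blob-derived size.
#' @param stride window stride in pixels; default `max(4, h/8)` of the
#'   window height.
#' @param threshold minimum human probability to keep a window.
#' @param desc [hog_descriptor()] (taken from `model` when it carries one).
#' @param min_density minimum foreground fraction inside a window.
#' @return data frame of candidates: `x0, y0, x1, y1, p_human` (possibly
#'   zero rows).
#' @export
detect_humans <- function(frame, mask, model, scales = c(1, 1.25),
                          stride = NULL, threshold = 0.5, desc = NULL,
                          min_density = 0.1) {
  if (inherits(model, "human_detector")) {
    desc <- model$descriptor
    rvm_model <- model$model
  } else rvm_model <- model
  if (is.null(desc)) desc <- hog_descriptor()
  h <- nrow(frame); w <- ncol(frame)
  empty <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), p_human = numeric(0))
  blobs <- .motion_blobs(mask)
  if (length(blobs) == 0) return(empty)
  aspect <- desc$window_w / desc$window_h
  cand_boxes <- list()
  for (b in blobs) {
    bh <- b["y1"] - b["y0"]; bw <- b["x1"] - b["x0"]
    base_h <- max(bh, bw / aspect) * 1.15
    for (sc in scales) {
      wh <- min(h, max(16, base_h * sc))
      ww <- wh * aspect
      st <- if (is.null(stride)) max(4, round(wh / 8)) else stride
      xs <- seq(b["x0"] - ww * 0.2, max(b["x0"] - ww * 0.2, b["x1"] - ww * 0.8),
                by = st)
      ys <- seq(b["y0"] - wh * 0.2, max(b["y0"] - wh * 0.2, b["y1"] - wh * 0.8),
                by = st)
      for (x0 in xs) for (y0 in ys) {
        x0c <- min(max(0, x0), w - ww); y0c <- min(max(0, y0), h - wh)
        cand_boxes[[length(cand_boxes) + 1]] <-
          c(x0c, y0c, min(w, x0c + ww), min(h, y0c + wh))
      }
    }
    # the blob's own padded box: a lying subject is wide and flat, and the
    # person-aspect windows around it would fail the density gate
    px <- bw * 0.1; py <- bh * 0.1
    cand_boxes[[length(cand_boxes) + 1]] <-
      c(max(0, b["x0"] - px), max(0, b["y0"] - py),
        min(w, b["x1"] + px), min(h, b["y1"] + py))
  }
  if (length(cand_boxes) == 0) return(empty)
  boxes <- unique(do.call(rbind, cand_boxes))
  # motion gating: foreground density inside the window
  dens <- apply(boxes, 1, function(bx) {
    ii <- (floor(bx[2]) + 1):ceiling(bx[4]); jj <- (floor(bx[1]) + 1):ceiling(bx[3])
    mean(mask[ii, jj])
  })
  keep_d <- dens > min_density
  boxes <- boxes[keep_d, , drop = FALSE]
  dens <- dens[keep_d]
  if (nrow(boxes) == 0) return(empty)
  feats <- t(apply(boxes, 1, function(bx) {
    ii <- (floor(bx[2]) + 1):ceiling(bx[4]); jj <- (floor(bx[1]) + 1):ceiling(bx[3])
    extract_hog(frame[ii, jj, drop = FALSE], desc)
  }))
  p <- predict(rvm_model, feats, type = "response")
  keep <- p > threshold
  if (!any(keep)) return(empty)
  out <- data.frame(x0 = boxes[keep, 1], y0 = boxes[keep, 2],
                    x1 = boxes[keep, 3], y1 = boxes[keep, 4],
                    p_human = p[keep])
  # the RVM saturates on easy windows, so equal-probability ties are
  # broken toward windows with greater silhouette support
  out <- out[order(-out$p_human, -dens[keep]), , drop = FALSE]
  out <- .nms(out, 0.5)
  rownames(out) <- NULL
  out
}

#' Most probable human-presence paths by dynamic programming
#'
#' Given per-frame detection candidates, finds the maximum-likelihood
#' sequences of candidates under frame-level independence: a path picks one
#' candidate per frame between the first and last frames that have
#' candidates, maximizing the sum of `log(p_human)` subject to spatial
#' smoothness (consecutive box centers within `smooth_radius_px` per frame
#' gap). Frames with no admissible candidate may be skipped, at most
#' `max_skip` in a row, each skip costing `skip_penalty`. The `n_best`
#' highest-scoring candidate-disjoint paths are returned. Ties in score are
#' broken by smaller total displacement, then lexicographically by candidate
#' order (the dynamic program is deterministic).
#'
#' @param candidates_per_frame list (one element per frame) of candidate
#'   data frames as returned by [detect_humans()]; `NULL` or zero-row
#'   entries mean no detections in that frame.
#' @param smooth_radius_px admissible center displacement per frame gap;
#'   `NULL` uses 1.5 x the previous box diagonal.
#' @param n_best number of disjoint paths to return.
#' @param skip_penalty additive log-likelihood penalty per skipped frame.
#' @param max_skip maximum consecutive skipped frames.
#' @return list of `track_path` objects: `boxes` (data frame `frame, x0,
#'   y0, x1, y1, p_human`), `log_likelihood` (sum of member log
#'   probabilities), `score` (including skip penalties).
#' @export
viterbi_paths <- function(candidates_per_frame, smooth_radius_px = NULL,
                          n_best = 3, skip_penalty = log(0.05),
                          max_skip = 2) {
  if (length(candidates_per_frame) == 0)
    stop("empty candidate structure")
  cpf <- lapply(candidates_per_frame, function(d) {
    if (is.null(d) || nrow(d) == 0) NULL else d
  })
  if (all(vapply(cpf, is.null, TRUE))) stop("no candidates in any frame")
  paths <- list()
  for (b in seq_len(n_best)) {
    res <- .viterbi_single(cpf, smooth_radius_px, skip_penalty, max_skip)
    if (is.null(res)) break
    paths[[b]] <- res$path
    # enforce disjointness: remove the consumed candidates
    for (r in seq_len(nrow(res$used))) {
      f <- res$used$frame[r]; i <- res$used$cand[r]
      d <- cpf[[f]][-i, , drop = FALSE]
      cpf[[f]] <- if (nrow(d) == 0) NULL else d
    }
    if (all(vapply(cpf, is.null, TRUE))) break
  }
  paths
}

.viterbi_single <- function(cpf, radius, skip_penalty, max_skip) {
  nz <- which(!vapply(cpf, is.null, TRUE))
  if (length(nz) == 0) return(NULL)
  f0 <- min(nz); f1 <- max(nz)
  frames <- f0:f1
  # node bookkeeping: per frame, vectors of score / displacement / backptr
  sc <- disp <- bp_f <- bp_i <- vector("list", length(frames))
  centers <- lapply(cpf, function(d) {
    if (is.null(d)) NULL
    else cbind((d$x0 + d$x1) / 2, (d$y0 + d$y1) / 2)
  })
  for (ti in seq_along(frames)) {
    f <- frames[ti]
    d <- cpf[[f]]
    if (is.null(d)) next
    m <- nrow(d)
    sc[[ti]] <- rep(-Inf, m); disp[[ti]] <- rep(0, m)
    bp_f[[ti]] <- rep(NA_integer_, m); bp_i[[ti]] <- rep(NA_integer_, m)
    for (j in seq_len(m)) {
      lp <- log(d$p_human[j])
      if (ti == 1) { sc[[ti]][j] <- lp; next }
      best <- -Inf; bestd <- Inf; bf <- NA_integer_; bi <- NA_integer_
      # connect back across up to max_skip skipped frames
      for (gap in 1:(max_skip + 1)) {
        pi_ <- ti - gap
        if (pi_ < 1) {
          # the path may start a few frames late, paying the skip penalty
          if (ti - 1 <= max_skip) {
            s0 <- lp + skip_penalty * (ti - 1)
            if (s0 > best + 1e-12) { best <- s0; bestd <- 0
              bf <- NA_integer_; bi <- NA_integer_ }
          }
          break
        }
        prev <- cpf[[frames[pi_]]]
        if (is.null(prev)) next
        for (i in seq_len(nrow(prev))) {
          if (!is.finite(sc[[pi_]][i])) next
          dx <- centers[[f]][j, 1] - centers[[frames[pi_]]][i, 1]
          dy <- centers[[f]][j, 2] - centers[[frames[pi_]]][i, 2]
          dd <- sqrt(dx * dx + dy * dy)
          r <- if (is.null(radius)) {
            bb <- prev[i, ]
            1.5 * sqrt((bb$x1 - bb$x0)^2 + (bb$y1 - bb$y0)^2)
          } else radius
          if (dd > r * gap) next
          cand_sc <- sc[[pi_]][i] + lp + skip_penalty * (gap - 1)
          cand_d <- disp[[pi_]][i] + dd
          if (cand_sc > best + 1e-12 ||
              (abs(cand_sc - best) <= 1e-12 &&
               (cand_d < bestd - 1e-12 ||
                (abs(cand_d - bestd) <= 1e-12 &&
                 (is.na(bf) || pi_ < bf || (pi_ == bf && i < bi)))))) {
            best <- cand_sc; bestd <- cand_d; bf <- pi_; bi <- i
          }
        }
      }
      if (is.finite(best)) {
        sc[[ti]][j] <- best; disp[[ti]][j] <- bestd
        bp_f[[ti]][j] <- bf; bp_i[[ti]][j] <- bi
      }
    }
  }
  # terminal: best node in the last frame (allowing trailing skips back to
  # within max_skip of the end)
  best <- -Inf; bestd <- Inf; bt <- NULL
  for (ti in rev(seq_along(frames))) {
    if (is.null(sc[[ti]])) next
    trailing <- length(frames) - ti
    if (trailing > max_skip) break
    for (j in seq_along(sc[[ti]])) {
      s <- sc[[ti]][j] + skip_penalty * trailing
      if (!is.finite(s)) next
      if (s > best + 1e-12 ||
          (abs(s - best) <= 1e-12 && disp[[ti]][j] < bestd - 1e-12)) {
        best <- s; bestd <- disp[[ti]][j]; bt <- c(ti, j)
      }
    }
  }
  if (is.null(bt)) return(NULL)
  # backtrack
  rows <- list(); used <- list()
  ti <- bt[1]; j <- bt[2]
  loglik <- 0
  while (!is.na(ti)) {
    f <- frames[ti]
    d <- cpf[[f]][j, , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(frame = f, x0 = d$x0, y0 = d$y0,
                                           x1 = d$x1, y1 = d$y1,
                                           p_human = d$p_human)
    used[[length(used) + 1]] <- data.frame(frame = f, cand = j)
    loglik <- loglik + log(d$p_human)
    nf <- bp_f[[ti]][j]; ni <- bp_i[[ti]][j]
    ti <- nf; j <- ni
    if (is.null(ti) || length(ti) == 0) break
  }
  boxes <- do.call(rbind, rev(rows))
  rownames(boxes) <- NULL
  path <- structure(list(boxes = boxes, log_likelihood = loglik,
                         score = best),
                    class = "track_path")
  list(path = path, used = do.call(rbind, used))
}

#' @export
print.track_path <- function(x, ...) {
  cat(sprintf("Track path: frames %d-%d (%d boxes), log-likelihood %.3f\n",
              min(x$boxes$frame), max(x$boxes$frame), nrow(x$boxes),
              x$log_likelihood))
  invisible(x)
}

#' Crop the per-frame subregions of a path
#'
#' Crops each path box (dilated on every side by `padding_fraction` of its
#' width/height, clipped to the frame bounds) out of the corresponding
#' frame, discarding the rest of the frame.
#'
#' @param frames list of grayscale matrices.
#' @param path a `track_path`.
#' @param padding_fraction box dilation per side.
#' @return list of cropped matrices, ordered by frame.
#' @export
crop_clip <- function(frames, path, padding_fraction = 0.25) {
  boxes <- if (inherits(path, "track_path")) path$boxes else path
  if (is.null(boxes) || nrow(boxes) == 0) stop("empty path")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  lapply(seq_len(nrow(boxes)), function(k) {
    b <- boxes[k, ]
    bw <- b$x1 - b$x0; bh <- b$y1 - b$y0
    x0 <- max(0, floor(b$x0 - padding_fraction * bw))
    y0 <- max(0, floor(b$y0 - padding_fraction * bh))
    x1 <- min(w, ceiling(b$x1 + padding_fraction * bw))
    y1 <- min(h, ceiling(b$y1 + padding_fraction * bh))
    if (x1 <= x0) { x0 <- max(0, x1 - 1); x1 <- max(1, x1) }
    if (y1 <= y0) { y0 <- max(0, y1 - 1); y1 <- max(1, y1) }
    frames[[b$frame]][(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  })
}
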