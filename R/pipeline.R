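# End-to-end monitor: background subtraction -> motion-gated detection ->
# Viterbi paths -> clip classification -> crafted rules -> alarms; plus the
# corpus-level trainers for the two RVMs and multi-camera merging.

# subset a fall_feature_series, keeping its attributes
.subset_series <- function(series, idx) {
  out <- series[idx, , drop = FALSE]
  attr(out, "H_0") <- attr(series, "H_0")
  attr(out, "dT") <- attr(series, "dT")
  attr(out, "H_0_reliable") <- attr(series, "H_0_reliable")
  class(out) <- class(series)
  out
}

# evenly spaced selection of k items from 1..n
.spaced <- function(n, k) unique(round(seq(1, n, length.out = min(n, k))))

# foreground pixels of mask m inside box b (x0, y0, x1, y1)
.fg_in_box <- function(m, b) {
  y0 <- max(0, floor(b[2])); y1 <- min(nrow(m), ceiling(b[4]))
  x0 <- max(0, floor(b[1])); x1 <- min(ncol(m), ceiling(b[3]))
  if (y1 <= y0 || x1 <= x0) return(0L)
  sum(m[(y0 + 1):y1, (x0 + 1):x1])
}

# Duplicate-path suppression: with a single subject in view, the n-best
# candidate-disjoint Viterbi paths still exist — the runner-up is assembled
# from the same blob's displaced windows, and its frame-to-frame jitter
# reads as violent (spurious) motion downstream. Two paths are duplicates
# when they enclose essentially the same silhouette pixels; paths arrive
# sorted by score, so the better one wins. Distinct subjects share almost
# no foreground and are never merged.
.dedup_paths <- function(paths, masks, share_min = 0.5) {
  kept <- list()
  for (p in paths) {
    dup <- FALSE
    for (q in kept) {
      common <- intersect(p$boxes$frame, q$boxes$frame)
      if (length(common) == 0) next
      common <- common[.spaced(length(common), 12)]
      share <- vapply(common, function(f) {
        a <- as.numeric(p$boxes[p$boxes$frame == f, c("x0", "y0", "x1", "y1")])
        b <- as.numeric(q$boxes[q$boxes$frame == f, c("x0", "y0", "x1", "y1")])
        m <- masks[[f]]
        fa <- .fg_in_box(m, a); fb <- .fg_in_box(m, b)
        if (fa == 0 || fb == 0) return(0)
        both <- c(max(a[1], b[1]), max(a[2], b[2]),
                  min(a[3], b[3]), min(a[4], b[4]))
        .fg_in_box(m, both) / min(fa, fb)
      }, 0)
      if (median(share) >= share_min) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- p
  }
  kept
}

#' Train the sliding-window human detector
#'
#' Positive windows are the ground-truth actor boxes (dilated 25%) sampled
#' from each clip's action frames; negative windows are person-shaped boxes
#' sampled from the actor-free background sections. HOG features feed a
#' histogram-intersection-kernel RVM.
#'
#' @param corpus a [build_corpus()] result.
#' @param desc a [hog_descriptor()].
#' @param frames_per_clip positive windows sampled per clip.
#' @param neg_per_clip negative windows sampled per clip.
#' @param seed RNG seed for the negative-window sampling.
#' @return object of class `human_detector`: `model` (the [rvm()]),
#'   `descriptor`.
#' @export
train_human_detector <- function(corpus, desc = hog_descriptor(),
                                 frames_per_clip = 3, neg_per_clip = 3,
                                 seed = 1) {
  feats <- list(); labs <- integer(0)
  .with_seed(seed, {
    for (clip in corpus$clips) {
      tr <- clip$truth
      h <- clip$camera$height_px; w <- clip$camera$width_px
      vis <- which(tr$visible)
      pick <- vis[.spaced(length(vis), frames_per_clip)]
      for (k in pick) {
        b <- tr[k, ]
        bw <- b$x1 - b$x0; bh <- b$y1 - b$y0
        x0 <- max(0, b$x0 - 0.25 * bw); x1 <- min(w, b$x1 + 0.25 * bw)
        y0 <- max(0, b$y0 - 0.25 * bh); y1 <- min(h, b$y1 + 0.25 * bh)
        crop <- clip$frames[[k]][(floor(y0) + 1):ceiling(y1),
                                 (floor(x0) + 1):ceiling(x1), drop = FALSE]
        feats[[length(feats) + 1]] <- extract_hog(crop, desc)
        labs <- c(labs, 1L)
      }
      bgk <- which(!tr$visible)
      if (length(bgk) == 0) bgk <- 1L
      ref <- tr[vis[1], ]
      for (j in seq_len(neg_per_clip)) {
        k <- sample(bgk, 1)
        bh <- (ref$y1 - ref$y0) * runif(1, 0.7, 1.3)
        bw <- bh * desc$window_w / desc$window_h
        x0 <- runif(1, 0, max(1e-6, w - bw)); y0 <- runif(1, 0, max(1e-6, h - bh))
        crop <- clip$frames[[k]][(floor(y0) + 1):ceiling(min(h, y0 + bh)),
                                 (floor(x0) + 1):ceiling(min(w, x0 + bw)),
                                 drop = FALSE]
        feats[[length(feats) + 1]] <- extract_hog(crop, desc)
        labs <- c(labs, 0L)
      }
    }
  })
  X <- do.call(rbind, feats)
  model <- rvm(X, labs, kernel = "histogram_intersection")
  structure(list(model = model, descriptor = desc), class = "human_detector")
}

#' @export
print.human_detector <- function(x, ...) {
  cat("HOG + RVM human detector\n")
  print(x$model)
  invisible(x)
}

#' Train the fall clip classifier
#'
#' For every clip the tagged event window (the initial-fall and true-fall
#' sections plus one second of post-fall; for daily activities, the action
#' window) is cropped along the ground-truth boxes, converted to a
#' fixed-length concatenated-HOG vector, PCA-compressed (fitting the
#' projector before any involvement of the labels), standardized physics
#' columns are appended, and a linear-kernel RVM is fit on the result (the
#' projected features are no longer histograms, so the histogram
#' intersection kernel does not apply).
#'
#' @param corpus a [build_corpus()] result (labeled).
#' @param desc a [hog_descriptor()].
#' @param retain_fraction PCA variance retention.
#' @param n_frames canonical clip length.
#' @param config a [fallmon_config()] (crop padding, background window).
#' @return object of class `fall_classifier`: `model`, `projector`,
#'   `descriptor`, `n_frames`, `physics_center`, `physics_scale`,
#'   `tau_classifier`.
#' @export
train_fall_classifier <- function(corpus, desc = hog_descriptor(),
                                  retain_fraction = 0.95, n_frames = 16,
                                  config = fallmon_config()) {
  hogs <- list(); phys <- list(); labs <- integer(0)
  for (clip in corpus$clips) {
    prep <- .training_window(clip, config)
    if (is.null(prep)) next
    hogs[[length(hogs) + 1]] <- clip_features(prep$crops, desc,
                                              n_frames = n_frames)[
      seq_len(n_frames * hog_length(desc))]
    phys[[length(phys) + 1]] <- .physics_columns(prep$series_win)
    labs <- c(labs, as.integer(clip$label == "fall"))
  }
  H <- do.call(rbind, hogs)
  P <- do.call(rbind, phys)
  projector <- fit_pca(H, retain_fraction)
  Hp <- predict(projector, H)
  ctr <- colMeans(P); scl <- apply(P, 2, sd)
  scl[scl < 1e-12] <- 1
  Ps <- sweep(sweep(P, 2, ctr), 2, scl, "/")
  X <- cbind(Hp, Ps)
  model <- rvm(X, labs, kernel = "linear")
  structure(list(model = model, projector = projector, descriptor = desc,
                 n_frames = n_frames, physics_center = ctr,
                 physics_scale = scl, tau_classifier = config$tau_classifier),
            class = "fall_classifier")
}

#' @export
print.fall_classifier <- function(x, ...) {
  cat("PCA-compressed fall clip classifier\n")
  print(x$projector)
  print(x$model)
  invisible(x)
}

# masks, event-window crops and series for a labeled clip, using the truth
# boxes (the training-time analogue of the detected path)
.training_window <- function(clip, config) {
  ts <- clip$timestamps
  t1 <- clip$sections[1]; t3 <- clip$sections[3]
  masks <- .clip_masks(clip, config)
  tr <- clip$truth
  vis <- which(tr$visible)
  if (length(vis) < 3) return(NULL)
  boxes <- data.frame(frame = vis, x0 = tr$x0[vis], y0 = tr$y0[vis],
                      x1 = tr$x1[vis], y1 = tr$y1[vis])
  series <- tryCatch(extract_series(masks, boxes, ts),
                     error = function(e) NULL)
  if (is.null(series)) return(NULL)
  win <- which(series$T >= t1 - 1e-9 & series$T <= t3 + 1.0 + 1e-9)
  if (length(win) < 3) return(NULL)
  rows <- match(series$frame[win], boxes$frame)
  crops <- crop_clip(clip$frames, boxes[rows, , drop = FALSE],
                     config$crop_padding)
  list(crops = crops, series = series,
       series_win = .subset_series(series, win))
}

.clip_masks <- function(clip, config) {
  bg_idx <- which(clip$timestamps < config$background_s - 1e-9)
  if (length(bg_idx) == 0) bg_idx <- 1L
  bg_idx <- bg_idx[.spaced(length(bg_idx), 3)]
  subtract_background(clip$frames, background_window = bg_idx)
}

#' Classify a cropped candidate clip as fall / non-fall
#'
#' Computes the clip's feature vector (concatenated per-frame HOG,
#' PCA-projected, standardized physics columns appended) and returns the
#' fall emission probability `y` from the classifier RVM; the event is a
#' fall when `y > tau_classifier`.
#'
#' @param crops list of cropped frames (see [crop_clip()]).
#' @param classifier a [train_fall_classifier()] result.
#' @param series optional [extract_series()] rows covering the clip window
#'   (used for the physics columns).
#' @param tau_classifier threshold; defaults to the classifier's.
#' @return probability `y` with attribute `event` (`y > tau_classifier`).
#' @export
classify_clip <- function(crops, classifier, series = NULL,
                          tau_classifier = NULL) {
  if (!inherits(classifier, "fall_classifier"))
    stop("classifier must be a trained fall_classifier")
  tau <- tau_classifier %||% classifier$tau_classifier
  x <- clip_features(crops, classifier$descriptor, classifier$projector,
                     series, classifier$n_frames,
                     classifier$physics_center, classifier$physics_scale)
  y <- unname(predict(classifier$model, x))
  attr(y, "event") <- y > tau
  y
}

#' Run the fall monitor over a video clip
#'
#' Full chain on one camera stream: background subtraction to silhouette
#' masks, motion-gated sliding-window human detection, Viterbi selection of
#' candidate human-presence paths, per-path extraction of the fall
#' parameters, clip classification of the descent window, and the crafted
#' rule engine. Emits at most one alarm per path per refractory window.
#'
#' @param clip a `labeled_clip`, or a list with `frames` (list of grayscale
#'   matrices), `timestamps` and `fps`.
#' @param models list with `human` (a `human_detector`) and `fall`
#'   (a `fall_classifier`).
#' @param camera a [camera_model()]; defaults to the clip's.
#' @param config a [fallmon_config()].
#' @param fence a [fence_spec()]; `NULL` = default bottom-edge fence.
#' @param tau_classifier optional threshold override.
#' @return list of `fall_alarm` objects (possibly empty), with attribute
#'   `paths` (the candidate paths) and `degraded` (below-minimum frame
#'   rate flag).
#' @export
monitor <- function(clip, models, camera = NULL, config = fallmon_config(),
                    fence = NULL, tau_classifier = NULL) {
  stopifnot(is.list(models), inherits(models$fall, "fall_classifier"))
  frames <- clip$frames; ts <- clip$timestamps
  if (is.null(camera)) camera <- clip$camera
  stopifnot(inherits(camera, "camera_model"))
  fps <- clip$fps %||% (1 / median(diff(ts)))
  degraded <- FALSE
  if (fps < config$min_fps) {
    warning(sprintf("stream at %.1f FPS is below the %g FPS minimum; %s",
                    fps, config$min_fps, "processing continues flagged degraded"))
    degraded <- TRUE
  }
  if (is.null(fence))
    fence <- fence_spec(camera$height_px, camera$width_px)

  masks <- .clip_masks(clip, config)
  cands <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    if (sum(masks[[k]]) < 25) next
    cands[[k]] <- detect_humans(frames[[k]], masks[[k]], models$human)
  }
  if (all(vapply(cands, function(d) is.null(d) || nrow(d) == 0, TRUE)))
    return(structure(list(), paths = list(), degraded = degraded))
  paths <- viterbi_paths(cands, n_best = config$n_best)
  paths <- .dedup_paths(paths, masks)

  alarms <- list()
  for (path in paths) {
    if (nrow(path$boxes) < 3) next
    series <- tryCatch(extract_series(masks, path, ts),
                       error = function(e) NULL)
    if (is.null(series)) next
    ew <- .event_window(series, config$v_trigger)
    if (is.null(ew)) next
    t_ev <- series$T[ew]
    win <- which(series$T >= t_ev[1] - 0.3 - 1e-9 &
                 series$T <= t_ev[2] + 1.0 + 1e-9)
    if (length(win) < 2) next
    rows <- match(series$frame[win], path$boxes$frame)
    crops <- crop_clip(frames, path$boxes[rows, , drop = FALSE],
                       config$crop_padding)
    y <- classify_clip(crops, models$fall, .subset_series(series, win),
                       tau_classifier)
    verdict <- apply_rules(series, path, camera, fence, config)
    tau <- tau_classifier %||% config$tau_classifier
    if (y > tau && verdict$passed) {
      cap <- series$frame[which.max(ifelse(is.na(series$V), -Inf, series$V))]
      alarms[[length(alarms) + 1]] <- structure(list(
        camera_id = camera$id, time_span_s = t_ev, y_fall = as.numeric(y),
        verdict = verdict, captured_frame = cap, path = path,
        degraded = degraded), class = "fall_alarm")
    }
  }
  # refractory dedup: overlapping event windows collapse to the highest y
  if (length(alarms) > 1) {
    ord <- order(-vapply(alarms, function(a) a$y_fall, 0))
    kept <- list()
    for (i in ord) {
      a <- alarms[[i]]
      dup <- any(vapply(kept, function(b)
        a$time_span_s[1] < b$time_span_s[2] + config$refractory_s &&
        b$time_span_s[1] < a$time_span_s[2] + config$refractory_s, TRUE))
      if (!dup) kept[[length(kept) + 1]] <- a
    }
    alarms <- kept[order(vapply(kept, function(a) a$time_span_s[1], 0))]
  }
  structure(alarms, paths = paths, degraded = degraded)
}

#' @export
print.fall_alarm <- function(x, ...) {
  cat(sprintf(
    "FALL alarm [%s]: t = %.2f-%.2f s, y = %.3f, frame %d captured%s\n",
    x$camera_id, x$time_span_s[1], x$time_span_s[2], x$y_fall,
    x$captured_frame, if (x$degraded) " (degraded stream)" else ""))
  invisible(x)
}

#' Merge alarm streams from multiple cameras
#'
#' Takes the union (logical OR) of the per-camera alarms — a fall is missed
#' only if every camera misses it — and deduplicates alarms raised by
#' different cameras covering the same zone within `window_s` seconds into
#' a single multi-camera-confirmed event.
#'
#' @param alarm_streams named list: camera id -> list of `fall_alarm`.
#' @param zone_map named character vector or list mapping camera id to a
#'   zone label; cameras sharing a zone see the same area.
#' @param window_s deduplication time window in seconds.
#' @return list of merged events: `time_span_s`, `cameras`, `zone`,
#'   `multi_camera_confirmed`, `alarms`.
#' @export
merge_cameras <- function(alarm_streams, zone_map, window_s = 5) {
  stopifnot(is.list(alarm_streams))
  unknown <- setdiff(names(alarm_streams), names(zone_map))
  if (length(unknown))
    stop("unknown camera id: ", paste(unknown, collapse = ", "))
  recs <- list()
  for (cam in names(alarm_streams)) {
    for (a in alarm_streams[[cam]]) {
      recs[[length(recs) + 1]] <- list(cam = cam, zone = zone_map[[cam]],
                                       t = mean(a$time_span_s), alarm = a)
    }
  }
  if (length(recs) == 0) return(list())
  ord <- order(vapply(recs, function(r) r$t, 0))
  recs <- recs[ord]
  events <- list()
  for (r in recs) {
    merged <- FALSE
    for (i in seq_along(events)) {
      e <- events[[i]]
      if (e$zone == r$zone && abs(r$t - e$t_ref) <= window_s) {
        e$cameras <- union(e$cameras, r$cam)
        e$alarms <- c(e$alarms, list(r$alarm))
        e$time_span_s <- range(c(e$time_span_s, r$alarm$time_span_s))
        e$multi_camera_confirmed <- length(e$cameras) > 1
        events[[i]] <- e
        merged <- TRUE
        break
      }
    }
    if (!merged)
      events[[length(events) + 1]] <- list(
        time_span_s = r$alarm$time_span_s, t_ref = r$t, zone = r$zone,
        cameras = r$cam, multi_camera_confirmed = FALSE,
        alarms = list(r$alarm))
  }
  events
}

#' Evaluate the monitor over a labeled corpus
#'
#' Runs [monitor()] on every clip and tabulates alarms against the ground
#' truth labels.
#'
#' @param corpus a [build_corpus()] result.
#' @param models as for [monitor()].
#' @param config a [fallmon_config()].
#' @param target_fps optionally resample every clip to this rate first.
#' @return list with `table` (per-clip data frame: `id, event_type, label,
#'   n_alarms, alarmed`), `precision`, `recall` (event-level, alarms as
#'   positives).
#' @export
eval_corpus <- function(corpus, models, config = fallmon_config(),
                        target_fps = NULL) {
  rows <- list()
  for (i in seq_along(corpus$clips)) {
    clip <- corpus$clips[[i]]
    if (!is.null(target_fps)) clip <- resample_fps(clip, target_fps)
    al <- suppressWarnings(monitor(clip, models, config = config))
    rows[[i]] <- data.frame(id = corpus$index$id[i],
                            event_type = corpus$index$event_type[i],
                            label = corpus$index$label[i],
                            n_alarms = length(al),
                            alarmed = length(al) > 0)
  }
  tab <- do.call(rbind, rows)
  tp <- sum(tab$alarmed & tab$label == "fall")
  fp <- sum(tab$alarmed & tab$label != "fall")
  fn <- sum(!tab$alarmed & tab$label == "fall")
  list(table = tab,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
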