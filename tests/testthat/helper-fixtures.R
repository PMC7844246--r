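# Shared fixtures, built lazily once per test run and cached. The trained
# models take ~1 minute; everything that needs them shares one instance.

.fx <- new.env(parent = emptyenv())

fx_camera <- function() {
  if (is.null(.fx$camera))
    .fx$camera <- camera_model(160, 120, 110, mount_height_m = 1.5,
                               downward_angle_deg = 0)
  .fx$camera
}

# 36-clip training corpus: every event type at directions 0/90/180
fx_train_corpus <- function() {
  if (is.null(.fx$train_corpus)) {
    spec <- unlist(lapply(event_types(), function(ev)
      lapply(c(0, 90, 180), function(d)
        scenario(ev, direction_deg = d, distance_m = 3, fps = 10))),
      recursive = FALSE)
    .fx$train_corpus <- build_corpus(spec, fx_camera(), master_seed = 20260101)
  }
  .fx$train_corpus
}

fx_models <- function() {
  if (is.null(.fx$models)) {
    corpus <- fx_train_corpus()
    .fx$models <- suppressWarnings(list(
      human = train_human_detector(corpus),
      fall = train_fall_classifier(corpus)))
  }
  .fx$models
}

# Table-1 stand-in evaluation: 10 held-out mid-distance stumbles and 30
# held-out daily-activity clips, monitored at the native 10 FPS and after
# 7 FPS subsampling. Shared between the scaled-down-results and
# rule-invariant acceptance blocks.
fx_accept_eval <- function() {
  if (is.null(.fx$accept_eval)) {
    cam <- fx_camera()
    models <- fx_models()
    stumbles <- lapply(1:10, function(i)
      scenario("stumble", direction_deg = ((i - 1) %% 4) * 90,
               distance_m = 3, fps = 10))
    acts <- unlist(lapply(c("bow", "tie_shoelaces", "pushup", "situp",
                            "get_down_to_floor", "jump"), function(ev)
      lapply(c(0, 90, 180, 270, 0), function(d)
        scenario(ev, direction_deg = d, distance_m = 3, fps = 10))),
      recursive = FALSE)
    corpus <- build_corpus(c(stumbles, acts), cam, master_seed = 90210)
    run <- function(target_fps) {
      lapply(corpus$clips, function(clip) {
        if (!is.null(target_fps)) clip <- resample_fps(clip, target_fps)
        suppressWarnings(monitor(clip, models))
      })
    }
    .fx$accept_eval <- list(index = corpus$index,
                            alarms10 = run(NULL), alarms7 = run(7))
  }
  .fx$accept_eval
}

# one rendered stumble clip (direction 0, mid distance), reused widely
fx_stumble_clip <- function() {
  if (is.null(.fx$stumble))
    .fx$stumble <- render_clip(
      scenario("stumble", direction_deg = 0, distance_m = 3, fps = 10,
               seed = 4242), fx_camera())
  .fx$stumble
}

# masks + truth-box path + feature series for the stumble clip
fx_stumble_series <- function() {
  if (is.null(.fx$stumble_series)) {
    clip <- fx_stumble_clip()
    masks <- subtract_background(clip$frames,
                                 background_window = c(1, 10, 19))
    tr <- clip$truth
    vis <- which(tr$visible)
    boxes <- data.frame(frame = vis, x0 = tr$x0[vis], y0 = tr$y0[vis],
                        x1 = tr$x1[vis], y1 = tr$y1[vis])
    .fx$stumble_series <- list(
      clip = clip, masks = masks, boxes = boxes,
      series = extract_series(masks, boxes, clip$timestamps))
  }
  .fx$stumble_series
}

# truth-box feature series for an arbitrary clip
truth_series <- function(clip) {
  masks <- subtract_background(clip$frames, background_window = c(1, 10, 19))
  tr <- clip$truth
  vis <- which(tr$visible)
  boxes <- data.frame(frame = vis, x0 = tr$x0[vis], y0 = tr$y0[vis],
                      x1 = tr$x1[vis], y1 = tr$y1[vis])
  extract_series(masks, boxes, clip$timestamps)
}

# hand-built fall_feature_series for rule-engine tests
make_series <- function(T, H, H_0 = max(H), W = rep(10, length(H)),
                        bx = NULL) {
  n <- length(H)
  V <- c(NA, (H[-n] - H[-1]) / (H_0 * diff(T)))
  a <- rep(NA_real_, n)
  if (n >= 3)
    a[3:n] <- fall_acceleration(H[1:(n - 2)], H[2:(n - 1)], H[3:n],
                                T[1:(n - 2)], T[2:(n - 1)], T[3:n], H_0)
  out <- data.frame(frame = seq_len(n), T = T, H = H, W = W,
                    theta = tilt_angle(H, H_0), V = V, a = a)
  if (!is.null(bx)) {
    out$bx0 <- bx$x0; out$by0 <- bx$y0; out$bx1 <- bx$x1; out$by1 <- bx$y1
  }
  structure(out, class = c("fall_feature_series", "data.frame"),
            H_0 = H_0, dT = median(diff(T)), H_0_reliable = TRUE)
}

# boxes data frame helper aligned with make_series frames
make_boxes <- function(n, x0, y0, x1, y1) {
  data.frame(frame = seq_len(n), x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}
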