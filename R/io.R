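# Disk I/O: clips as numbered PNG frames plus a JSON metadata file, alarm
# logs as JSON lines, and debug overlays.

#' Write a clip to a directory of PNG frames
#'
#' Frames are written as `frame_0001.png`, ... with a `clip.json` carrying
#' timestamps, frame rate, camera parameters and (when present) the ground
#' truth table, so the clip round-trips through [read_clip()].
#'
#' @param clip a `labeled_clip` (see [render_clip()]) or a list with
#'   `frames`, `timestamps`, `fps`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_clip <- function(clip, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(clip$frames)) {
    png::writePNG(clip$frames[[k]],
                  file.path(dir, sprintf("frame_%04d.png", k)))
  }
  meta <- list(timestamps = clip$timestamps, fps = clip$fps,
               sections = clip$sections, H_upright_px = clip$H_upright_px)
  if (!is.null(clip$camera)) meta$camera <- unclass(clip$camera)
  if (!is.null(clip$scenario))
    meta$scenario <- unclass(clip$scenario)[c(
      "event_type", "distance_m", "direction_deg", "fps",
      "section_durations_s", "actor_height_m", "lateral_offset_m",
      "label", "seed")]
  if (!is.null(clip$label)) meta$label <- clip$label
  if (!is.null(clip$truth)) meta$truth <- clip$truth
  jsonlite::write_json(meta, file.path(dir, "clip.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")
  invisible(dir)
}

#' Read a clip written by [write_clip()]
#'
#' @param dir the clip directory.
#' @return a list with `frames`, `timestamps`, `fps`, and any stored
#'   metadata (`camera` restored as a [camera_model()], `truth`,
#'   `sections`); class `labeled_clip` when ground truth is present.
#' @export
read_clip <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "clip.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frames in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
  out <- list(frames = frames, timestamps = meta$timestamps, fps = meta$fps,
              sections = meta$sections, H_upright_px = meta$H_upright_px)
  if (!is.null(meta$camera))
    out$camera <- do.call(camera_model, meta$camera[c(
      "width_px", "height_px", "diag_view_angle_deg", "mount_height_m",
      "downward_angle_deg", "id")])
  if (!is.null(meta$label)) out$label <- meta$label
  if (!is.null(meta$truth)) {
    out$truth <- as.data.frame(meta$truth)
    class(out) <- "labeled_clip"
  }
  out
}

#' Write an alarm log as JSON lines
#'
#' One JSON object per alarm: camera id, event time span, classifier
#' probability, rule verdict summary and the captured frame index.
#'
#' @param alarms list of `fall_alarm` objects (as from [monitor()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_alarm_log <- function(alarms, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (a in alarms) {
    rec <- list(camera_id = a$camera_id, time_span_s = a$time_span_s,
                y_fall = a$y_fall, captured_frame = a$captured_frame,
                degraded = a$degraded,
                scenario_flags = a$verdict$scenario_flags,
                direction = a$verdict$direction)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(file)
}

#' Save a frame with box overlays for debugging
#'
#' Burns rectangle outlines into a copy of the frame and writes it as PNG.
#'
#' @param frame grayscale matrix in \[0, 1\].
#' @param boxes data frame with `x0, y0, x1, y1`.
#' @param file output path.
#' @param value outline intensity.
#' @return `file`, invisibly.
#' @export
write_overlay <- function(frame, boxes, file, value = 1) {
  img <- frame
  h <- nrow(img); w <- ncol(img)
  for (k in seq_len(nrow(boxes))) {
    b <- boxes[k, ]
    ii <- max(1, floor(b$y0) + 1):min(h, ceiling(b$y1))
    jj <- max(1, floor(b$x0) + 1):min(w, ceiling(b$x1))
    img[ii[1], jj] <- value; img[ii[length(ii)], jj] <- value
    img[ii, jj[1]] <- value; img[ii, jj[length(jj)]] <- value
  }
  png::writePNG(img, file)
  invisible(file)
}
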