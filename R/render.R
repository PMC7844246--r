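# Synthetic clip rendering: articulated 2-D actor (head disc, torso ellipse,
# two leg segments) animated by per-event tilt schedules, drawn over a static
# seeded texture and projected by the weak-perspective camera model.

# run expr with a private, seeded RNG stream; restores global state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# image-plane projection of a world offset (dx right, dy up, dz away), px
.proj_offset <- function(off, sx, s, tau) {
  c(sx * off[1], -s * (off[2] * cos(tau) + off[3] * sin(tau)))
}

# fill an ellipse given centre (u,v), long semi-vector a (px), short semi b
# (px) into matrix `img`; returns the modified matrix
.draw_ellipse <- function(img, u, v, a, b, value) {
  h <- nrow(img); w <- ncol(img)
  la <- sqrt(sum(a^2))
  if (la < 1e-6) a <- c(max(b, 0.5), 0)
  la <- sqrt(sum(a^2))
  bv <- b * c(-a[2], a[1]) / la
  ext <- abs(a) + abs(bv)
  jmin <- max(1L, floor(u - ext[1])); jmax <- min(w, ceiling(u + ext[1]))
  imin <- max(1L, floor(v - ext[2])); imax <- min(h, ceiling(v + ext[2]))
  if (jmin > jmax || imin > imax) return(img)
  xs <- (jmin:jmax) - 0.5 - u
  ys <- (imin:imax) - 0.5 - v
  det <- a[1] * bv[2] - a[2] * bv[1]
  if (abs(det) < 1e-9) return(img)
  # coordinates in the (a, b) basis
  t1 <- outer(ys, xs, function(y, x) ( bv[2] * x - bv[1] * y) / det)
  t2 <- outer(ys, xs, function(y, x) (-a[2] * x + a[1] * y) / det)
  inside <- t1 * t1 + t2 * t2 <= 1
  sub <- img[imin:imax, jmin:jmax, drop = FALSE]
  sub[inside] <- value
  img[imin:imax, jmin:jmax] <- sub
  img
}

# body parts for a pose; offsets are metres relative to the actor's ground
# point. Returns list of parts: list(center, axis (semi-long vector), width)
.body_parts <- function(pose, L, dir_deg) {
  phi <- dir_deg * pi / 180
  g <- c(sin(phi), 0, -cos(phi))       # action direction on the ground
  p <- c(cos(phi), 0, sin(phi))        # lateral perpendicular
  up <- c(0, 1, 0)
  axis_at <- function(th) g * cos(th * pi / 180) + up * sin(th * pi / 180)
  o0 <- pose$base_height * up
  hip <- o0 + 0.5 * L * axis_at(pose$theta_legs)
  at <- axis_at(pose$theta_torso)
  parts <- list()
  for (sgn in c(-1, 1)) {
    foot <- o0 + sgn * 0.07 * L * p
    parts[[length(parts) + 1]] <- list(center = (foot + hip) / 2,
                                       axis = (hip - foot) / 2,
                                       width = 0.055 * L)
  }
  parts[[length(parts) + 1]] <- list(center = hip + 0.18 * L * at,
                                     axis = 0.20 * L * at, width = 0.11 * L)
  parts[[length(parts) + 1]] <- list(center = hip + 0.43 * L * at,
                                     axis = 0.07 * L * at, width = 0.07 * L)
  parts
}

# draw an actor; returns list(img, extent = c(min_u, min_v, max_u, max_v))
.draw_actor <- function(img, parts, base, value) {
  sx <- base$scale_x; s <- base$scale; tau <- base$tau
  mins <- c(Inf, Inf); maxs <- c(-Inf, -Inf)
  for (pt in parts) {
    ctr <- .proj_offset(pt$center, sx, s, tau) + c(base$u, base$v)
    a <- .proj_offset(pt$axis, sx, s, tau)
    b <- s * pt$width
    img <- .draw_ellipse(img, ctr[1], ctr[2], a, b, value)
    # tight extent of the filled ellipse: sqrt(a^2 + bv^2) per component,
    # with bv the short semi-axis vector as used by .draw_ellipse
    la <- sqrt(sum(a^2))
    av <- if (la < 1e-6) c(max(b, 0.5), 0) else a
    la <- sqrt(sum(av^2))
    bv <- b * c(-av[2], av[1]) / la
    ext <- sqrt(av^2 + bv^2)
    mins <- pmin(mins, ctr - ext); maxs <- pmax(maxs, ctr + ext)
  }
  list(img = img, extent = c(mins[1], mins[2], maxs[1], maxs[2]))
}

#' Render a synthetic labeled clip
#'
#' Draws the articulated actor executing the scenario's event over a static
#' seeded background texture, using a weak-perspective projection (pixel
#' scale `f / z`, vertical extents foreshortened by `cos(tau)` at downward
#' angle `tau`). The clip carries per-frame ground truth: the actor bounding
#' box, true apparent height in pixels and true tilt angle.
#'
#' @param scn a [scenario()].
#' @param camera a [camera_model()].
#' @param actor_intensity,background_range grayscale levels in \[0, 1\].
#' @return an object of class `labeled_clip`: list with `frames` (list of
#'   height x width matrices in \[0,1\]), `timestamps` (seconds), `fps`,
#'   `truth` (data frame: `frame, x0, y0, x1, y1, H_px, theta_deg`, boxes
#'   half-open, clipped to the frame), `label`, `sections` (cumulative
#'   section end times), `H_upright_px`, plus the scenario and camera.
#' @examples
#' cam <- camera_model(160, 120, 110, mount_height_m = 1.5)
#' clip <- render_clip(scenario("stumble", distance_m = 3, fps = 10,
#'                              section_durations_s = c(1, 0.6, 0.5, 1)), cam)
#' length(clip$frames)
#' @export
render_clip <- function(scn, camera, actor_intensity = 0.12,
                        background_range = c(0.45, 0.8)) {
  stopifnot(inherits(scn, "fall_scenario"), inherits(camera, "camera_model"))
  h <- camera$height_px; w <- camera$width_px
  L <- scn$actor_height_m
  total <- sum(scn$section_durations_s)
  n <- floor(total * scn$fps)
  if (n < 1) stop("clip would contain no frames")
  ts <- (seq_len(n) - 1) / scn$fps

  .with_seed(scn$seed, {
    bg <- matrix(runif(h * w, background_range[1], background_range[2]), h, w)
    occ <- scn$occluders
    if (!is.null(occ)) {
      for (r in occ) {
        ii <- max(1, r[2] + 1):min(h, r[4]); jj <- max(1, r[1] + 1):min(w, r[3])
        bg[ii, jj] <- matrix(runif(length(ii) * length(jj), 0.25, 0.35),
                             length(ii), length(jj))
      }
    }
    # upright reference extent (for truth tilt angles)
    base0 <- .project_base(camera, scn$lateral_offset_m, scn$distance_m)
    up_parts <- .body_parts(list(theta_legs = 90, theta_torso = 90,
                                 base_height = 0, disp = 0), L,
                            scn$direction_deg)
    up_ext <- .draw_actor(matrix(0, h, w), up_parts, base0, 1)$extent
    H_up <- up_ext[4] - up_ext[2]

    by_phase <- runif(1, 0, 2 * pi)  # bystander walk phase
    frames <- vector("list", n)
    truth <- data.frame(frame = seq_len(n), visible = FALSE, x0 = 0, y0 = 0,
                        x1 = 0, y1 = 0, H_px = 0, theta_deg = 0)
    phi <- scn$direction_deg * pi / 180
    t_bg <- scn$section_durations_s[1]
    seen <- FALSE
    for (k in seq_len(n)) {
      img <- bg
      # the background section contains only static scenery; the actor is
      # present from the initial-fall (action) section onward
      visible <- ts[k] >= t_bg - 1e-9
      ext <- c(NA_real_, NA_real_, NA_real_, NA_real_)
      if (visible) {
        pose <- .pose_at(scn, ts[k])
        # ground displacement moves the base point
        bx <- scn$lateral_offset_m + pose$disp * sin(phi)
        bz <- scn$distance_m - pose$disp * cos(phi)
        base <- .project_base(camera, bx, bz)
        parts <- .body_parts(pose, L, scn$direction_deg)
        res <- .draw_actor(img, parts, base, actor_intensity)
        img <- res$img
        ext <- res$extent
      }
      if (scn$bystander && visible) {
        # second, upright actor pacing laterally 1.5 m behind the primary
        bx2 <- 1.0 * sin(2 * pi * 0.15 * ts[k] + by_phase)
        base2 <- .project_base(camera, bx2, scn$distance_m + 1.5)
        parts2 <- .body_parts(list(theta_legs = 90, theta_torso = 90,
                                   base_height = 0, disp = 0), L * 0.95, 90)
        img <- .draw_actor(img, parts2, base2, 0.2)$img
      }
      if (!is.null(occ)) {
        for (r in occ) {
          ii <- max(1, r[2] + 1):min(h, r[4]); jj <- max(1, r[1] + 1):min(w, r[3])
          img[ii, jj] <- bg[ii, jj]
        }
      }
      frames[[k]] <- img
      truth$visible[k] <- visible
      if (visible) {
        truth$x0[k] <- max(0, floor(ext[1])); truth$y0[k] <- max(0, floor(ext[2]))
        truth$x1[k] <- min(w, ceiling(ext[3])); truth$y1[k] <- min(h, ceiling(ext[4]))
        truth$H_px[k] <- ext[4] - ext[2]
        truth$theta_deg[k] <- asin(min(1, max(0, truth$H_px[k] / H_up))) * 180 / pi
        if (!seen && (truth$x1[k] <= truth$x0[k] || truth$y1[k] <= truth$y0[k]))
          stop("scene configuration error: actor projected outside the frame")
        seen <- TRUE
      } else {
        truth$x0[k] <- truth$y0[k] <- truth$x1[k] <- truth$y1[k] <- NA_real_
        truth$H_px[k] <- NA_real_; truth$theta_deg[k] <- NA_real_
      }
    }
    structure(list(
      frames = frames, timestamps = ts, fps = scn$fps, truth = truth,
      label = scn$label, sections = cumsum(scn$section_durations_s),
      H_upright_px = H_up, scenario = scn, camera = camera
    ), class = "labeled_clip")
  })
}

#' @export
print.labeled_clip <- function(x, ...) {
  cat(sprintf("Labeled clip: %s (%s), %d frames at %g FPS, %dx%d px\n",
              x$scenario$event_type, x$label, length(x$frames), x$fps,
              x$camera$width_px, x$camera$height_px))
  invisible(x)
}

#' Subsample a clip to a lower frame rate
#'
#' Frames are selected at a uniform stride of `fps / target_fps` source
#' frames; original timestamps are preserved (not rescaled) and the truth
#' series is subsampled identically, mirroring the frame-rate subsampling
#' used to study recall/precision versus processing rate.
#'
#' @param clip a [render_clip()] output.
#' @param target_fps target nominal rate, `0 < target_fps <= clip$fps`.
#' @return a `labeled_clip` at the new nominal rate.
#' @export
resample_fps <- function(clip, target_fps) {
  stopifnot(inherits(clip, "labeled_clip"))
  if (!is.numeric(target_fps) || target_fps <= 0)
    stop("target_fps must be > 0")
  if (target_fps > clip$fps) stop("target_fps must be <= the clip frame rate")
  if (target_fps == clip$fps) return(clip)
  n <- length(clip$frames)
  stride <- clip$fps / target_fps
  idx <- unique(pmin(n, floor(seq(1, n + 1e-9, by = stride))))
  out <- clip
  out$frames <- clip$frames[idx]
  out$timestamps <- clip$timestamps[idx]
  out$truth <- clip$truth[idx, , drop = FALSE]
  out$truth$frame <- seq_along(idx)
  rownames(out$truth) <- NULL
  out$fps <- target_fps
  out$source_index <- idx
  out
}

#' Generate a labeled synthetic corpus
#'
#' Renders every requested scenario `reps` times with deterministic per-clip
#' seeds derived from a master seed, and returns the clips together with a
#' balanced metadata index.
#'
#' @param spec a list whose elements are `list(scenario = <fall_scenario>,
#'   reps = <int>)` (or bare `fall_scenario` objects, meaning 1 repetition).
#' @param camera a [camera_model()].
#' @param master_seed integer; per-clip seeds are derived from it.
#' @return list with `clips` (list of `labeled_clip`) and `index`
#'   (data frame: `id, event_type, direction_deg, distance_m, fps, label,
#'   seed`).
#' @export
build_corpus <- function(spec, camera, master_seed = 1) {
  if (length(spec) == 0) stop("corpus spec must be nonempty")
  items <- lapply(spec, function(e) {
    if (inherits(e, "fall_scenario")) list(scenario = e, reps = 1L) else e
  })
  clips <- list(); rows <- list(); i <- 0L
  for (it in items) {
    stopifnot(inherits(it$scenario, "fall_scenario"), it$reps >= 1)
    for (r in seq_len(it$reps)) {
      i <- i + 1L
      scn <- it$scenario
      scn$seed <- as.integer((as.numeric(master_seed) * 7919 + i * 104729) %% 2147483647)
      clips[[i]] <- render_clip(scn, camera)
      rows[[i]] <- data.frame(id = i, event_type = scn$event_type,
                              direction_deg = scn$direction_deg,
                              distance_m = scn$distance_m, fps = scn$fps,
                              label = scn$label, seed = scn$seed)
    }
  }
  list(clips = clips, index = do.call(rbind, rows))
}
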