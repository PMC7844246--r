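#' Camera model for a surveillance view
#'
#' Describes a mounted surveillance camera by its pixel resolution, diagonal
#' view angle, mounting height and downward viewing angle. The horizontal and
#' vertical view angles are derived from the diagonal one by the linear
#' decomposition `angle * side / diagonal` (a small-angle approximation that
#' is the field convention for spec-sheet view angles); focal lengths in
#' pixels are then derived from the component angles so that a point on the
#' optical axis projects to the image centre.
#'
#' @param width_px,height_px positive integers, frame size in pixels.
#' @param diag_view_angle_deg diagonal view angle in degrees, in (0, 180).
#' @param mount_height_m camera height above the floor in metres (>= 0).
#' @param downward_angle_deg downward tilt of the optical axis below the
#'   horizontal, degrees in \[0, 90).
#' @param id optional camera identifier (used by [merge_cameras()]).
#' @return an object of class `camera_model`.
#' @examples
#' cam <- camera_model(704, 480, 110)
#' view_angles(704, 480, 110)
#' @export
camera_model <- function(width_px, height_px, diag_view_angle_deg = 110,
                         mount_height_m = 1.5, downward_angle_deg = 0,
                         id = "cam1") {
  stopifnot(length(width_px) == 1, length(height_px) == 1)
  if (!is.finite(width_px) || width_px <= 0 || !is.finite(height_px) || height_px <= 0)
    stop("frame dimensions must be positive")
  if (!is.finite(diag_view_angle_deg) || diag_view_angle_deg <= 0 ||
      diag_view_angle_deg >= 180)
    stop("diag_view_angle_deg must lie in (0, 180)")
  if (mount_height_m < 0) stop("mount_height_m must be >= 0")
  if (downward_angle_deg < 0 || downward_angle_deg >= 90)
    stop("downward_angle_deg must lie in [0, 90)")
  va <- view_angles(width_px, height_px, diag_view_angle_deg, round_deg = FALSE)
  # focal lengths in pixels from the component view angles
  fx <- (width_px / 2) / tan(va[["horizontal_deg"]] * pi / 360)
  fy <- (height_px / 2) / tan(va[["vertical_deg"]] * pi / 360)
  structure(list(
    id = id,
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    diag_view_angle_deg = diag_view_angle_deg,
    mount_height_m = mount_height_m,
    downward_angle_deg = downward_angle_deg,
    horizontal_view_angle_deg = va[["horizontal_deg"]],
    vertical_view_angle_deg = va[["vertical_deg"]],
    fx = fx, fy = fy,
    cx = width_px / 2, cy = height_px / 2
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Camera '%s': %d x %d px, diagonal view angle %g deg\n",
              x$id, x$width_px, x$height_px, x$diag_view_angle_deg))
  cat(sprintf("  horizontal %g deg, vertical %g deg (rounded: %d / %d)\n",
              x$horizontal_view_angle_deg, x$vertical_view_angle_deg,
              round(x$horizontal_view_angle_deg), round(x$vertical_view_angle_deg)))
  cat(sprintf("  mounted at %g m, downward angle %g deg\n",
              x$mount_height_m, x$downward_angle_deg))
  invisible(x)
}

#' Decompose a diagonal view angle into horizontal and vertical components
#'
#' Uses the linear spec-sheet decomposition: `horizontal = diag * width /
#' sqrt(width^2 + height^2)` and analogously for the vertical component.
#' This is a small-angle approximation, not exact trigonometry; raw values
#' are returned unless `round_deg = TRUE`, which rounds to whole degrees as
#' conventionally printed.
#'
#' @param width_px,height_px positive frame dimensions in pixels.
#' @param diag_view_angle_deg diagonal view angle in degrees, in (0, 180).
#' @param round_deg round the components to integer degrees?
#' @return named numeric vector `c(horizontal_deg=, vertical_deg=)`.
#' @examples
#' view_angles(704, 480, 110, round_deg = TRUE)  # 91, 62
#' @export
view_angles <- function(width_px, height_px, diag_view_angle_deg,
                        round_deg = FALSE) {
  if (any(!is.finite(c(width_px, height_px, diag_view_angle_deg))) ||
      width_px <= 0 || height_px <= 0)
    stop("frame dimensions must be positive")
  if (diag_view_angle_deg <= 0 || diag_view_angle_deg >= 180)
    stop("diag_view_angle_deg must lie in (0, 180)")
  diag_px <- sqrt(width_px^2 + height_px^2)
  h <- diag_view_angle_deg * width_px / diag_px
  v <- diag_view_angle_deg * height_px / diag_px
  if (round_deg) c(horizontal_deg = round(h), vertical_deg = round(v))
  else c(horizontal_deg = h, vertical_deg = v)
}

#' Detectable distance at a different vertical resolution
#'
#' A subject resolvable at `ref_distance_m` with `ref_pixels` of vertical
#' resolution remains resolvable at `ref_distance_m * target_pixels /
#' ref_pixels` when the camera provides `target_pixels` at the same view
#' angle: detectable distance is linear in resolution.
#'
#' @param ref_distance_m reference detectable distance in metres (> 0).
#' @param ref_pixels vertical resolution at the reference distance (> 0).
#' @param target_pixels vertical resolution of the target camera (> 0).
#' @param round_m round the result to 0.1 m (the conventional reporting
#'   precision)?
#' @return distance in metres.
#' @examples
#' detectable_distance(10, 354, 1080)  # 30.5
#' detectable_distance(10, 354, 2160)  # 61.0
#' @export
detectable_distance <- function(ref_distance_m, ref_pixels, target_pixels,
                                round_m = TRUE) {
  vals <- c(ref_distance_m, ref_pixels, target_pixels)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive")
  d <- ref_distance_m * target_pixels / ref_pixels
  if (round_m) round(d, 1) else d
}

#' Apparent-height foreshortening under a downward viewing angle
#'
#' An upright subject viewed from a camera tilted down by `tau` degrees has
#' its apparent (projected) height reduced to `H0 * cos(tau)`.
#'
#' @param downward_angle_deg downward viewing angle in degrees, \[0, 90).
#' @return the foreshortening ratio in (0, 1\].
#' @examples
#' apparent_height_ratio(60)  # 0.5
#' @export
apparent_height_ratio <- function(downward_angle_deg) {
  if (any(!is.finite(downward_angle_deg)) || any(downward_angle_deg < 0) ||
      any(downward_angle_deg >= 90))
    stop("downward_angle_deg must lie in [0, 90)")
  cos(downward_angle_deg * pi / 180)
}

#' Electronic-fence specification
#'
#' The electronic fence is a virtual boundary along the lower edge of the
#' camera's viewable area (by default the bottom frame edge); events whose
#' bounding box comes within `margin_px` of it are treated as fence-touching
#' and handled by the crafted rules. A custom polyline (matrix of x, y pixel
#' vertices) may be supplied.
#'
#' @param frame_height_px frame height in pixels (used for the default
#'   bottom-edge boundary).
#' @param frame_width_px frame width in pixels.
#' @param boundary optional n x 2 matrix of polyline vertices (x, y), pixel
#'   coordinates, origin top-left, y down.
#' @param margin_px nonnegative tolerance in pixels.
#' @return an object of class `fence_spec`.
#' @export
fence_spec <- function(frame_height_px, frame_width_px,
                       boundary = NULL, margin_px = 0) {
  if (margin_px < 0) stop("margin_px must be >= 0")
  if (is.null(boundary)) {
    boundary <- rbind(c(0, frame_height_px), c(frame_width_px, frame_height_px))
  }
  boundary <- as.matrix(boundary)
  if (ncol(boundary) != 2 || nrow(boundary) < 2)
    stop("boundary must be an n x 2 polyline with n >= 2")
  if (any(boundary[, 1] < 0) || any(boundary[, 1] > frame_width_px) ||
      any(boundary[, 2] < 0) || any(boundary[, 2] > frame_height_px))
    stop("boundary must lie within frame bounds")
  structure(list(boundary = boundary, margin_px = margin_px,
                 frame_height_px = frame_height_px,
                 frame_width_px = frame_width_px),
            class = "fence_spec")
}

# distance from a point to a segment
.point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Does a bounding box touch the electronic fence?
#'
#' True when the box comes within `margin_px` of the fence polyline. Boxes
#' are half-open `[x0, x1) x [y0, y1)` in pixel coordinates, origin top-left.
#'
#' @param box numeric vector `c(x0, y0, x1, y1)`.
#' @param fence a [fence_spec()].
#' @return logical.
#' @export
touches_fence <- function(box, fence) {
  stopifnot(inherits(fence, "fence_spec"), length(box) == 4)
  b <- fence$boundary
  m <- fence$margin_px
  # distance from the box (as a filled rectangle) to each boundary segment:
  # clamp segment sample points into the box and measure
  for (i in seq_len(nrow(b) - 1)) {
    x1 <- b[i, 1]; y1 <- b[i, 2]; x2 <- b[i + 1, 1]; y2 <- b[i + 1, 2]
    # sample the segment densely enough for pixel-scale fences
    n <- max(2, ceiling(sqrt((x2 - x1)^2 + (y2 - y1)^2)))
    t <- seq(0, 1, length.out = n)
    sx <- x1 + t * (x2 - x1); sy <- y1 + t * (y2 - y1)
    # distance from each sample to the rectangle
    ddx <- pmax(box[1] - sx, 0, sx - box[3])
    ddy <- pmax(box[2] - sy, 0, sy - box[4])
    if (min(sqrt(ddx^2 + ddy^2)) <= m) return(TRUE)
  }
  FALSE
}

# Weak-perspective projection used by the synthetic renderer.
#
# The renderer places an actor's base (feet) at lateral offset x_m and ground
# distance z_m from the camera wall and projects with a per-actor scale
# s = fy / z_cam (pixels per metre), where z_cam is the depth of the base
# point along the tilted optical axis. World offsets (dx, dy up, dz away)
# from the base map to image offsets
#   du = s * dx
#   dv = s * (-dy * cos(tau) - dz * sin(tau))
# which realises the cos(tau) foreshortening of vertical extents that the
# crafted rules assume. Returns the image position of the base point and the
# scale. Internal.
.project_base <- function(camera, x_m, z_m) {
  tau <- camera$downward_angle_deg * pi / 180
  hc <- camera$mount_height_m
  zc <- hc * sin(tau) + z_m * cos(tau)
  if (zc <= 0) stop("point behind the camera")
  s <- camera$fy / zc    # vertical scale, px per metre
  sx <- camera$fx / zc   # lateral scale, px per metre
  # image y of the base (floor) point under full perspective, so frame
  # placement is correct; x uses the same scale
  y_up <- (0 - hc) * cos(tau) + z_m * sin(tau)
  v <- camera$cy - camera$fy * y_up / zc
  u <- camera$cx + camera$fx * x_m / zc
  list(u = u, v = v, scale = s, scale_x = sx, tau = tau)
}
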