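#' @name scenario
#' @rdname scenario
NULL

.FALL_EVENTS <- c("stumble", "slip", "faint", "collapse_on_standing",
                  "fall_off_ladder", "jump_down_and_fall")
.NONFALL_EVENTS <- c("bow", "tie_shoelaces", "pushup", "situp",
                     "get_down_to_floor", "jump")

#' Event types known to the synthetic generator
#'
#' Six fall types and six daily (non-fall) activities.
#' @return character vector of event type names.
#' @export
event_types <- function() c(.FALL_EVENTS, .NONFALL_EVENTS)

#' Is an event type a fall?
#' @param event_type character.
#' @return logical.
#' @export
is_fall_event <- function(event_type) event_type %in% .FALL_EVENTS

# Per-event default section durations (background, initial, true, post), s.
# The background default is 5 s (desk scale; a live deployment would use
# a much longer background section) and is configurable.
.default_sections <- function(event_type) {
  switch(event_type,
    stumble = ,
    slip = ,
    faint = ,
    collapse_on_standing = ,
    fall_off_ladder = ,
    jump_down_and_fall = c(5, 0.6, 0.5, 5),
    bow = c(5, 1.2, 2.6, 5),
    tie_shoelaces = c(5, 0.5, 2.0, 5),
    pushup = c(5, 2.0, 6.0, 5),
    situp = c(5, 2.0, 6.0, 5),
    get_down_to_floor = c(5, 1.5, 2.0, 5),
    jump = c(5, 0.4, 0.6, 5),
    stop("unknown event type: ", event_type))
}

#' Describe a synthetic fall / daily-activity scenario
#'
#' A scenario fixes everything the renderer needs to produce a clip
#' deterministically: the event type, the direction of the action relative to
#' the camera (0 deg = toward the camera, in 30-degree increments), the ground
#' distance from the camera, frame rate, actor height, the four-section clip
#' structure (background / initial fall 90->60 deg / true fall 60->0 deg /
#' post fall), and a seed. Identical scenario + camera + seed yields a
#' bitwise-identical clip.
#'
#' @param event_type one of [event_types()].
#' @param direction_deg multiple of 30 in \[0, 330\]; 0 = toward the camera,
#'   90 = to the camera's right, 180 = away.
#' @param distance_m ground distance of the actor from the camera (> 0).
#' @param fps frames per second (> 0).
#' @param actor_height_m standing height of the actor in metres.
#' @param seed integer RNG seed for the clip.
#' @param section_durations_s numeric(4), nonnegative durations in seconds of
#'   the background, initial-fall, true-fall and post-fall sections; `NULL`
#'   uses per-event defaults (for non-fall events sections 2-3 hold the
#'   action).
#' @param lateral_offset_m lateral position of the actor (metres, + right).
#' @param occluders optional list of static occluder rectangles, each
#'   `c(x0, y0, x1, y1)` in pixels, drawn over the scene.
#' @param bystander add a second, walking (non-falling) actor?
#' @return an object of class `fall_scenario`.
#' @examples
#' sc <- scenario("stumble", direction_deg = 0, distance_m = 3, fps = 10)
#' @export
scenario <- function(event_type, direction_deg = 0, distance_m = 3,
                     fps = 10, actor_height_m = 1.7, seed = 1,
                     section_durations_s = NULL, lateral_offset_m = 0,
                     occluders = NULL, bystander = FALSE) {
  event_type <- match.arg(event_type, event_types())
  if (!(direction_deg %in% seq(0, 330, by = 30)))
    stop("direction_deg must be a multiple of 30 in [0, 330]")
  if (distance_m <= 0) stop("distance_m must be > 0")
  if (fps <= 0) stop("fps must be > 0")
  if (actor_height_m <= 0) stop("actor_height_m must be > 0")
  if (is.null(section_durations_s))
    section_durations_s <- .default_sections(event_type)
  if (length(section_durations_s) != 4 || any(section_durations_s < 0))
    stop("section_durations_s must be four nonnegative durations")
  structure(list(
    event_type = event_type, direction_deg = direction_deg,
    distance_m = distance_m, fps = fps, actor_height_m = actor_height_m,
    seed = as.integer(seed), section_durations_s = section_durations_s,
    lateral_offset_m = lateral_offset_m, occluders = occluders,
    bystander = isTRUE(bystander),
    label = if (is_fall_event(event_type)) "fall" else "non-fall"
  ), class = "fall_scenario")
}

#' @export
print.fall_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s (%s), direction %d deg, %g m, %g FPS, seed %d\n",
              x$event_type, x$label, x$direction_deg, x$distance_m, x$fps,
              x$seed))
  cat(sprintf("  sections (bg/initial/true/post): %s s\n",
              paste(x$section_durations_s, collapse = "/")))
  invisible(x)
}

# smooth ramp with continuous velocity (3u^2 - 2u^3)
.sstep <- function(u) { u <- pmin(1, pmax(0, u)); u * u * (3 - 2 * u) }

# Pose of the articulated actor at absolute clip time t (seconds).
# Returns list(theta_legs, theta_torso [deg from ground], base_height_m,
# disp_m [ground displacement along the action direction]).
# Fall events follow the section structure exactly: 90 -> 60 linear in the
# initial section, then constant angular acceleration 60 -> 0 in the true
# section (free-fall-like). Non-fall schedules are slow by construction so
# that their normalized accelerations stay strictly below the fall regime;
# `jump` is the sanctioned exception (fast landing crouch).
.pose_at <- function(scn, t) {
  d <- scn$section_durations_s
  t1 <- d[1]; t2 <- t1 + d[2]; t3 <- t2 + d[3]
  A <- d[2] + d[3]                      # action duration for non-falls
  a <- if (A > 0) (t - t1) / A else 1   # normalized action time
  ev <- scn$event_type
  legs <- 90; torso <- 90; base <- 0; disp <- 0

  if (is_fall_event(ev)) {
    theta <- if (t < t1) 90
    else if (t < t2) 90 - 30 * (t - t1) / d[2]
    else if (t < t3) { s <- (t - t2) / d[3]; 60 * (1 - s * s) }
    else 0
    legs <- torso <- theta
    h0 <- switch(ev, fall_off_ladder = 1.0, jump_down_and_fall = 0.8, 0)
    if (h0 > 0) {
      base <- if (t < t2) h0
      else if (t < t3) { s <- (t - t2) / d[3]; h0 * (1 - s * s) }
      else 0
    }
    # feet slide out during a slip
    if (ev == "slip" && t >= t1)
      disp <- -0.25 * scn$actor_height_m * .sstep((t - t1) / max(A, 1e-9))
  } else if (ev == "bow") {
    dn <- 1.2; up <- 1.2
    torso <- if (t < t1) 90
    else if (t < t1 + dn) 90 - 75 * .sstep((t - t1) / dn)
    else if (t < t3 - up) 15
    else if (t < t3) 15 + 75 * .sstep((t - (t3 - up)) / up)
    else 90
  } else if (ev == "tie_shoelaces") {
    dn <- 0.5; up <- 0.5
    u <- if (t < t1) 0
    else if (t < t1 + dn) .sstep((t - t1) / dn)
    else if (t < t3 - up) 1
    else if (t < t3) 1 - .sstep((t - (t3 - up)) / up)
    else 0
    legs <- 90 - 55 * u; torso <- 90 - 45 * u
  } else if (ev == "pushup" || ev == "situp") {
    dn <- 2.0; up <- 2.0
    low_l <- if (ev == "pushup") 25 else 22
    low_t <- if (ev == "pushup") 25 else 30
    if (t < t1) { legs <- torso <- 90 }
    else if (t < t1 + dn) {
      u <- .sstep((t - t1) / dn)
      legs <- 90 - (90 - low_l) * u; torso <- 90 - (90 - low_t) * u
    } else if (t < t3 - up) {
      legs <- low_l
      osc <- sin(2 * pi * 0.35 * (t - t1 - dn))
      torso <- low_t + (if (ev == "pushup") 8 else 15) * (0.5 + 0.5 * osc)
    } else if (t < t3) {
      u <- .sstep((t - (t3 - up)) / up)
      legs <- low_l + (90 - low_l) * u; torso <- low_t + (90 - low_t) * u
    } else { legs <- torso <- 90 }
  } else if (ev == "get_down_to_floor") {
    # slow, controlled descent all the way to the floor; stays down
    u <- .sstep((t - t1) / max(A, 1e-9))
    if (t < t1) u <- 0
    legs <- torso <- 90 - 84 * u
  } else if (ev == "jump") {
    prep <- 0.25; v0 <- 2.42; g <- 9.81; flight <- 2 * v0 / g  # apex ~0.3 m
    land <- 0.3
    tt <- t - t1
    if (t < t1) { legs <- torso <- 90 }
    else if (tt < prep) { legs <- 90 - 25 * .sstep(tt / prep) }
    else if (tt < prep + flight) {
      tf <- tt - prep
      base <- max(0, v0 * tf - 0.5 * g * tf^2)
    } else if (tt < prep + flight + land) {
      # fast landing crouch: the one non-fall with fall-like acceleration
      u <- (tt - prep - flight) / land
      dip <- sin(pi * min(1, u))
      legs <- 90 - 45 * dip; torso <- 90 - 30 * dip
    } else { legs <- torso <- 90 }
  }
  list(theta_legs = legs, theta_torso = torso, base_height = base,
       disp = disp)
}
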