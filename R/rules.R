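# Crafted post-classifier rules: the scenarios a bare clip classifier would
# get wrong (subject partly off screen, steep downward viewing angle,
# electronic-fence contact, very fast bends, purposeful jumps) are resolved
# with explicit, documented logic on the fall-parameter series.

#' Pipeline configuration
#'
#' Collects the tunable thresholds of the monitor and rule engine with
#' their defaults. Any subset may be overridden.
#'
#' @param ... name-value overrides of the defaults listed below.
#' @return a named list (class `fallmon_config`).
#' @section Defaults:
#' \describe{
#'   \item{tau_classifier = 0.5}{fall-probability threshold; raise for a
#'     high-precision profile, lower for high recall.}
#'   \item{visible_min = 0.6}{minimum visible body fraction (Scenario I).}
#'   \item{inactive_s = 10}{stillness (s) that confirms a fall in
#'     ambiguous scenarios.}
#'   \item{steep_angle_deg = 45}{downward angle beyond which the
#'     steep-angle final-height rules apply (Scenario II).}
#'   \item{forward_final = c(0.65, 0.95)}{admissible final apparent-height
#'     ratio for a forward fall at steep angles.}
#'   \item{backward_final = c(0.40, 0.70)}{same for a backward fall.}
#'   \item{sideway_final = c(0, 0.70)}{same for a sideway fall.}
#'   \item{fast_bend_s = 0.3}{descents completing faster than this with
#'     immediately resumed motion are rejected (shoelace pattern).}
#'   \item{recover_ratio = 0.8}{post-event height recovery above this
#'     fraction of `H_0` marks a purposeful, non-fall event.}
#'   \item{inactive_v = 0.05}{|V| (1/s) below which the subject counts as
#'     still.}
#'   \item{inactive_disp_frac = 0.02}{box-center displacement per second,
#'     as a fraction of frame height, below which the subject is still.}
#'   \item{v_trigger = 0.4}{minimum peak descent velocity (1/s) for a path
#'     to yield a candidate event.}
#'   \item{background_s = 2}{seconds of leading frames used for the
#'     background model.}
#'   \item{n_best = 3}{candidate paths kept by the Viterbi step.}
#'   \item{refractory_s = 30}{at most one alarm per path per this window.}
#'   \item{min_fps = 7}{below this nominal rate the monitor warns and flags
#'     operation as degraded.}
#'   \item{crop_padding = 0.25}{box dilation when cropping clips.}
#' }
#' @export
fallmon_config <- function(...) {
  cfg <- list(
    tau_classifier = 0.5, visible_min = 0.6, inactive_s = 10,
    steep_angle_deg = 45, forward_final = c(0.65, 0.95),
    backward_final = c(0.40, 0.70), sideway_final = c(0, 0.70),
    fast_bend_s = 0.3, recover_ratio = 0.8,
    inactive_v = 0.05, inactive_disp_frac = 0.02,
    v_trigger = 0.4, background_s = 2, n_best = 3, refractory_s = 30,
    min_fps = 7, crop_padding = 0.25)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "fallmon_config")
}

# event (descent) window on a series: frames where V exceeds half its peak
.event_window <- function(series, v_trigger) {
  V <- series$V
  if (all(is.na(V))) return(NULL)
  vmax <- max(V, na.rm = TRUE)
  if (vmax < v_trigger) return(NULL)
  hi <- which(!is.na(V) & V > 0.5 * vmax)
  c(min(hi), max(hi))
}

# duration (s) of the stillness run at the end of the series
.inactive_duration <- function(series, boxes, frame_h, cfg) {
  n <- nrow(series)
  if (n < 2) return(0)
  cx <- (boxes$x0 + boxes$x1) / 2
  cy <- (boxes$y0 + boxes$y1) / 2
  tt <- series$T
  ok <- rep(TRUE, n)
  for (i in 2:n) {
    dt <- tt[i] - tt[i - 1]
    rate <- sqrt((cx[i] - cx[i - 1])^2 + (cy[i] - cy[i - 1])^2) / dt
    still <- rate < cfg$inactive_disp_frac * frame_h / 1 &&
      (is.na(series$V[i]) || abs(series$V[i]) < cfg$inactive_v)
    ok[i] <- still
  }
  # maximal still suffix
  i <- n
  while (i >= 2 && ok[i]) i <- i - 1
  if (i >= n) 0 else tt[n] - tt[i]
}

#' Apply the crafted rules to a candidate fall
#'
#' Evaluates the rule table on a fall-parameter series and its track path:
#' Scenario I (subject substantially off screen) suppresses the event;
#' Scenario II (downward viewing angle beyond 45 degrees) accepts only
#' falls whose final apparent-height ratio lies in the direction-specific
#' band (forward 0.65-0.95, backward 0.40-0.70) and that are followed by
#' more than `inactive_s` seconds of stillness; Scenario III
#' (electronic-fence contact) likewise requires the inactivity
#' confirmation; a fast-bend guard rejects descents completing in under
#' `fast_bend_s` with immediately resumed motion; a post-event activity
#' check rejects events after which the subject stands back up (purposeful
#' jumps).
#'
#' @param series a [extract_series()] result.
#' @param path the matching `track_path` (or its `boxes` data frame).
#' @param camera the [camera_model()] (supplies the downward angle and
#'   frame size).
#' @param fence a [fence_spec()]; `NULL` for the default bottom-edge fence.
#' @param config a [fallmon_config()].
#' @param visible_fraction optional explicit visible body fraction; when
#'   `NULL` it is estimated from frame-edge contact of the path boxes.
#' @return object of class `rule_verdict`: `scenario_flags`,
#'   `visible_fraction`, `final_height_ratio`, `inactive_duration_s`,
#'   `direction`, `passed`, `reasons` (ordered rule trace; nonempty
#'   whenever `passed` is `FALSE`).
#' @export
apply_rules <- function(series, path, camera, fence = NULL,
                        config = fallmon_config(), visible_fraction = NULL) {
  cfg <- config
  boxes <- if (inherits(path, "track_path")) path$boxes else path
  flags <- character(0); reasons <- character(0)
  fail <- function(passed, vf, fr, inact, dir) {
    structure(list(scenario_flags = flags, visible_fraction = vf,
                   final_height_ratio = fr, inactive_duration_s = inact,
                   direction = dir, passed = passed, reasons = reasons),
              class = "rule_verdict")
  }
  if (is.null(series) || nrow(series) < 3) {
    reasons <- "series shorter than 3 frames: undeterminable, suppressed"
    return(fail(FALSE, NA_real_, NA_real_, 0, NA_character_))
  }
  if (nrow(boxes) != nrow(series)) {
    rows <- match(series$frame, boxes$frame)
    if (anyNA(rows)) stop("path does not cover the series frames")
    boxes <- boxes[rows, , drop = FALSE]
  }
  # geometry rules run on the tight silhouette boxes when available: the
  # detector's search windows are clamped to the frame and would report
  # spurious frame-edge and fence contact
  if (all(c("bx0", "by0", "bx1", "by1") %in% names(series)) &&
      !anyNA(series$bx0)) {
    boxes <- data.frame(frame = series$frame, x0 = series$bx0,
                        y0 = series$by0, x1 = series$bx1, y1 = series$by1)
  }
  H_0 <- attr(series, "H_0")
  n <- nrow(series)
  frame_h <- camera$height_px; frame_w <- camera$width_px
  if (is.null(fence)) fence <- fence_spec(frame_h, frame_w)

  ew <- .event_window(series, cfg$v_trigger)
  post_idx <- if (is.null(ew)) n else min(n, ew[2] + 1):n
  ev_idx <- if (is.null(ew)) seq_len(n) else ew[1]:ew[2]

  # final apparent-height ratio over the last few frames
  last <- max(1, n - 2):n
  final_ratio <- mean(series$H[last]) / H_0

  # visible fraction: 1 unless boxes hit the side/top frame borders, in
  # which case the truncated extent is compared to the largest one seen
  vf <- visible_fraction
  if (is.null(vf)) {
    vf <- 1
    side <- boxes$x0[ev_idx] <= 1 | boxes$x1[ev_idx] >= frame_w - 1
    topc <- boxes$y0[ev_idx] <= 1
    if (any(side)) {
      Wmax <- max(series$W, na.rm = TRUE)
      vf <- min(vf, min(series$W[ev_idx][side], na.rm = TRUE) / Wmax)
    }
    if (any(topc)) vf <- min(vf, min(series$H[ev_idx][topc] / H_0, na.rm = TRUE))
  }

  inact <- .inactive_duration(series, boxes, frame_h, cfg)

  # direction from the base-level shift across the event
  pre_base <- boxes$y1[max(1, (if (is.null(ew)) 1 else ew[1]) - 1)]
  post_base <- boxes$y1[n]
  dbase <- post_base - pre_base
  direction <- if (dbase > cfg$inactive_disp_frac * frame_h * 2) "forward"
  else if (final_ratio >= cfg$backward_final[1]) "backward"
  else "sideway"

  passed <- TRUE

  # Scenario I: too much of the body off screen — not enough to analyse
  if (vf < cfg$visible_min) {
    flags <- c(flags, "off_screen_I")
    reasons <- c(reasons, sprintf(
      "Scenario I: only %.0f%% of the body visible (< %.0f%%), suppressed",
      100 * vf, 100 * cfg$visible_min))
    passed <- FALSE
  }

  # Scenario II: steep downward viewing angle
  if (camera$downward_angle_deg > cfg$steep_angle_deg) {
    flags <- c(flags, "steep_angle_II")
    band <- switch(direction, forward = cfg$forward_final,
                   backward = cfg$backward_final, cfg$sideway_final)
    in_band <- final_ratio >= band[1] && final_ratio <= band[2]
    if (!in_band) {
      reasons <- c(reasons, sprintf(
        "Scenario II: final height ratio %.2f outside the %s band [%.2f, %.2f]",
        final_ratio, direction, band[1], band[2]))
      passed <- FALSE
    } else if (inact <= cfg$inactive_s) {
      reasons <- c(reasons, sprintf(
        "Scenario II: inactive %.1f s does not exceed %.0f s, unconfirmed",
        inact, cfg$inactive_s))
      passed <- FALSE
    }
  }

  # Scenario III: electronic-fence contact
  fence_hit <- any(vapply(post_idx, function(i)
    touches_fence(c(boxes$x0[i], boxes$y0[i], boxes$x1[i], boxes$y1[i]),
                  fence), TRUE))
  if (fence_hit) {
    flags <- c(flags, "fence_touch_III")
    if (inact <= cfg$inactive_s) {
      reasons <- c(reasons, sprintf(
        paste0("Scenario III: fence touched and inactive %.1f s does not",
               " exceed %.0f s, suppressed"), inact, cfg$inactive_s))
      passed <- FALSE
    }
  }

  # fast-bend guard (tying-shoelaces pattern)
  if (!is.null(ew)) {
    descent_s <- series$T[ew[2]] - series$T[ew[1]]
    resumed <- inact < 2
    if (descent_s < cfg$fast_bend_s && resumed && inact <= cfg$inactive_s) {
      reasons <- c(reasons, sprintf(
        "fast bend: descent in %.2f s with resumed motion, rejected",
        descent_s))
      passed <- FALSE
    }
  }

  # post-event activity: subject standing back up marks a purposeful event
  if (length(post_idx) >= 2 && !is.null(ew)) {
    recov <- max(series$H[post_idx]) / H_0
    if (recov > cfg$recover_ratio) {
      reasons <- c(reasons, sprintf(
        "post-event recovery to %.0f%% of H0: purposeful action, rejected",
        100 * recov))
      passed <- FALSE
    }
  }

  fail(passed, vf, final_ratio, inact, direction)
}

#' @export
print.rule_verdict <- function(x, ...) {
  cat(sprintf("Rule verdict: %s", if (x$passed) "PASSED" else "suppressed"))
  if (length(x$scenario_flags))
    cat(" [", paste(x$scenario_flags, collapse = ", "), "]", sep = "")
  cat(sprintf("\n  visible %.2f, final height ratio %.2f, inactive %.1f s, %s\n",
              x$visible_fraction, x$final_height_ratio,
              x$inactive_duration_s, x$direction))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
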