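# 10 FPS height trajectory: upright hold, fast descent, ground hold
fall_profile <- function(pre_s = 1, post_s, H_0 = 100, H_final = 15,
                         descent_s = 0.5, dT = 0.1) {
  T <- seq(0, pre_s + descent_s + post_s, by = dT)
  H <- vapply(T, function(t) {
    if (t < pre_s) H_0
    else if (t < pre_s + descent_s)
      H_0 - (H_0 - H_final) * (t - pre_s) / descent_s
    else H_final
  }, 0)
  list(T = T, H = H)
}

centered_boxes <- function(T, H, frame_w = 160, frame_h = 120, cx = 80,
                           ground = 100) {
  n <- length(H)
  data.frame(frame = seq_len(n), x0 = cx - 10, y0 = ground - H,
             x1 = cx + 10, y1 = rep(ground, n))
}

test_that("an unremarkable fall passes with no scenario flags", {
  pf <- fall_profile(post_s = 12)
  boxes <- centered_boxes(pf$T, pf$H)
  ser <- make_series(pf$T, pf$H,
                     bx = boxes[, c("x0", "y0", "x1", "y1")])
  cam <- camera_model(160, 120, 110, downward_angle_deg = 0)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config())
  expect_true(v$passed)
  expect_length(v$scenario_flags, 0)
  expect_length(v$reasons, 0)
  expect_equal(v$visible_fraction, 1)
})

test_that("fence-touching descent with resumed motion is suppressed", {
  pf <- fall_profile(post_s = 3)
  n <- length(pf$H)
  # subject walks away after 3 s: moving box centers at the end
  boxes <- centered_boxes(pf$T, pf$H, ground = 120)  # boxes on the fence
  walk <- (n - 9):n
  boxes$x0[walk] <- boxes$x0[walk] + seq(2, 20, length.out = 10)
  boxes$x1[walk] <- boxes$x1[walk] + seq(2, 20, length.out = 10)
  pf$H[walk] <- 100  # back upright
  ser <- make_series(pf$T, pf$H, H_0 = 100,
                     bx = boxes[, c("x0", "y0", "x1", "y1")])
  cam <- camera_model(160, 120, 110)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config())
  expect_false(v$passed)
  expect_true("fence_touch_III" %in% v$scenario_flags)
  expect_true(any(grepl("Scenario III", v$reasons)))
  expect_lte(v$inactive_duration_s, 10)
})

test_that("steep-angle backward fall with long stillness is accepted", {
  # final apparent-height ratio 0.55, still for 12 s, tau = 50 degrees
  pf <- fall_profile(post_s = 12, H_0 = 100, H_final = 55)
  boxes <- centered_boxes(pf$T, pf$H, ground = 90)
  ser <- make_series(pf$T, pf$H, H_0 = 100,
                     bx = boxes[, c("x0", "y0", "x1", "y1")])
  cam <- camera_model(160, 120, 110, downward_angle_deg = 50)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config())
  expect_true(v$passed)
  expect_true("steep_angle_II" %in% v$scenario_flags)
  expect_equal(v$direction, "backward")
  expect_equal(v$final_height_ratio, 0.55, tolerance = 0.02)
  expect_gt(v$inactive_duration_s, 10)

  # forward fall (base shifts down-frame) with a collapsed final ratio:
  # outside the forward band [0.65, 0.95], suppressed
  pf2 <- fall_profile(post_s = 12, H_0 = 100, H_final = 20)
  boxes2 <- centered_boxes(pf2$T, pf2$H, ground = 90)
  after <- pf2$T > 1               # strictly after the pre-event reference
  boxes2$y1[after] <- 100          # base drops 10 px during the fall
  boxes2$y0 <- boxes2$y1 - pf2$H
  ser2 <- make_series(pf2$T, pf2$H, H_0 = 100,
                      bx = boxes2[, c("x0", "y0", "x1", "y1")])
  v2 <- apply_rules(ser2, boxes2, cam, config = fallmon_config())
  expect_equal(v2$direction, "forward")
  expect_false(v2$passed)
  expect_true(any(grepl("Scenario II", v2$reasons)))
})

test_that("a mostly off-screen subject triggers Scenario I", {
  pf <- fall_profile(post_s = 12)
  boxes <- centered_boxes(pf$T, pf$H)
  ser <- make_series(pf$T, pf$H,
                     bx = boxes[, c("x0", "y0", "x1", "y1")])
  cam <- camera_model(160, 120, 110)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config(),
                   visible_fraction = 0.4)
  expect_false(v$passed)
  expect_true("off_screen_I" %in% v$scenario_flags)
  expect_true(any(grepl("Scenario I", v$reasons)))
})

test_that("sub-0.3-second bends with resumed motion are rejected", {
  # descent in 0.2 s at 20 FPS, then immediately back up
  dT <- 0.05
  T <- seq(0, 4, by = dT)
  H <- vapply(T, function(t) {
    if (t < 1) 100
    else if (t < 1.2) 100 - 85 * (t - 1) / 0.2
    else if (t < 2.0) 15
    else 100
  }, 0)
  boxes <- centered_boxes(T, H)
  # keep moving afterwards
  tail10 <- (length(T) - 19):length(T)
  boxes$x0[tail10] <- boxes$x0[tail10] + seq(1, 40, length.out = 20)
  boxes$x1[tail10] <- boxes$x1[tail10] + seq(1, 40, length.out = 20)
  ser <- make_series(T, H, H_0 = 100,
                     bx = boxes[, c("x0", "y0", "x1", "y1")])
  cam <- camera_model(160, 120, 110)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config())
  expect_false(v$passed)
  expect_true(any(grepl("fast bend|recovery", v$reasons)))
})

test_that("post-event recovery to standing rejects purposeful events", {
  dT <- 0.1
  T <- seq(0, 6, by = dT)
  H <- vapply(T, function(t) {
    if (t < 1) 100
    else if (t < 1.5) 100 - 85 * (t - 1) / 0.5
    else if (t < 3) 15
    else 100  # stands back up
  }, 0)
  boxes <- centered_boxes(T, H)
  ser <- make_series(T, H, H_0 = 100,
                     bx = boxes[, c("x0", "y0", "x1", "y1")])
  cam <- camera_model(160, 120, 110)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config())
  expect_false(v$passed)
  expect_true(any(grepl("recovery", v$reasons)))
})

test_that("degenerate series are suppressed with a reason", {
  cam <- camera_model(160, 120, 110)
  ser <- make_series(c(0, 0.1), c(100, 99))
  boxes <- make_boxes(2, 10, 10, 30, 60)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config())
  expect_false(v$passed)
  expect_gt(length(v$reasons), 0)
})

test_that("every failure carries a nonempty reason trace", {
  # property over the worked examples: !passed implies reasons
  pf <- fall_profile(post_s = 3)
  boxes <- centered_boxes(pf$T, pf$H, ground = 120)
  ser <- make_series(pf$T, pf$H,
                     bx = boxes[, c("x0", "y0", "x1", "y1")])
  cam <- camera_model(160, 120, 110, downward_angle_deg = 50)
  v <- apply_rules(ser, boxes, cam, config = fallmon_config())
  if (!v$passed) expect_gt(length(v$reasons), 0)
})

test_that("configuration rejects unknown fields and accepts overrides", {
  cfg <- fallmon_config(tau_classifier = 0.7, inactive_s = 5)
  expect_equal(cfg$tau_classifier, 0.7)
  expect_equal(cfg$inactive_s, 5)
  expect_equal(cfg$visible_min, 0.6)
  expect_error(fallmon_config(bogus = 1), "unknown config fields")
})
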