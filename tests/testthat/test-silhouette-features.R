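test_that("background subtraction yields clean 1-bit masks", {
  # static scene: all-zero masks
  f <- matrix(runif(50 * 60), 50, 60)
  masks <- subtract_background(list(f, f, f))
  expect_true(all(vapply(masks, function(m) all(m == 0), TRUE)))
  expect_true(all(vapply(masks, is.integer, TRUE)))

  # additive noise below the threshold: still all zero
  noisy <- f + matrix(runif(50 * 60, -0.05, 0.05), 50, 60)
  masks <- subtract_background(list(f, noisy), threshold = 25 / 255)
  expect_true(all(masks[[2]] == 0))

  # synthetic actor: mask bounding box overlaps truth at IoU >= 0.7
  fix <- fx_stumble_series()
  tr <- fix$clip$truth
  k <- which(tr$visible)[3]
  m <- fix$masks[[k]]
  idx <- which(m == 1, arr.ind = TRUE)
  mbox <- c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
  tbox <- c(tr$x0[k], tr$y0[k], tr$x1[k], tr$y1[k])
  expect_gte(fallmon:::.box_iou(mbox, tbox), 0.7)
})

test_that("silhouette measurement returns extents and tight boxes", {
  m <- matrix(0L, 120, 60)
  m[11:110, 11:50] <- 1L
  hw <- measure_silhouette(m)
  expect_equal(as.numeric(hw), c(100, 40))
  expect_equal(unname(attr(hw, "box")), c(10, 10, 50, 110))

  m1 <- matrix(0L, 20, 20); m1[5, 7] <- 1L
  expect_equal(as.numeric(measure_silhouette(m1)), c(1, 1))

  expect_null(measure_silhouette(matrix(0L, 10, 10)))
  expect_error(measure_silhouette(m, c(-1, 0, 10, 10)), "outside")

  # upright synthetic actor: H within 5% of the analytic truth height (the
  # rasterizer samples pixel centres, trimming the sub-pixel ellipse tips)
  fix <- fx_stumble_series()
  tr <- fix$clip$truth
  k <- which(tr$visible)[2]
  hw <- measure_silhouette(fix$masks[[k]],
                           c(tr$x0[k], tr$y0[k], tr$x1[k], tr$y1[k]))
  expect_equal(hw[["H"]], tr$H_px[k], tolerance = 0.05)
})

test_that("tilt angle is the arcsine of the height ratio", {
  expect_equal(tilt_angle(180, 180), 90)
  expect_equal(tilt_angle(0, 180), 0)
  expect_equal(tilt_angle(90, 180), 30, tolerance = 1e-12)
  expect_equal(tilt_angle(200, 180), 90)  # clipped
  expect_error(tilt_angle(10, 0), "H_0")
})

test_that("velocity matches Eq. (1) and its hand-worked example", {
  expect_equal(fall_velocity(100, 100, 0, 0.1, 100), 0)
  expect_equal(fall_velocity(180, 162, 0.5, 0.6, 180), 1.0, tolerance = 1e-12)
  # linear descent gives constant velocity
  H <- seq(100, 60, by = -4); T <- seq(0, 1, by = 0.1)
  n <- length(H)
  V <- fall_velocity(H[-n], H[-1], T[-n], T[-1], 100)
  expect_lt(diff(range(V)), 1e-9)
  expect_error(fall_velocity(1, 1, 1, 1, 100), "increasing")
})

test_that("acceleration matches Eq. (3) on the hand-worked example", {
  expect_equal(fall_acceleration(100, 90, 70, 0, 0.1, 0.2, 100), 10,
               tolerance = 1e-9)
  expect_equal(fall_acceleration_uniform(100, 90, 70, 0.1, 100), 10,
               tolerance = 1e-9)
  # constant-velocity descent: zero acceleration
  expect_equal(fall_acceleration(100, 90, 80, 0, 0.1, 0.2, 100), 0,
               tolerance = 1e-9)
})

test_that("general and uniform acceleration agree on 1000 random series", {
  set.seed(99)
  for (rep in 1:1000) {
    H <- runif(3, 10, 200)
    dT <- runif(1, 0.01, 0.5)
    H_0 <- runif(1, 100, 250)
    t0 <- runif(1, 0, 10)
    a2 <- fall_acceleration(H[1], H[2], H[3], t0, t0 + dT, t0 + 2 * dT, H_0)
    a3 <- fall_acceleration_uniform(H[1], H[2], H[3], dT, H_0)
    expect_equal(a2, a3, tolerance = 1e-9)
  }
})

test_that("discrete integration of velocity recovers the height series", {
  set.seed(7)
  H <- cumsum(c(150, -runif(30, 0, 5)))
  T <- cumsum(c(0, runif(30, 0.05, 0.2)))
  H_0 <- 150
  n <- length(H)
  V <- fall_velocity(H[-n], H[-1], T[-n], T[-1], H_0)
  # telescoping: H_i = H_1 - H_0 * sum_j V_j * dT_j
  H_rec <- H[1] - H_0 * cumsum(V * diff(T))
  expect_equal(H_rec, H[-1], tolerance = 1e-9)
})

test_that("extracted series matches the generator on a stumble clip", {
  fix <- fx_stumble_series()
  ser <- fix$series
  expect_s3_class(ser, "fall_feature_series")
  expect_true(all(c("H", "W", "theta", "V", "a", "bx0") %in% names(ser)))
  # V defined from the 2nd row, a from the 3rd
  expect_true(is.na(ser$V[1]) && !is.na(ser$V[2]))
  expect_true(all(is.na(ser$a[1:2])) && !is.na(ser$a[3]))
  expect_equal(attr(ser, "dT"), 0.1, tolerance = 1e-9)
  expect_true(attr(ser, "H_0_reliable"))
  # endpoints: upright at the start; flat at the end (the articulated body
  # keeps its ~0.11 H_0 thickness when lying, so the terminal angle floor
  # is the body-thickness angle, not exactly 0)
  expect_equal(ser$theta[1], 90, tolerance = 5)
  expect_lt(ser$theta[nrow(ser)], 15)
  expect_lt(ser$H[nrow(ser)] / attr(ser, "H_0"), 0.3)
  # extracted V correlates with truth V at r >= 0.9
  tr <- fix$clip$truth
  k <- match(ser$frame, tr$frame)
  Ht <- tr$H_px[k]; Tt <- fix$clip$timestamps[k]
  n <- length(Ht)
  Vt <- c(NA, fall_velocity(Ht[-n], Ht[-1], Tt[-n], Tt[-1],
                            fix$clip$H_upright_px))
  ok <- !is.na(Vt) & !is.na(ser$V)
  expect_gte(cor(ser$V[ok], Vt[ok]), 0.9)
})

test_that("a static subject yields zero velocity and acceleration", {
  m <- matrix(0L, 60, 80); m[21:50, 31:40] <- 1L
  masks <- rep(list(m), 6)
  boxes <- make_boxes(6, 28, 18, 44, 52)
  ser <- extract_series(masks, boxes, seq(0, 0.5, by = 0.1))
  expect_true(all(ser$V[-1] == 0))
  expect_true(all(ser$a[-(1:2)] == 0))
  expect_false(attr(ser, "H_0_reliable"))
})

test_that("short measurement gaps are interpolated, NTSC spacing preserved", {
  m <- matrix(0L, 60, 80); m[21:50, 31:40] <- 1L
  empty <- matrix(0L, 60, 80)
  masks <- list(m, m, empty, empty, m, m)
  boxes <- make_boxes(6, 28, 18, 44, 52)
  ts <- (0:5) / 29.97
  ser <- extract_series(masks, boxes, ts)
  expect_equal(nrow(ser), 6)
  expect_equal(ser$H[3], 30)  # interpolated between equal neighbours
  expect_equal(attr(ser, "dT"), 1 / 29.97, tolerance = 1e-12)
  # a gap longer than max_gap is dropped instead
  masks2 <- list(m, m, empty, empty, empty, m)
  ser2 <- extract_series(masks2, boxes, ts, max_gap = 2)
  expect_equal(nrow(ser2), 3)
})

test_that("series CSV export round-trips", {
  fix <- fx_stumble_series()
  f <- tempfile(fileext = ".csv")
  write_series_csv(fix$series, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(fix$series))
  expect_equal(back$H, fix$series$H)
  unlink(f)
})
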