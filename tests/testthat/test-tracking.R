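test_that("dynamic program equals exhaustive enumeration on 500 instances", {
  for (seed in 1:500) {
    cpf <- rand_instance(seed)
    radius <- if (seed %% 2 == 0) runif(1, 10, 60) else NULL
    paths <- viterbi_paths(cpf, smooth_radius_px = radius, n_best = 1)
    oracle <- viterbi_oracle_score(cpf, radius)
    expect_equal(paths[[1]]$score, oracle, tolerance = 1e-9,
                 label = paste("instance", seed))
  }
})

test_that("single-candidate chains return the unique path", {
  cpf <- lapply(1:4, function(f)
    data.frame(x0 = 10, y0 = 10, x1 = 20, y1 = 30,
               p_human = c(0.9, 0.8, 0.7, 0.95)[f]))
  paths <- viterbi_paths(cpf)
  expect_length(paths, 1)
  p <- paths[[1]]
  expect_equal(p$boxes$frame, 1:4)
  expect_equal(p$log_likelihood, sum(log(c(0.9, 0.8, 0.7, 0.95))),
               tolerance = 1e-9)
  expect_equal(p$score, p$log_likelihood, tolerance = 1e-9)
})

test_that("the toy two-frame example picks the highest product", {
  mkbox <- function(x, p) data.frame(x0 = x, y0 = 10, x1 = x + 10, y1 = 30,
                                     p_human = p)
  cpf <- list(rbind(mkbox(10, 0.9), mkbox(40, 0.2)),
              rbind(mkbox(12, 0.8), mkbox(42, 0.7)))
  p <- viterbi_paths(cpf, smooth_radius_px = 15, n_best = 1)[[1]]
  expect_equal(p$boxes$p_human, c(0.9, 0.8))
  expect_equal(exp(p$log_likelihood), 0.72, tolerance = 1e-9)

  # A -> C beyond the radius: falls back to the best admissible path
  cpf2 <- list(rbind(mkbox(10, 0.9), mkbox(40, 0.2)),
               rbind(mkbox(45, 0.8)))
  p2 <- viterbi_paths(cpf2, smooth_radius_px = 15, n_best = 1)[[1]]
  oracle <- viterbi_oracle_score(cpf2, 15)
  expect_equal(p2$score, oracle, tolerance = 1e-9)
  expect_equal(p2$boxes$p_human, c(0.2, 0.8))
})

test_that("path frames are strictly increasing and within the radius", {
  for (seed in c(11, 22, 33)) {
    cpf <- rand_instance(seed)
    paths <- viterbi_paths(cpf, smooth_radius_px = 40)
    for (p in paths) {
      fr <- p$boxes$frame
      expect_true(all(diff(fr) >= 1))
      expect_equal(p$log_likelihood, sum(log(p$boxes$p_human)),
                   tolerance = 1e-9)
      if (nrow(p$boxes) > 1) {
        cx <- (p$boxes$x0 + p$boxes$x1) / 2
        cy <- (p$boxes$y0 + p$boxes$y1) / 2
        dd <- sqrt(diff(cx)^2 + diff(cy)^2)
        expect_true(all(dd <= 40 * diff(fr) + 1e-9))
      }
    }
  }
})

test_that("removing a candidate never improves the best path", {
  set.seed(77)
  for (rep in 1:25) {
    cpf <- rand_instance(1000 + rep)
    s0 <- viterbi_paths(cpf, smooth_radius_px = 50, n_best = 1)[[1]]$score
    nz <- which(!vapply(cpf, is.null, TRUE))
    f <- sample(nz, 1)
    i <- sample(nrow(cpf[[f]]), 1)
    # removing the sole candidate of the first/last nonempty frame shrinks
    # the spanned range, dropping its skip penalties -- a different
    # objective, so monotonicity is only claimed away from the boundary
    if (nrow(cpf[[f]]) == 1 && f %in% range(nz)) next
    cpf[[f]] <- cpf[[f]][-i, , drop = FALSE]
    if (all(vapply(cpf, function(d) is.null(d) || nrow(d) == 0, TRUE))) next
    s1 <- viterbi_paths(cpf, smooth_radius_px = 50, n_best = 1)[[1]]$score
    expect_lte(s1, s0 + 1e-9)
  }
})

test_that("the n-best paths are candidate-disjoint", {
  set.seed(88)
  cpf <- lapply(1:5, function(f) {
    x0 <- runif(4, 0, 100); y0 <- runif(4, 0, 80)
    data.frame(x0 = x0, y0 = y0, x1 = x0 + 12, y1 = y0 + 25,
               p_human = runif(4, 0.2, 0.95))
  })
  paths <- viterbi_paths(cpf, smooth_radius_px = 200, n_best = 3)
  keys <- unlist(lapply(paths, function(p)
    paste(p$boxes$frame, p$boxes$x0, p$boxes$y0)))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(diff(vapply(paths, function(p) p$score, 0)) <= 1e-9))
})

test_that("human detection obeys motion gating and suppression", {
  models <- fx_models()
  fix <- fx_stumble_series()
  clip <- fix$clip
  # static frame: no candidates
  empty <- detect_humans(clip$frames[[1]],
                         matrix(0L, nrow(clip$frames[[1]]),
                                ncol(clip$frames[[1]])), models$human)
  expect_equal(nrow(empty), 0)
  # frame with the actor: best candidate overlaps truth at IoU >= 0.5
  tr <- clip$truth
  k <- which(tr$visible)[3]
  det <- detect_humans(clip$frames[[k]], fix$masks[[k]], models$human)
  expect_gt(nrow(det), 0)
  best <- det[which.max(det$p_human), ]
  iou <- fallmon:::.box_iou(c(best$x0, best$y0, best$x1, best$y1),
                            c(tr$x0[k], tr$y0[k], tr$x1[k], tr$y1[k]))
  expect_gte(iou, 0.5)
})

test_that("two non-overlapping actors survive suppression", {
  models <- fx_models()
  cam <- fx_camera()
  clip <- render_clip(scenario("bow", distance_m = 3, fps = 5, seed = 66,
                               bystander = TRUE,
                               section_durations_s = c(2, 1.2, 2.6, 1)), cam)
  masks <- subtract_background(clip$frames, background_window = c(1, 5, 9))
  k <- which(clip$truth$visible)[4]
  det <- detect_humans(clip$frames[[k]], masks[[k]], models$human)
  expect_gte(nrow(det), 2)
})

test_that("clip cropping respects padding and frame bounds", {
  frames <- lapply(1:3, function(i) matrix(runif(60 * 80), 60, 80))
  boxes <- data.frame(frame = 1:3, x0 = c(10, 0, 70), y0 = c(10, 0, 50),
                      x1 = c(30, 10, 80), y1 = c(40, 20, 60))
  crops0 <- crop_clip(frames, boxes, padding_fraction = 0)
  expect_equal(dim(crops0[[1]]), c(30, 20))
  # corner box stays within bounds and is never empty
  crops <- crop_clip(frames, boxes, padding_fraction = 0.25)
  expect_true(all(vapply(crops, function(m) all(dim(m) > 0), TRUE)))
  expect_equal(dim(crops[[3]]), c(60 - 47, 80 - 67))

  # a padded fall path keeps at least 95% of the truth foreground
  fix <- fx_stumble_series()
  clip <- fix$clip
  path <- fix$boxes
  crops <- crop_clip(clip$frames, path, padding_fraction = 0.25)
  total_fg <- kept_fg <- 0
  for (j in seq_len(nrow(path))) {
    k <- path$frame[j]
    m <- fix$masks[[k]]
    total_fg <- total_fg + sum(m)
    b <- path[j, ]
    bw <- b$x1 - b$x0; bh <- b$y1 - b$y0
    x0 <- max(0, floor(b$x0 - 0.25 * bw)); y0 <- max(0, floor(b$y0 - 0.25 * bh))
    x1 <- min(ncol(m), ceiling(b$x1 + 0.25 * bw))
    y1 <- min(nrow(m), ceiling(b$y1 + 0.25 * bh))
    kept_fg <- kept_fg + sum(m[(y0 + 1):y1, (x0 + 1):x1])
  }
  expect_gte(kept_fg / total_fg, 0.95)
})
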