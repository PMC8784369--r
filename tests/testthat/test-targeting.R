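test_that("displacement decomposition matches the axis-aligned case and Pythagoras", {
  p <- pose_at(c(0, 0, 0))
  d0 <- decompose_displacement(p, c(0, 0, 0))
  expect_equal(unname(d0$lateral), c(0, 0))
  expect_equal(d0$depth, 0)

  d <- decompose_displacement(p, c(3, 4, 5))
  expect_equal(unname(d$lateral), c(3, 4))
  expect_equal(d$depth, 5)
  expect_equal(d$lateral_norm, 5)

  set.seed(81)
  for (i in 1:200) {
    pose <- instrument_pose(rnorm(3, sd = 50), random_rotation())
    tgt <- rnorm(3, sd = 50)
    dd <- decompose_displacement(pose, tgt)
    expect_equal(dd$lateral_norm^2 + dd$depth^2, sum((tgt - pose$tip)^2),
                 tolerance = 1e-9)
  }
})

test_that("displacement is invariant under a joint world rotation", {
  set.seed(82)
  pose <- instrument_pose(c(10, -5, 3), random_rotation())
  tgt <- c(-20, 14, 40)
  base <- decompose_displacement(pose, tgt)
  for (i in 1:5) {
    T1 <- random_rigid()
    pose2 <- instrument_pose(apply_transform(T1, pose$tip),
                             T1$rotation %*% pose$axes)
    d2 <- decompose_displacement(pose2, apply_transform(T1, tgt))
    expect_near(d2$lateral, base$lateral, 1e-9)
    expect_equal(d2$depth, base$depth, tolerance = 1e-9)
  }
})

test_that("cue state honors its display contracts", {
  params <- display_params(lateral_scale = 10, depth_scale = 8,
                           in_range_radius = 5, zero_tolerance = 0.05,
                           out_of_range_circle_diameter = 120)
  mk <- function(lx, ly, depth) {
    structure(list(lateral = c(lx, ly), depth = depth,
                   lateral_norm = sqrt(lx^2 + ly^2),
                   total = sqrt(lx^2 + ly^2 + depth^2)),
              class = "tip_displacement")
  }
  # at target: cues overlap and the depth circle vanishes
  s <- cue_state(mk(0, 0, 0), params)
  expect_equal(s$mode, "in_range")
  expect_equal(unname(s$blob_offset_px), c(0, 0))
  expect_false(s$circle_visible)
  expect_false(s$blink)

  # overreach: blink, diameter proportional to |depth|
  s <- cue_state(mk(0.1, 0, -2), params)
  expect_true(s$blink)
  expect_equal(s$circle_diameter_px, 16)
  # ahead of target: same diameter, no blink
  expect_false(cue_state(mk(0.1, 0, 2), params)$blink)
  # proportionality: halving depth halves the diameter
  expect_equal(cue_state(mk(0, 0, 1), params)$circle_diameter_px,
               cue_state(mk(0, 0, 2), params)$circle_diameter_px / 2)

  # boundary: ties go in range; just beyond switches to the arrow display
  expect_equal(cue_state(mk(5, 0, 1), params)$mode, "in_range")
  s <- cue_state(mk(5 + 1e-9, 0, 1), params)
  expect_equal(s$mode, "out_of_range")
  expect_null(s$blob_offset_px)
  expect_equal(s$circle_diameter_px, 120)      # constant while out of range
  expect_equal(s$arrow_direction, 0)           # arrow along +x toward target
  expect_equal(cue_state(mk(0, 7, 1), params)$arrow_direction, pi / 2)

  # blink is still signalled out of range when overreached
  expect_true(cue_state(mk(9, 0, -3), params)$blink)

  # pure function: identical inputs give identical outputs
  expect_identical(cue_state(mk(1, 2, 3), params), cue_state(mk(1, 2, 3), params))
})

test_that("dwell capture stores a held position and rejects drift", {
  # constant position for 3 s at 10 Hz, dwell 2 s
  tt <- seq(0, 3, by = 0.1)
  pos <- matrix(rep(c(10, 20, 30), length(tt)), ncol = 3, byrow = TRUE)
  cap <- dwell_capture(tt, pos, stability_radius = 1, dwell_time = 2)
  expect_near(cap$position, c(10, 20, 30), 1e-12)
  expect_equal(cap$spread, 0)
  expect_equal(cap$dwell_start, 0)

  # continuous 5 mm/s drift never stabilizes within 1 mm over 2 s
  tt <- seq(0, 6, by = 0.1)
  drift <- cbind(5 * tt, 0 * tt, 0 * tt)
  expect_null(dwell_capture(tt, drift, stability_radius = 1, dwell_time = 2))
  # brute-force confirmation: every 2 s window spans 10 mm > 2 * radius
  expect_true(all(vapply(which(tt <= 4), function(i) {
    w <- which(tt >= tt[i] & tt <= tt[i] + 2)
    diff(range(drift[w, 1])) > 2
  }, logical(1))))

  # jitter around a point: captured near the true point
  set.seed(83)
  tt <- seq(0, 4, by = 0.05)
  pos <- matrix(rep(c(-5, 2, 7), length(tt)), ncol = 3, byrow = TRUE) +
    matrix(rnorm(3 * length(tt), sd = 0.2), ncol = 3)
  cap <- dwell_capture(tt, pos, stability_radius = 1, dwell_time = 2)
  expect_lt(sqrt(sum((cap$position - c(-5, 2, 7))^2)), 0.1)

  expect_error(dwell_capture(c(1, 0.5), matrix(0, 2, 3)), "sorted")
})

test_that("navigation replay summarizes path length, duration and mode switches", {
  # stationary two-frame stream
  st <- list(time = c(0, 1), positions = matrix(rep(c(1, 2, 3), 2), 2,
                                                byrow = TRUE))
  r <- replay_navigation(st, c(1, 2, 3))
  expect_equal(r$summary$path_length_cm, 0)
  expect_equal(r$summary$duration_s, 1)

  # straight 10 mm approach along +z at 10 Hz
  tt <- seq(0, 2, by = 0.1)
  pos <- cbind(0, 0, seq(-10, 0, length.out = length(tt)))
  r <- replay_navigation(list(time = tt, positions = pos), c(0, 0, 0))
  expect_equal(r$summary$path_length_cm, 1.0, tolerance = 1e-9)
  expect_equal(r$summary$final_distance_mm, 0, tolerance = 1e-9)
  circ <- r$frames$circle_diameter_px
  expect_true(all(diff(circ) <= 1e-12))          # monotonically shrinking

  # an approach that crosses the lateral range boundary exactly once
  params <- display_params(in_range_radius = 5)
  lat <- seq(12, 0, length.out = 25)
  pos <- cbind(lat, 0, -3)
  r <- replay_navigation(list(time = seq_along(lat) / 10, positions = pos),
                         c(0, 0, 0), params)
  switches <- sum(diff(r$frames$mode == "in_range") != 0)
  expect_equal(switches, 1)
  expect_equal(r$frames$mode[1], "out_of_range")
  expect_equal(r$frames$mode[25], "in_range")

  expect_error(replay_navigation(list(time = numeric(0),
                                      positions = matrix(0, 0, 3)), c(0, 0, 0)),
               "empty")
})
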