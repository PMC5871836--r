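test_that("body bend angle from the two-line midline fit", {
  straight <- cbind(seq(0, 1, length.out = 5), rep(0, 5))
  expect_equal(body_bend_angle(straight), 0)
  bent90 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(2, 2))
  expect_equal(body_bend_angle(bent90), 90)
  # anterior half rotated by 25 degrees about the middle sample
  rot <- 25 * pi / 180
  ant <- cbind(c(0, cos(rot), 2 * cos(rot)), c(0, sin(rot), 2 * sin(rot)))
  m <- rbind(c(-2, 0), c(-1, 0), ant + rep(c(0, 0), each = 3))
  expect_equal(body_bend_angle(m), 25, tolerance = 0.5)
  expect_equal(body_bend_angle(m, signed = TRUE), 25, tolerance = 0.5)  # left +
  expect_error(body_bend_angle(matrix(1, 5, 2)), "degenerate")
  expect_error(body_bend_angle(straight[1:2, ]), "at least 3")
})

test_that("a straight constant-speed track is one run", {
  tr <- straight_track(dur_s = 100, t0 = 0)
  p <- segmentation_params(discard_initial_s = 0)
  expect_warning(thr <- estimate_speed_threshold(tr, p), "provisional")
  expect_equal(thr, 0.5 * 0.1, tolerance = 1e-6)
  seg <- segment_track(tr, p, threshold = thr)
  expect_equal(seg$events$type, "run")
  expect_equal(nrow(seg$sweeps), 0)
  expect_equal(seg$events$start_heading, 0, tolerance = 1e-6)
})

test_that("run - two sweeps - run segments into one turn with labels", {
  tr <- handmade_turn_track()
  p <- segmentation_params(discard_initial_s = 0)
  seg <- segment_track(tr, p, threshold = 0.05)
  expect_equal(seg$events$type[order(seg$events$t_start)],
               c("run", "turn", "run"))
  expect_equal(nrow(seg$sweeps), 2)
  sw <- seg$sweeps[order(seg$sweeps$t_start), ]
  expect_equal(sw$side, c("left", "right"))
  expect_equal(sw$outcome, c("rejected", "accepted"))
  expect_equal(sw$ordinal, c(1L, 2L))
  expect_equal(sw$max_bend_deg, c(45, 45), tolerance = 1)
  turn <- seg$events[seg$events$type == "turn", ]
  expect_equal(turn$prior_heading, 0, tolerance = 2)
  expect_equal(turn$new_heading, -45, tolerance = 2)
})

test_that("slow aligned interval without sweeps is a pause", {
  tr <- handmade_turn_track(pause_s = 4, amp = 0)
  # amp 0: no sweeps at all, just a stationary aligned gap
  p <- segmentation_params(discard_initial_s = 0)
  seg <- segment_track(tr, p, threshold = 0.05)
  expect_true("pause" %in% seg$events$type)
  expect_equal(nrow(seg$sweeps), 0)
})

test_that("speed threshold lands between run and turn speeds", {
  tr <- handmade_turn_track(speed = 0.1)
  p <- segmentation_params(discard_initial_s = 0)
  thr <- estimate_speed_threshold(tr, p)
  expect_gt(thr, 0.01)
  expect_lt(thr, 0.1)
  expect_identical(thr, estimate_speed_threshold(tr, p))  # deterministic
})

test_that("track filters drop short tracks and clip the first minute", {
  p <- segmentation_params()
  short <- straight_track(1, dur_s = 29, t0 = 100)
  expect_equal(nrow(filter_tracks(short, p)), 0)
  slow <- straight_track(2, dur_s = 40, t0 = 100, speed_cm_s = 0.009)
  expect_equal(nrow(filter_tracks(slow, p)), 0)        # 0.36 cm < 0.5 cm
  early <- straight_track(3, dur_s = 31, t0 = 0)
  expect_equal(nrow(filter_tracks(early, p)), 0)       # nothing after 60 s
  ok <- straight_track(4, dur_s = 100, t0 = 30)
  kept <- filter_tracks(ok, p)
  expect_gt(nrow(kept), 0)
  expect_true(all(kept$t_s >= 60))
})

test_that("segmentation partitions every frame exactly once", {
  sim <- simulate_experiment(sim_config(n_agents = 3, duration_s = 150,
                                        seed = 5, stimulus = temporal_ramp(n_cycles = 3)))
  p <- segmentation_params(discard_initial_s = 0)
  for (id in 1:3) {
    tr <- sim$tracks[sim$tracks$track_id == id, ]
    seg <- segment_track(tr, p)
    cov <- integer(nrow(tr))
    for (k in seq_len(nrow(seg$events)))
      cov[seg$events$i_start[k]:seg$events$i_end[k]] <-
        cov[seg$events$i_start[k]:seg$events$i_end[k]] + 1L
    expect_true(all(cov == 1L))
  }
})

test_that("raising the sweep-start threshold never adds sweeps", {
  sim <- simulate_experiment(sim_config(n_agents = 4, duration_s = 200,
                                        seed = 9, stimulus = temporal_ramp(n_cycles = 4)))
  counts <- sapply(c(15, 20, 30, 40), function(bs) {
    p <- segmentation_params(bend_start_deg = bs, discard_initial_s = 0)
    nrow(segment_experiment(sim$tracks, p)$sweeps)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation is deterministic", {
  sim <- simulate_experiment(sim_config(n_agents = 2, duration_s = 120,
                                        seed = 3, stimulus = temporal_ramp(n_cycles = 2)))
  p <- segmentation_params(discard_initial_s = 0)
  s1 <- segment_experiment(sim$tracks, p)
  s2 <- segment_experiment(sim$tracks, p)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$sweeps, s2$sweeps)
})
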