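field0 <- directional_field()

test_that("navigation index hits its limits on constructed runs", {
  p <- segmentation_params(discard_initial_s = 0)
  toward <- do.call(rbind, lapply(1:4, function(i)
    straight_track(i, heading_deg = 0, start = c(4, 4 + 4 * i))))
  seg <- segment_experiment(toward, p)
  expect_equal(navigation_index(seg, field0), 1, tolerance = 1e-12)
  away <- do.call(rbind, lapply(1:4, function(i)
    straight_track(i, heading_deg = 180, start = c(20, 4 + 4 * i))))
  expect_equal(navigation_index(segment_experiment(away, p), field0), -1,
               tolerance = 1e-12)
  iso <- do.call(rbind, lapply(1:4, function(i)
    straight_track(i, heading_deg = c(0, 90, 180, -90)[i],
                   start = c(12, 4 + 4 * i))))
  expect_equal(navigation_index(segment_experiment(iso, p), field0), 0,
               tolerance = 1e-12)
  expect_error(navigation_index(fake_seg(events = data.frame(type = "turn")),
                                field0), "no runs")
})

test_that("first sweep direction maps sides per prior-heading bin", {
  sw <- data.frame(ordinal = 1L,
                   heading_before = c(90, -90, 90, -90, 0, 10, -10),
                   side = c("left", "left", "right", "right", "left",
                            "left", "left"),
                   outcome = "accepted")
  seg <- fake_seg(sweeps = sw)
  r <- first_sweep_direction(seg, field0, "perpendicular")
  # +90/left = away, -90/left = toward, +90/right = toward, -90/right = away
  expect_equal(r$rate$k, 2); expect_equal(r$rate$n, 4)
  expect_equal(r$skipped, 3)
  r2 <- first_sweep_direction(seg, field0, "half_disk")
  # positive half: left = away; negative half (incl. 0): left = toward
  expect_equal(r2$rate$n, 7)
  expect_equal(r2$rate$k, 2 + 1)   # 90/left, 10/left away; others toward/away mix
  # symmetric L/R sweeps from both perpendicular bins give 50 %
  sym <- fake_seg(sweeps = data.frame(
    ordinal = 1L, heading_before = rep(c(90, -90), each = 2),
    side = rep(c("left", "right"), 2), outcome = "accepted"))
  expect_equal(first_sweep_direction(sym, field0)$rate$p, 50)
})

test_that("turn direction uses the turn sense against the prior bin", {
  ev <- data.frame(type = "turn",
                   prior_heading = c(92, -90, 0, 90),
                   new_heading = c(150, -150, 40, 90))
  seg <- fake_seg(events = ev)
  r <- turn_direction(seg, field0)
  # +92 -> +150 is CCW = away; -90 -> -150 is CW = away; 0-bin skipped;
  # zero net change excluded
  expect_equal(r$rate$k, 2); expect_equal(r$rate$n, 2)
  expect_equal(r$skipped, 2)
  rt <- turn_direction(seg, field0, prior_bin = "toward")
  expect_equal(rt$rate$k, 1); expect_equal(rt$rate$n, 1)  # 0 -> +40 is left
})

test_that("run heading change wraps correctly", {
  runs <- data.frame(start_heading = c(90, 50, 170), end_heading = c(110, 50, -170))
  expect_equal(run_heading_change(runs), c(20, 0, 20))
})

test_that("steering pools perpendicular-bin runs away-positive", {
  ev <- data.frame(type = "run",
                   start_heading = c(80, 80, -80, 100),
                   end_heading = c(90, 110, -110, 100),
                   mean_heading = c(85, 95, -95, 100),
                   t_start = c(2, 3, 4, 5))
  seg <- fake_seg(events = ev)
  st <- mean_steering(seg, field0, by = "bin")
  expect_equal(st$plus90, mean(c(10, 30, 0)))
  expect_equal(st$minus90, -30)
  expect_equal(st$combined, mean(c(10, 30, 0, 30)))
  stp <- mean_steering(seg, temporal_ramp(), by = "phase")
  expect_equal(stp$increase, mean(c(10, 30, 30, 0)))   # all runs start in increase
  expect_true(is.nan(stp$decrease))
})

test_that("acceptance rate by phase with formula-(1) SEM", {
  r <- temporal_ramp()   # increase 1..24.5, decrease 31..54.5 within cycle 1
  sw <- data.frame(ordinal = 1L,
                   t_start = c(rep(10, 10), rep(40, 10), 25.2),
                   outcome = c(rep(c("accepted", "rejected"), c(3, 7)),
                               rep(c("accepted", "rejected"), c(6, 4)),
                               "accepted"))
  seg <- fake_seg(sweeps = sw)
  a <- acceptance_rate(seg, r)
  expect_equal(a$decrease$p, 60)
  expect_equal(a$decrease$sem, sqrt(60 * 40) / sqrt(10), tolerance = 1e-12)
  expect_equal(round(a$decrease$sem, 2), 15.49)
  expect_equal(a$increase$p, 30)
  expect_equal(a$excluded, 1)                      # the sweep in the hold window
  none <- fake_seg(sweeps = data.frame(ordinal = 1L, t_start = rep(10, 5),
                                       outcome = "rejected"))
  expect_equal(acceptance_rate(none, r)$increase$p, 0)
  expect_equal(acceptance_rate(none, r)$increase$sem, 0)
})

test_that("turn size, delta and binary SEM arithmetic", {
  ev <- data.frame(type = "turn", prior_heading = c(10, 0, 170),
                   new_heading = c(70, 100, -170), t_start = c(10, 12, 40))
  seg <- fake_seg(events = ev)
  ts <- turn_size(seg, temporal_ramp())
  expect_equal(sort(ts$sizes$size_deg), c(20, 60, 100))
  expect_equal(ts$mean_increase, 80)      # 60 and 100 in increase
  expect_equal(ts$mean_decrease, 20)
  expect_equal(ts$delta, 60)
  expect_equal(binary_sem(50, 100), 5)
  expect_equal(binary_sem(0, 17), 0)
  expect_equal(binary_sem(60, 10), 15.4919, tolerance = 1e-4)
})

test_that("turn rate normalizes by phase animal-minutes", {
  r <- temporal_ramp()
  tracks <- data.frame(t_s = rep(seq(60, 660 - 1/13, by = 1/13), 2),
                       track_id = rep(1:2, each = 7800))
  ev <- data.frame(type = "turn", t_start = c(70, 100, 130, 220),
                   prior_heading = 0, new_heading = 10)
  seg <- fake_seg(events = ev, tracks = tracks)
  tr <- turn_rate(seg, r)
  # 10 cycles remain after t=60 within each track; 23.5 s labeled per phase
  expect_equal(tr$animal_min_increase, 2 * 10 * 23.5 / 60, tolerance = 0.05)
  expect_equal(tr$increase, sum(phase_of(r, ev$t_start) == "increase") /
                 tr$animal_min_increase)
  expect_equal(tr$delta, tr$increase - tr$decrease)
})

test_that("head sweep size and run speed summaries", {
  sw <- data.frame(outcome = c("accepted", "rejected", "rejected", "truncated"),
                   heading_before = c(0, 0, 10, 0),
                   max_heading = c(35, -20, 40, 90))
  expect_equal(head_sweep_size(fake_seg(sweeps = sw))$accepted, 35)
  expect_equal(head_sweep_size(fake_seg(sweeps = sw))$rejected, 25)
  ev <- data.frame(type = "run", path_cm = c(2, 0), duration_s = c(30, 10))
  expect_equal(run_speed(fake_seg(events = ev)), mean(c(2 / 30, 0)))
})

test_that("mirror symmetry: index invariant, signed metrics negate", {
  sim <- simulate_experiment(sim_config(n_agents = 8, duration_s = 300,
                                        seed = 17, stimulus = field0))
  seg <- segment_experiment(sim$tracks, segmentation_params(discard_initial_s = 0))
  mir <- larvatax:::mirror_segmentation(seg, field0)
  expect_equal(navigation_index(mir, field0), navigation_index(seg, field0),
               tolerance = 1e-9)
  fs <- first_sweep_direction(seg, field0)$rate
  fsm <- first_sweep_direction(mir, field0)$rate
  expect_equal(fsm$k, fs$k); expect_equal(fsm$n, fs$n)
  st <- mean_steering(seg, field0); stm <- mean_steering(mir, field0)
  expect_equal(stm$plus90, -st$minus90, tolerance = 1e-9)
  expect_equal(stm$combined, st$combined, tolerance = 1e-9)
  ts <- turn_size(seg); tsm <- turn_size(mir)
  expect_equal(sort(tsm$sizes$size_deg), sort(ts$sizes$size_deg), tolerance = 1e-9)
})

test_that("parameter recovery: acceptance rates match the generator", {
  ramp <- temporal_ramp()
  sims <- simulate_experiments(sim_config(n_agents = 30, duration_s = 660,
                                          seed = 61, stimulus = ramp,
                                          n_experiments = 2))
  segs <- lapply(sims, function(s) segment_experiment(s$tracks))
  acc <- acceptance_rate(larvatax:::pool_segmentations(segs), ramp)
  for (ph in c("increase", "decrease")) {
    truth <- if (ph == "increase") 45 else 65
    r <- acc[[ph]]
    expect_lt(abs(r$p - truth), 3 * binary_sem(truth, r$n))
  }
})
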