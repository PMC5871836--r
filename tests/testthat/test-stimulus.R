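test_that("directional field intensity follows the linear gradient", {
  f <- directional_field(edge_intensity = 4331, gradient = 103)
  expect_equal(directional_intensity(f, 24.5, 12), 4331)        # distance 0
  expect_equal(directional_intensity(f, 23.5, 5), 4331 - 103)   # distance 1
  u <- directional_field(edge_intensity = 200, gradient = 0)
  expect_equal(directional_intensity(u, 1, 1), 200)             # uniform
  far <- directional_field(edge_intensity = 50, gradient = 103)
  expect_equal(directional_intensity(far, 0, 0), 0)             # clipped at 0
  expect_error(directional_intensity(f, 30, 5), "outside")
})

test_that("sensed rate of change scales speed by the gradient", {
  f <- directional_field(gradient = 103)
  expect_equal(round(sensed_rate_of_change(f, 4), 2), 6.87)
  expect_equal(sensed_rate_of_change(f, 0), 0)
  expect_equal(sensed_rate_of_change(f, 60), 103)
  expect_error(sensed_rate_of_change(f, -1), "non-negative")
})

test_that("temporal ramp is piecewise linear with plateaus", {
  r <- temporal_ramp(i_max = 380, t_ramp = 25.5, t_hold = 4.5, n_cycles = 11)
  expect_equal(temporal_intensity(r, 25.5), 380)                 # peak
  expect_equal(temporal_intensity(r, 25.5 + 2.25), 380)          # hold
  step <- temporal_intensity(r, 10.1) - temporal_intensity(r, 10.0)
  expect_equal(step, 380 / 25.5 * 0.1, tolerance = 1e-10)
  expect_lt(abs(step - 1.5), 0.02)                               # ~1.5 per 100 ms
  expect_error(temporal_intensity(r, -1), "outside")
  expect_error(temporal_intensity(r, 11 * r$period + 1), "outside")
  # down_first starts at the peak and is continuous across cycles
  d <- temporal_ramp(phase_order = "down_first")
  expect_equal(temporal_intensity(d, 0), 380)
  expect_equal(temporal_intensity(d, d$period - 1e-9), 380, tolerance = 1e-4)
})

test_that("intensity is continuous and |dI| sums to 2 i_max per cycle", {
  r <- temporal_ramp()
  tt <- seq(0, r$period, by = 0.01)
  ii <- temporal_intensity(r, pmin(tt, 11 * r$period - 1e-9))
  expect_lt(max(abs(diff(ii))), 380 / 25.5 * 0.01 + 1e-9)
  expect_equal(sum(abs(diff(ii))), 2 * 380, tolerance = 1e-6)
})

test_that("phase labeling dilates holds and balances phase durations", {
  r <- temporal_ramp()   # up_first, margin 1
  expect_equal(phase_of(r, 10), "increase")
  expect_equal(phase_of(r, 25.0), "excluded")   # within 1 s of hold onset
  expect_equal(phase_of(r, 40), "decrease")
  expect_equal(phase_of(r, 0.5), "excluded")    # trimmed segment start
  tt <- seq(0.0005, r$period, by = 0.001)
  ph <- phase_of(r, tt)
  expect_equal(sum(ph == "increase") * 0.001, 25.5 - 2, tolerance = 0.01)
  expect_equal(sum(ph == "increase"), sum(ph == "decrease"))
  d <- temporal_ramp(phase_order = "down_first")
  expect_equal(phase_of(d, 10), "decrease")
})

test_that("compass convention: toward = 0, left positive", {
  f <- directional_field(light_angle_deg = 0)
  expect_equal(to_compass(0, f), 0)
  expect_equal(to_compass(180, f), 180)
  expect_equal(to_compass(90, f), 90)    # heading 90 deg CCW of the light
  expect_equal(vector_to_compass(0, 1, f), 90)
  expect_error(vector_to_compass(0, 0, f), "zero vector")
  # rotating arena and light together leaves the compass unchanged
  for (rot in c(30, -120, 200)) {
    f2 <- directional_field(light_angle_deg = rot)
    expect_equal(to_compass(45 + rot, f2), 45)
  }
})

test_that("bins partition the compass deterministically", {
  expect_equal(as.character(bin4(c(0, -100, 45, 135, -45, 180))),
               c("toward", "minus90", "plus90", "away", "toward", "away"))
  expect_equal(as.character(bin2(c(10, -10, 0, 180))),
               c("positive_half", "negative_half", "negative_half",
                 "positive_half"))
  set.seed(5)
  th <- wrap_deg(runif(500, -180, 180))
  expect_false(any(is.na(bin4(th))))
  expect_false(any(is.na(bin2(th))))
  nz <- th[abs(th) > 1e-9 & abs(abs(th) - 180) > 1e-9]
  expect_true(all(bin2(nz) != bin2(-nz)))
  # rotation invariance of bin4 through the compass
  f0 <- directional_field(light_angle_deg = 10)
  f1 <- directional_field(light_angle_deg = 10 + 77)
  expect_equal(bin4(to_compass(th, f0)), bin4(to_compass(th + 77, f1)))
})

test_that("stimulus configs round-trip through JSON", {
  d <- tempfile(fileext = ".json")
  write_stimulus_config(directional_field(light_angle_deg = 90), d)
  f <- read_stimulus_config(d)
  expect_s3_class(f, "directional_field")
  expect_equal(f$light_angle_deg, 90)
  write_stimulus_config(temporal_ramp(phase_order = "down_first"), d)
  r <- read_stimulus_config(d)
  expect_equal(r$phase_order, "down_first")
  expect_equal(r$i_max, 380)
})
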