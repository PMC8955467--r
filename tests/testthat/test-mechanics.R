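test_that("system resistance recomputes from printed peak pairs to 4 d.p.", {
  rows <- table3_rows()
  r <- resistance_from_peak(rows$p_drop, rows$pif)
  ok <- rows$printed_consistent
  expect_equal(round(r[ok], 4), rows$printed[ok])
  # the one inconsistent cell recomputes to 0.0321, one ulp above the print
  expect_equal(round(r[!ok], 4), 0.0321)
  expect_equal(resistance_from_peak(1, 1), 1)
  expect_error(resistance_from_peak(-1, 10), "positive")
})

test_that("resistance and predicted pressure drop are exact inverses", {
  expect_equal(predicted_pressure_drop(0.0504, sqrt(4) / 0.0504), 4)
  expect_equal(predicted_pressure_drop(0.2, 0), 0)
  set.seed(21)
  r <- runif(200, 0.005, 0.1)
  q <- runif(200, 1, 150)
  expect_equal(resistance_from_peak(predicted_pressure_drop(r, q), q), r,
               tolerance = 1e-12)
})

test_that("maneuver features come out of simple geometric profiles", {
  # rectangular 60 L/min for 2 s
  tr <- flow_trace(seq(0, 2, 0.01), rep(60, 201), device = "rect",
                   phase_marks = c(201L, 201L))
  f <- extract_features(tr, device_resistance = 0.03)
  expect_equal(f$v_inh, 2)
  expect_equal(f$pif, 60)
  expect_equal(f$t_inh, 2)
  expect_equal(f$p_drop, (0.03 * 60)^2)
  expect_equal(f$resistance, 0.03)

  # triangular 0 -> 60 -> 0 over 2 s: area 1 L
  t <- seq(0, 2, 0.01)
  tri <- flow_trace(t, 60 * (1 - abs(t - 1)), phase_marks = c(201L, 201L))
  expect_equal(extract_features(tri, device_resistance = 0.03)$v_inh, 1,
               tolerance = 1e-9)
})

test_that("phase segmentation falls back to threshold crossing with hysteresis", {
  t <- seq(0, 12, 0.01)
  flow <- ifelse(t <= 2, 50 * sin(pi * t / 4),
                 ifelse(t <= 7, 0, 30))
  tr <- flow_trace(t, flow, device = "x")          # no phase marks
  marks <- segment_phases(tr)
  expect_equal(t[marks[1L]], 2, tolerance = 0.02)
  expect_equal(t[marks[2L]], 7, tolerance = 0.02)
  expect_equal(marks[3L], length(t))
  # flutter dipping below threshold early must not end the phase
  # (hysteresis: not armed until flow exceeded twice the threshold)
  flutter <- flow + ifelse(t <= 0.5, -flow, 0)     # flow stays 0 until 0.5 s
  tr2 <- flow_trace(t, flutter)
  expect_equal(segment_phases(tr2)[1L], marks[1L])
  expect_error(extract_features(flow_trace(0, 5, phase_marks = c(1L, 1L)),
                                device_resistance = 1),
               "fewer than two")
})

test_that("adequacy flags encode the 1 kPa minimum and 4 kPa target", {
  man <- maneuver_spec()
  res <- data.frame(device = c("a", "b", "c"), p_drop = c(3.25, 0.5, 4.27))
  flags <- adequacy_check(res, man)
  expect_equal(flags$met_minimum, c(TRUE, FALSE, TRUE))
  expect_equal(flags$met_target, c(FALSE, FALSE, TRUE))
  expect_error(maneuver_spec(pressure_target = 1, pressure_minimum = 2),
               "exceed")
})
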