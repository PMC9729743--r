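test_that("the exercise protocol table is exact and bijective", {
  expect_equal(unclass(exercise_protocol("rest"))[2:4],
               list(ivc_flow_multiplier = 1, svc_flow_multiplier = 1,
                    resistance_multiplier = 1.00))
  expect_equal(unclass(exercise_protocol("light"))[2:4],
               list(ivc_flow_multiplier = 2, svc_flow_multiplier = 1,
                    resistance_multiplier = 0.95))
  expect_equal(unclass(exercise_protocol("moderate"))[2:4],
               list(ivc_flow_multiplier = 3, svc_flow_multiplier = 1,
                    resistance_multiplier = 0.90))
  expect_equal(unclass(exercise_protocol("heavy"))[2:4],
               list(ivc_flow_multiplier = 4, svc_flow_multiplier = 1.5,
                    resistance_multiplier = 0.85))
  expect_error(exercise_protocol("sprint"),
               class = "fontanflow_validation_error")
  # level -> protocol -> level round trip
  for (lv in c("rest", "light", "moderate", "heavy"))
    expect_identical(exercise_protocol(lv)$level, lv)
})

test_that("waveforms are periodic, mean-preserving and non-negative", {
  w <- inlet_waveform("IVC", 0.30)
  expect_equal(waveform_value(w, 0), waveform_value(w, 2.54))
  t <- (0:2539) * 0.001
  expect_equal(mean(waveform_value(w, t)), 0.30, tolerance = 1e-6)
  expect_true(all(waveform_value(w, seq(0, 10, by = 0.003)) >= 0))
  # no modulation: constant at the base mean
  w0 <- inlet_waveform("SVC", 0.25, modulation = list())
  expect_equal(waveform_value(w0, c(0, 0.7, 2.54)), rep(0.25, 3))
  # amplitude budget |a| <= 1 guards non-negativity
  expect_error(inlet_waveform("IVC", 0.3,
                              modulation = list(list(harmonic = 1,
                                                     amplitude = 1.2,
                                                     phase = 0))),
               class = "fontanflow_validation_error")
})

test_that("apply_protocol scales means and resistances as the table says", {
  b <- default_boundaries()
  rest <- apply_protocol(b, "rest")
  expect_equal(rest$waveforms$IVC$base_mean_velocity,
               b$waveforms$IVC$base_mean_velocity)
  expect_equal(rest$resistances$LPA$resistance, b$resistances$LPA$resistance)

  mod <- apply_protocol(b, "moderate")
  expect_equal(mod$waveforms$IVC$base_mean_velocity, 3 * 0.30)
  expect_equal(mod$waveforms$SVC$base_mean_velocity, 0.25)
  expect_equal(mod$resistances$LPA$resistance,
               b$resistances$LPA$resistance * 0.90)

  # the scaled waveform mean is linear in the multiplier, and stays periodic
  # and non-negative
  t <- (0:2539) * 0.001
  for (lv in c("light", "moderate", "heavy")) {
    sc <- apply_protocol(b, lv)
    mult <- exercise_protocol(lv)$ivc_flow_multiplier
    v <- waveform_value(sc$waveforms$IVC, t)
    expect_equal(mean(v), 0.30 * mult, tolerance = 1e-6)
    expect_true(all(v >= 0))
    expect_equal(waveform_value(sc$waveforms$IVC, 0),
                 waveform_value(sc$waveforms$IVC, 2.54))
  }
})
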