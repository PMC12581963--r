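test_that("raw pulse synthesis: width, polarity, charge balance", {
  p <- synthesize_pulse(5, 0.24, 32768)
  expect_equal(length(p), 8)           # 0.24 ms x 32768 Hz ~ 7.86 samples
  expect_true(all(p == 5))
  expect_identical(synthesize_pulse(-1, 1, 32768),
                   -synthesize_pulse(1, 1, 32768))
  pr <- synthesize_pulse(1, 1, 32768, recharge = TRUE)
  expect_lt(abs(sum(pr)) / sum(abs(pr)), 0.01)   # signed area cancels
  expect_lte(max(abs(pr[pr < 0])), 0.1)          # tail <= 10% amplitude
  expect_error(synthesize_pulse(1, 0.001, 32768), "shorter")
})

test_that("pre-amplifier reduces peak and slew rate and adds a rebound", {
  pp <- preamp_params()
  pad <- numeric(3277)  # 100 ms at 32768 Hz
  x <- c(pad, synthesize_pulse(5, 0.24, 32768), numeric(32768 / 2))
  y <- preamp_filter(x, pp)
  expect_lt(max(abs(y)), 5)
  expect_lt(min(y), 0)  # opposite-polarity rebound
  expect_lt(max(abs(diff(y))), max(abs(diff(x))))
  expect_lt(abs(mean(y[(length(y) - 1000):length(y)])), 1e-3)  # AC coupling
  expect_true(all(preamp_filter(numeric(1000), pp) == 0))
  # time invariance: two pulses 1 s apart superpose two single responses
  fs <- 32768
  one <- numeric(3 * fs); one[100:107] <- 5
  two <- one; two[(fs + 100):(fs + 107)] <- 5
  y1 <- preamp_filter(one, pp)
  y2 <- preamp_filter(two, pp)
  shifted <- c(numeric(fs), y1[1:(2 * fs)])
  expect_lt(max(abs(y2 - (y1 + shifted))), 1e-8)
})

test_that("overlay places pulses at the pacing rate and is purely additive", {
  rec <- loop_episode(generate_vf_episode(vf_model_params(seed = 6)), 60)
  spec <- overlay_spec(rate_ppm = 60, spike_amp_mv = 2.5, pulse_width_ms = 1,
                       phase_s = 0)
  ov <- overlay_pacing(rec, spec)
  expect_equal(nrow(ov$markers), 60)
  expect_equal(diff(ov$markers$time_s), rep(1, 59))

  # zero amplitude leaves the samples untouched
  z <- overlay_pacing(rec, overlay_spec(rate_ppm = 60, spike_amp_mv = 0))
  expect_identical(z$samples, rec$samples)

  # the added artefact is independent of the underlying recording
  rec2 <- loop_episode(generate_vf_episode(vf_model_params(seed = 7)), 60)
  d1 <- overlay_pacing(rec, spec)$samples - rec$samples
  d2 <- overlay_pacing(rec2, spec)$samples - rec2$samples
  expect_lt(max(abs(d1 - d2)), 1e-10)

  # the sensed artefact peak equals the requested spike amplitude
  quiet <- egm_recording(numeric(60 * 256), 256)
  art <- overlay_pacing(quiet, spec)
  expect_equal(max(abs(art$samples)), 2.5, tolerance = 1e-6)

  # ratio on an all-zero recording is undefined
  expect_error(overlay_pacing(quiet, overlay_spec(rate_ppm = 60, ratio = 2)),
               "all-zero")
  expect_error(overlay_spec(rate_ppm = 60), "exactly one")
  expect_error(overlay_spec(rate_ppm = 60, spike_amp_mv = 1, ratio = 1),
               "exactly one")
})

test_that("mean VF amplitude measures per-cycle rectified peaks", {
  t <- seq(0, 8, by = 1 / 256)
  sine <- egm_recording(0.5 * sin(2 * pi * 4 * t), 256)
  expect_equal(mean_vf_amplitude(sine), 0.5, tolerance = 0.02)
  # homogeneity
  rec <- generate_vf_episode(vf_model_params(seed = 8))
  a1 <- mean_vf_amplitude(rec)
  a2 <- mean_vf_amplitude(egm_recording(2 * rec$samples, rec$fs))
  expect_equal(a2, 2 * a1, tolerance = 1e-10)
  expect_error(mean_vf_amplitude(egm_recording(numeric(1024), 256)),
               "all-zero")
  expect_error(mean_vf_amplitude(egm_recording(c(0, 1), 256)), "2 s")
})

test_that("spike-to-VF ratios reproduce the closest-case table arithmetic", {
  sensed <- c(6.04, 3.75, 2.26, 5.46, 2.13, 1.39, 3.67, 1.71, 1.09,
              2.90, 1.26, 0.82)
  ratios <- c(7.02, 4.36, 2.63, 6.35, 2.48, 1.62, 4.27, 1.99, 1.27,
              3.37, 1.47, 0.95)
  expect_equal(round(vapply(sensed, compute_ratio, numeric(1),
                            vf_amp_mv = 0.86), 2), ratios)
  expect_equal(compute_ratio(1.7, 1.7), 1)
  expect_error(compute_ratio(1, 0), "> 0")
})
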