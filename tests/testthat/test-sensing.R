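test_that("band-rectify output is non-negative, kills DC, doubles a tone", {
  z <- band_rectify(egm_recording(numeric(512), 256))
  expect_true(all(z$samples == 0))
  dc <- band_rectify(egm_recording(rep(1, 2048), 256))
  expect_lt(max(dc$samples[1025:2048]), 1e-3)
  # full-wave rectification doubles the fundamental of an in-band tone
  t <- seq(0, 4 - 1 / 256, by = 1 / 256)
  tone <- band_rectify(egm_recording(sin(2 * pi * 40 * t), 256))
  y <- tone$samples[257:1024] - mean(tone$samples[257:1024])
  sp <- Mod(stats::fft(y))[1:384]
  f <- (seq_along(sp) - 1) * 256 / 768
  expect_equal(f[which.max(sp)], 80, tolerance = 1)
  expect_true(all(tone$samples >= 0))
})

test_that("auto-adjusting sensing matches its contract on simple inputs", {
  p <- sensing_params()
  expect_length(sense_events(egm_recording(numeric(1024), 256), p), 0)
  # isolated peak -> exactly one event
  x <- numeric(1024); x[300] <- 1
  expect_length(sense_events(egm_recording(x, 256), p), 1)
  # periodic 0.5 mV humps at 200 ms -> one event per hump
  x2 <- numeric(256 * 10)
  starts <- seq(1, length(x2) - 10, by = round(0.2 * 256))
  for (s in starts) x2[s:(s + 4)] <- 0.5 * c(0.3, 0.8, 1, 0.8, 0.3)
  ev <- sense_events(egm_recording(x2, 256), p)
  expect_equal(length(ev), length(starts))
  expect_true(all(abs(diff(ev) * 1000 - 200) <= 4))
  expect_error(sense_events(egm_recording(c(-1, 1, 0), 256), p),
               "non-negative")
})

test_that("sensing threshold respects the floor and the cap", {
  p <- sensing_params()
  # signal strictly below the floor is never sensed
  sub <- egm_recording(rep(p$sensitivity_floor_mv * 0.95, 2048), 256)
  expect_length(sense_events(sub, p), 0)
  # after a huge peak the restart is capped: a plateau just above the cap
  # re-triggers immediately after blanking
  x <- numeric(2048); x[100] <- 100
  x[101:2048] <- p$max_threshold_mv * 1.04
  ev <- sense_events(egm_recording(x, 256), p)
  nb <- round(p$blank_ms / 1000 * 256)
  expect_gte(length(ev), 2)
  expect_lte(ev[2] - ev[1], (nb + 2) / 256)
})

test_that("chunked sensing agrees exactly with the sample-by-sample oracle", {
  p <- sensing_params()
  for (s in 1:6) {
    rec <- generate_vf_episode(vf_model_params(
      target_mean_amp_mv = runif(1, 0.15, 1.0), duration_s = 4, seed = s))
    sensed <- band_rectify(rec)
    x <- sensed$samples[1:1000]
    short <- egm_recording(x, 256)
    expect_identical(sense_events(short, p),
                     brute_sense_events(x, 256, p))
  }
  # also under non-default parameters
  p2 <- sensing_params(sensitivity_floor_mv = 0.3, peak_fraction = 0.4,
                       decay_tau_ms = 250, blank_ms = 120,
                       max_threshold_mv = 1)
  rec <- band_rectify(generate_vf_episode(vf_model_params(seed = 99, duration_s = 4)))
  x <- rec$samples[1:1000]
  expect_identical(sense_events(egm_recording(x, 256), p2),
                   brute_sense_events(x, 256, p2))
})

test_that("lowering the sensitivity floor never loses sensed deflections", {
  for (s in c(21, 22, 23)) {
    sen <- band_rectify(generate_vf_episode(vf_model_params(
      target_mean_amp_mv = 0.5, seed = s)))
    hi <- sense_events(sen, sensing_params(sensitivity_floor_mv = 0.30))
    lo <- sense_events(sen, sensing_params(sensitivity_floor_mv = 0.15))
    expect_gte(length(lo), length(hi))
    # every event at the coarse floor has a counterpart within one blanking
    # period at the fine floor (timings may shift slightly)
    blank_s <- sensing_params()$blank_ms / 1000
    expect_true(all(vapply(hi, function(t) min(abs(lo - t)) <= blank_s,
                           logical(1))))
  }
})

test_that("interval counting detects X-of-Y short intervals", {
  d <- detection_params(vf_interval_ms = 320, nid_x = 18, nid_y = 24,
                        charge_time_s = 8)
  ev <- seq(0, by = 0.180, length.out = 40)
  res <- detect_vf(ev, d, episode_duration_s = 60)
  expect_true(res$detected)
  expect_equal(res$t_detect_s, ev[19])   # 18 qualifying intervals
  expect_equal(res$t_therapy_s, res$t_detect_s + 8)

  slow <- detect_vf(seq(0, by = 1, length.out = 50), d, 60)
  expect_false(slow$detected)
  none <- detect_vf(numeric(0), d, 60)
  expect_false(none$detected)
  expect_true(is.na(none$t_detect_s))
  expect_error(detect_vf(c(1, 0.5), d, 60), "sorted")

  # brute-force window count agreement on irregular event streams
  set.seed(14)
  ev2 <- cumsum(runif(120, 0.1, 0.6))
  res2 <- detect_vf(ev2, d, episode_duration_s = max(ev2) + 1)
  iv <- diff(ev2) * 1000
  brute <- NA
  for (k in seq_along(iv)) {
    w <- iv[max(1, k - 23):k]
    if (sum(w < 320) >= 18) { brute <- ev2[k + 1]; break }
  }
  expect_equal(res2$detected, !is.na(brute))
  if (res2$detected) expect_equal(res2$t_detect_s, brute)
})

test_that("the full detector detects clean VF quickly and scales monotonely", {
  rec <- loop_episode(generate_vf_episode(
    vf_model_params(target_mean_amp_mv = 0.86, duration_s = 8, seed = 1)), 60)
  res <- run_detector(rec)
  expect_true(res$detected)
  expect_lt(res$t_detect_s, 5)
  # scaling clean VF up never loses detection
  for (f in c(2, 4)) {
    up <- egm_recording(rec$samples * f, rec$fs)
    expect_true(run_detector(up)$detected)
  }
})
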