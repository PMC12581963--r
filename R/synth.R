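#' Parameters of the synthetic VF waveform model
#'
#' The generator emulates device-recorded ventricular fibrillation (VF)
#' electrograms as a train of short biphasic intracardiac-style deflections
#' whose cycle lengths are jittered around a dominant frequency and whose
#' per-cycle amplitudes are modulated around a target mean, plus band-limited
#' noise. It reproduces the amplitude/interval statistics that a sense
#' amplifier consumes without claiming physiological fidelity.
#'
#' @param dominant_freq_hz Mean VF cycle frequency in Hz. The default 4.5 Hz
#'   corresponds to a mean cycle length of ~222 ms, inside the 140-330 ms
#'   range typical of VF.
#' @param freq_jitter Relative standard deviation of cycle-to-cycle frequency
#'   (0 disables jitter).
#' @param target_mean_amp_mv Target mean per-cycle peak amplitude in mV (> 0).
#' @param amp_cv Coefficient of variation of per-cycle amplitude (in [0, 1)).
#' @param noise_rms_mv RMS of additive band-limited noise in mV.
#' @param duration_s Episode length in seconds; device episodes typically
#'   last 6-10 s.
#' @param deflection_width_ms Width of each biphasic deflection in ms. The
#'   default 45 ms puts most deflection energy in the 10-25 Hz band where
#'   ICD sense amplifiers operate.
#' @param seed Integer seed; every generated episode is a pure function of
#'   its parameters including the seed.
#'
#' @return A list of class `vf_model_params`.
#' @export
vf_model_params <- function(dominant_freq_hz = 4.5, freq_jitter = 0.12,
                            target_mean_amp_mv = 0.5, amp_cv = 0.25,
                            noise_rms_mv = 0.02, duration_s = 8,
                            deflection_width_ms = 45, seed = 1) {
  stopifnot_scalar(dominant_freq_hz, "dominant_freq_hz", positive = TRUE)
  stopifnot_scalar(freq_jitter, "freq_jitter", nonneg = TRUE)
  stopifnot_scalar(target_mean_amp_mv, "target_mean_amp_mv", positive = TRUE)
  stopifnot_scalar(amp_cv, "amp_cv", nonneg = TRUE)
  if (amp_cv >= 1) stop("`amp_cv` must be in [0, 1)", call. = FALSE)
  stopifnot_scalar(noise_rms_mv, "noise_rms_mv", nonneg = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(deflection_width_ms, "deflection_width_ms", positive = TRUE)
  structure(as.list(environment()), class = "vf_model_params")
}

# Unit-peak biphasic deflection shape on u in [0, 1]: one positive and one
# negative hump of equal magnitude (sine under a Hann window), normalized so
# max |s| = 1.
deflection_shape <- function(u) {
  s <- sin(2 * pi * u) * 0.5 * (1 - cos(2 * pi * u))
  s[u < 0 | u > 1] <- 0
  s / 0.6495190528  # max of sin(2*pi*u)*hann(u) on [0,1]
}

#' Generate a synthetic VF episode
#'
#' Draws jittered cycle lengths and per-cycle amplitudes, renders one biphasic
#' deflection per cycle, rescales the clean waveform so that its measured
#' [mean_vf_amplitude()] equals the target, then adds band-limited noise.
#'
#' @param params A [vf_model_params()] object.
#' @param fs Sampling rate in Hz (device rate 256 Hz by default).
#' @return An [egm_recording()] of `params$duration_s` seconds at `fs` whose
#'   measured mean per-cycle peak amplitude is within 10% of
#'   `target_mean_amp_mv`, reproducible for a fixed seed.
#' @export
generate_vf_episode <- function(params, fs = 256) {
  stopifnot(inherits(params, "vf_model_params"))
  stopifnot_scalar(fs, "fs", positive = TRUE)
  with_local_seed(params$seed, {
    n <- round(params$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    w <- params$deflection_width_ms / 1000

    # jittered cycle onset times, clipped to keep cycle lengths plausible
    n_cyc_max <- ceiling(params$duration_s * params$dominant_freq_hz * 2) + 4
    f_k <- params$dominant_freq_hz *
      (1 + params$freq_jitter * stats::rnorm(n_cyc_max))
    f_k <- pmin(pmax(f_k, 0.55 * params$dominant_freq_hz),
                1.8 * params$dominant_freq_hz)
    onsets <- cumsum(c(0, 1 / f_k))
    # snap onsets to the sample grid so each deflection is sampled
    # identically; in the jitter-free case the episode is exactly periodic
    onsets <- round(onsets * fs) / fs
    onsets <- onsets[onsets + w <= params$duration_s]
    n_cyc <- length(onsets)
    if (n_cyc < 2L)
      stop("episode too short for the requested dominant frequency",
           call. = FALSE)

    a_k <- 1 + params$amp_cv * stats::rnorm(n_cyc)
    a_k <- pmax(a_k, 0.05)

    x <- numeric(n)
    for (k in seq_len(n_cyc)) {
      u <- (t - onsets[k]) / w
      inside <- which(u >= 0 & u <= 1)
      x[inside] <- x[inside] + a_k[k] * deflection_shape(u[inside])
    }

    # calibrate the clean waveform to the target measured amplitude
    clean <- egm_recording(x * params$target_mean_amp_mv, fs)
    measured <- mean_vf_amplitude(clean)
    x <- x * params$target_mean_amp_mv * (params$target_mean_amp_mv / measured)

    if (params$noise_rms_mv > 0) {
      noise <- stats::rnorm(n)
      bf <- signal::butter(2, min(0.9, 40 / (fs / 2)), type = "low")
      noise <- as.numeric(signal::filter(bf, noise))
      noise <- noise / stats::sd(noise) * params$noise_rms_mv
      x <- x + noise
    }
    egm_recording(x, fs,
                  label = sprintf("synthetic VF %.2f mV seed %d",
                                  params$target_mean_amp_mv,
                                  as.integer(params$seed)))
  })
}

#' Generate a library of synthetic VF episodes
#'
#' Target mean amplitudes are drawn uniformly from `amp_range_mv` and episode
#' durations uniformly from 6-10 s (unless `draw_duration = FALSE`), mirroring
#' the sensed-amplitude range and episode lengths of device-recorded VF.
#' Each episode is seeded deterministically from `(seed, index)`.
#'
#' @param n Number of episodes (>= 1).
#' @param amp_range_mv Length-2 vector `(low, high)` in mV, `0 < low < high`.
#' @param base A [vf_model_params()] supplying all other model parameters.
#' @param seed Integer master seed.
#' @param draw_duration If `TRUE` (default) draw each episode's duration
#'   uniformly in [6, 10] s; otherwise use `base$duration_s`.
#' @return A list of `n` [egm_recording()] objects with attribute `manifest`,
#'   a data frame of episode id, seed, target amplitude and duration.
#' @export
generate_episode_library <- function(n, amp_range_mv = c(0.15, 1.0), base = vf_model_params(),
                                     seed = 1, draw_duration = TRUE) {
  stopifnot_scalar(n, "n", positive = TRUE)
  if (length(amp_range_mv) != 2L || !all(is.finite(amp_range_mv)) ||
      amp_range_mv[1] <= 0 || amp_range_mv[1] >= amp_range_mv[2])
    stop("`amp_range_mv` must be (low, high) with 0 < low < high",
         call. = FALSE)
  stopifnot(inherits(base, "vf_model_params"))
  draws <- with_local_seed(seed, {
    data.frame(
      amp = stats::runif(n, amp_range_mv[1], amp_range_mv[2]),
      dur = if (draw_duration) stats::runif(n, 6, 10)
            else rep(base$duration_s, n)
    )
  })
  episodes <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base
    p$target_mean_amp_mv <- draws$amp[i]
    p$duration_s <- draws$dur[i]
    p$seed <- child_seed(seed, i)
    episodes[[i]] <- generate_vf_episode(p)
  }
  attr(episodes, "manifest") <- data.frame(
    episode = seq_len(n),
    seed = vapply(seq_len(n), function(i) child_seed(seed, i), integer(1)),
    target_amp_mv = draws$amp,
    duration_s = draws$dur
  )
  episodes
}

#' Sample inter-device distance pairs from a multivariate normal
#'
#' Models the joint distribution of the two inter-device electrode distances
#' (D1: ICD Ring2 to pacemaker tip; D2: ICD Ring1 to pacemaker ring) as a
#' bivariate normal fitted elsewhere (see [fit_mvn()]). Negative draws are
#' retained; truncation is the caller's decision (see [prob_both_below()]).
#'
#' @param n Number of pairs (>= 0).
#' @param mean Length-2 mean vector in mm.
#' @param cov 2x2 symmetric positive semi-definite covariance in mm^2.
#' @param seed Integer seed.
#' @return A data frame with columns `d1_mm`, `d2_mm` and `n` rows.
#' @export
sample_distance_pairs <- function(n, mean, cov, seed = 1) {
  stopifnot_scalar(n, "n", nonneg = TRUE)
  if (length(mean) != 2L) stop("`mean` must have length 2", call. = FALSE)
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
    stop("`cov` must be symmetric", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop("`cov` must be positive semi-definite", call. = FALSE)
  if (n == 0)
    return(data.frame(d1_mm = numeric(0), d2_mm = numeric(0)))
  x <- with_local_seed(seed, MASS::mvrnorm(n, mu = mean, Sigma = cov))
  x <- matrix(x, ncol = 2)
  data.frame(d1_mm = x[, 1], d2_mm = x[, 2])
}

#' A pacing program
#'
#' @param amplitude_v Programmed pacing amplitude in V (> 0).
#' @param pulse_width_ms Pulse width in ms (> 0); tested widths are 0.24,
#'   0.40 and 1.00 ms.
#' @param rate_ppm Pacing rate in pulses per minute (> 0).
#' @return A list of class `pacing_program`.
#' @export
pacing_program <- function(amplitude_v, pulse_width_ms = 0.24, rate_ppm = 60) {
  stopifnot_scalar(amplitude_v, "amplitude_v", positive = TRUE)
  stopifnot_scalar(pulse_width_ms, "pulse_width_ms", positive = TRUE)
  stopifnot_scalar(rate_ppm, "rate_ppm", positive = TRUE)
  structure(list(amplitude_v = amplitude_v, pulse_width_ms = pulse_width_ms,
                 rate_ppm = rate_ppm), class = "pacing_program")
}

#' Sample pacing programs from a clinical prevalence distribution
#'
#' Draws programmed amplitudes at 0.24 ms pulse width from a discrete
#' distribution calibrated so that, by default, 90.5% of devices are at or
#' below 1.0 V and 96.5% at or below 3.0 V, matching the cumulative
#' programming prevalence reported for real-world leadless pacemaker
#' populations.
#'
#' @param n Number of programs (>= 1).
#' @param seed Integer seed.
#' @param levels_v Amplitude levels in V.
#' @param probs Probability of each level (must sum to 1).
#' @param pulse_width_ms Pulse width attached to every program.
#' @param rate_ppm Rate attached to every program.
#' @return A data frame with columns `amplitude_v`, `pulse_width_ms`,
#'   `rate_ppm`.
#' @export
sample_pacing_programs <- function(n, seed = 1,
                                   levels_v = c(0.5, 1.0, 1.5, 2.0, 3.0, 5.0),
                                   probs = c(0.405, 0.500, 0.025, 0.020,
                                             0.015, 0.035),
                                   pulse_width_ms = 0.24, rate_ppm = 60) {
  stopifnot_scalar(n, "n", positive = TRUE)
  if (length(levels_v) != length(probs))
    stop("`levels_v` and `probs` must have equal length", call. = FALSE)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must be non-negative and sum to 1", call. = FALSE)
  amps <- with_local_seed(seed,
    sample(levels_v, size = n, replace = TRUE, prob = probs))
  data.frame(amplitude_v = amps, pulse_width_ms = pulse_width_ms,
             rate_ppm = rate_ppm)
}
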