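# Sweep harnesses reproducing the in-silico result surfaces: detection
# grids over pulse width/amplitude/rate, spike-to-VF ratio response and
# timing curves, and the closest-case table.

# Loop every library episode to the simulated duration once, caching the
# per-episode mean VF amplitude and a per-episode uniform phase draw.
prepare_library <- function(library, duration_s = 60, seed = 1) {
  stopifnot(is.list(library), length(library) >= 1L)
  looped <- lapply(library, loop_episode, target_duration_s = duration_s)
  u <- with_local_seed(seed, stats::runif(length(looped)))
  list(looped = looped,
       vf_amp = vapply(looped, mean_vf_amplitude, numeric(1)),
       phase_u = u)
}

#' Detection grid over pulse width, spike amplitude and rate
#'
#' For every cell each library episode is looped to 60 s, overlaid with
#' asynchronous pacing at a seeded random phase (one phase per episode) and
#' run through the detector; the cell value is the percentage of episodes
#' detected. Amplitudes are sensed (post-front-end) spike amplitudes in mV.
#' The baseline is the detection percentage of the identical looped library
#' with no pacing.
#'
#' @param library A list of [egm_recording()] episodes (e.g. from
#'   [generate_episode_library()]).
#' @param widths_ms,amps_mv,rates_ppm Grid axes.
#' @param sp,dp Sensing and detection parameters.
#' @param seed Integer seed for the pacing phases.
#' @param duration_s Simulated episode duration (default 60 s).
#' @return A list of class `detection_grid` with `cells` (data frame of
#'   `rate_ppm`, `width_ms`, `amp_mv`, `pct_detected`), `baseline_pct` and
#'   `n_episodes`.
#' @export
run_grid <- function(library, widths_ms = c(0.24, 0.40, 1.00),
                     amps_mv = c(0.5, 1, 2, 4), rates_ppm = c(60, 90, 150, 180),
                     sp = sensing_params(), dp = detection_params(),
                     seed = 1, duration_s = 60) {
  if (length(library) == 0L) stop("empty episode library", call. = FALSE)
  if (length(widths_ms) == 0L || length(amps_mv) == 0L ||
      length(rates_ppm) == 0L)
    stop("all grid axes must be non-empty", call. = FALSE)
  prep <- prepare_library(library, duration_s, seed)
  base_det <- vapply(prep$looped, function(r) run_detector(r, sp, dp)$detected,
                     logical(1))
  cells <- expand.grid(rate_ppm = rates_ppm, width_ms = widths_ms,
                       amp_mv = amps_mv, KEEP.OUT.ATTRS = FALSE)
  cells$pct_detected <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    if (cells$amp_mv[ci] == 0) {
      cells$pct_detected[ci] <- 100 * mean(base_det)
      next
    }
    det <- logical(length(prep$looped))
    period <- 60 / cells$rate_ppm[ci]
    for (ei in seq_along(prep$looped)) {
      spec <- overlay_spec(rate_ppm = cells$rate_ppm[ci],
                           spike_amp_mv = cells$amp_mv[ci],
                           pulse_width_ms = cells$width_ms[ci],
                           phase_s = prep$phase_u[ei] * period)
      rec <- overlay_pacing(prep$looped[[ei]], spec)
      det[ei] <- run_detector(rec, sp, dp)$detected
    }
    cells$pct_detected[ci] <- 100 * mean(det)
  }
  structure(list(cells = cells, baseline_pct = 100 * mean(base_det),
                 n_episodes = length(library)),
            class = "detection_grid")
}

#' Detection percentage as a function of the spike-to-VF ratio
#'
#' Per episode the sensed spike amplitude is set to `ratio` times that
#' episode's own mean VF amplitude, so the curve isolates the ratio as the
#' undersensing predictor.
#'
#' @param library Episode list.
#' @param ratios Ratios to evaluate (the studies span 0-8).
#' @param rate_ppm Pacing rate.
#' @param width_ms Pulse width.
#' @param sp,dp Sensing and detection parameters.
#' @param seed Seed for pacing phases.
#' @param duration_s Simulated episode duration.
#' @return Data frame with columns `ratio` and `pct_detected`.
#' @export
detection_vs_ratio <- function(library, ratios, rate_ppm = 60,
                               width_ms = 1.0, sp = sensing_params(),
                               dp = detection_params(), seed = 1,
                               duration_s = 60) {
  if (length(library) == 0L) stop("empty episode library", call. = FALSE)
  prep <- prepare_library(library, duration_s, seed)
  period <- 60 / rate_ppm
  pct <- vapply(ratios, function(r) {
    det <- logical(length(prep$looped))
    for (ei in seq_along(prep$looped)) {
      if (r == 0) {
        rec <- prep$looped[[ei]]
      } else {
        spec <- overlay_spec(rate_ppm = rate_ppm,
                             spike_amp_mv = r * prep$vf_amp[ei],
                             pulse_width_ms = width_ms,
                             phase_s = prep$phase_u[ei] * period)
        rec <- overlay_pacing(prep$looped[[ei]], spec)
      }
      det[ei] <- run_detector(rec, sp, dp)$detected
    }
    100 * mean(det)
  }, numeric(1))
  data.frame(ratio = ratios, pct_detected = pct)
}

#' Time to detection and therapy as a function of the spike-to-VF ratio
#'
#' Statistics are computed over detected episodes only; a ratio with zero
#' detections reports `NA` statistics. Therapy time equals detection time
#' plus the capacitor charge time exactly.
#'
#' @inheritParams detection_vs_ratio
#' @return Data frame with columns `ratio`, `n_detected`, `mean_t_detect_s`,
#'   `q25_t_detect_s`, `q75_t_detect_s`, `mean_t_therapy_s`.
#' @export
timing_vs_ratio <- function(library, ratios, rate_ppm = 60, width_ms = 1.0,
                            sp = sensing_params(), dp = detection_params(),
                            seed = 1, duration_s = 60) {
  if (length(library) == 0L) stop("empty episode library", call. = FALSE)
  prep <- prepare_library(library, duration_s, seed)
  period <- 60 / rate_ppm
  rows <- lapply(ratios, function(r) {
    tdet <- rep(NA_real_, length(prep$looped))
    for (ei in seq_along(prep$looped)) {
      if (r == 0) {
        rec <- prep$looped[[ei]]
      } else {
        spec <- overlay_spec(rate_ppm = rate_ppm,
                             spike_amp_mv = r * prep$vf_amp[ei],
                             pulse_width_ms = width_ms,
                             phase_s = prep$phase_u[ei] * period)
        rec <- overlay_pacing(prep$looped[[ei]], spec)
      }
      res <- run_detector(rec, sp, dp)
      if (res$detected) tdet[ei] <- res$t_detect_s
    }
    det <- tdet[!is.na(tdet)]
    data.frame(
      ratio = r, n_detected = length(det),
      mean_t_detect_s = if (length(det)) mean(det) else NA_real_,
      q25_t_detect_s = if (length(det))
        unname(stats::quantile(det, 0.25)) else NA_real_,
      q75_t_detect_s = if (length(det))
        unname(stats::quantile(det, 0.75)) else NA_real_,
      mean_t_therapy_s = if (length(det))
        mean(det) + dp$charge_time_s else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' The closest-case pacing-output inputs
#'
#' Programmed pacing outputs and the corresponding sensed spike amplitudes
#' measured with the pacemaker in closest proximity to the ICD lead; the
#' standard 12-row input to [closest_case_table()].
#'
#' @return Data frame with columns `amplitude_v`, `pulse_width_ms`,
#'   `sensed_mv`.
#' @export
closest_case_inputs <- function() {
  data.frame(
    amplitude_v = c(5.0, 5.0, 5.0, 3.0, 3.0, 3.0, 2.0, 2.0, 2.0,
                    1.5, 1.5, 1.5),
    pulse_width_ms = rep(c(1.00, 0.40, 0.24), 4),
    sensed_mv = c(6.04, 3.75, 2.26, 5.46, 2.13, 1.39, 3.67, 1.71, 1.09,
                  2.90, 1.26, 0.82)
  )
}

#' Closest-case detection table
#'
#' For each programmed pacing output (with its measured sensed spike
#' amplitude), a synthetic VF episode at `vf_amp_mv` is looped to 60 s,
#' overlaid with asynchronous pacing at `rate_ppm`, and run through the
#' detector. The table reports the spike-to-VF ratio (2 decimals) and the
#' detection outcome per row.
#'
#' @param vf_amp_mv Mean VF amplitude of the injected episode in mV
#'   (default 0.86, the reference mean sensed VF amplitude).
#' @param sensed_spikes Data frame with columns `amplitude_v`,
#'   `pulse_width_ms`, `sensed_mv` (default [closest_case_inputs()]).
#' @param sp,dp Sensing and detection parameters.
#' @param seed Seed for the episode and pacing phases.
#' @param rate_ppm Pacing rate (default 80 ppm, the rate used in the
#'   low-amplitude-VF injections).
#' @return `sensed_spikes` with added columns `ratio` and `detected`.
#' @export
closest_case_table <- function(vf_amp_mv = 0.86,
                               sensed_spikes = closest_case_inputs(),
                               sp = sensing_params(), dp = detection_params(),
                               seed = 1, rate_ppm = 80) {
  stopifnot_scalar(vf_amp_mv, "vf_amp_mv", positive = TRUE)
  params <- vf_model_params(target_mean_amp_mv = vf_amp_mv, duration_s = 8,
                            seed = child_seed(seed, 1))
  rec <- loop_episode(generate_vf_episode(params), 60)
  period <- 60 / rate_ppm
  phases <- with_local_seed(child_seed(seed, 2),
                            stats::runif(nrow(sensed_spikes), 0, period))
  out <- sensed_spikes
  out$ratio <- round(out$sensed_mv / vf_amp_mv, 2)
  out$detected <- vapply(seq_len(nrow(out)), function(i) {
    spec <- overlay_spec(rate_ppm = rate_ppm,
                         spike_amp_mv = out$sensed_mv[i],
                         pulse_width_ms = out$pulse_width_ms[i],
                         phase_s = phases[i])
    run_detector(overlay_pacing(rec, spec), sp, dp)$detected
  }, logical(1))
  out
}
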