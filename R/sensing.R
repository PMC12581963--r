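#' Auto-adjusting sensitivity parameters
#'
#' Generic extravascular-ICD sense-amplifier behaviour: after each sensed
#' event the threshold restarts at a fraction of the measured event peak
#' (capped at `max_threshold_mv`) and decays exponentially toward the
#' programmed sensitivity floor, which it never undershoots. A post-sense
#' blanking period suppresses re-triggering on the same deflection.
#'
#' Defaults are the package's one-time calibration of a transvenous-ICD-class
#' sensing chain against the synthetic VF library (baseline detection >= 99%
#' and a spike/VF ratio response with severe undersensing near ratio 7).
#'
#' @param sensitivity_floor_mv Programmed sensitivity in mV (default 0.15,
#'   the device default).
#' @param peak_fraction Starting threshold as a fraction of the last sensed
#'   peak (in (0, 1)).
#' @param decay_tau_ms Exponential decay time constant in ms.
#' @param blank_ms Post-sense blanking in ms.
#' @param max_threshold_mv Cap on the adapted threshold in mV.
#' @return A list of class `sensing_params`.
#' @export
sensing_params <- function(sensitivity_floor_mv = 0.15, peak_fraction = 0.58,
                           decay_tau_ms = 900, blank_ms = 90,
                           max_threshold_mv = 5.0) {
  stopifnot_scalar(sensitivity_floor_mv, "sensitivity_floor_mv",
                   positive = TRUE)
  stopifnot_scalar(peak_fraction, "peak_fraction", positive = TRUE)
  if (peak_fraction >= 1)
    stop("`peak_fraction` must be in (0, 1)", call. = FALSE)
  stopifnot_scalar(decay_tau_ms, "decay_tau_ms", positive = TRUE)
  stopifnot_scalar(blank_ms, "blank_ms", nonneg = TRUE)
  stopifnot_scalar(max_threshold_mv, "max_threshold_mv", positive = TRUE)
  structure(as.list(environment()), class = "sensing_params")
}

#' VF detection (interval-counting) parameters
#'
#' Interval-based X-of-Y detection: VF is declared at the first sensed event
#' where at least `nid_x` of the last `nid_y` sensed intervals are shorter
#' than `vf_interval_ms`. Therapy follows detection after a fixed capacitor
#' charge time.
#'
#' @param vf_interval_ms Interval threshold in ms classifying a sensed
#'   interval as VF.
#' @param nid_x Required count (X).
#' @param nid_y Window size (Y), with `0 < nid_x <= nid_y`.
#' @param charge_time_s Delay from detection to therapy in seconds.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(vf_interval_ms = 400, nid_x = 20, nid_y = 24,
                             charge_time_s = 8) {
  stopifnot_scalar(vf_interval_ms, "vf_interval_ms", positive = TRUE)
  stopifnot_scalar(nid_x, "nid_x", positive = TRUE)
  stopifnot_scalar(nid_y, "nid_y", positive = TRUE)
  if (nid_x > nid_y) stop("need nid_x <= nid_y", call. = FALSE)
  stopifnot_scalar(charge_time_s, "charge_time_s", nonneg = TRUE)
  structure(list(vf_interval_ms = vf_interval_ms, nid_x = as.integer(nid_x),
                 nid_y = as.integer(nid_y), charge_time_s = charge_time_s),
            class = "detection_params")
}

#' Band-pass filter and rectify a recording
#'
#' The sensed EGM: the device-rate signal is band-pass filtered (second-order
#' high-pass and low-pass sharing the pre-amplifier corners by default) and
#' full-wave rectified.
#'
#' @param rec An [egm_recording()] at the device rate.
#' @param hp_corner_hz,lp_corner_hz Band corners in Hz.
#' @return A non-negative [egm_recording()].
#' @export
band_rectify <- function(rec, hp_corner_hz = 10, lp_corner_hz = 95) {
  stopifnot(inherits(rec, "egm_recording"))
  nyq <- rec$fs / 2
  if (lp_corner_hz >= nyq) lp_corner_hz <- 0.95 * nyq
  hp <- signal::butter(2, hp_corner_hz / nyq, type = "high")
  lp <- signal::butter(2, lp_corner_hz / nyq, type = "low")
  y <- as.numeric(signal::filter(hp, rec$samples))
  y <- as.numeric(signal::filter(lp, y))
  egm_recording(abs(y), rec$fs, label = paste0(rec$label, " [sensed]"),
                markers = rec$markers)
}

#' Sense events with an auto-adjusting threshold
#'
#' Walks the rectified sensed signal emitting an event whenever the signal
#' reaches the current threshold outside blanking. At each event the local
#' peak within the blanking window is measured; the threshold restarts at
#' `min(peak_fraction * peak, max_threshold_mv)` (never below the floor) and
#' decays exponentially toward the sensitivity floor.
#'
#' @param sensed A non-negative [egm_recording()] (output of
#'   [band_rectify()]).
#' @param p A [sensing_params()] object.
#' @return Numeric vector of event times in seconds, strictly increasing
#'   with spacing >= `blank_ms`.
#' @export
sense_events <- function(sensed, p = sensing_params()) {
  stopifnot(inherits(sensed, "egm_recording"), inherits(p, "sensing_params"))
  x <- sensed$samples
  if (any(x < 0))
    stop("`sensed` must be non-negative (run band_rectify first)",
         call. = FALSE)
  fs <- sensed$fs
  n <- length(x)
  nb <- round(p$blank_ms / 1000 * fs)
  tau <- p$decay_tau_ms / 1000 * fs
  floor_mv <- p$sensitivity_floor_mv

  events <- integer(0)
  thr0 <- floor_mv   # restart level of the current decay segment
  dstart <- 1L       # sample index where the decay segment begins
  i <- 1L
  chunk <- 4096L
  while (i <= n) {
    found <- NA_integer_
    j0 <- i
    while (j0 <= n) {
      jj <- j0:min(n, j0 + chunk - 1L)
      thr <- floor_mv + (thr0 - floor_mv) * exp(-pmax(0, jj - dstart) / tau)
      hit <- which(x[jj] >= thr)
      if (length(hit) > 0L) { found <- jj[hit[1L]]; break }
      j0 <- jj[length(jj)] + 1L
    }
    if (is.na(found)) break
    events <- c(events, found)
    peak <- max(x[found:min(n, found + nb)])
    thr0 <- max(min(p$peak_fraction * peak, p$max_threshold_mv), floor_mv)
    dstart <- found + nb
    i <- found + nb + 1L
  }
  (events - 1) / fs
}

#' Interval-based VF detection
#'
#' @param events Sorted ascending event times in seconds (from
#'   [sense_events()]).
#' @param d A [detection_params()] object.
#' @param episode_duration_s Episode duration in seconds.
#' @return A list of class `detection_result` with fields `detected`,
#'   `t_detect_s` (NA if undetected), `t_therapy_s`, `events` and
#'   `intervals_ms`.
#' @export
detect_vf <- function(events, d = detection_params(), episode_duration_s) {
  stopifnot(inherits(d, "detection_params"))
  stopifnot_scalar(episode_duration_s, "episode_duration_s", positive = TRUE)
  if (is.unsorted(events, strictly = TRUE) && length(events) > 1L)
    stop("`events` must be sorted strictly ascending", call. = FALSE)
  intervals <- diff(events) * 1000
  res <- list(detected = FALSE, t_detect_s = NA_real_, t_therapy_s = NA_real_,
              events = events, intervals_ms = intervals)
  class(res) <- "detection_result"
  m <- length(intervals)
  if (m == 0L) return(res)
  qual <- as.integer(intervals < d$vf_interval_ms)
  cs <- cumsum(qual)
  lo <- pmax(0L, seq_len(m) - d$nid_y)
  win <- cs - c(0, cs)[lo + 1L]
  k <- which(win >= d$nid_x)
  if (length(k) > 0L) {
    t_det <- events[k[1L] + 1L]
    if (t_det <= episode_duration_s) {
      res$detected <- TRUE
      res$t_detect_s <- t_det
      res$t_therapy_s <- t_det + d$charge_time_s
    }
  }
  res
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<detection_result> VF detected at %.2f s (therapy %.2f s), %d events\n",
                x$t_detect_s, x$t_therapy_s, length(x$events)))
  else
    cat(sprintf("<detection_result> VF not detected (%d events)\n",
                length(x$events)))
  invisible(x)
}

#' Run the full sensing and detection chain on a recording
#'
#' Composition [band_rectify()] -> [sense_events()] -> [detect_vf()];
#' deterministic for a fixed input.
#'
#' @param rec An [egm_recording()] at the device rate.
#' @param sp A [sensing_params()] object.
#' @param dp A [detection_params()] object.
#' @return A `detection_result` (see [detect_vf()]).
#' @export
run_detector <- function(rec, sp = sensing_params(), dp = detection_params()) {
  sensed <- band_rectify(rec)
  ev <- sense_events(sensed, sp)
  detect_vf(ev, dp, episode_duration_s = duration_s(rec))
}
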