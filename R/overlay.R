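#' Pre-amplifier model parameters
#'
#' The ICD front end is modelled as a second-order high-pass cascaded with a
#' second-order low-pass (Butterworth, bilinear-discretized at the internal
#' synthesis rate). On a sub-millisecond rectangular pacing pulse this
#' produces the characteristic reduction in slew rate and a slight
#' opposite-polarity rebound, with AC coupling driving the long-run mean to
#' zero.
#'
#' @param hp_corner_hz High-pass corner in Hz (default 10).
#' @param lp_corner_hz Low-pass corner in Hz (default 95).
#' @param order Filter order per section (default 2).
#' @param internal_fs_hz Internal synthesis rate in Hz (default 32768;
#'   configurable upward, a fidelity knob rather than a semantic one).
#' @return A list of class `preamp_params`.
#' @export
preamp_params <- function(hp_corner_hz = 10, lp_corner_hz = 95, order = 2,
                          internal_fs_hz = 32768) {
  stopifnot_scalar(hp_corner_hz, "hp_corner_hz", positive = TRUE)
  stopifnot_scalar(lp_corner_hz, "lp_corner_hz", positive = TRUE)
  stopifnot_scalar(order, "order", positive = TRUE)
  stopifnot_scalar(internal_fs_hz, "internal_fs_hz", positive = TRUE)
  if (!(hp_corner_hz < lp_corner_hz && lp_corner_hz < internal_fs_hz / 2))
    stop("need hp_corner_hz < lp_corner_hz < internal_fs_hz / 2",
         call. = FALSE)
  structure(list(hp_corner_hz = hp_corner_hz, lp_corner_hz = lp_corner_hz,
                 order = as.integer(order), internal_fs_hz = internal_fs_hz),
            class = "preamp_params")
}

#' Synthesize a raw pacing pulse at the internal rate
#'
#' @param amp_mv Pulse amplitude in mV (non-zero; sign is preserved).
#' @param width_ms Pulse width in ms (must span at least one internal sample).
#' @param internal_fs_hz Internal synthesis rate in Hz.
#' @param recharge If `TRUE`, append an opposite-polarity recharge tail of
#'   10% amplitude and 10x width so the total signed area cancels
#'   (charge balance).
#' @return Numeric waveform at the internal rate (no padding).
#' @export
synthesize_pulse <- function(amp_mv, width_ms, internal_fs_hz = 32768,
                             recharge = FALSE) {
  stopifnot_scalar(amp_mv, "amp_mv")
  if (amp_mv == 0) stop("`amp_mv` must be non-zero", call. = FALSE)
  stopifnot_scalar(width_ms, "width_ms", positive = TRUE)
  n_w <- round(width_ms / 1000 * internal_fs_hz)
  if (n_w < 1)
    stop("pulse width is shorter than one internal sample", call. = FALSE)
  pulse <- rep(amp_mv, n_w)
  if (recharge)
    pulse <- c(pulse, rep(-amp_mv / 10, 10L * n_w))
  pulse
}

#' Apply the pre-amplifier model to a waveform
#'
#' Causal application of the high-pass/low-pass cascade described in
#' [preamp_params()]. For a rectangular pulse the output peak is reduced, the
#' maximum slew rate drops, and an opposite-polarity rebound follows the main
#' deflection.
#'
#' @param waveform Numeric vector at the internal rate.
#' @param params A [preamp_params()] object.
#' @return Filtered waveform, same length.
#' @export
preamp_filter <- function(waveform, params = preamp_params()) {
  stopifnot(inherits(params, "preamp_params"))
  nyq <- params$internal_fs_hz / 2
  hp <- signal::butter(params$order, params$hp_corner_hz / nyq, type = "high")
  lp <- signal::butter(params$order, params$lp_corner_hz / nyq, type = "low")
  out <- as.numeric(signal::filter(hp, waveform))
  as.numeric(signal::filter(lp, out))
}

# Build the sensed-artefact template at the device rate for a given pulse
# width: synthesize -> pre-amp -> anti-aliased resample -> edge taper ->
# normalize to unit peak. Returns list(template, onset_lead_s).
pacing_template <- function(width_ms, preamp = preamp_params(),
                            device_fs = 256, recharge = FALSE) {
  fs_i <- preamp$internal_fs_hz
  lead_s <- 0.010
  tail_s <- 0.240
  pulse <- synthesize_pulse(1, width_ms, fs_i, recharge = recharge)
  x <- c(numeric(round(lead_s * fs_i)), pulse,
         numeric(round(tail_s * fs_i) - length(pulse)))
  y <- preamp_filter(x, preamp)
  # anti-alias before decimating to the device rate (zero-phase so the
  # artefact peak is not delayed further)
  aa <- signal::butter(4, min(0.95, 0.45 * device_fs / (fs_i / 2)),
                       type = "low")
  y <- as.numeric(signal::filtfilt(aa, y))
  t_i <- (seq_along(y) - 1) / fs_i
  t_d <- seq(0, max(t_i), by = 1 / device_fs)
  tpl <- stats::approx(t_i, y, xout = t_d)$y
  # cubic taper over the first/last 2 device samples for a smooth insertion
  ramp <- function(u) u^2 * (3 - 2 * u)
  k <- 2L
  tpl[seq_len(k)] <- tpl[seq_len(k)] * ramp(seq_len(k) / (k + 1))
  n <- length(tpl)
  tpl[(n - k + 1):n] <- tpl[(n - k + 1):n] * rev(ramp(seq_len(k) / (k + 1)))
  peak <- max(abs(tpl))
  list(template = tpl / peak, onset_lead_s = lead_s)
}

#' Pacing-overlay specification
#'
#' Exactly one of `spike_amp_mv` (sensed artefact peak at the device rate, in
#' mV) or `ratio` (spike-to-mean-VF amplitude ratio) must be given.
#'
#' @param rate_ppm Pacing rate in pulses/min (60, 90, 150, 180 in the studies;
#'   any positive value accepted).
#' @param spike_amp_mv Sensed (post-field, post-front-end) spike amplitude in
#'   mV, or `NULL`.
#' @param ratio Spike-to-mean-VF amplitude ratio, or `NULL`.
#' @param pulse_width_ms Pulse width in ms.
#' @param phase_s Offset of the first pulse in seconds.
#' @param recharge If `TRUE`, pulses carry a charge-balancing recharge tail.
#' @return A list of class `overlay_spec`.
#' @export
overlay_spec <- function(rate_ppm = 60, spike_amp_mv = NULL, ratio = NULL,
                         pulse_width_ms = 0.24, phase_s = 0,
                         recharge = FALSE) {
  if (is.null(spike_amp_mv) == is.null(ratio))
    stop("specify exactly one of `spike_amp_mv` or `ratio`", call. = FALSE)
  stopifnot_scalar(rate_ppm, "rate_ppm", positive = TRUE)
  stopifnot_scalar(pulse_width_ms, "pulse_width_ms", positive = TRUE)
  stopifnot_scalar(phase_s, "phase_s", nonneg = TRUE)
  if (!is.null(spike_amp_mv)) stopifnot_scalar(spike_amp_mv, "spike_amp_mv",
                                               nonneg = TRUE)
  if (!is.null(ratio)) stopifnot_scalar(ratio, "ratio", nonneg = TRUE)
  structure(list(rate_ppm = rate_ppm, spike_amp_mv = spike_amp_mv,
                 ratio = ratio, pulse_width_ms = pulse_width_ms,
                 phase_s = phase_s, recharge = isTRUE(recharge)),
            class = "overlay_spec")
}

#' Superimpose asynchronous pacing artefacts on a recording
#'
#' Pulses are synthesized at the internal rate, passed through the
#' pre-amplifier model, resampled to the device rate with anti-aliasing, edge
#' tapered, normalized so the artefact peak equals the requested sensed spike
#' amplitude, and added to the recording at times
#' `phase_s + k * 60 / rate_ppm`. Pulse timing is asynchronous to the VF
#' content; true pulse times are recorded as markers.
#'
#' @param rec An [egm_recording()] at the device rate.
#' @param spec An [overlay_spec()].
#' @param preamp A [preamp_params()] object.
#' @return An [egm_recording()] with the additive artefact and `pace`
#'   markers. A zero spike amplitude returns the input samples unchanged.
#' @export
overlay_pacing <- function(rec, spec, preamp = preamp_params()) {
  stopifnot(inherits(rec, "egm_recording"), inherits(spec, "overlay_spec"))
  amp <- spec$spike_amp_mv
  if (is.null(amp)) {
    vf <- mean_vf_amplitude(rec)   # errors on an all-zero recording
    amp <- spec$ratio * vf
  }
  dur <- duration_s(rec)
  times <- seq(spec$phase_s, dur - 1e-9, by = 60 / spec$rate_ppm)
  times <- times[times < dur]
  markers <- data.frame(time_s = times, tag = "pace")
  if (amp == 0 || length(times) == 0)
    return(egm_recording(rec$samples, rec$fs, rec$label, markers = markers))
  tpl <- pacing_template(spec$pulse_width_ms, preamp, device_fs = rec$fs,
                         recharge = spec$recharge)$template * amp
  out <- rec$samples
  n <- length(out)
  for (t0 in times) {
    i0 <- round(t0 * rec$fs) + 1L
    idx <- i0:min(n, i0 + length(tpl) - 1L)
    if (length(idx) < 1L || idx[1] > n) next
    out[idx] <- out[idx] + tpl[seq_along(idx)]
  }
  egm_recording(out, rec$fs,
                label = sprintf("%s + pacing %.3g mV @ %g ppm / %g ms",
                                rec$label, amp, spec$rate_ppm,
                                spec$pulse_width_ms),
                markers = markers)
}

# Centered running maximum with half-window `halfwin` samples.
running_max <- function(x, halfwin) {
  out <- x
  for (k in seq_len(halfwin)) {
    n <- length(x)
    out <- pmax(out,
                c(x[-seq_len(k)], rep(x[n], k)),
                c(rep(x[1], k), x[seq_len(n - k)]))
  }
  out
}

#' Mean VF amplitude of a recording
#'
#' Mean of per-cycle peak amplitudes of the rectified device-rate signal,
#' with cycles delimited by upward crossings of a threshold at 25% of the
#' running peak (1 s centered window). This mirrors how a sense amplifier
#' "sees" amplitude: each deflection contributes its rectified peak.
#'
#' @param rec An [egm_recording()] of at least 2 s.
#' @return Mean per-cycle peak amplitude in mV (strictly positive).
#' @export
mean_vf_amplitude <- function(rec) {
  stopifnot(inherits(rec, "egm_recording"))
  if (duration_s(rec) < 2)
    stop("recording must be at least 2 s long", call. = FALSE)
  r <- abs(rec$samples)
  if (max(r) == 0)
    stop("amplitude undefined for an all-zero recording", call. = FALSE)
  thr <- 0.25 * running_max(r, halfwin = round(rec$fs / 2))
  up <- which(r[-1] >= thr[-1] & r[-length(r)] < thr[-length(r)]) + 1L
  if (length(up) == 0)
    return(max(r))
  seg <- findInterval(seq_along(r), up)
  keep <- seg >= 1L
  peaks <- tapply(r[keep], seg[keep], max)
  mean(peaks)
}

#' Spike-to-VF amplitude ratio
#'
#' @param spike_amp_mv Sensed pacing-spike amplitude in mV.
#' @param vf_amp_mv Mean VF amplitude in mV (> 0).
#' @return The dimensionless ratio `spike_amp_mv / vf_amp_mv` (unrounded;
#'   tabular output rounds to 2 decimals).
#' @export
compute_ratio <- function(spike_amp_mv, vf_amp_mv) {
  stopifnot_scalar(spike_amp_mv, "spike_amp_mv", nonneg = TRUE)
  stopifnot_scalar(vf_amp_mv, "vf_amp_mv")
  if (vf_amp_mv <= 0)
    stop("`vf_amp_mv` must be > 0", call. = FALSE)
  spike_amp_mv / vf_amp_mv
}
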