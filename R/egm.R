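#' Electrogram recording container
#'
#' A uniformly sampled bipolar electrogram in millivolts. This is the object
#' that flows through every signal-processing stage of the package: synthesis,
#' looping, pacing overlay, sensing.
#'
#' @param samples Numeric vector of amplitudes in mV (length >= 2, all finite).
#' @param fs Sampling rate in Hz (> 0). The device rate used throughout is
#'   256 Hz.
#' @param label Free-text provenance string.
#' @param markers Optional data frame with columns `time_s` and `tag`
#'   annotating events (e.g. true pacing-pulse times).
#'
#' @return An object of class `egm_recording` with fields `samples`, `fs`,
#'   `label` and `markers`.
#' @export
egm_recording <- function(samples, fs, label = "", markers = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("an egm_recording needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (!is.null(markers)) {
    markers <- as.data.frame(markers)
    if (!all(c("time_s", "tag") %in% names(markers)))
      stop("`markers` must have columns time_s and tag", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, label = as.character(label)[1],
         markers = markers),
    class = "egm_recording"
  )
}

#' @export
print.egm_recording <- function(x, ...) {
  cat(sprintf("<egm_recording> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, duration_s(x),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  cat(sprintf("  amplitude range: [%.4f, %.4f] mV\n",
              min(x$samples), max(x$samples)))
  if (!is.null(x$markers))
    cat(sprintf("  markers: %d\n", nrow(x$markers)))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec An [egm_recording()].
#' @return Duration in seconds (`length(samples) / fs`).
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "egm_recording"))
  length(rec$samples) / rec$fs
}

#' Quantize a recording to 8-bit resolution
#'
#' Maps samples onto 256 uniform levels spanning
#' `[-full_scale_mv, +full_scale_mv]`, clipping at the rails, emulating the
#' 8-bit device-recorded electrograms the rest of the pipeline consumes.
#' Maximum quantization error for in-range samples is one half LSB,
#' `full_scale_mv / 255`.
#'
#' @param rec An [egm_recording()].
#' @param full_scale_mv Full-scale amplitude in mV (> 0); default 8 mV.
#' @return A quantized [egm_recording()] with at most 256 distinct sample
#'   values; `fs` and markers are unchanged.
#' @export
quantize_8bit <- function(rec, full_scale_mv = 8) {
  stopifnot(inherits(rec, "egm_recording"))
  stopifnot_scalar(full_scale_mv, "full_scale_mv", positive = TRUE)
  idx <- round((rec$samples + full_scale_mv) / (2 * full_scale_mv) * 255)
  idx <- pmin(pmax(idx, 0), 255)
  q <- idx / 255 * 2 * full_scale_mv - full_scale_mv
  egm_recording(q, rec$fs, label = paste0(rec$label, " [8-bit]"),
                markers = rec$markers)
}
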