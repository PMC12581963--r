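# Waveform and configuration I/O. Units are embedded in column headers:
# times in seconds, amplitudes in mV.

#' Read a waveform CSV into an electrogram recording
#'
#' Expects a header `time_s,amp_mv` and a uniform time base (maximum
#' timestamp jitter below 1% of the mean interval); the sampling rate is
#' inferred from the mean interval.
#'
#' @param path Path to the CSV file.
#' @return An [egm_recording()].
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) < 2L)
    stop("waveform file needs at least 2 rows: ", path, call. = FALSE)
  if (!all(c("time_s", "amp_mv") %in% names(df)))
    stop("expected header `time_s,amp_mv` in ", path, call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) {
    line <- which(dt <= 0)[1] + 2L  # +1 header, +1 second row of the pair
    stop(sprintf("non-monotone time at line %d of %s", line, path),
         call. = FALSE)
  }
  jitter <- max(abs(dt - mean(dt)))
  if (jitter >= 0.01 * mean(dt)) {
    line <- which.max(abs(dt - mean(dt))) + 2L
    stop(sprintf("non-uniform sampling (jitter at line %d) in %s",
                 line, path), call. = FALSE)
  }
  egm_recording(df$amp_mv, fs = 1 / mean(dt), label = basename(path))
}

#' Write a recording to a waveform CSV
#'
#' @param rec An [egm_recording()].
#' @param path Output path.
#' @param digits Decimal digits for both columns (default 6).
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(rec, path, digits = 6) {
  stopifnot(inherits(rec, "egm_recording"))
  t <- (seq_along(rec$samples) - 1) / rec$fs
  df <- data.frame(time_s = round(t, digits),
                   amp_mv = round(rec$samples, digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a serializable run configuration
#'
#' Collects the seed and all stage parameters into one plain named list that
#' round-trips losslessly through on-disk text serialization (e.g. dput/YAML/
#' JSON handled by the caller), so any two runs with an identical config are
#' reproducible.
#'
#' @param seed Integer master seed.
#' @param sensing A [sensing_params()] object.
#' @param detection A [detection_params()] object.
#' @param preamp A [preamp_params()] object.
#' @param grid Optional list of grid axes (`widths_ms`, `amps_mv`,
#'   `rates_ppm`).
#' @param mc Optional list of Monte Carlo settings (`threshold_mm`,
#'   `n_samples`, `truncate_low_mm`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, sensing = sensing_params(),
                       detection = detection_params(),
                       preamp = preamp_params(), grid = NULL, mc = NULL) {
  structure(list(seed = as.integer(seed),
                 sensing = unclass(sensing),
                 detection = unclass(detection),
                 preamp = unclass(preamp),
                 grid = grid, mc = mc),
            class = "run_config")
}
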