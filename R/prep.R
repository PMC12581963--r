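#' Find a near-isoelectric junction point for looping
#'
#' Scans the trailing `search_window_ms` of a recording for the sample with
#' the smallest absolute amplitude. Looping an episode at a near-isoelectric
#' sample minimizes the amplitude spike at each stitch junction. Ties are
#' broken by the latest index, which keeps the longest usable segment.
#'
#' @param rec An [egm_recording()].
#' @param search_window_ms Length of the trailing search window in ms
#'   (default 250 ms).
#' @return A list of class `junction_spec` with `junction_index` (1-based
#'   sample index), `search_window_ms` and `smooth_halfwidth_samples`
#'   (default 4).
#' @export
find_junction_point <- function(rec, search_window_ms = 250) {
  stopifnot(inherits(rec, "egm_recording"))
  stopifnot_scalar(search_window_ms, "search_window_ms", positive = TRUE)
  n <- length(rec$samples)
  w <- round(search_window_ms / 1000 * rec$fs)
  if (w >= n)
    stop("search window must be shorter than the recording", call. = FALSE)
  idx0 <- n - w + 1L
  window <- abs(rec$samples[idx0:n])
  # latest index attaining the minimum
  j <- idx0 + max(which(window == min(window))) - 1L
  structure(list(junction_index = j, search_window_ms = search_window_ms,
                 smooth_halfwidth_samples = 4L),
            class = "junction_spec")
}

# Cubic Hermite segment through (x0,y0,m0) and (x1,y1,m1), evaluated at xs.
hermite_eval <- function(x0, y0, m0, x1, y1, m1, xs) {
  h <- x1 - x0
  u <- (xs - x0) / h
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  h00 * y0 + h10 * h * m0 + h01 * y1 + h11 * h * m1
}

#' Loop (stitch) an episode to a target duration
#'
#' Device-recorded VF episodes last only 6-10 s; to simulate an ongoing
#' arrhythmia the recording is truncated at a near-isoelectric junction and
#' tiled until the target duration is reached. At each stitch junction a cubic
#' polynomial segment replaces `smooth_halfwidth_samples` samples on each
#' side, interpolating the surrounding values so the junction jump never
#' exceeds the raw tiled jump. Away from junction neighbourhoods the output
#' equals the tiled input exactly.
#'
#' @param rec An [egm_recording()].
#' @param target_duration_s Target duration in seconds (>= input duration;
#'   60 s is the conventional simulated-episode length).
#' @param junction A `junction_spec` from [find_junction_point()]; computed
#'   automatically if `NULL`.
#' @return An [egm_recording()] whose duration is within one sample of
#'   `target_duration_s`. Inputs already at or beyond the target are returned
#'   unchanged.
#' @export
loop_episode <- function(rec, target_duration_s = 60, junction = NULL) {
  stopifnot(inherits(rec, "egm_recording"))
  stopifnot_scalar(target_duration_s, "target_duration_s", positive = TRUE)
  if (target_duration_s < duration_s(rec) - 1 / rec$fs / 2)
    stop("target duration is shorter than the recording", call. = FALSE)
  if (duration_s(rec) >= target_duration_s)
    return(rec)
  if (is.null(junction)) junction <- find_junction_point(rec)
  stopifnot(inherits(junction, "junction_spec"))
  j <- junction$junction_index
  if (j < 2L || j > length(rec$samples))
    stop("junction index out of bounds", call. = FALSE)
  h <- junction$smooth_halfwidth_samples

  seg <- rec$samples[seq_len(j)]
  n_out <- round(target_duration_s * rec$fs)
  reps <- ceiling(n_out / j)
  out <- rep(seg, reps)[seq_len(n_out)]

  # smooth each junction with a cubic through the surrounding samples
  junctions <- seq(j, by = j, length.out = reps - 1) + 1L  # first sample of each new tile
  for (jj in junctions) {
    lo <- jj - h       # first replaced sample
    hi <- jj + h - 1L  # last replaced sample
    if (lo < 2L || hi > n_out - 1L) next
    x0 <- lo - 1L; x1 <- hi + 1L
    y0 <- out[x0]; y1 <- out[x1]
    m0 <- if (x0 > 1L) (out[x0] - out[x0 - 1L]) else 0
    m1 <- if (x1 < n_out) (out[x1 + 1L] - out[x1]) else 0
    smoothed <- hermite_eval(x0, y0, m0, x1, y1, m1, lo:hi)
    # guard: never let smoothing worsen the local step size
    before <- max(abs(diff(out[x0:x1])))
    after <- max(abs(diff(c(y0, smoothed, y1))))
    if (after <= before) out[lo:hi] <- smoothed
  }
  egm_recording(out, rec$fs,
                label = sprintf("%s [looped to %gs]", rec$label,
                                target_duration_s))
}
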