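#' Implant geometry of both devices
#'
#' 3-D electrode positions (mm, right-handed Cartesian, patient-agnostic) of
#' the leadless pacemaker (tip and ring on one rigid body) and the ICD
#' sensing electrodes (two lead rings and optionally the can).
#'
#' @param ppg_tip,ppg_ring Length-3 positions of the pacemaker tip and ring.
#' @param icd_ring1,icd_ring2 Length-3 positions of the ICD lead rings.
#' @param icd_can Optional length-3 position of the device can.
#' @return A list of class `device_geometry`.
#' @export
device_geometry <- function(ppg_tip, ppg_ring, icd_ring1, icd_ring2,
                            icd_can = NULL) {
  pts <- list(ppg_tip = ppg_tip, ppg_ring = ppg_ring, icd_ring1 = icd_ring1,
              icd_ring2 = icd_ring2)
  if (!is.null(icd_can)) pts$icd_can <- icd_can
  for (nm in names(pts)) {
    p <- as.numeric(pts[[nm]])
    if (length(p) != 3L || !all(is.finite(p)))
      stop(sprintf("`%s` must be a finite 3-vector", nm), call. = FALSE)
    pts[[nm]] <- p
  }
  structure(pts, class = "device_geometry")
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Inter-device electrode distances
#'
#' The two distances used throughout the geometry analyses: D1 from the ICD
#' Ring2 electrode to the pacemaker tip, and D2 from the ICD Ring1 electrode
#' to the pacemaker ring.
#'
#' @param g A [device_geometry()].
#' @return A list of class `distance_pair` with `d1_mm` and `d2_mm`.
#' @export
electrode_distances <- function(g) {
  stopifnot(inherits(g, "device_geometry"))
  structure(list(d1_mm = dist3(g$icd_ring2, g$ppg_tip),
                 d2_mm = dist3(g$icd_ring1, g$ppg_ring)),
            class = "distance_pair")
}

#' Sum of the two inter-device distances
#'
#' The scalar that drives the sensed pacing-spike amplitude across rotation
#' poses: rotation matters only through the distances it creates.
#'
#' @param g A [device_geometry()].
#' @return `d1_mm + d2_mm` in mm.
#' @export
rotation_distance_sum <- function(g) {
  d <- electrode_distances(g)
  d$d1_mm + d$d2_mm
}

#' Collinear distance trade-off
#'
#' In the antiparallel collinear arrangement of pacemaker and lead, moving
#' the pacemaker tip closer to Ring2 by some amount moves the pacemaker ring
#' farther from Ring1 by the same amount — dual proximity below ~10 mm is
#' geometrically unfeasible.
#'
#' @param tip_dist_mm Current tip-to-Ring2 distance in mm.
#' @param ring_dist_mm Current ring-to-Ring1 distance in mm.
#' @param new_tip_dist_mm New tip-to-Ring2 distance in mm.
#' @return The new ring-to-Ring1 distance,
#'   `ring_dist_mm + (tip_dist_mm - new_tip_dist_mm)`.
#' @export
collinear_tradeoff <- function(tip_dist_mm, ring_dist_mm, new_tip_dist_mm) {
  stopifnot_scalar(tip_dist_mm, "tip_dist_mm", nonneg = TRUE)
  stopifnot_scalar(ring_dist_mm, "ring_dist_mm", nonneg = TRUE)
  stopifnot_scalar(new_tip_dist_mm, "new_tip_dist_mm", nonneg = TRUE)
  ring_dist_mm + (tip_dist_mm - new_tip_dist_mm)
}

#' Construct a coplanar geometry realizing given inter-device distances
#'
#' Places the ICD lead on the x-axis (Ring2 at the origin, Ring1 at
#' `lead_sep_mm`) and searches tip orientations for a placement with the
#' requested D1 (Ring2-tip) and D2 (Ring1-ring) under the rigid tip-ring
#' separation. Deterministic: among feasible orientations the median is
#' chosen.
#'
#' @param d1_mm,d2_mm Target distances in mm.
#' @param lead_sep_mm Ring1-Ring2 separation (default 30 mm).
#' @param ppg_len_mm Pacemaker tip-ring separation (default 18 mm).
#' @param can_offset_mm Optional lateral offset for a can electrode at
#'   `(lead_sep_mm / 2, -can_offset_mm, 0)`; `NULL` omits the can.
#' @return A [device_geometry()].
#' @export
geometry_from_distances <- function(d1_mm, d2_mm, lead_sep_mm = 30,
                                    ppg_len_mm = 18, can_offset_mm = NULL) {
  stopifnot_scalar(d1_mm, "d1_mm", positive = TRUE)
  stopifnot_scalar(d2_mm, "d2_mm", positive = TRUE)
  ring2 <- c(0, 0, 0)
  ring1 <- c(lead_sep_mm, 0, 0)
  feasible <- list()
  for (theta in seq(0, pi, length.out = 721)) {
    tip <- d1_mm * c(cos(theta), sin(theta), 0)
    # ring must lie on circle(tip, ppg_len) and circle(ring1, d2)
    dtr <- dist3(tip, ring1)
    if (dtr > ppg_len_mm + d2_mm || dtr < abs(ppg_len_mm - d2_mm) ||
        dtr < 1e-9) next
    a <- (ppg_len_mm^2 - d2_mm^2 + dtr^2) / (2 * dtr)
    h2 <- ppg_len_mm^2 - a^2
    if (h2 < 0) next
    h <- sqrt(h2)
    base <- tip + a * (ring1 - tip) / dtr
    perp <- c(-(ring1 - tip)[2], (ring1 - tip)[1], 0) / dtr
    ring <- base + h * perp
    feasible[[length(feasible) + 1L]] <- list(tip = tip, ring = ring)
  }
  if (length(feasible) == 0L)
    stop("no coplanar placement realizes the requested distances",
         call. = FALSE)
  pick <- feasible[[ceiling(length(feasible) / 2)]]
  device_geometry(ppg_tip = pick$tip, ppg_ring = pick$ring,
                  icd_ring1 = ring1, icd_ring2 = ring2,
                  icd_can = if (is.null(can_offset_mm)) NULL
                            else c(lead_sep_mm / 2, -can_offset_mm, 0))
}

#' Sensed pacing-spike amplitude from an idealized volume conductor
#'
#' Models the pacing dipole as a point current source/sink pair at the
#' pacemaker tip and ring in an infinite homogeneous medium of resistivity
#' `rho` (Ohm cm): the potential at a point is
#' `rho * I / (4 * pi) * (1 / r_tip - 1 / r_ring)` with the injected current
#' derived from the programmed amplitude through a fixed electrode-interface
#' impedance. The sensed amplitude is the absolute potential difference
#' across the selected ICD electrode pair. Only relative amplitudes are
#' meaningful; the model captures the 1/r decay with distance, not tank
#' measurements.
#'
#' @param g A [device_geometry()].
#' @param program A [pacing_program()].
#' @param resistivity_ohm_cm Medium resistivity (default 375 Ohm cm, the
#'   saline value emulating blood and cardiac tissue).
#' @param vector Sensing vector: `"ring1-ring2"`, `"ring1-can"` or
#'   `"ring2-can"`.
#' @param interface_ohm Electrode-interface impedance converting programmed
#'   volts to injected current (default 500 Ohm).
#' @return Sensed amplitude in mV (>= 0).
#' @export
sensed_amplitude <- function(g, program, resistivity_ohm_cm = 375,
                             vector = c("ring1-ring2", "ring1-can",
                                        "ring2-can"),
                             interface_ohm = 500) {
  stopifnot(inherits(g, "device_geometry"), inherits(program, "pacing_program"))
  stopifnot_scalar(resistivity_ohm_cm, "resistivity_ohm_cm", positive = TRUE)
  vector <- match.arg(vector)
  pair <- switch(vector,
                 "ring1-ring2" = list(g$icd_ring1, g$icd_ring2),
                 "ring1-can" = list(g$icd_ring1, g$icd_can),
                 "ring2-can" = list(g$icd_ring2, g$icd_can))
  if (any(vapply(pair, is.null, logical(1))))
    stop("selected vector needs a can electrode in the geometry",
         call. = FALSE)
  current_a <- program$amplitude_v / interface_ohm
  phi <- function(p) {
    r_tip <- dist3(p, g$ppg_tip) / 10   # mm -> cm
    r_ring <- dist3(p, g$ppg_ring) / 10
    if (r_tip < 1e-9 || r_ring < 1e-9)
      stop("electrode coincides with a source point (singularity)",
           call. = FALSE)
    resistivity_ohm_cm * current_a / (4 * pi) * (1 / r_tip - 1 / r_ring)
  }
  abs(phi(pair[[1]]) - phi(pair[[2]])) * 1000  # V -> mV
}
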