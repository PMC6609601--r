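#' Collimator specification
#'
#' Physical slit collimator of a panoramic unit: slit height and width and
#' the focus-to-collimator distance (FCD). Beam dimensions at the reference
#' plane follow by similar triangles, see [beam_dimensions()].
#'
#' @param height_cm Collimator height (cm), default 3.78.
#' @param width_cm Collimator width (cm), default 0.09.
#' @param fcd_cm Focus-to-collimator distance (cm), default 13.0.
#' @return List of class `ppd_collimator`.
#' @export
collimator_spec <- function(height_cm = 3.78, width_cm = 0.09, fcd_cm = 13.0) {
  if (height_cm <= 0 || width_cm <= 0 || fcd_cm <= 0)
    stop("collimator dimensions and FCD must be positive")
  structure(list(height_cm = height_cm, width_cm = width_cm,
                 fcd_cm = fcd_cm), class = "ppd_collimator")
}

#' Beam dimensions at the reference plane
#'
#' Projects the collimator slit to the focus-to-reference distance:
#' `height = collimator_height * frd / fcd`, and likewise for the width.
#' Note that machine-reported beam sizes are often rounded; the package
#' accepts either explicit beam dimensions in [exposure_geometry()] or a
#' collimator spec here, and never silently reconciles the two.
#'
#' @param spec A [collimator_spec()].
#' @param frd Focus-to-reference distance (cm), must be >= FCD.
#' @return Named numeric `c(height, width)` in cm.
#' @export
#' @examples
#' beam_dimensions(collimator_spec(), frd = 35)
beam_dimensions <- function(spec, frd) {
  if (frd < spec$fcd_cm)
    stop("frd < fcd: reference point lies inside the collimator")
  c(height = spec$height_cm * frd / spec$fcd_cm,
    width = spec$width_cm * frd / spec$fcd_cm)
}

#' Exposure geometry of a panoramic run
#'
#' The seven dose-determining factors plus the dose-area product and the
#' reference point. Coordinates are in the body frame: X left-to-right,
#' Y posterior-to-anterior, Z inferior-to-superior, origin at the
#' whole-body centre. The reference point is where the central ray from all
#' projection angles intersects (default `(0, -3, 47)`, the centre of the
#' dental arch of a 5-year-old). Defaults are the general paediatric
#' conditions: 240° rotation, -8° vertical angle (source below, beam
#' tilting upward), FRD 35 cm, beam 0.20 cm x 10.00 cm at the reference,
#' 2.8 mmAl filtration, 66 kVp.
#'
#' @param rotation_angle Source arc in degrees, in \[0, 360\] (0 = single
#'   posterior projection).
#' @param vertical_angle Central-ray tilt in degrees (negative = upward
#'   from below).
#' @param frd Focus-to-reference distance (cm).
#' @param beam_width,beam_height Beam size at the reference plane (cm).
#' @param filtration Aluminum filtration (mmAl).
#' @param kvp Tube voltage (kVp).
#' @param dap Dose-area product (mGy cm^2) of the whole exposure. The
#'   default 60 is a representative paediatric panoramic value; absolute
#'   doses scale linearly with it.
#' @param reference_point Numeric length-3, cm in the body frame.
#' @return List of class `ppd_geometry`.
#' @export
exposure_geometry <- function(rotation_angle = 240, vertical_angle = -8,
                              frd = 35, beam_width = 0.20,
                              beam_height = 10.00, filtration = 2.8,
                              kvp = 66, dap = 60,
                              reference_point = c(0, -3, 47)) {
  if (rotation_angle < 0 || rotation_angle > 360)
    stop("rotation_angle must lie in [0, 360]")
  if (beam_width <= 0 || beam_height <= 0) stop("beam dimensions must be > 0")
  if (frd <= 0) stop("frd must be > 0")
  if (dap <= 0) stop("dap must be > 0")
  if (filtration < 0) stop("filtration must be >= 0")
  if (length(reference_point) != 3) stop("reference_point must be length 3")
  structure(list(rotation_angle = rotation_angle,
                 vertical_angle = vertical_angle, frd = frd,
                 beam_width = beam_width, beam_height = beam_height,
                 filtration = filtration, kvp = kvp, dap = dap,
                 reference_point = as.numeric(reference_point)),
            class = "ppd_geometry")
}

#' @export
print.ppd_geometry <- function(x, ...) {
  cat(sprintf(paste0("Panoramic exposure geometry: rotation %g deg, ",
                     "vertical %g deg, FRD %g cm\n  beam %g x %g cm, ",
                     "filtration %g mmAl, %g kVp, DAP %g mGy.cm^2\n",
                     "  reference point (%g, %g, %g) cm\n"),
              x$rotation_angle, x$vertical_angle, x$frd, x$beam_width,
              x$beam_height, x$filtration, x$kvp, x$dap,
              x$reference_point[1], x$reference_point[2],
              x$reference_point[3]))
  invisible(x)
}

#' Discretized source positions along the rotation arc
#'
#' Places `n_steps` equally-weighted source positions on the arc, centred
#' behind the head (posterior, -Y side of the reference point) and sweeping
#' symmetrically left/right, as in panoramic practice. Every source lies at
#' distance `frd` from the reference point; its central ray passes through
#' the reference point, tilted by the vertical angle from horizontal
#' (negative vertical angle: source below the reference plane, ray going
#' up).
#'
#' @param geom An [exposure_geometry()].
#' @param n_steps Number of arc samples (default: about one per degree).
#' @return List with matrices `source` (n x 3) and `direction` (n x 3,
#'   unit central rays), vector `arc_deg` (azimuth from posterior), and
#'   `weight` (`1/n_steps` each).
#' @export
arc_positions <- function(geom, n_steps = max(1L, ceiling(geom$rotation_angle))) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  rot <- geom$rotation_angle
  # midpoint rule: n samples spaced rot/n apart, symmetric about posterior
  theta <- (-rot / 2 + (seq_len(n_steps) - 0.5) * rot / n_steps) * pi / 180
  v <- geom$vertical_angle * pi / 180
  ref <- geom$reference_point
  src <- cbind(ref[1] + geom$frd * cos(v) * sin(theta),
               ref[2] - geom$frd * cos(v) * cos(theta),
               ref[3] + geom$frd * sin(v))
  dir <- (matrix(ref, nrow = n_steps, ncol = 3, byrow = TRUE) - src) / geom$frd
  list(source = src, direction = dir,
       arc_deg = theta * 180 / pi, weight = rep(1 / n_steps, n_steps))
}
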