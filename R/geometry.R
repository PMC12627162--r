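#' Screen geometry
#'
#' Physical description of the display used to convert between pixels and
#' degrees of visual angle. Defaults describe a 23.8-inch 1920x1080 monitor
#' viewed from 57 cm, the classical distance at which 1 cm on screen subtends
#' almost exactly 1 degree.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param diag_inches Physical diagonal of the panel, in inches.
#' @param view_dist_cm Eye-to-screen distance in centimetres.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_to_deg(100, geom)
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1080L,
                            diag_inches = 23.8, view_dist_cm = 57) {
  stopifnot(width_px > 0, height_px > 0, diag_inches > 0)
  if (!is.numeric(view_dist_cm) || view_dist_cm <= 0)
    stop("viewing distance must be positive", call. = FALSE)
  diag_px <- sqrt(width_px^2 + height_px^2)
  cm_per_px <- diag_inches * 2.54 / diag_px
  structure(list(width_px = width_px, height_px = height_px,
                 diag_inches = diag_inches, view_dist_cm = view_dist_cm,
                 cm_per_px = cm_per_px),
            class = "screen_geometry")
}

#' Convert a pixel length to degrees of visual angle
#'
#' Uses the full (non-small-angle) formula
#' \eqn{2 \arctan\{(s/2)/D\}} where \eqn{s} is the physical size of the
#' extent and \eqn{D} the viewing distance, so the mapping is sub-additive:
#' doubling a pixel extent less than doubles its angular size.
#'
#' @param px Length in pixels (vectorised).
#' @param geometry A [screen_geometry()].
#' @return Degrees of visual angle.
#' @export
px_to_deg <- function(px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(px < 0)) stop("pixel lengths must be non-negative", call. = FALSE)
  cm <- px * geometry$cm_per_px
  2 * atan2(cm / 2, geometry$view_dist_cm) * 180 / pi
}

#' Convert degrees of visual angle to pixels
#'
#' Inverse of [px_to_deg()].
#' @inheritParams px_to_deg
#' @param deg Angular extent in degrees.
#' @export
deg_to_px <- function(deg, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  2 * geometry$view_dist_cm * tan(deg / 2 * pi / 180) / geometry$cm_per_px
}

#' Screen extent in degrees
#'
#' Half-extent of the display along each axis, in screen-centred degrees.
#' Used by generators to clamp simulated gaze to the physical screen.
#' @inheritParams px_to_deg
#' @return Named numeric: `half_width_deg`, `half_height_deg`.
#' @export
screen_half_extent_deg <- function(geometry) {
  c(half_width_deg  = px_to_deg(geometry$width_px, geometry) / 2,
    half_height_deg = px_to_deg(geometry$height_px, geometry) / 2)
}
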