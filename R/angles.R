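# Angular conventions used throughout: bearings in degrees, measured
# clockwise from North (+y), so that a step of length dr at heading a is
# (dx, dy) = (dr * sin(a), dr * cos(a)).

DEG2RAD <- pi / 180

#' Wrap an angle into (-180, 180]
#'
#' Headings and heading errors are always reduced to the principal interval
#' before they enter the feedback filter, so that the controller steers the
#' short way round.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Angles wrapped into `(-180, 180]`, same length as input.
#' @examples
#' wrap_angle(c(190, -190, 180, 360))
#' @export
wrap_angle <- function(angle) {
  angle - 360 * ceiling((angle - 180) / 360)
}

#' Compass bearing from one point to another
#'
#' @param from,to Numeric length-2 vectors `(x, y)` in cm.
#' @return Bearing in degrees clockwise from North, in `(-180, 180]`.
#' @export
bearing_to <- function(from, to) {
  wrap_angle(atan2(to[1] - from[1], to[2] - from[2]) / DEG2RAD)
}

# Unit displacement for a heading (degrees, clockwise from North).
heading_unit <- function(angle) {
  c(sin(angle * DEG2RAD), cos(angle * DEG2RAD))
}

# Bearing of a point as seen from the pool centre, in [0, 360).
bearing_from_centre <- function(x, y) {
  (atan2(x, y) / DEG2RAD) %% 360
}
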