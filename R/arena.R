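# Arena geometry and trial protocol: a circular pool with origin at the pool
# centre, +y pointing North and +x pointing East. The hidden platform sits in
# the NE quadrant; landmarks hang outside the pool.

COMPASS_BEARINGS <- c(
  N = 0, NE = 45, E = 90, SE = 135,
  S = 180, SW = 225, W = 270, NW = 315
)

#' Specify a landmark cue
#'
#' A cue is a point landmark outside the pool with a salience weight
#' \eqn{\alpha_i \in [0, 1]} that scales all of its associative-learning
#' updates. Brightness labels are descriptive only; physical prominence
#' enters the model solely through the salience.
#'
#' @param cue_id Character identifier, e.g. `"Near"` or `"Far"`.
#' @param position Numeric length-2 `(x, y)` in cm; must lie outside the pool
#'   it is eventually attached to (validated by [arena_config()]).
#' @param salience Dimensionless weight in `[0, 1]`.
#' @param brightness_label Free-text annotation (e.g. `"40 W"`).
#' @return An object of class `cue_spec`.
#' @export
cue_spec <- function(cue_id, position, salience = 0.5, brightness_label = "") {
  stopifnot(is.character(cue_id), length(cue_id) == 1L,
            is.numeric(position), length(position) == 2L)
  if (!is.numeric(salience) || length(salience) != 1L ||
      salience < 0 || salience > 1) {
    stop("salience must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(cue_id = cue_id, position = as.numeric(position),
         salience = as.numeric(salience),
         brightness_label = as.character(brightness_label)),
    class = "cue_spec"
  )
}

#' Construct a water-maze arena and trial protocol
#'
#' @param pool_radius Pool radius in cm.
#' @param platform_center Numeric length-2 `(x, y)` of the platform centre, cm.
#' @param platform_radius Platform radius in cm; reaching within this distance
#'   of the platform centre counts as an escape.
#' @param escape_region_radius Radius (cm) of the circular scoring region
#'   around the platform location used for time-in-platform-area measures on
#'   probe trials. Must be at least `platform_radius`.
#' @param cues List of [cue_spec()] objects; all must lie outside the pool.
#' @param trial_duration Trial length in seconds.
#' @param trials_per_day,n_days Acquisition protocol.
#' @param start_positions Compass labels on the pool rim used during
#'   acquisition (pseudorandomly permuted within each day).
#' @param probe_start Compass label for the retention/probe start position.
#' @return An object of class `arena_config`.
#' @seealso [make_default_arena()] for the standard two-cue setup.
#' @export
arena_config <- function(pool_radius,
                         platform_center,
                         platform_radius,
                         escape_region_radius,
                         cues,
                         trial_duration = 60,
                         trials_per_day = 4,
                         n_days = 10,
                         start_positions = c("N", "S", "E", "W"),
                         probe_start = "SW") {
  stopifnot(is.numeric(pool_radius), pool_radius > 0,
            is.numeric(platform_center), length(platform_center) == 2L,
            is.numeric(platform_radius), platform_radius > 0,
            is.numeric(escape_region_radius),
            trial_duration > 0, trials_per_day >= 1, n_days >= 1)
  if (sqrt(sum(platform_center^2)) + platform_radius >= pool_radius) {
    stop("platform must lie strictly inside the pool", call. = FALSE)
  }
  if (escape_region_radius < platform_radius) {
    stop("escape_region_radius must be >= platform_radius", call. = FALSE)
  }
  if (!all(start_positions %in% names(COMPASS_BEARINGS)) ||
      !probe_start %in% names(COMPASS_BEARINGS)) {
    stop("start positions must be compass labels (N, NE, E, ..., NW)",
         call. = FALSE)
  }
  stopifnot(length(cues) >= 1L)
  ids <- vapply(cues, function(cue) {
    if (!inherits(cue, "cue_spec")) stop("cues must be cue_spec objects",
                                         call. = FALSE)
    if (sqrt(sum(cue$position^2)) <= pool_radius) {
      stop("cue '", cue$cue_id, "' must lie outside the pool", call. = FALSE)
    }
    cue$cue_id
  }, character(1))
  if (anyDuplicated(ids)) stop("cue ids must be unique", call. = FALSE)
  names(cues) <- ids
  structure(
    list(pool_radius = pool_radius,
         platform_center = as.numeric(platform_center),
         platform_radius = platform_radius,
         escape_region_radius = escape_region_radius,
         cues = cues,
         trial_duration = trial_duration,
         trials_per_day = as.integer(trials_per_day),
         n_days = as.integer(n_days),
         start_positions = start_positions,
         probe_start = probe_start),
    class = "arena_config"
  )
}

#' The standard two-cue water-maze arena
#'
#' A 1.7 m diameter pool with a 9 cm diameter platform submerged in the NE
#' quadrant, two light-bulb cues hanging outside the pool in the NE ("Near",
#' close to the platform) and NW ("Far") positions, 4 x 1-minute trials/day
#' for 10 days from pseudorandomly ordered N/S/E/W rim starts, and a 60 s
#' platform-absent probe from the novel SW start.
#'
#' The platform eccentricity (47.5 cm at bearing 45 degrees, near the areal
#' centroid of the NE quadrant) and the cue mounting radius (120 cm) are
#' standard placements, exposed as arguments because only the quadrant and
#' the inside-the-curtain mounting are physically fixed.
#'
#' @param cue_radius Radial distance of both cues from the pool centre, cm.
#' @param platform_bearing,platform_eccentricity Platform centre placement:
#'   compass bearing (degrees) and distance from the pool centre (cm).
#' @param saliences Named numeric vector of saliences for the `Near` and
#'   `Far` cues.
#' @param escape_region_radius Probe-trial scoring radius around the platform
#'   location, cm.
#' @return An `arena_config`.
#' @examples
#' arena <- make_default_arena()
#' arena$pool_radius                      # 85 cm
#' arena$trials_per_day * arena$n_days    # 40 acquisition trials
#' @export
make_default_arena <- function(cue_radius = 120,
                               platform_bearing = 45,
                               platform_eccentricity = 47.5,
                               saliences = c(Near = 0.5, Far = 0.5),
                               escape_region_radius = 15) {
  platform <- platform_eccentricity * heading_unit(platform_bearing)
  arena_config(
    pool_radius = 85,
    platform_center = platform,
    platform_radius = 4.5,
    escape_region_radius = escape_region_radius,
    cues = list(
      cue_spec("Near", cue_radius * heading_unit(45),
               salience = unname(saliences["Near"]),
               brightness_label = "NE light"),
      cue_spec("Far", cue_radius * heading_unit(315),
               salience = unname(saliences["Far"]),
               brightness_label = "NW light")
    ),
    trial_duration = 60,
    trials_per_day = 4,
    n_days = 10,
    start_positions = c("N", "S", "E", "W"),
    probe_start = "SW"
  )
}

#' Quadrant and escape-region membership of a point
#'
#' Quadrants partition the pool into four equal sectors by the bearing of the
#' point from the pool centre, using half-open intervals: `[0, 90)` = NE,
#' `[90, 180)` = SE, `[180, 270)` = SW, `[270, 360)` = NW. The pool centre
#' (bearing 0 by convention) falls in NE; the tie rule is deterministic.
#'
#' @param point Numeric length-2 `(x, y)` in cm; must lie inside the pool.
#' @param arena An `arena_config`.
#' @return A list with `quadrant` (one of `"NE"`, `"SE"`, `"SW"`, `"NW"`) and
#'   `in_escape_region` (logical: within `escape_region_radius` of the
#'   platform centre).
#' @export
region_membership <- function(point, arena) {
  stopifnot(inherits(arena, "arena_config"),
            is.numeric(point), length(point) == 2L)
  if (sqrt(sum(point^2)) > arena$pool_radius + 1e-9) {
    stop("point lies outside the pool", call. = FALSE)
  }
  list(
    quadrant = quadrant_of(point[1], point[2]),
    in_escape_region =
      sqrt(sum((point - arena$platform_center)^2)) <= arena$escape_region_radius
  )
}

# Vectorised quadrant classification (no pool check); used by occupancy code.
quadrant_of <- function(x, y) {
  b <- bearing_from_centre(x, y)
  c("NE", "SE", "SW", "NW")[findInterval(b, c(0, 90, 180, 270))]
}

#' Rim coordinates of a compass start position
#'
#' @param label Compass label (`"N"`, `"NE"`, ..., `"NW"`).
#' @param arena An `arena_config`.
#' @return Numeric length-2 `(x, y)` on the pool rim.
#' @export
start_position <- function(label, arena) {
  if (!label %in% names(COMPASS_BEARINGS)) {
    stop("unknown compass label: ", label, call. = FALSE)
  }
  arena$pool_radius * heading_unit(COMPASS_BEARINGS[[label]])
}

#' True polar offset from a cue to the platform
#'
#' The cue-to-platform vector in polar form `(r, phi)`: `r` is the distance
#' in cm, `phi` the bearing in degrees. Adding this offset back to the cue
#' position reproduces the platform centre exactly; it is the distribution
#' centre around which learned distance/direction guesses scatter.
#'
#' @param arena An `arena_config`.
#' @param cue_id Cue identifier present in `arena$cues`.
#' @return Named numeric vector `c(r = , phi = )`.
#' @export
cue_platform_offset <- function(arena, cue_id) {
  cue <- arena$cues[[cue_id]]
  if (is.null(cue)) stop("unknown cue: ", cue_id, call. = FALSE)
  d <- arena$platform_center - cue$position
  c(r = sqrt(sum(d^2)), phi = wrap_angle(atan2(d[1], d[2]) / DEG2RAD))
}

#' Saliences of all cues in an arena
#'
#' @param arena An `arena_config`.
#' @return Named numeric vector of per-cue saliences.
#' @export
arena_saliences <- function(arena) {
  vapply(arena$cues, function(cue) cue$salience, numeric(1))
}

#' @export
print.arena_config <- function(x, ...) {
  cat("Water-maze arena\n")
  cat(sprintf("  pool radius: %.1f cm; platform: (%.1f, %.1f) r = %.1f cm\n",
              x$pool_radius, x$platform_center[1], x$platform_center[2],
              x$platform_radius))
  for (cue in x$cues) {
    cat(sprintf("  cue %-5s at (%6.1f, %6.1f) cm, salience %.2f %s\n",
                cue$cue_id, cue$position[1], cue$position[2], cue$salience,
                if (nzchar(cue$brightness_label))
                  paste0("[", cue$brightness_label, "]") else ""))
  }
  cat(sprintf("  protocol: %d x %d s trials/day, %d days, starts %s, probe %s\n",
              x$trials_per_day, x$trial_duration, x$n_days,
              paste(x$start_positions, collapse = "/"), x$probe_start))
  invisible(x)
}
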