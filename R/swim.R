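# Directed random walk with AR(2) heading dynamics and proportional feedback
# control of the heading error. Per sampling interval dt:
#
#   x_t = x_{t-dt} + dr_t * sin(a_t)         dr_t ~ Rayleigh(scale)
#   y_t = y_{t-dt} + dr_t * cos(a_t)
#   a_t = a_{t-dt} + da_t
#   da_t = A1 * da_{t-dt} + A2 * da_{t-2dt} + u_t
#   u_t  = K * ehat_t + nu_t                 nu_t ~ N(0, noise_std^2)
#   ehat_t = (1 - F) * ehat_{t-dt} + F * wrap(a_desired - a_{t-dt})
#
# With no goal (random swimming) the controller is disengaged: ehat is held
# at 0 so u_t reduces to the noise term.

#' Parameters of the swimming model
#'
#' Defaults are calibrated so that (a) an uninformed swim is a meandering
#' random walk that covers the pool within a 60 s trial and rarely finds the
#' 4.5 cm platform by chance, and (b) a fully informed swim started on the
#' rim reaches the platform in roughly 5--10 s. See the package vignette for
#' the calibration procedure.
#'
#' @param A1,A2 Autoregressive coefficients weighting the two previous
#'   heading changes.
#' @param K Proportional feedback gain applied to the filtered heading error.
#' @param F Low-pass filter weight in `[0, 1]`; `F = 1` uses the raw error,
#'   `F = 0` freezes the estimate.
#' @param rayleigh_scale Scale (cm) of the Rayleigh step-length distribution;
#'   mean step is `rayleigh_scale * sqrt(pi / 2)`.
#' @param noise_std Standard deviation (degrees) of the heading-change
#'   noise nu_t.
#' @param dt Sampling time (s) of one step.
#' @param n_steps Steps per behavioural episode (random swimming or
#'   cue approach) before the strategy loop re-evaluates.
#' @param goal_tolerance Distance (cm) to an inferred platform location at
#'   which a goal-approach episode is considered complete.
#' @param contact_margin Body half-width (cm) added to the platform radius
#'   in the escape test: the swimmer escapes when its path passes within
#'   `platform_radius + contact_margin` of the platform centre, i.e. when
#'   its body, not its centroid, encounters the platform.
#' @param goal_step_factor Goal-approach episodes are abandoned after
#'   `goal_step_factor * n_steps` steps.
#' @param boundary Either `"clamp"` (a step that would exit the pool is
#'   radially clamped to the wall, heading preserved) or `"reflect"`
#'   (position reflected at the wall).
#' @param guess_in_pool If `TRUE` (default), the navigator redraws an
#'   inferred platform location that falls outside the pool before swimming
#'   to it: the animal knows the platform stands in the water, so an
#'   inference beyond the wall is implausible and is replaced. The raw
#'   inference distribution returned by [infer_platform()] is unaffected.
#' @param random_mode Behaviour when no cue is selected: `"disengaged"`
#'   (default; the error filter is held at zero, so heading changes are pure
#'   AR noise) or `"north"` (the controller literally steers towards
#'   bearing 0).
#' @return An object of class `swim_params`.
#' @export
swim_params <- function(A1 = 0.15,
                        A2 = 0.05,
                        K = 1.0,
                        F = 0.8,
                        rayleigh_scale = 0.9255,
                        noise_std = 8,
                        dt = 0.05,
                        n_steps = 7,
                        goal_tolerance = 5,
                        goal_step_factor = 24,
                        contact_margin = 7,
                        guess_in_pool = TRUE,
                        boundary = c("clamp", "reflect"),
                        random_mode = c("disengaged", "north")) {
  boundary <- match.arg(boundary)
  random_mode <- match.arg(random_mode)
  if (!is.numeric(F) || F < 0 || F > 1) {
    stop("filter weight F must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(rayleigh_scale) || rayleigh_scale <= 0) {
    stop("rayleigh_scale must be positive", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  stopifnot(noise_std >= 0, n_steps >= 1, goal_tolerance > 0,
            goal_step_factor >= 1, contact_margin >= 0)
  structure(
    list(A1 = A1, A2 = A2, K = K, F = F,
         rayleigh_scale = rayleigh_scale, noise_std = noise_std,
         dt = dt, n_steps = as.integer(n_steps),
         goal_tolerance = goal_tolerance,
         goal_step_factor = goal_step_factor,
         contact_margin = contact_margin,
         guess_in_pool = isTRUE(guess_in_pool),
         boundary = boundary, random_mode = random_mode),
    class = "swim_params"
  )
}

#' Instantaneous state of the swimmer
#'
#' @param position Numeric length-2 `(x, y)` in cm.
#' @param heading Heading in degrees clockwise from North.
#' @param dalpha1,dalpha2 The two previous heading changes (degrees).
#' @param ehat Current filtered heading-error estimate (degrees).
#' @return An object of class `swim_state`.
#' @export
swim_state <- function(position, heading = 0, dalpha1 = 0, dalpha2 = 0,
                       ehat = 0) {
  stopifnot(is.numeric(position), length(position) == 2L)
  structure(
    list(position = as.numeric(position), heading = heading,
         dalpha1 = dalpha1, dalpha2 = dalpha2, ehat = ehat),
    class = "swim_state"
  )
}

#' Draw Rayleigh-distributed step lengths
#'
#' @param params A `swim_params`.
#' @param n Number of draws.
#' @return Non-negative step lengths in cm.
#' @export
draw_step_size <- function(params, n = 1) {
  if (params$rayleigh_scale <= 0) {
    stop("rayleigh_scale must be positive", call. = FALSE)
  }
  params$rayleigh_scale * sqrt(-2 * log(stats::runif(n)))
}

#' One update of the heading-error low-pass filter
#'
#' `ehat_new = (1 - F) * ehat + F * wrap(a_desired - heading)`, with the raw
#' error wrapped into `(-180, 180]` so the filter always tracks the short
#' way round.
#'
#' @param state A `swim_state`.
#' @param desired_heading Desired heading in degrees.
#' @param params A `swim_params`.
#' @return The updated filtered error (degrees).
#' @export
update_error_filter <- function(state, desired_heading, params) {
  (1 - params$F) * state$ehat +
    params$F * wrap_angle(desired_heading - state$heading)
}

#' Control input for one step
#'
#' `u_t = K * ehat + nu_t`, with `nu_t` a zero-mean normal draw of standard
#' deviation `noise_std`.
#'
#' @param state A `swim_state` (only `ehat` is used).
#' @param params A `swim_params`.
#' @return Heading-change control input in degrees.
#' @export
control_input <- function(state, params) {
  params$K * state$ehat + stats::rnorm(1, 0, params$noise_std)
}

#' Advance the swimmer by one step
#'
#' Applies, in order: the error-filter update (or disengagement if
#' `desired_heading` is `NULL`), the control input, the AR(2) heading-change
#' recursion, the position update, and the pool-boundary rule.
#'
#' @param state A `swim_state`.
#' @param desired_heading Desired heading in degrees, or `NULL` for
#'   undirected swimming.
#' @param params A `swim_params`.
#' @param arena An `arena_config` (for the pool boundary).
#' @return The updated `swim_state`.
#' @export
swim_step <- function(state, desired_heading, params, arena) {
  if (is.null(desired_heading)) {
    if (params$random_mode == "north") {
      ehat <- update_error_filter(state, 0, params)
    } else {
      ehat <- 0
    }
  } else {
    ehat <- update_error_filter(state, desired_heading, params)
  }
  u <- params$K * ehat + stats::rnorm(1, 0, params$noise_std)
  dalpha <- params$A1 * state$dalpha1 + params$A2 * state$dalpha2 + u
  heading <- wrap_angle(state$heading + dalpha)
  dr <- draw_step_size(params, 1)
  pos <- state$position + dr * heading_unit(heading)
  pos <- apply_boundary(pos, arena$pool_radius, params$boundary)
  swim_state(pos, heading, dalpha1 = dalpha, dalpha2 = state$dalpha1,
             ehat = ehat)
}

# Keep a position inside the pool. "clamp": scale the radius back to the
# wall; "reflect": fold the excess radius back inside.
apply_boundary <- function(pos, pool_radius, boundary) {
  r <- sqrt(sum(pos^2))
  if (r <= pool_radius) return(pos)
  if (boundary == "clamp") {
    pos * (pool_radius / r)
  } else {
    pos * ((2 * pool_radius - r) / r)
  }
}

#' @export
print.swim_params <- function(x, ...) {
  cat("Swim model parameters\n")
  cat(sprintf("  AR: A1 = %.2f, A2 = %.2f; control: K = %.2f, F = %.2f\n",
              x$A1, x$A2, x$K, x$F))
  cat(sprintf("  step: Rayleigh scale %.1f cm, noise sd %.1f deg, dt %.2f s\n",
              x$rayleigh_scale, x$noise_std, x$dt))
  cat(sprintf("  episodes: %d steps; goal tolerance %.1f cm (budget x%g); %s wall, %s when cueless\n",
              x$n_steps, x$goal_tolerance, x$goal_step_factor, x$boundary,
              x$random_mode))
  invisible(x)
}
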