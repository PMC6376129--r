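# From learned strengths to platform guesses. The uncertainty about a cue's
# vector information is the complement of its associative strength
# (sigma = 1 - V); guesses scatter around the true cue-to-platform polar
# offset with normally distributed errors whose standard deviations are
# 200 * sigma_dist (cm) and 75 * sigma_dir (degrees).

DIST_ERROR_SCALE <- 200 # cm of distance-error sd at full uncertainty
DIR_ERROR_SCALE <- 75   # degrees of direction-error sd at full uncertainty

#' Uncertainty of a cue's learned vector information
#'
#' `sigma_dist = 1 - V_dist` and `sigma_dir = 1 - V_dir` for the selected
#' cue: a fully learned channel has zero uncertainty, an unlearned one has
#' uncertainty one.
#'
#' @param state A `learning_state`.
#' @param cue_id Cue identifier present in the state.
#' @return Named numeric vector `c(sigma_dist = , sigma_dir = )`.
#' @export
uncertainties <- function(state, cue_id) {
  if (!cue_id %in% names(state$V_dist)) {
    stop("cue '", cue_id, "' not present in learning state", call. = FALSE)
  }
  c(sigma_dist = unname(1 - state$V_dist[[cue_id]]),
    sigma_dir = unname(1 - state$V_dir[[cue_id]]))
}

#' Sample platform-guess errors
#'
#' Draws `eps_dist ~ N(0, (200 * sigma_dist)^2)` in cm and
#' `eps_dir ~ N(0, (75 * sigma_dir)^2)` in degrees. The multipliers scale the
#' standard deviation, so the sampled error sd grows linearly in the
#' uncertainty with slopes 200 cm and 75 degrees.
#'
#' @param sigma_dist,sigma_dir Uncertainties in `[0, 1]`.
#' @param n Number of draws.
#' @return A data.frame with columns `eps_dist` (cm) and `eps_dir` (degrees).
#' @export
sample_errors <- function(sigma_dist, sigma_dir, n = 1) {
  stopifnot(sigma_dist >= 0, sigma_dist <= 1, sigma_dir >= 0, sigma_dir <= 1)
  data.frame(
    eps_dist = stats::rnorm(n, 0, DIST_ERROR_SCALE * sigma_dist),
    eps_dir = stats::rnorm(n, 0, DIR_ERROR_SCALE * sigma_dir)
  )
}

#' Infer platform locations from one cue
#'
#' Each guess is the cue (anchor) position plus the learned polar offset
#' perturbed by sampled errors: `(r + eps_dist, phi + eps_dir)`. A negative
#' perturbed radius is by default reflected through the anchor
#' (`|r + eps|` with the bearing flipped by 180 degrees), keeping the polar
#' map total; `negative_radius = "truncate"` clips the radius at zero
#' instead. Guesses may fall outside the pool: they act as target headings
#' for the swimmer, not as positions, and the pool wall constrains the swim
#' itself.
#'
#' @param state A `learning_state`.
#' @param cue_id Identifier of the cue whose learned offsets are used.
#' @param arena An `arena_config` (supplies the true cue-to-platform offset).
#' @param n Number of guesses to draw.
#' @param anchor_cue Optional id of the cue at whose physical position the
#'   learned offset is applied; defaults to the learned cue itself.
#'   Learned vectors live in a cue-centred frame (the offset bearing is
#'   carried relative to the cue's bearing around the pool), so anchoring
#'   cue `j`'s relationship at another cue rotates the inferred location by
#'   the cues' angular separation -- this is what displaces the search when
#'   a presented cue is mistaken for a different learned one.
#' @param negative_radius `"reflect"` (default) or `"truncate"`.
#' @return A data.frame with one row per guess: `x`, `y`, `source_cue`,
#'   `eps_dist`, `eps_dir`.
#' @export
infer_platform <- function(state, cue_id, arena, n = 1, anchor_cue = NULL,
                           negative_radius = c("reflect", "truncate")) {
  negative_radius <- match.arg(negative_radius)
  offset <- cue_platform_offset(arena, cue_id)
  phi <- offset[["phi"]]
  if (is.null(anchor_cue)) anchor_cue <- cue_id
  anchor <- arena$cues[[anchor_cue]]$position
  if (!identical(anchor_cue, cue_id)) {
    cue_pos <- arena$cues[[cue_id]]$position
    phi <- phi + bearing_from_centre(anchor[1], anchor[2]) -
      bearing_from_centre(cue_pos[1], cue_pos[2])
  }
  sig <- uncertainties(state, cue_id)
  err <- sample_errors(sig[["sigma_dist"]], sig[["sigma_dir"]], n)
  guess_from_offset(anchor, offset[["r"]], phi,
                    err$eps_dist, err$eps_dir, cue_id, negative_radius)
}

# Vectorised polar-offset guess construction shared with the navigator.
guess_from_offset <- function(anchor, r, phi, eps_dist, eps_dir, cue_id,
                              negative_radius = "reflect") {
  radius <- r + eps_dist
  angle <- phi + eps_dir
  neg <- radius < 0
  if (any(neg)) {
    if (negative_radius == "reflect") {
      radius[neg] <- -radius[neg]
      angle[neg] <- angle[neg] + 180
    } else {
      radius[neg] <- 0
    }
  }
  rad <- angle * DEG2RAD
  data.frame(
    x = anchor[1] + radius * sin(rad),
    y = anchor[2] + radius * cos(rad),
    source_cue = cue_id,
    eps_dist = eps_dist,
    eps_dir = eps_dir
  )
}

#' Density of inferred platform locations over the arena
#'
#' Pools guesses across cues in proportion to their usage strengths and bins
#' them on a square grid spanning the arena; the returned density is
#' normalised to sum to one over the bins (guesses falling outside the grid
#' are discarded before normalisation).
#'
#' @param state A `learning_state`; at least one cue must have positive
#'   `V_use`.
#' @param arena An `arena_config`.
#' @param n_samples Number of guesses to pool.
#' @param bins Number of grid cells per axis.
#' @param pad Grid half-width as a multiple of the pool radius.
#' @return A list with `density` (a `bins x bins` matrix, x varying over
#'   rows), `breaks_x`, `breaks_y`, and `guesses` (the sampled data.frame).
#' @export
guess_heatmap <- function(state, arena, n_samples, bins = 25, pad = 1.2) {
  stopifnot(n_samples >= 1)
  w <- state$V_use
  if (sum(w) <= 0) {
    stop("guess_heatmap needs at least one cue with positive V_use",
         call. = FALSE)
  }
  counts <- stats::rmultinom(1, n_samples, w / sum(w))[, 1]
  guesses <- do.call(rbind, lapply(names(w)[counts > 0], function(id) {
    infer_platform(state, id, arena, n = counts[[id]])
  }))
  lim <- pad * arena$pool_radius
  breaks <- seq(-lim, lim, length.out = bins + 1L)
  keep <- guesses$x >= -lim & guesses$x <= lim &
    guesses$y >= -lim & guesses$y <= lim
  gx <- cut(guesses$x[keep], breaks, include.lowest = TRUE, labels = FALSE)
  gy <- cut(guesses$y[keep], breaks, include.lowest = TRUE, labels = FALSE)
  dens <- matrix(0, bins, bins)
  if (any(keep)) {
    tab <- table(factor(gx, levels = seq_len(bins)),
                 factor(gy, levels = seq_len(bins)))
    dens <- matrix(as.numeric(tab), bins, bins)
    if (sum(dens) > 0) dens <- dens / sum(dens)
  }
  list(density = dens, breaks_x = breaks, breaks_y = breaks, guesses = guesses)
}

#' Fraction of guesses landing in the target (NE) pool quadrant
#'
#' A concentration measure for guess clouds: the share of guesses that fall
#' both inside the pool and in the quadrant containing the platform.
#'
#' @param guesses Data.frame with `x`, `y` columns.
#' @param arena An `arena_config`.
#' @param quadrant Target quadrant label (default the platform's).
#' @return A single fraction in `[0, 1]`.
#' @export
guess_fraction_in_quadrant <- function(guesses, arena, quadrant = NULL) {
  if (is.null(quadrant)) {
    quadrant <- quadrant_of(arena$platform_center[1], arena$platform_center[2])
  }
  inside <- sqrt(guesses$x^2 + guesses$y^2) <= arena$pool_radius
  mean(inside & quadrant_of(guesses$x, guesses$y) == quadrant)
}
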