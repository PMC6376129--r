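# The strategy loop binding learning, inference and swimming:
#   1. Pick a cue: cue i with probability V_i,use, no cue with probability
#      1 - sum(V_use) (mutually exclusive draw).
#   2. No cue selected -> swim randomly for n_steps, then return to 1.
#   3. Cue selected -> swim towards it for n_steps (desired heading
#      recomputed from the current position every step).
#   4. Swim to a freshly inferred platform location until within
#      goal_tolerance or the episode budget runs out.
#   5. Return to 1.
# The trial ends at platform contact (centre-to-centre distance within the
# platform radius) or at the trial duration.

#' Cue-interpretation policy for retention scenarios
#'
#' Governs how a presented cue is mapped onto a learned cue-platform
#' relationship when the simulated animal re-encounters the (possibly
#' manipulated) cue array:
#'
#' * `identity` -- each presented cue is engaged with probability equal to
#'   its own usage strength and interpreted as itself (the animal fully
#'   discriminates the cues).
#' * `indistinguishable` -- the cues cannot be told apart. With the full
#'   training array present the configuration disambiguates them and the
#'   policy reduces to `identity`; with a partial array the animal engages
#'   with probability `sum(V_use)` and assigns one of the learned
#'   relationships to the available cue at random, with probabilities
#'   proportional to the usage strengths, re-drawn every swimming episode.
#' * `generalize_to_salient` -- same machinery as `indistinguishable`; at
#'   extreme salience splits (1:0) the usage strengths degenerate so the
#'   relationship of the dominant cue is always applied, and at 50:50 it
#'   coincides with `indistinguishable`.
#' * `probabilistic_misinterpretation` -- the animal recognises the cues
#'   (engages with probability `sum(V_use)`) but, when presented with the
#'   designated `confusable_cue`, applies the other cue's relationship with
#'   probability `misinterpretation_probability` and its own otherwise.
#'
#' In every non-identity mode the learned relationship is anchored at the
#' PRESENTED cue's physical position: treating a Near cue as the Far one
#' displaces the search by the Far cue's learned vector applied at the Near
#' cue's location.
#'
#' @param mode One of `"identity"`, `"indistinguishable"`,
#'   `"generalize_to_salient"`, `"probabilistic_misinterpretation"`.
#' @param misinterpretation_probability Probability in `[0, 1]` (used only
#'   by the last mode).
#' @param confusable_cue Identifier of the cue subject to misinterpretation.
#' @return An object of class `interpretation_policy`.
#' @export
interpretation_policy <- function(mode = c("identity", "indistinguishable",
                                           "generalize_to_salient",
                                           "probabilistic_misinterpretation"),
                                  misinterpretation_probability = 0,
                                  confusable_cue = NULL) {
  mode <- match.arg(mode)
  if (misinterpretation_probability < 0 || misinterpretation_probability > 1) {
    stop("misinterpretation_probability must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "probabilistic_misinterpretation" && is.null(confusable_cue)) {
    stop("probabilistic_misinterpretation needs a confusable_cue",
         call. = FALSE)
  }
  structure(
    list(mode = mode,
         misinterpretation_probability = misinterpretation_probability,
         confusable_cue = confusable_cue),
    class = "interpretation_policy"
  )
}

#' Select a cue for the next swimming episode
#'
#' A single mutually exclusive draw: cue `i` is selected with probability
#' `V_i,use`, and no cue with probability `1 - sum(V_use)`.
#'
#' @param state A `learning_state` with `sum(V_use) <= 1`.
#' @param presented Character vector of cue ids available to be selected
#'   (defaults to all cues in the state).
#' @return A cue id, or `NA_character_` if no cue is selected.
#' @export
select_cue <- function(state, presented = names(state$V_use)) {
  v <- state$V_use
  if (sum(v) > 1 + 1e-9) {
    stop("invalid learning state: sum(V_use) exceeds 1", call. = FALSE)
  }
  p <- v[presented]
  u <- stats::runif(1)
  cum <- cumsum(p)
  hit <- which(u <= cum)
  if (length(hit) == 0L) NA_character_ else presented[hit[1L]]
}

# Episode-level engagement/interpretation draw. Returns list(engaged,
# anchor, interp). `anchor` is a presented cue id; `interp` the learned
# relationship applied there.
choose_episode <- function(state, presented, policy, forced_cue) {
  if (!is.null(forced_cue)) {
    return(list(engaged = TRUE, anchor = forced_cue, interp = forced_cue))
  }
  all_ids <- names(state$V_use)
  v <- state$V_use
  total <- sum(v)
  mode <- policy$mode
  if (mode %in% c("indistinguishable", "generalize_to_salient") &&
      setequal(presented, all_ids)) {
    mode <- "identity" # full array: the configuration disambiguates the cues
  }
  if (mode == "identity") {
    sel <- select_cue(state, presented)
    if (is.na(sel)) return(list(engaged = FALSE))
    return(list(engaged = TRUE, anchor = sel, interp = sel))
  }
  # remaining modes: engage with probability sum(V_use), capped at 1
  if (stats::runif(1) > min(1, total)) return(list(engaged = FALSE))
  anchor <- if (length(presented) == 1L) {
    presented
  } else if (sum(v[presented]) > 0) {
    presented[sample.int(length(presented), 1L, prob = v[presented])]
  } else {
    presented[sample.int(length(presented), 1L)]
  }
  interp <- switch(
    mode,
    indistinguishable = ,
    generalize_to_salient = {
      if (total > 0) all_ids[sample.int(length(all_ids), 1L, prob = v)]
      else anchor
    },
    probabilistic_misinterpretation = {
      if (identical(anchor, policy$confusable_cue) &&
          stats::runif(1) < policy$misinterpretation_probability) {
        others <- setdiff(all_ids, anchor)
        if (sum(v[others]) > 0) {
          others[sample.int(length(others), 1L, prob = v[others])]
        } else {
          others[sample.int(length(others), 1L)]
        }
      } else {
        anchor
      }
    }
  )
  list(engaged = TRUE, anchor = anchor, interp = interp)
}

#' Simulate one water-maze trial
#'
#' Runs the full strategy loop for a single trial. Episodes are logged with
#' their kind (`random`, `cue`, `goal`), the presented cue engaged, the
#' learned relationship applied, and the platform guess steered towards; a
#' fresh guess is drawn for every goal-approach episode.
#'
#' @param learning A `learning_state`.
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param start Compass label on the rim, or a numeric `(x, y)` position.
#' @param platform_present If `FALSE` (probe trial), the trial always runs
#'   to `trial_duration` and latency is `NA`.
#' @param interpretation An [interpretation_policy()].
#' @param presented_cues Cue ids physically present during the trial.
#' @param forced_cue If non-`NULL`, this cue is engaged every episode
#'   regardless of usage strengths (used to dissect single-cue strategies).
#' @param record_trajectory If `FALSE`, skip building the trajectory and
#'   episode data.frames (faster for large cohorts).
#' @return An object of class `trial_record`: a list with `latency` (s; the
#'   trial duration if censored, `NA` on probe trials), `censored`,
#'   `escaped`, `time_swum` (s), `start`, and -- when recorded --
#'   `trajectory` (t, x, y, heading, episode, kind) and `episodes`.
#' @export
simulate_trial <- function(learning, arena, swim, start,
                           platform_present = TRUE,
                           interpretation = interpretation_policy("identity"),
                           presented_cues = names(arena$cues),
                           forced_cue = NULL,
                           record_trajectory = TRUE) {
  stopifnot(inherits(learning, "learning_state"),
            inherits(arena, "arena_config"), inherits(swim, "swim_params"))
  if (!all(presented_cues %in% names(arena$cues))) {
    stop("presented_cues must name cues in the arena", call. = FALSE)
  }

  pos0 <- if (is.character(start)) start_position(start, arena) else
    as.numeric(start)
  start_label <- if (is.character(start)) start else NA_character_

  n_total <- as.integer(round(arena$trial_duration / swim$dt))
  # per-cue lookups
  ids <- names(learning$V_use)
  cue_x <- vapply(ids, function(i) arena$cues[[i]]$position[1], numeric(1))
  cue_y <- vapply(ids, function(i) arena$cues[[i]]$position[2], numeric(1))
  off <- vapply(ids, function(i) cue_platform_offset(arena, i), numeric(2))
  cue_bearing <- vapply(ids, function(i) bearing_from_centre(cue_x[[i]],
                                                             cue_y[[i]]),
                        numeric(1))
  sig_dist <- 1 - learning$V_dist
  sig_dir <- 1 - learning$V_dir

  # scalar swim state
  x <- pos0[1]; y <- pos0[2]
  hd <- bearing_to(pos0, c(0, 0)) # released facing the pool centre
  da1 <- 0; da2 <- 0; ehat <- 0
  A1 <- swim$A1; A2 <- swim$A2; K <- swim$K; Fw <- swim$F
  scale <- swim$rayleigh_scale; nsd <- swim$noise_std
  north_mode <- swim$random_mode == "north"
  reflect_wall <- swim$boundary == "reflect"
  R <- arena$pool_radius
  px <- arena$platform_center[1]; py <- arena$platform_center[2]
  pr2 <- (arena$platform_radius + swim$contact_margin)^2
  tol2 <- swim$goal_tolerance^2
  wall2 <- (R - 1e-9)^2
  goal_budget <- as.integer(swim$goal_step_factor * swim$n_steps)
  goal_outside <- FALSE
  guess_tries <- if (isTRUE(swim$guess_in_pool)) 100L else 1L

  # trajectory buffers
  tx <- numeric(n_total); ty <- numeric(n_total); th <- numeric(n_total)
  tep <- integer(n_total); tkd <- integer(n_total) # 1 random, 2 cue, 3 goal
  ep_kind <- character(0); ep_anchor <- character(0); ep_interp <- character(0)
  ep_gx <- numeric(0); ep_gy <- numeric(0)

  escaped <- platform_present && (x - px)^2 + (y - py)^2 <= pr2
  xp <- x; yp <- y # previous position for segment-based contact
  step_i <- 0L
  mode <- 0L # 0 none, 1 random, 2 cue, 3 goal
  steps_left <- 0L
  gx <- 0; gy <- 0 # current target (cue position or guess)
  cur_anchor <- NA_character_; cur_interp <- NA_character_
  episode_i <- 0L

  while (step_i < n_total && !escaped) {
    if (steps_left <= 0L) {
      if (mode == 2L) {
        # cue approach complete: infer a platform location and head there.
        # Inferences falling outside the pool are implausible to the animal
        # (the platform is in the water) and are redrawn.
        j <- cur_interp
        ax <- cue_x[[cur_anchor]]; ay <- cue_y[[cur_anchor]]
        # learned vectors are carried in a cue-centred frame: applying cue
        # j's relationship at another cue's position rotates the offset by
        # the cues' angular separation around the pool
        base_ang <- off["phi", j] + cue_bearing[[cur_anchor]] - cue_bearing[[j]]
        for (try in seq_len(guess_tries)) {
          ed <- stats::rnorm(1, 0, 200 * sig_dist[[j]])
          ea <- stats::rnorm(1, 0, 75 * sig_dir[[j]])
          radius <- off["r", j] + ed
          ang <- base_ang + ea
          if (radius < 0) { radius <- -radius; ang <- ang + 180 }
          gx <- ax + radius * sin(ang * DEG2RAD)
          gy <- ay + radius * cos(ang * DEG2RAD)
          goal_outside <- gx * gx + gy * gy > R * R
          if (!goal_outside) break
        }
        mode <- 3L
        steps_left <- goal_budget
        episode_i <- episode_i + 1L
        ep_kind <- c(ep_kind, "goal")
        ep_anchor <- c(ep_anchor, cur_anchor)
        ep_interp <- c(ep_interp, cur_interp)
        ep_gx <- c(ep_gx, gx); ep_gy <- c(ep_gy, gy)
      } else {
        ep <- choose_episode(learning, presented_cues, interpretation,
                             forced_cue)
        episode_i <- episode_i + 1L
        if (!ep$engaged) {
          mode <- 1L
          steps_left <- swim$n_steps
          cur_anchor <- NA_character_; cur_interp <- NA_character_
          ep_kind <- c(ep_kind, "random")
          ep_anchor <- c(ep_anchor, NA_character_)
          ep_interp <- c(ep_interp, NA_character_)
          ep_gx <- c(ep_gx, NA_real_); ep_gy <- c(ep_gy, NA_real_)
        } else {
          mode <- 2L
          steps_left <- swim$n_steps
          cur_anchor <- ep$anchor; cur_interp <- ep$interp
          gx <- cue_x[[cur_anchor]]; gy <- cue_y[[cur_anchor]]
          ep_kind <- c(ep_kind, "cue")
          ep_anchor <- c(ep_anchor, cur_anchor)
          ep_interp <- c(ep_interp, cur_interp)
          ep_gx <- c(ep_gx, NA_real_); ep_gy <- c(ep_gy, NA_real_)
        }
      }
    }

    # error filter + control (same update order as swim_step)
    if (mode == 1L) {
      if (north_mode) {
        ehat <- (1 - Fw) * ehat + Fw * wrap_angle(-hd)
      } else {
        ehat <- 0
      }
    } else {
      desired <- atan2(gx - x, gy - y) / DEG2RAD
      ehat <- (1 - Fw) * ehat + Fw * wrap_angle(desired - hd)
    }
    u <- K * ehat + stats::rnorm(1, 0, nsd)
    da <- A1 * da1 + A2 * da2 + u
    hd <- wrap_angle(hd + da)
    dr <- scale * sqrt(-2 * log(stats::runif(1)))
    x <- x + dr * sin(hd * DEG2RAD)
    y <- y + dr * cos(hd * DEG2RAD)
    rr2 <- x * x + y * y
    if (rr2 > R * R) {
      rr <- sqrt(rr2)
      f <- if (reflect_wall) (2 * R - rr) / rr else R / rr
      x <- x * f; y <- y * f
    }
    da2 <- da1; da1 <- da
    step_i <- step_i + 1L
    tx[step_i] <- x; ty[step_i] <- y; th[step_i] <- hd
    tep[step_i] <- episode_i; tkd[step_i] <- mode
    steps_left <- steps_left - 1L

    if (platform_present) {
      # contact if the swum segment passes within the platform radius:
      # the path is continuous, so escape cannot be stepped over
      sx <- x - xp; sy <- y - yp
      qx <- px - xp; qy <- py - yp
      len2 <- sx * sx + sy * sy
      tt <- if (len2 > 0) min(1, max(0, (qx * sx + qy * sy) / len2)) else 0
      dx <- qx - tt * sx; dy <- qy - tt * sy
      if (dx * dx + dy * dy <= pr2) escaped <- TRUE
    }
    if (!escaped && mode == 3L) {
      if ((x - gx)^2 + (y - gy)^2 <= tol2) {
        steps_left <- 0L # guess reached: back to cue selection
      } else if (goal_outside && x * x + y * y >= wall2) {
        # guess lies beyond the wall and the wall is reached: the closest
        # feasible approach is attained, so the approach is over
        steps_left <- 0L
      }
    }
    xp <- x; yp <- y
  }

  latency <- if (!platform_present) NA_real_ else if (escaped)
    step_i * swim$dt else arena$trial_duration
  rec <- list(
    latency = latency,
    censored = platform_present && !escaped,
    escaped = escaped,
    time_swum = step_i * swim$dt,
    start = start_label,
    start_position = pos0,
    n_steps_taken = step_i
  )
  if (record_trajectory) {
    keep <- seq_len(step_i)
    rec$trajectory <- data.frame(
      t = keep * swim$dt, x = tx[keep], y = ty[keep], heading = th[keep],
      episode = tep[keep],
      kind = c("random", "cue", "goal")[tkd[keep]]
    )
    rec$episodes <- data.frame(
      episode = seq_along(ep_kind), kind = ep_kind, anchor_cue = ep_anchor,
      interpreted_cue = ep_interp, guess_x = ep_gx, guess_y = ep_gy
    )
  }
  class(rec) <- "trial_record"
  rec
}

#' @export
print.trial_record <- function(x, ...) {
  if (is.na(x$latency)) {
    cat(sprintf("Probe trial: %.1f s swum, %d steps\n", x$time_swum,
                x$n_steps_taken))
  } else {
    cat(sprintf("Trial: latency %.1f s%s (%d steps)\n", x$latency,
                if (x$censored) " [censored]" else "", x$n_steps_taken))
  }
  invisible(x)
}

#' Simulate an acquisition experiment
#'
#' Runs the full training protocol for a cohort. The learning recursion is
#' trial-level and independent of the swim, so the associative-state
#' trajectory is computed once ([run_training()]) and each simulated rat
#' swims its trials under the state reached before that trial. Start
#' positions are permuted pseudorandomly within each day, per rat. Each rat
#' draws from its own random stream derived from `(seed, rat index)`, so
#' results for rat `i` do not depend on the cohort size.
#'
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param learning_params A `learning_params`.
#' @param n_rats Cohort size.
#' @param seed Master seed (integer).
#' @param saliences Optional named salience vector overriding the arena's.
#' @return A list with `latencies` (data.frame: rat, day, trial, start,
#'   latency, censored), `states` (per-trial `learning_state`s), `final_state`
#'   and `history` (the learning trajectory).
#' @export
run_acquisition <- function(arena, swim, learning_params, n_rats, seed,
                            saliences = NULL) {
  stopifnot(n_rats >= 1)
  n_trials <- arena$trials_per_day * arena$n_days
  training <- run_training(arena, learning_params, n_trials, saliences)
  naive <- learning_state(names(arena$cues))
  # state in effect DURING trial k is the state after k-1 trials
  state_before <- c(list(naive), training$states[seq_len(n_trials - 1L)])

  n_per_day <- arena$trials_per_day
  rows_rat <- vector("list", n_rats)
  for (rat in seq_len(n_rats)) {
    set.seed(derive_seed(seed, rat))
    lat <- numeric(n_trials); cen <- logical(n_trials)
    sts <- character(n_trials)
    k <- 0L
    for (day in seq_len(arena$n_days)) {
      starts <- sample(arena$start_positions)
      for (tr in seq_len(n_per_day)) {
        k <- k + 1L
        rec <- simulate_trial(state_before[[k]], arena, swim, starts[tr],
                              record_trajectory = FALSE)
        lat[k] <- rec$latency; cen[k] <- rec$censored; sts[k] <- starts[tr]
      }
    }
    rows_rat[[rat]] <- data.frame(
      rat = rat,
      day = rep(seq_len(arena$n_days), each = n_per_day),
      trial = seq_len(n_trials),
      start = sts, latency = lat, censored = cen
    )
  }
  list(latencies = do.call(rbind, rows_rat),
       states = training$states,
       final_state = training$final,
       history = training$history)
}

#' Simulate a retention (probe) experiment
#'
#' Platform-absent trials of the full trial duration, started from the probe
#' position, under an arbitrary presented-cue set and interpretation policy.
#' No learning occurs during probes.
#'
#' @param learning A trained `learning_state`.
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param n_rats Cohort size.
#' @param seed Master seed.
#' @param presented_cues Cue ids present during the probe.
#' @param interpretation An [interpretation_policy()].
#' @param start Start position label (defaults to the arena's probe start).
#' @return A data.frame with one row per rat: occupancy fractions `NE`,
#'   `SE`, `SW`, `NW`, the fraction `escape_region` of time inside the
#'   platform-area scoring circle, and `time_in_area` (s).
#' @export
run_retention <- function(learning, arena, swim, n_rats, seed,
                          presented_cues = names(arena$cues),
                          interpretation = interpretation_policy("identity"),
                          start = arena$probe_start) {
  stopifnot(n_rats >= 1)
  rows <- vector("list", n_rats)
  for (rat in seq_len(n_rats)) {
    set.seed(derive_seed(seed, rat))
    rec <- simulate_trial(learning, arena, swim, start,
                          platform_present = FALSE,
                          interpretation = interpretation,
                          presented_cues = presented_cues,
                          record_trajectory = TRUE)
    occ <- trajectory_occupancy(rec$trajectory, arena,
                                start_pos = rec$start_position)
    rows[[rat]] <- data.frame(
      rat = rat, NE = occ[["NE"]], SE = occ[["SE"]], SW = occ[["SW"]],
      NW = occ[["NW"]], escape_region = occ[["escape_region"]],
      time_in_area = occ[["escape_region"]] * rec$time_swum
    )
  }
  do.call(rbind, rows)
}
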