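# Rescorla-Wagner learning. Three associative quantities are tracked per cue:
#
#   V_use  -- learning to use the cue. Competitive: the increments share one
#             error term (lambda_use - V_sum), so the cues divide a fixed
#             total capacity according to their saliences.
#   V_dir  -- certainty about the cue-to-platform direction. Independent:
#             each cue's increment uses its own error (lambda_dir - V_i,dir).
#   V_dist -- certainty about the cue-to-platform distance, likewise
#             independent.
#
# Updates are trial-level: after each trial V_new = V_old + delta_V.

#' Rescorla-Wagner learning parameters
#'
#' Defaults place the cue-usage pool and both information channels near
#' asymptote within the standard 40-trial protocol: with two cues of
#' salience 0.5 each and rates of 0.15, total usage reaches 99.8% of
#' capacity and each information channel about 0.95 by trial 40.
#'
#' @param beta_use,beta_dir,beta_dist Learning rates per trial, in `(0, 1]`.
#' @param lambda_use,lambda_dir,lambda_dist Asymptotes, in `(0, 1]`.
#'   `lambda_use` is the total usage capacity shared by all cues;
#'   `lambda_dir`/`lambda_dist` cap each cue's channel independently.
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(beta_use = 0.15, beta_dir = 0.15,
                            beta_dist = 0.15,
                            lambda_use = 1, lambda_dir = 1, lambda_dist = 1) {
  vals <- c(beta_use, beta_dir, beta_dist, lambda_use, lambda_dir, lambda_dist)
  if (any(vals <= 0) || any(vals > 1)) {
    stop("learning rates and asymptotes must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(beta_use = beta_use, beta_dir = beta_dir, beta_dist = beta_dist,
         lambda_use = lambda_use, lambda_dir = lambda_dir,
         lambda_dist = lambda_dist),
    class = "learning_params"
  )
}

#' Per-cue associative strengths
#'
#' @param cue_ids Character vector of cue identifiers.
#' @param V_use,V_dir,V_dist Initial strengths, recycled to the number of
#'   cues. A naive animal starts at zero.
#' @return An object of class `learning_state` holding named vectors
#'   `V_use`, `V_dir`, `V_dist`.
#' @export
learning_state <- function(cue_ids, V_use = 0, V_dir = 0, V_dist = 0) {
  stopifnot(is.character(cue_ids), length(cue_ids) >= 1L)
  mk <- function(v) {
    v <- rep_len(as.numeric(v), length(cue_ids))
    names(v) <- cue_ids
    v
  }
  structure(
    list(V_use = mk(V_use), V_dir = mk(V_dir), V_dist = mk(V_dist)),
    class = "learning_state"
  )
}

#' Competitive cue-usage update (one trial)
#'
#' Every cue's usage strength is incremented by
#' `alpha_i * beta_use * (lambda_use - V_sum)` where `V_sum` is the
#' pre-update total over all cues -- a simultaneous (Jacobi-style) update, so
#' both cues see the same error term. Because the error is shared, the cues
#' compete: once one cue has claimed 70% of the capacity only 30% remains
#' for the other. If an aggressive rate would overshoot the capacity within
#' a single trial, the increments are rescaled proportionally so that
#' `sum(V_use) <= lambda_use` always holds.
#'
#' @param state A `learning_state`.
#' @param saliences Named numeric vector of per-cue saliences in `[0, 1]`;
#'   names must match the state's cues.
#' @param params A `learning_params`.
#' @return The updated `learning_state`.
#' @export
update_use <- function(state, saliences, params) {
  saliences <- match_saliences(state, saliences)
  v_sum <- sum(state$V_use)
  delta <- saliences * params$beta_use * (params$lambda_use - v_sum)
  inc <- sum(delta)
  headroom <- params$lambda_use - v_sum
  if (inc > headroom && inc > 0) delta <- delta * (headroom / inc)
  state$V_use <- state$V_use + delta
  state
}

#' Independent direction/distance updates (one trial)
#'
#' Each cue's direction and distance strengths relax towards their own
#' asymptote: `delta = alpha_i * beta * (lambda - V_i)`. There is no shared
#' error term, so learning one cue's vector information never affects the
#' other's; both cues can reach 100% simultaneously.
#'
#' @inheritParams update_use
#' @return The updated `learning_state`.
#' @export
update_info <- function(state, saliences, params) {
  saliences <- match_saliences(state, saliences)
  state$V_dir <- state$V_dir +
    saliences * params$beta_dir * (params$lambda_dir - state$V_dir)
  state$V_dist <- state$V_dist +
    saliences * params$beta_dist * (params$lambda_dist - state$V_dist)
  state
}

match_saliences <- function(state, saliences) {
  ids <- names(state$V_use)
  if (is.null(names(saliences))) {
    stopifnot(length(saliences) == length(ids))
    names(saliences) <- ids
  }
  if (!all(ids %in% names(saliences))) {
    stop("saliences must be named for every cue in the state", call. = FALSE)
  }
  if (any(saliences < 0 | saliences > 1)) {
    stop("saliences must lie in [0, 1]", call. = FALSE)
  }
  saliences[ids]
}

#' Run the trial-level learning recursion
#'
#' Applies the competitive usage update followed by the independent
#' information updates once per trial, starting from a naive (all-zero)
#' state unless one is supplied. The recursion is deterministic: it depends
#' only on saliences and parameters, not on the simulated swim.
#'
#' @param arena An `arena_config`; supplies the cue roster and (by default)
#'   the saliences.
#' @param params A `learning_params`.
#' @param n_trials Number of trials (default: the arena's full protocol).
#' @param saliences Optional named salience vector overriding the arena's.
#' @param init Optional initial `learning_state`.
#' @return A list with `final` (the `learning_state` after `n_trials`),
#'   `states` (list of states after each trial) and `history` (a long
#'   data.frame: trial, cue, V_use, V_dir, V_dist; trial 0 is the initial
#'   state).
#' @export
run_training <- function(arena, params, n_trials = NULL, saliences = NULL,
                         init = NULL) {
  stopifnot(inherits(arena, "arena_config"), inherits(params, "learning_params"))
  if (is.null(n_trials)) n_trials <- arena$trials_per_day * arena$n_days
  stopifnot(n_trials >= 0)
  if (is.null(saliences)) saliences <- arena_saliences(arena)
  state <- if (is.null(init)) learning_state(names(arena$cues)) else init
  states <- vector("list", n_trials)
  rows <- vector("list", n_trials + 1L)
  rows[[1L]] <- state_rows(state, 0L)
  if (n_trials > 0) {
    for (trial in seq_len(n_trials)) {
      state <- update_use(state, saliences, params)
      state <- update_info(state, saliences, params)
      states[[trial]] <- state
      rows[[trial + 1L]] <- state_rows(state, trial)
    }
  }
  list(final = state, states = states,
       history = do.call(rbind, rows))
}

state_rows <- function(state, trial) {
  data.frame(trial = trial, cue = names(state$V_use),
             V_use = unname(state$V_use), V_dir = unname(state$V_dir),
             V_dist = unname(state$V_dist), row.names = NULL)
}

#' @export
print.learning_state <- function(x, ...) {
  cat("Associative strengths\n")
  df <- data.frame(cue = names(x$V_use), V_use = round(unname(x$V_use), 4),
                   V_dir = round(unname(x$V_dir), 4),
                   V_dist = round(unname(x$V_dist), 4))
  print(df, row.names = FALSE)
  invisible(x)
}
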