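# Declarative reproductions of the simulation experiments: single-channel
# dissection, salience sweeps, cue-removal retention, cue-uncertainty
# models, and the direct overshadowing design.

#' Bundle the options of a retention scenario
#'
#' A light container pairing training conditions with a probe manipulation,
#' used by [cue_removal_retention()] and the command-line driver.
#'
#' @param name Scenario label.
#' @param training_saliences Named salience vector used during training.
#' @param retention_cues List of presented-cue sets to probe, e.g.
#'   `list(both = c("Near", "Far"), near_only = "Near")`.
#' @param interpretation An [interpretation_policy()].
#' @param n_rats Cohort size per probe condition.
#' @param seed Master seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, training_saliences, retention_cues,
                          interpretation = interpretation_policy("identity"),
                          n_rats = 50, seed = 1) {
  stopifnot(is.character(name), is.list(retention_cues),
            inherits(interpretation, "interpretation_policy"))
  structure(
    list(name = name, training_saliences = training_saliences,
         retention_cues = retention_cues, interpretation = interpretation,
         n_rats = as.integer(n_rats), seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

# Learning state with a single channel of a single cue set to `strength`,
# everything else zero; used to dissect what each channel contributes.
single_channel_state <- function(arena, cue, channel, strength) {
  state <- learning_state(names(arena$cues))
  if (channel == "direction") {
    state$V_dir[cue] <- strength
  } else {
    state$V_dist[cue] <- strength
  }
  state
}

#' Dissect the contribution of one information channel of one cue
#'
#' Simulates a cohort in which the named cue is engaged on every episode and
#' only the named channel carries information (at the given strength; the
#' other channel is fully uncertain). Returns the escape-latency
#' distribution and the corresponding platform-guess cloud.
#'
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param channel `"direction"` or `"distance"`.
#' @param cue Cue id (`"Near"` or `"Far"` in the default arena).
#' @param strength Associative strength of the learned channel in `[0, 1]`.
#' @param n_rats Number of simulated rats (one trial each, start positions
#'   cycling through the acquisition set).
#' @param seed Master seed.
#' @return A list with `latencies` (data.frame: rat, start, latency,
#'   censored), `guesses` (one platform guess per rat) and `summary`
#'   (a [latency_summary()] row).
#' @export
dissect_information <- function(arena, swim,
                                channel = c("direction", "distance"),
                                cue, strength = 0.95, n_rats = 1000,
                                seed = 1) {
  channel <- match.arg(channel)
  stopifnot(strength >= 0, strength <= 1, n_rats >= 1)
  state <- single_channel_state(arena, cue, channel, strength)
  starts <- arena$start_positions
  lat <- numeric(n_rats); cen <- logical(n_rats); st <- character(n_rats)
  for (rat in seq_len(n_rats)) {
    set.seed(derive_seed(seed, rat))
    s <- starts[(rat - 1L) %% length(starts) + 1L]
    rec <- simulate_trial(state, arena, swim, s, forced_cue = cue,
                          record_trajectory = FALSE)
    lat[rat] <- rec$latency; cen[rat] <- rec$censored; st[rat] <- s
  }
  set.seed(derive_seed(seed, n_rats + 1L))
  guesses <- infer_platform(state, cue, arena, n = n_rats)
  list(
    latencies = data.frame(rat = seq_len(n_rats), start = st, latency = lat,
                           censored = cen),
    guesses = guesses,
    summary = cbind(data.frame(cue = cue, channel = channel,
                               strength = strength),
                    latency_summary(lat, cen))
  )
}

#' Sweep cue salience against guess-cloud concentration
#'
#' For every combination of overall salience strength and salience ratio,
#' trains the learning model for the full protocol with per-cue saliences
#' `alpha_i = 2 * strength * ratio_i` (so a 50:50 ratio at strength 0.5
#' gives the default 0.5/0.5 cues), optionally blanks the unused information
#' channel, samples a platform-guess cloud, and scores its concentration.
#'
#' @param arena An `arena_config`.
#' @param learning_params A `learning_params`.
#' @param strengths Numeric vector of salience strengths in `(0, 0.5]`.
#' @param ratios List of length-2 salience shares summing to 1, named by the
#'   cues (e.g. `list(c(Near = 0.5, Far = 0.5))`).
#' @param channels Character subset of `c("direction", "distance")`; both by
#'   default.
#' @param n_samples Guesses per condition.
#' @param seed Master seed.
#' @param n_trials Training trials per condition (default: full protocol).
#' @param bins Heatmap grid resolution.
#' @return A list with `grid` (tidy data.frame: strength, ratio label,
#'   channel set, per-cue saliences, fraction of guesses in the target
#'   quadrant, guess-cloud entropy) and `heatmaps` (per-condition
#'   [guess_heatmap()] results, named by condition).
#' @export
salience_sweep <- function(arena, learning_params,
                           strengths = seq(0.1, 0.5, by = 0.1),
                           ratios = list(c(Near = 0.5, Far = 0.5)),
                           channels = c("direction", "distance"),
                           n_samples = 2000, seed = 1, n_trials = NULL,
                           bins = 25) {
  stopifnot(all(channels %in% c("direction", "distance")),
            length(channels) >= 1L)
  rows <- list(); maps <- list()
  for (ratio in ratios) {
    if (abs(sum(ratio) - 1) > 1e-9) {
      stop("each salience ratio must sum to 1", call. = FALSE)
    }
    ratio_label <- paste0(round(100 * ratio), "%", collapse = ":")
    for (strength in strengths) {
      alphas <- 2 * strength * ratio
      if (any(alphas > 1)) stop("strength too large for ratio", call. = FALSE)
      trained <- run_training(arena, learning_params, n_trials,
                              saliences = alphas)
      state <- trained$final
      if (!"direction" %in% channels) state$V_dir[] <- 0
      if (!"distance" %in% channels) state$V_dist[] <- 0
      key <- sprintf("%s|s=%.2f|%s", ratio_label, strength,
                     paste(channels, collapse = "+"))
      set.seed(derive_seed(seed, length(maps) + 1L))
      hm <- guess_heatmap(state, arena, n_samples, bins = bins)
      maps[[key]] <- hm
      p <- hm$density[hm$density > 0]
      rows[[key]] <- data.frame(
        strength = strength, ratio = ratio_label,
        channels = paste(channels, collapse = "+"),
        alpha_1 = unname(alphas[1]), alpha_2 = unname(alphas[2]),
        frac_target = guess_fraction_in_quadrant(hm$guesses, arena),
        entropy = -sum(p * log(p))
      )
    }
  }
  list(grid = do.call(rbind, rows), heatmaps = maps)
}

#' Retention after removing cues from the training array
#'
#' Trains with the scenario's saliences, then probes each presented-cue
#' condition under the scenario's interpretation policy and returns the
#' occupancy tables.
#'
#' @param spec A [scenario_spec()].
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param learning_params A `learning_params`.
#' @return A list with `occupancy` (named list of per-rat occupancy tables,
#'   one per probe condition), `summary` (tidy data.frame of mean occupancy
#'   per condition and region) and `state` (the trained `learning_state`).
#' @export
cue_removal_retention <- function(spec, arena, swim, learning_params) {
  stopifnot(inherits(spec, "scenario_spec"))
  trained <- run_training(arena, learning_params,
                          saliences = spec$training_saliences)
  state <- trained$final
  occ <- list(); rows <- list()
  for (cond in names(spec$retention_cues)) {
    cues <- spec$retention_cues[[cond]]
    tab <- run_retention(state, arena, swim, spec$n_rats,
                         seed = derive_seed(spec$seed, match(cond, names(spec$retention_cues))),
                         presented_cues = cues,
                         interpretation = spec$interpretation)
    occ[[cond]] <- tab
    sm <- occupancy_summary(tab)
    sm$condition <- cond
    sm$presented <- paste(cues, collapse = "+")
    rows[[cond]] <- sm
  }
  list(occupancy = occ, summary = do.call(rbind, rows), state = state)
}

#' Cue-uncertainty models for unequal-brightness training
#'
#' Two accounts of how animals treat a poorly learned dim cue:
#'
#' * `"ignore_dim"`: the bright cue's salience so dominates that the dim cue
#'   carries none (`alpha_dim = 0`, `alpha_bright = 1`). Probed with the dim
#'   cue alone under the identity policy the animal never engages it and
#'   searching is random across quadrants.
#' * `"misinterpret"`: both cues acquire salience (`alpha_dim = 0.2`,
#'   `alpha_bright = 0.8`) but, probed with the dim cue alone, the animal
#'   misinterprets it as the bright cue with probability
#'   `misinterpretation_probability`, splitting its search between the
#'   correct region and the region implied by the bright cue's relationship
#'   anchored at the dim cue's position.
#'
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param learning_params A `learning_params`.
#' @param model `"ignore_dim"` or `"misinterpret"`.
#' @param bright_cue Which cue is the bright one.
#' @param n_rats Cohort size per probe condition.
#' @param seed Master seed.
#' @param misinterpretation_probability Probability of treating the dim cue
#'   as the bright one (misinterpret model).
#' @param dim_salience,bright_salience Training saliences for the
#'   misinterpret model.
#' @return A list with `occupancy` (per-rat tables for probes `dim_only`,
#'   `bright_only`, `both`), `summary` and the trained `state`.
#' @export
uncertainty_models <- function(arena, swim, learning_params,
                               model = c("ignore_dim", "misinterpret"),
                               bright_cue = "Near", n_rats = 50, seed = 1,
                               misinterpretation_probability = 0.5,
                               dim_salience = 0.2, bright_salience = 0.8) {
  model <- match.arg(model)
  ids <- names(arena$cues)
  stopifnot(bright_cue %in% ids, length(ids) == 2L)
  dim_cue <- setdiff(ids, bright_cue)
  saliences <- if (model == "ignore_dim") {
    stats::setNames(as.numeric(ids == bright_cue), ids)
  } else {
    stats::setNames(ifelse(ids == bright_cue, bright_salience, dim_salience),
                    ids)
  }
  policy <- if (model == "ignore_dim") {
    interpretation_policy("identity")
  } else {
    interpretation_policy("probabilistic_misinterpretation",
                          misinterpretation_probability,
                          confusable_cue = dim_cue)
  }
  spec <- scenario_spec(
    name = paste0("uncertainty-", model),
    training_saliences = saliences,
    retention_cues = list(dim_only = dim_cue, bright_only = bright_cue,
                          both = ids),
    interpretation = policy, n_rats = n_rats, seed = seed
  )
  out <- cue_removal_retention(spec, arena, swim, learning_params)
  out$model <- model
  out$bright_cue <- bright_cue
  out$dim_cue <- dim_cue
  out
}

#' Direct overshadowing experiment
#'
#' Five cohorts: trained and retested with the Far cue alone (`Far-Far`),
#' with the Near cue alone (`Near-Near`), trained with both cues and
#' retested with one (`Both-Far`, `Both-Near`), and the `Both-Both` control.
#' Compound training splits the usage capacity between the cues, so each
#' cue alone commands less search than after single-cue training -- the
#' overshadowing signature: `Far-Far > Both-Far` and `Near-Near > Both-Near`
#' in mean time-in-platform-area.
#'
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param learning_params A `learning_params`.
#' @param n_rats Rats per group.
#' @param seed Master seed.
#' @return A list with `groups` (per-rat occupancy tables named by group),
#'   `summary` (data.frame: group, mean/sd percent time-in-platform-area)
#'   and `quadrants` (mean occupancy fraction per group and quadrant).
#' @export
overshadowing_experiment <- function(arena, swim, learning_params,
                                     n_rats = 50, seed = 1) {
  ids <- names(arena$cues)
  stopifnot(all(c("Near", "Far") %in% ids))
  single <- function(cue) stats::setNames(as.numeric(ids == cue), ids)
  both <- stats::setNames(rep(0.5, length(ids)), ids)
  groups <- list(
    `Far-Far` = list(train = single("Far"), probe = "Far"),
    `Near-Near` = list(train = single("Near"), probe = "Near"),
    `Both-Far` = list(train = both, probe = "Far"),
    `Both-Near` = list(train = both, probe = "Near"),
    `Both-Both` = list(train = both, probe = ids)
  )
  occ <- list(); sum_rows <- list(); quad_rows <- list()
  for (g in names(groups)) {
    trained <- run_training(arena, learning_params,
                            saliences = groups[[g]]$train)
    tab <- run_retention(trained$final, arena, swim, n_rats,
                         seed = derive_seed(seed, match(g, names(groups))),
                         presented_cues = groups[[g]]$probe)
    occ[[g]] <- tab
    pct <- 100 * tab$escape_region
    sum_rows[[g]] <- data.frame(group = g, n = n_rats,
                                mean_pct_platform_area = mean(pct),
                                sd_pct_platform_area = stats::sd(pct))
    quad_rows[[g]] <- data.frame(
      group = g, quadrant = c("NE", "SE", "SW", "NW"),
      mean_fraction = c(mean(tab$NE), mean(tab$SE), mean(tab$SW),
                        mean(tab$NW))
    )
  }
  list(groups = occ,
       summary = do.call(rbind, c(sum_rows, list(make.row.names = FALSE))),
       quadrants = do.call(rbind, c(quad_rows, list(make.row.names = FALSE))))
}
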