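#!/usr/bin/env Rscript
# Evaluates a swim parameterisation against the behavioural regimes the
# defaults are calibrated to:
#   (a) an uninformed swim meanders and rarely escapes within 60 s;
#   (b) a fully informed swim escapes in a few seconds;
#   (c) the four single-channel strategies (strength 0.95) produce mean
#       latencies near 11 / 7.8 / 6.9 / 12.1 s with both ordinal relations
#       (Far-direction < Near-direction, Near-distance < Far-distance).
#
# Usage:
#   Rscript scripts/calibrate_swim.R [--seed N] [--n-rats N] [--grid]
#
# Without --grid the current swim_params() defaults are scored; with
# --grid a small neighbourhood of speeds and contact margins is swept.

suppressPackageStartupMessages(library(landmaze))

args <- commandArgs(trailingOnly = TRUE)
get_flag <- function(name, default) {
  i <- match(paste0("--", name), args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
seed <- as.integer(get_flag("seed", "1"))
n <- as.integer(get_flag("n-rats", "400"))
do_grid <- "--grid" %in% args

arena <- make_default_arena()

score <- function(swim) {
  starts <- arena$start_positions
  run <- function(state, n_use, forced = NULL, sd_off = 0) {
    vapply(seq_len(n_use), function(rat) {
      set.seed(derive_seed(seed + sd_off, rat))
      simulate_trial(state, arena, swim,
                     starts[(rat - 1L) %% 4L + 1L],
                     forced_cue = forced,
                     record_trajectory = FALSE)$latency
    }, numeric(1))
  }
  naive <- learning_state(names(arena$cues))
  trained <- learning_state(names(arena$cues), V_use = 0.5,
                            V_dir = 0.95, V_dist = 0.95)
  single <- function(cue, channel) {
    st <- learning_state(names(arena$cues))
    if (channel == "direction") st$V_dir[cue] <- 0.95
    else st$V_dist[cue] <- 0.95
    mean(run(st, n, forced = cue, sd_off = 2))
  }
  c(untrained = mean(run(naive, ceiling(n / 4))),
    trained = mean(run(trained, n, sd_off = 1)),
    near_dir = single("Near", "direction"),
    far_dir = single("Far", "direction"),
    near_dist = single("Near", "distance"),
    far_dist = single("Far", "distance"))
}

report <- function(label, s) {
  cat(sprintf(
    "%-28s untrained %5.1f | trained %4.1f | dir N/F %5.2f/%5.2f | dist N/F %5.2f/%5.2f\n",
    label, s[["untrained"]], s[["trained"]],
    s[["near_dir"]], s[["far_dir"]], s[["near_dist"]], s[["far_dist"]]))
  ok_ord <- s[["far_dir"]] < s[["near_dir"]] &&
    s[["near_dist"]] < s[["far_dist"]]
  cat("  orderings (Fdir < Ndir, Ndist < Fdist): ",
      if (ok_ord) "ok" else "VIOLATED", "\n", sep = "")
}

cat(sprintf("reference regime: dir N/F 11/7.8 s, dist N/F 6.9/12.1 s (n = %d)\n", n))
report("defaults", score(swim_params()))

if (do_grid) {
  for (speed in c(21, 23.2, 25)) {
    for (margin in c(5, 7, 9)) {
      sp <- swim_params(rayleigh_scale = speed * 0.05 / sqrt(pi / 2),
                        contact_margin = margin)
      report(sprintf("speed %.1f cm/s, margin %.0f cm", speed, margin),
             score(sp))
    }
  }
}
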