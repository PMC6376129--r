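# Configuration, seeding, tabular output and test fixtures.

#' Derive a per-unit random seed from a master seed
#'
#' A two-round Lehmer mix (multiplier 48271 modulo the Mersenne prime
#' 2^31 - 1) of the master seed and a unit index. Each simulated rat seeds
#' its own stream with `derive_seed(master, rat)`, so rat `i`'s results are
#' bit-identical regardless of cohort size or execution order.
#'
#' @param master Master seed (integer).
#' @param index Non-negative unit index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  a <- 48271
  s <- (abs(as.numeric(master)) %% (m - 1)) + 1
  s <- (a * s) %% m
  s <- (a * ((s + as.numeric(index)) %% m)) %% m
  as.integer(s %% (m - 1))
}

#' Read an arena configuration from a file
#'
#' Accepts a flat YAML or JSON document (dispatched on the file extension)
#' with keys matching the arguments of [arena_config()]; cues are given as a
#' list of records with `cue_id`, `position`, `salience` and optional
#' `brightness_label`. Missing keys fall back to the standard arena's
#' values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `arena_config`.
#' @export
read_arena_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("config must be a .yaml/.yml or .json file", call. = FALSE)
  }
  default <- make_default_arena()
  pick <- function(key, fallback) if (!is.null(raw[[key]])) raw[[key]] else
    fallback
  cues <- if (!is.null(raw$cues)) {
    lapply(raw$cues, function(cue) {
      for (key in c("cue_id", "position", "salience")) {
        if (is.null(cue[[key]])) {
          stop("cue entry missing key: ", key, call. = FALSE)
        }
      }
      cue_spec(cue$cue_id, unlist(cue$position), cue$salience,
               if (is.null(cue$brightness_label)) "" else cue$brightness_label)
    })
  } else {
    default$cues
  }
  arena_config(
    pool_radius = pick("pool_radius", default$pool_radius),
    platform_center = unlist(pick("platform_center",
                                  default$platform_center)),
    platform_radius = pick("platform_radius", default$platform_radius),
    escape_region_radius = pick("escape_region_radius",
                                default$escape_region_radius),
    cues = cues,
    trial_duration = pick("trial_duration", default$trial_duration),
    trials_per_day = pick("trials_per_day", default$trials_per_day),
    n_days = pick("n_days", default$n_days),
    start_positions = unlist(pick("start_positions",
                                  default$start_positions)),
    probe_start = pick("probe_start", default$probe_start)
  )
}

#' Write a results table as CSV
#'
#' Comma-separated text with a header row and no row names -- the format all
#' tabular outputs of the command-line driver use.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Manifest describing a completed run
#'
#' @param config_snapshot List of the configuration values used.
#' @param seed Master seed of the run.
#' @param outputs Character vector of files written.
#' @return A list with the package version, timestamp, seed, configuration
#'   and per-output md5 checksums; re-running with the same configuration
#'   and seed reproduces files with identical checksums.
#' @export
run_manifest <- function(config_snapshot, seed, outputs) {
  sums <- if (length(outputs)) tools::md5sum(outputs) else character(0)
  list(
    package = "landmaze",
    version = as.character(utils::packageVersion("landmaze")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config_snapshot,
    outputs = lapply(seq_along(outputs), function(i) {
      list(file = outputs[i], md5 = unname(sums[i]))
    })
  )
}

#' Deterministic fixtures for metric and inference tests
#'
#' @param kind One of `"straight_line"` (a constant-speed South-to-North
#'   swim through the pool centre: occupancy is split NE/SW by the quadrant
#'   tie rule), `"uniform_coverage"` (a serpentine scan visiting the pool
#'   uniformly: each quadrant near 0.25), `"trained_state"` (associative
#'   strengths at the default asymptotes: usage 0.5/0.5, both channels
#'   0.95) or `"untrained_state"` (all zeros).
#' @param arena An `arena_config`.
#' @param seed Seed for kinds with any randomness (none currently; kept for
#'   interface stability).
#' @return A trajectory data.frame (`t`, `x`, `y`) or a `learning_state`.
#' @export
generate_fixture <- function(kind = c("straight_line", "uniform_coverage",
                                      "trained_state", "untrained_state"),
                             arena = make_default_arena(), seed = 1) {
  kind <- match.arg(kind)
  switch(
    kind,
    straight_line = {
      n <- 121L
      y <- seq(-arena$pool_radius, arena$pool_radius, length.out = n)
      data.frame(t = seq(0, 60, length.out = n), x = 0, y = y)
    },
    uniform_coverage = {
      # serpentine scan over the inscribed grid, clipped to the pool
      r <- arena$pool_radius * 0.98
      xs <- seq(-r, r, length.out = 41L)
      ys <- seq(-r, r, length.out = 41L)
      pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
        xx <- if (i %% 2L == 0L) rev(xs) else xs
        cbind(xx, ys[i])
      }))
      keep <- sqrt(pts[, 1]^2 + pts[, 2]^2) <= r
      pts <- pts[keep, , drop = FALSE]
      data.frame(t = seq(0, 60, length.out = nrow(pts)),
                 x = pts[, 1], y = pts[, 2])
    },
    trained_state = learning_state(names(arena$cues), V_use = 0.5,
                                   V_dir = 0.95, V_dist = 0.95),
    untrained_state = learning_state(names(arena$cues))
  )
}
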