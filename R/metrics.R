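# Summary statistics over trial records: escape latencies, region occupancy,
# and the latency-vs-occupancy variability contrast.

#' Time-weighted region occupancy of a trajectory
#'
#' Each sampling interval contributes `dt` of occupancy at the membership of
#' the segment midpoint, which is unbiased for piecewise-linear paths at
#' small `dt`. The four quadrant fractions always sum to 1 for a trajectory
#' confined to the pool.
#'
#' @param trajectory Data.frame with columns `t`, `x`, `y` (as produced by
#'   [simulate_trial()]).
#' @param arena An `arena_config`.
#' @param start_pos Optional `(x, y)` release point prepended so the first
#'   interval is scored from the true start.
#' @return Named numeric vector: fractions `NE`, `SE`, `SW`, `NW` and
#'   `escape_region` (time inside the platform-area scoring circle).
#' @export
trajectory_occupancy <- function(trajectory, arena, start_pos = NULL) {
  x <- trajectory$x; y <- trajectory$y
  if (!is.null(start_pos)) {
    x <- c(start_pos[1], x); y <- c(start_pos[2], y)
  }
  n <- length(x)
  if (n < 2L) stop("trajectory needs at least two positions", call. = FALSE)
  mx <- (x[-1] + x[-n]) / 2
  my <- (y[-1] + y[-n]) / 2
  quad <- quadrant_of(mx, my)
  frac <- vapply(c("NE", "SE", "SW", "NW"), function(q) mean(quad == q),
                 numeric(1))
  d2 <- (mx - arena$platform_center[1])^2 + (my - arena$platform_center[2])^2
  c(frac, escape_region = mean(d2 <= arena$escape_region_radius^2))
}

#' Summarise escape latencies
#'
#' Censored trials (no escape within the trial duration) enter the summary
#' at the full trial duration, the standard water-maze convention; their
#' count is reported alongside.
#'
#' @param latencies Numeric vector of latencies in seconds (censored trials
#'   already at the trial duration).
#' @param censored Logical vector marking censored trials.
#' @return A one-row data.frame: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `cv`, `n_censored`.
#' @export
latency_summary <- function(latencies, censored = rep(FALSE, length(latencies))) {
  stopifnot(length(latencies) >= 1L, length(censored) == length(latencies))
  q <- stats::quantile(latencies, c(0.25, 0.5, 0.75), names = FALSE)
  m <- mean(latencies)
  s <- stats::sd(latencies)
  if (length(latencies) == 1L) s <- 0
  data.frame(
    n = length(latencies), mean = m, sd = s,
    median = q[2], q1 = q[1], q3 = q[3],
    cv = if (m > 0) s / m else NA_real_,
    n_censored = sum(censored)
  )
}

#' Summarise probe-trial occupancy over a cohort
#'
#' @param occupancy Data.frame as returned by [run_retention()].
#' @return A data.frame with one row per region (`NE`, `SE`, `SW`, `NW`,
#'   `escape_region`): mean, sd and cv of the occupancy fraction across rats.
#' @export
occupancy_summary <- function(occupancy) {
  regions <- c("NE", "SE", "SW", "NW", "escape_region")
  do.call(rbind, lapply(regions, function(rg) {
    v <- occupancy[[rg]]
    m <- mean(v)
    data.frame(region = rg, mean = m, sd = stats::sd(v),
               cv = if (m > 0) stats::sd(v) / m else NA_real_,
               n = length(v))
  }))
}

#' Latency-CV versus occupancy-CV contrast for a trained cohort
#'
#' For each simulated rat: one post-training escape trial (start positions
#' cycling through the acquisition set) giving a single-trial latency, and
#' one platform-absent probe from the probe start giving the time inside the
#' platform-area scoring circle. Returns the across-rat coefficients of
#' variation of both readouts. Escape latencies of individual trials are far
#' noisier than probe-trial time-in-platform-area, which integrates over the
#' whole 60 s path; the ratio of the two CVs quantifies that reliability
#' gap.
#'
#' @param learning A trained `learning_state`.
#' @param arena An `arena_config`.
#' @param swim A `swim_params`.
#' @param n_rats Cohort size.
#' @param seed Master seed.
#' @return A list with `cv_latency`, `cv_occupancy`, `ratio`
#'   (`cv_latency / cv_occupancy`), and the per-rat `latencies` and
#'   `occupancy` tables.
#' @export
cv_comparison <- function(learning, arena, swim, n_rats, seed) {
  stopifnot(n_rats >= 2)
  starts <- arena$start_positions
  lat <- numeric(n_rats); cen <- logical(n_rats)
  for (rat in seq_len(n_rats)) {
    set.seed(derive_seed(seed, rat))
    rec <- simulate_trial(learning, arena, swim,
                          starts[(rat - 1L) %% length(starts) + 1L],
                          record_trajectory = FALSE)
    lat[rat] <- rec$latency; cen[rat] <- rec$censored
  }
  occ <- run_retention(learning, arena, swim, n_rats, seed + 1L)
  cv_lat <- stats::sd(lat) / mean(lat)
  cv_occ <- stats::sd(occ$time_in_area) / mean(occ$time_in_area)
  list(cv_latency = cv_lat, cv_occupancy = cv_occ,
       ratio = cv_lat / cv_occ,
       latencies = data.frame(rat = seq_len(n_rats), latency = lat,
                              censored = cen),
       occupancy = occ)
}
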