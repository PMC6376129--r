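# Base-graphics figures: swim paths, learning curves, occupancy bars and
# guess-cloud heatmaps. Figures are side-effects only; no analysis reads
# them back.

#' Plot a swim path inside the arena
#'
#' @param record A `trial_record` with a recorded trajectory.
#' @param arena The `arena_config` the trial ran in.
#' @param ... Passed to [graphics::lines()] for the path.
#' @return The record, invisibly.
#' @export
plot_trajectory <- function(record, arena, ...) {
  if (is.null(record$trajectory)) {
    stop("trial was simulated with record_trajectory = FALSE", call. = FALSE)
  }
  r <- arena$pool_radius
  theta <- seq(0, 2 * pi, length.out = 200)
  plot(r * cos(theta), r * sin(theta), type = "l", asp = 1,
       xlab = "x (cm)", ylab = "y (cm)", main = "Swim path")
  graphics::symbols(arena$platform_center[1], arena$platform_center[2],
                    circles = arena$platform_radius, inches = FALSE,
                    add = TRUE, fg = "grey40", bg = "grey80")
  graphics::lines(record$trajectory$x, record$trajectory$y, ...)
  graphics::points(record$trajectory$x[1], record$trajectory$y[1], pch = 16)
  invisible(record)
}

#' Plot per-day mean escape latencies
#'
#' @param latencies The `latencies` data.frame from [run_acquisition()].
#' @param ... Passed to [graphics::plot()].
#' @return The per-day means, invisibly.
#' @export
plot_learning_curve <- function(latencies, ...) {
  m <- tapply(latencies$latency, latencies$day, mean)
  plot(as.integer(names(m)), m, type = "b", pch = 16,
       xlab = "Day", ylab = "Mean escape latency (s)",
       ylim = c(0, max(m) * 1.05), ...)
  invisible(m)
}

#' Bar chart of mean quadrant occupancy
#'
#' @param occupancy A per-rat occupancy table from [run_retention()].
#' @param ... Passed to [graphics::barplot()].
#' @return The mean fractions, invisibly.
#' @export
plot_occupancy_bars <- function(occupancy, ...) {
  m <- colMeans(occupancy[, c("NE", "SE", "SW", "NW")])
  graphics::barplot(m, ylab = "Fraction of probe time",
                    ylim = c(0, 1), ...)
  invisible(m)
}

#' Image plot of a guess-cloud heatmap
#'
#' @param heatmap A result of [guess_heatmap()].
#' @param arena Optional `arena_config`; when given, the pool outline is
#'   overlaid.
#' @param ... Passed to [graphics::image()].
#' @return The heatmap, invisibly.
#' @export
plot_guess_heatmap <- function(heatmap, arena = NULL, ...) {
  cx <- (heatmap$breaks_x[-1] + utils::head(heatmap$breaks_x, -1)) / 2
  cy <- (heatmap$breaks_y[-1] + utils::head(heatmap$breaks_y, -1)) / 2
  graphics::image(cx, cy, heatmap$density, asp = 1,
                  xlab = "x (cm)", ylab = "y (cm)", ...)
  if (!is.null(arena)) {
    theta <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(arena$pool_radius * cos(theta),
                    arena$pool_radius * sin(theta))
  }
  invisible(heatmap)
}
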