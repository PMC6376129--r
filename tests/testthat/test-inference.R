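test_that("uncertainty is the complement of associative strength", {
  st <- learning_state(c("Near", "Far"), V_dir = c(0.95, 0), V_dist = c(0.95, 1))
  expect_equal(uncertainties(st, "Near"),
               c(sigma_dist = 0.05, sigma_dir = 0.05))
  expect_equal(uncertainties(st, "Far"), c(sigma_dist = 0, sigma_dir = 1))
  expect_error(uncertainties(st, "Middle"), "not present")
})

test_that("guess errors scale linearly with uncertainty (200 cm, 75 deg)", {
  set.seed(21)
  expect_equal(unlist(sample_errors(0, 0, 5)), rep(0, 10), ignore_attr = TRUE)
  sig <- seq(0.1, 1, by = 0.1)
  sds <- t(vapply(sig, function(s) {
    e <- sample_errors(s, s, 4e4)
    c(sd(e$eps_dist), sd(e$eps_dir))
  }, numeric(2)))
  fit_dist <- lm(sds[, 1] ~ 0 + sig)
  fit_dir <- lm(sds[, 2] ~ 0 + sig)
  expect_equal(unname(coef(fit_dist)), 200, tolerance = 0.02)
  expect_equal(unname(coef(fit_dir)), 75, tolerance = 0.02)
  expect_error(sample_errors(1.2, 0), "sigma")
})

test_that("full knowledge infers the platform exactly, from either cue", {
  arena <- make_default_arena()
  st <- learning_state(c("Near", "Far"), V_dir = 1, V_dist = 1)
  for (id in c("Near", "Far")) {
    g <- infer_platform(st, id, arena, n = 3)
    expect_equal(unlist(g[, c("x", "y")], use.names = FALSE),
                 rep(arena$platform_center, each = 3), tolerance = 1e-10)
  }
})

test_that("mis-anchoring a relationship rotates the inferred location", {
  arena <- make_default_arena()
  st <- learning_state(c("Near", "Far"), V_dir = 1, V_dist = 1)
  p <- arena$platform_center
  # Far's relationship applied at the Near position: rotated 90 deg clockwise
  g <- infer_platform(st, "Far", arena, n = 1, anchor_cue = "Near")
  expect_equal(c(g$x, g$y), c(p[2], -p[1]), tolerance = 1e-10)
  # Near's relationship applied at the Far position: rotated anticlockwise
  g2 <- infer_platform(st, "Near", arena, n = 1, anchor_cue = "Far")
  expect_equal(c(g2$x, g2$y), c(-p[2], p[1]), tolerance = 1e-10)
})

test_that("negative perturbed radii reflect through the anchor by default", {
  arena <- make_default_arena()
  off <- cue_platform_offset(arena, "Near")
  anchor <- arena$cues$Near$position
  g <- guess_from_offset(anchor, off[["r"]], off[["phi"]],
                         eps_dist = -(off[["r"]] + 10), eps_dir = 0, "Near")
  d <- sqrt(sum((c(g$x, g$y) - anchor)^2))
  expect_equal(d, 10, tolerance = 1e-9)          # |r + eps| from the anchor
  gt <- guess_from_offset(anchor, off[["r"]], off[["phi"]],
                          eps_dist = -(off[["r"]] + 10), eps_dir = 0, "Near",
                          negative_radius = "truncate")
  expect_equal(c(gt$x, gt$y), anchor, tolerance = 1e-9)
})

test_that("single-channel guess clouds align with the cue-platform geometry", {
  arena <- make_default_arena()
  off <- cue_platform_offset(arena, "Near")
  ray <- c(sin(off[["phi"]] * pi / 180), cos(off[["phi"]] * pi / 180))
  principal_axis <- function(g) {
    e <- eigen(cov(cbind(g$x, g$y)))
    list(axis = e$vectors[, 1], ratio = e$values[1] / e$values[2])
  }
  set.seed(22)
  dir_only <- infer_platform(learning_state(c("Near", "Far"),
                                            V_dir = c(0.95, 0)),
                             "Near", arena, n = 3000)
  pa <- principal_axis(dir_only)
  expect_gt(abs(sum(pa$axis * ray)), 0.99)  # spread along the ray
  expect_gt(pa$ratio, 50)
  set.seed(23)
  dist_only <- infer_platform(learning_state(c("Near", "Far"),
                                             V_dist = c(0.95, 0)),
                              "Near", arena, n = 3000)
  pa2 <- principal_axis(dist_only)
  expect_lt(abs(sum(pa2$axis * ray)), 0.2)  # spread across the ray (arc)
  # distance from the cue stays near the learned radius
  d <- sqrt((dist_only$x - arena$cues$Near$position[1])^2 +
              (dist_only$y - arena$cues$Near$position[2])^2)
  expect_equal(mean(d), off[["r"]], tolerance = 0.05)
})

test_that("guess heatmaps are normalised mixtures weighted by usage", {
  arena <- make_default_arena()
  full <- learning_state(c("Near", "Far"), V_use = 0.5, V_dir = 1, V_dist = 1)
  hm <- guess_heatmap(full, arena, n_samples = 500, bins = 21)
  expect_equal(sum(hm$density), 1)
  # zero-error guesses all land in the platform's bin
  ix <- findInterval(arena$platform_center[1], hm$breaks_x)
  iy <- findInterval(arena$platform_center[2], hm$breaks_y)
  expect_equal(hm$density[ix, iy], 1)
  # a degenerate mixture uses only the surviving cue
  one <- learning_state(c("Near", "Far"), V_use = c(1, 0),
                        V_dir = 0.6, V_dist = 0.6)
  hm1 <- guess_heatmap(one, arena, n_samples = 400)
  expect_true(all(hm1$guesses$source_cue == "Near"))
  expect_error(guess_heatmap(learning_state(c("a", "b")), arena, 10),
               "positive V_use")
})

test_that("stronger learning concentrates the guess cloud", {
  arena <- make_default_arena()
  # strengths reached after training at salience strength 0.1 vs 0.5
  ent <- vapply(c(0.45, 0.95), function(v) {
    st <- learning_state(c("Near", "Far"), V_use = 0.5, V_dir = v, V_dist = v)
    set.seed(24)
    hm <- guess_heatmap(st, arena, n_samples = 4000)
    p <- hm$density[hm$density > 0]
    -sum(p * log(p))
  }, numeric(1))
  expect_lt(ent[2], ent[1])
})
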