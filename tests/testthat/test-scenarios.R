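test_that("the vector-information dissection reproduces the cue geometry", {
  arena <- default_arena
  n <- 250
  fd <- dissect_information(arena, default_swim, "direction", "Far",
                            n_rats = n, seed = 61)
  nd <- dissect_information(arena, default_swim, "direction", "Near",
                            n_rats = n, seed = 61)
  ns <- dissect_information(arena, default_swim, "distance", "Near",
                            n_rats = n, seed = 61)
  fs <- dissect_information(arena, default_swim, "distance", "Far",
                            n_rats = n, seed = 61)
  # far-direction beats near-direction; near-distance beats far-distance
  expect_lt(wilcox.test(fd$latencies$latency, nd$latencies$latency,
                        alternative = "less")$p.value, 0.01)
  expect_lt(wilcox.test(ns$latencies$latency, fs$latencies$latency,
                        alternative = "less")$p.value, 1e-6)
  # far-direction is also the more reliable strategy
  expect_lt(fd$summary$sd, nd$summary$sd)
  # near-distance guesses concentrate in the target quadrant
  expect_gt(guess_fraction_in_quadrant(ns$guesses, arena), 0.35)
  expect_gt(guess_fraction_in_quadrant(ns$guesses, arena),
            guess_fraction_in_quadrant(fs$guesses, arena))
})

test_that("salience strengthening concentrates search monotonically", {
  arena <- default_arena
  sw <- salience_sweep(arena, default_learning,
                       strengths = seq(0.1, 0.5, by = 0.1),
                       n_samples = 1500, seed = 62)
  expect_true(all(diff(sw$grid$frac_target) > 0))
  expect_true(all(diff(sw$grid$entropy) < 0))
  # direction-only, Far-dominant salience: mass in the northern half
  dir_far <- salience_sweep(arena, default_learning, strengths = 0.5,
                            ratios = list(c(Near = 0.17, Far = 0.83)),
                            channels = "direction", n_samples = 1500,
                            seed = 63)
  g <- dir_far$heatmaps[[1]]$guesses
  inside <- sqrt(g$x^2 + g$y^2) <= arena$pool_radius
  q <- quadrant_of(g$x[inside], g$y[inside])
  expect_gt(mean(q %in% c("NW", "NE")), 0.8)
  # distance-only, Near-dominant salience: mass confined to the target
  dist_near <- salience_sweep(arena, default_learning, strengths = 0.5,
                              ratios = list(c(Near = 0.83, Far = 0.17)),
                              channels = "distance", n_samples = 1500,
                              seed = 64)
  g2 <- dist_near$heatmaps[[1]]$guesses
  inside2 <- sqrt(g2$x^2 + g2$y^2) <= arena$pool_radius
  expect_gt(mean(quadrant_of(g2$x[inside2], g2$y[inside2]) == "NE"), 0.6)
  expect_error(salience_sweep(arena, default_learning,
                              ratios = list(c(Near = 0.6, Far = 0.6))),
               "sum to 1")
})

test_that("indistinguishable cues split the search between two regions", {
  arena <- default_arena
  spec <- scenario_spec("cr", c(Near = 0.5, Far = 0.5),
                        list(both = c("Near", "Far"), near_only = "Near",
                             far_only = "Far"),
                        interpretation_policy("indistinguishable"),
                        n_rats = 40, seed = 65)
  res <- cue_removal_retention(spec, arena, default_swim, default_learning)
  both <- colMeans(res$occupancy$both[, c("NE", "SE", "SW", "NW")])
  near <- colMeans(res$occupancy$near_only[, c("NE", "SE", "SW", "NW")])
  far <- colMeans(res$occupancy$far_only[, c("NE", "SE", "SW", "NW")])
  # full array: target quadrant only
  expect_equal(names(which.max(both)), "NE")
  expect_gt(both[["NE"]], 0.7)
  # near cue alone: bimodal NE + SE
  expect_gt(near[["NE"]], 0.3)
  expect_gt(near[["SE"]], 0.3)
  expect_lt(near[["NW"]] + near[["SW"]], 0.2)
  # far cue alone: bimodal NE + NW
  expect_gt(far[["NE"]], 0.3)
  expect_gt(far[["NW"]], 0.3)
  expect_lt(far[["SE"]] + far[["SW"]], 0.2)
})

test_that("distinguishable cues keep the search on target either way", {
  arena <- default_arena
  spec <- scenario_spec("identity", c(Near = 0.5, Far = 0.5),
                        list(near_only = "Near", far_only = "Far"),
                        interpretation_policy("identity"),
                        n_rats = 40, seed = 66)
  res <- cue_removal_retention(spec, arena, default_swim, default_learning)
  for (cond in names(res$occupancy)) {
    occ <- colMeans(res$occupancy[[cond]][, c("NE", "SE", "SW", "NW")])
    expect_equal(names(which.max(occ)), "NE")
    expect_gt(occ[["NE"]], 0.5)
  }
})

test_that("generalisation to the salient cue displaces the search", {
  arena <- default_arena
  # near cue maximally salient: far cue read as near -> search NW
  near_sal <- scenario_spec("gen-near", c(Near = 1, Far = 0),
                            list(near_only = "Near", far_only = "Far"),
                            interpretation_policy("generalize_to_salient"),
                            n_rats = 40, seed = 67)
  res_n <- cue_removal_retention(near_sal, arena, default_swim,
                                 default_learning)
  expect_gt(colMeans(res_n$occupancy$near_only)["NE"], 0.7)
  expect_gt(colMeans(res_n$occupancy$far_only)["NW"], 0.7)
  # far cue maximally salient: near cue read as far -> search SE
  far_sal <- scenario_spec("gen-far", c(Near = 0, Far = 1),
                           list(near_only = "Near", far_only = "Far"),
                           interpretation_policy("generalize_to_salient"),
                           n_rats = 40, seed = 68)
  res_f <- cue_removal_retention(far_sal, arena, default_swim,
                                 default_learning)
  expect_gt(colMeans(res_f$occupancy$near_only)["SE"], 0.7)
  expect_gt(colMeans(res_f$occupancy$far_only)["NE"], 0.7)
})

test_that("a 50:50 salience split makes generalisation and confusion identical", {
  arena <- default_arena
  base <- list(both = c("Near", "Far"), near_only = "Near")
  run_policy <- function(mode) {
    spec <- scenario_spec(mode, c(Near = 0.5, Far = 0.5), base,
                          interpretation_policy(mode), n_rats = 15, seed = 69)
    cue_removal_retention(spec, arena, default_swim, default_learning)
  }
  expect_identical(run_policy("indistinguishable")$occupancy,
                   run_policy("generalize_to_salient")$occupancy)
})

test_that("the two cue-uncertainty accounts produce their signatures", {
  arena <- default_arena
  # dominated dim cue: probing with it yields near-uniform search
  mc <- uncertainty_models(arena, default_swim, default_learning,
                           model = "ignore_dim", bright_cue = "Near",
                           n_rats = 40, seed = 70)
  dim_occ <- colMeans(mc$occupancy$dim_only[, c("NE", "SE", "SW", "NW")])
  expect_lt(max(dim_occ), 0.4)
  expect_gt(min(dim_occ), 0.1)
  bright_occ <- colMeans(mc$occupancy$bright_only[, c("NE", "SE", "SW", "NW")])
  expect_gt(bright_occ[["NE"]], 0.6)
  # partial misinterpretation of the dim near cue: NE and SE both elevated
  md <- uncertainty_models(arena, default_swim, default_learning,
                           model = "misinterpret", bright_cue = "Far",
                           n_rats = 40, seed = 71)
  dim_occ2 <- colMeans(md$occupancy$dim_only[, c("NE", "SE", "SW", "NW")])
  expect_gt(dim_occ2[["NE"]], 0.25)
  expect_gt(dim_occ2[["SE"]], 0.25)
  expect_gt(dim_occ2[["NE"]] + dim_occ2[["SE"]], 0.65)
  bright2 <- colMeans(md$occupancy$bright_only[, c("NE", "SE", "SW", "NW")])
  expect_gt(bright2[["NE"]], 0.6)
})

test_that("compound training overshadows each cue", {
  arena <- default_arena
  ov <- overshadowing_experiment(arena, default_swim, default_learning,
                                 n_rats = 25, seed = 72)
  s <- ov$summary
  get <- function(g) s$mean_pct_platform_area[s$group == g]
  expect_gt(get("Far-Far"), get("Both-Far"))
  expect_gt(get("Near-Near"), get("Both-Near"))
  # single-cue training drives that cue's usage to the full capacity
  single <- run_training(arena, default_learning,
                         saliences = c(Near = 0, Far = 1))$final
  expect_equal(single$V_use[["Far"]], default_learning$lambda_use,
               tolerance = 0.005)
  expect_equal(single$V_use[["Near"]], 0)
  # deterministic given the seed
  ov2 <- overshadowing_experiment(arena, default_swim, default_learning,
                                  n_rats = 25, seed = 72)
  expect_identical(ov$summary, ov2$summary)
})
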