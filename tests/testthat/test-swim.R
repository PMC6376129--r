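test_that("step sizes follow the configured Rayleigh distribution", {
  params <- swim_params(rayleigh_scale = 6)
  set.seed(1)
  draws <- draw_step_size(params, 2e5)
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), 6 * sqrt(pi / 2), tolerance = 0.01)
  expect_equal(var(draws), 6^2 * (2 - pi / 2), tolerance = 0.02)
  expect_error(swim_params(rayleigh_scale = 0), "positive")
})

test_that("the error filter is the stated convex combination with wrapping", {
  st <- swim_state(c(0, 0), heading = 0, ehat = 10)
  expect_equal(update_error_filter(st, 30, swim_params(F = 1)), 30)
  expect_equal(update_error_filter(st, 30, swim_params(F = 0)), 10)
  expect_equal(update_error_filter(st, 30, swim_params(F = 0.5)), 20)
  # error wraps the short way round: desired 350 at heading 0 is -10
  expect_equal(update_error_filter(swim_state(c(0, 0), ehat = 0), 350,
                                   swim_params(F = 1)), -10)
  expect_error(swim_params(F = 1.2), "\\[0, 1\\]")
})

test_that("the control input is gain times filtered error plus noise", {
  st <- swim_state(c(0, 0), ehat = 5)
  expect_equal(control_input(st, swim_params(K = 0, noise_std = 0)), 0)
  expect_equal(control_input(st, swim_params(K = 2, noise_std = 0)), 10)
  set.seed(2)
  u <- replicate(2e4, control_input(st, swim_params(K = 2, noise_std = 12)))
  expect_equal(mean(u), 10, tolerance = 0.05)
  expect_equal(sd(u), 12, tolerance = 0.05)
})

test_that("with all heading-change terms zero the walk is a straight line", {
  params <- swim_params(A1 = 0, A2 = 0, K = 0, noise_std = 0,
                        rayleigh_scale = 2)
  arena <- make_default_arena()
  st <- swim_state(c(0, -50), heading = 0)
  set.seed(3)
  for (i in 1:20) st <- swim_step(st, NULL, params, arena)
  expect_equal(st$heading, 0)
  expect_equal(st$position[1], 0)       # due North: x never changes
  expect_gt(st$position[2], -50)
  # heading 0 moves due North by the step length
  set.seed(4)
  st2 <- swim_step(swim_state(c(0, 0), heading = 0), NULL, params, arena)
  set.seed(4)
  dr <- draw_step_size(params, 1)
  expect_equal(st2$position, c(0, dr))
})

test_that("closed-loop heading converges and matches the linear-system oracle", {
  params <- swim_params(noise_std = 0)
  arena <- make_default_arena()
  # independent oracle: iterate the scalar recursion of the filter, AR
  # and integrator directly
  oracle <- function(h0, desired, n, p) {
    h <- h0; d1 <- 0; d2 <- 0; e <- 0
    out <- numeric(n)
    for (i in seq_len(n)) {
      e <- (1 - p$F) * e + p$F * wrap_angle(desired - h)
      da <- p$A1 * d1 + p$A2 * d2 + p$K * e
      h <- wrap_angle(h + da)
      d2 <- d1; d1 <- da
      out[i] <- h
    }
    out
  }
  st <- swim_state(c(0, 0), heading = 120)
  got <- numeric(40)
  set.seed(5)
  for (i in 1:40) {
    st <- swim_step(st, 0, params, arena)
    got[i] <- st$heading
  }
  expect_equal(got, oracle(120, 0, 40, params), tolerance = 1e-10)
  expect_lt(abs(wrap_angle(got[40])), 1e-4)  # error has decayed to zero
  # geometric decay: error envelope shrinks by a constant factor
  errs <- abs(wrap_angle(got))
  expect_lt(max(errs[30:40]), 1e-3 * max(errs[1:10]))
})

test_that("positions never leave the pool and wall rules behave", {
  params <- swim_params(noise_std = 40, rayleigh_scale = 8)
  arena <- make_default_arena()
  st <- swim_state(c(80, 0), heading = 90)
  set.seed(6)
  for (i in 1:300) {
    st <- swim_step(st, NULL, params, arena)
    expect_lte(sqrt(sum(st$position^2)), arena$pool_radius + 1e-9)
  }
  # clamp puts an exiting step exactly on the wall
  p_out <- c(100, 0)
  expect_equal(sqrt(sum(apply_boundary(p_out, 85, "clamp")^2)), 85)
  expect_equal(apply_boundary(p_out, 85, "reflect"), c(70, 0))
  expect_equal(apply_boundary(c(10, 10), 85, "clamp"), c(10, 10))
})

test_that("headings are invariant under adding full turns", {
  params <- swim_params()
  arena <- make_default_arena()
  st1 <- swim_state(c(10, 10), heading = 30)
  st2 <- swim_state(c(10, 10), heading = 30 + 360)
  set.seed(7); a <- swim_step(st1, 90, params, arena)
  set.seed(7); b <- swim_step(st2, 90, params, arena)
  expect_equal(a$position, b$position)
  expect_equal(wrap_angle(a$heading), wrap_angle(b$heading))
  expect_equal(wrap_angle(c(190, -190, 360, 180)), c(-170, 170, 0, 180))
})

test_that("an uninformed trial reproduces the bare swim recursion step by step", {
  arena <- make_default_arena()
  params <- swim_params()
  naive <- learning_state(names(arena$cues))
  set.seed(11)
  rec <- simulate_trial(naive, arena, params, "N", platform_present = FALSE)
  # emulate: every episode consumes one selection draw, then n_steps of
  # undirected swim_step
  set.seed(11)
  st <- swim_state(start_position("N", arena),
                   heading = bearing_to(start_position("N", arena), c(0, 0)))
  n_eps <- ceiling(nrow(rec$trajectory) / params$n_steps)
  pos <- matrix(NA_real_, 0, 2)
  for (ep in seq_len(n_eps)) {
    runif(1) # cue-selection draw (always "none" for a naive state)
    for (k in seq_len(params$n_steps)) {
      st <- swim_step(st, NULL, params, arena)
      pos <- rbind(pos, st$position)
    }
  }
  n <- nrow(rec$trajectory)
  expect_equal(rec$trajectory$x, pos[seq_len(n), 1])
  expect_equal(rec$trajectory$y, pos[seq_len(n), 2])
})
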