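test_that("strength update follows the enact/fail rules with fixed points", {
  p <- default_params
  expect_equal(update_strength(2 / 7, 1, p), 2 / 7 + 0.1 * (5 / 7))
  expect_equal(update_strength(2 / 7, 0, p), 0.9 * (2 / 7))
  # fixed points of the two rules
  expect_identical(update_strength(1, 1, p), 1)
  expect_identical(update_strength(0, 0, p), 0)
  # vectorized, stays in [0,1]
  s <- seq(0, 1, length.out = 51)
  expect_true(all(update_strength(s, 1, p) >= s))
  expect_true(all(update_strength(s, 0, p) <= s))
  expect_true(all(update_strength(s, 1, p) <= 1))
  expect_true(all(update_strength(s, 0, p) >= 0))
  expect_error(update_strength(1.5, 1, p), "0, 1")
  expect_error(update_strength(0.5, 2, p), "action")
})

test_that("repeated enactments converge to 1 and repeated failures to 0", {
  p <- default_params
  for (s0 in c(0.001, 0.3, 0.95)) {
    up <- Reduce(function(s, .) update_strength(s, 1, p), seq_len(200),
                 init = s0, accumulate = TRUE)
    expect_true(all(diff(up) > 0))
    expect_lt(abs(up[201] - 1), 1e-8)
    down <- Reduce(function(s, .) update_strength(s, 0, p), seq_len(200),
                   init = s0, accumulate = TRUE)
    expect_true(all(diff(down) < 0))
    expect_lt(down[201], 1e-8)
  }
})

test_that("enactments-to-goal reproduces the nonmonotone counts near 0.09", {
  p <- default_params
  expect_identical(n_to_goal(0.9, p), 0L)
  expect_identical(n_to_goal(0.09, p), 21L)
  expect_identical(n_to_goal(update_strength(0.09, 0, p), p), 22L)
  expect_identical(n_to_goal(0.08, p), 22L)
  expect_identical(n_to_goal(update_strength(0.08, 0, p), p), 22L)
  expect_identical(n_to_goal(0.10, p), 21L)
  expect_identical(n_to_goal(update_strength(0.10, 0, p), p), 21L)
  expect_identical(n_to_goal(0, p), 22L)
})

test_that("closed-form count equals brute-force iteration across parameters", {
  grid <- seq(0, 1, length.out = 101)
  sweep <- param_sweep()
  for (i in seq_len(nrow(sweep))) {
    p <- habit_params(alpha = sweep$alpha[i], theta = sweep$theta[i])
    bf <- vapply(grid, brute_force_n, integer(1), params = p)
    expect_identical(n_to_goal(grid, p), bf,
                     label = sprintf("alpha=%g theta=%g", p$alpha, p$theta))
  }
})

test_that("value-to-go matches the per-step cost summation", {
  p <- default_params
  expect_identical(value_to_go(0.9, p), 0)
  expect_equal(value_to_go(2 / 7, p), -6.17797, tolerance = 1e-4)
  expect_equal(value_to_go(0.9 * 2 / 7, p), -6.52543, tolerance = 1e-4)
  grid <- seq(0, 1, length.out = 101)
  bf <- vapply(grid, brute_force_value, numeric(1), params = p)
  expect_equal(value_to_go(grid, p), bf, tolerance = 1e-12)
  # goal_reward shifts every value by the same constant
  p10 <- habit_params(goal_reward = 10)
  expect_equal(value_to_go(grid, p10) - value_to_go(grid, p), rep(10, 101))
})

test_that("long-term benefit of enacting collapses to 1 - s below threshold", {
  p <- default_params
  s <- seq(0, p$theta - 1e-6, length.out = 1e4)
  f1 <- long_term_benefit(s, 1, p)
  expect_lt(max(abs(f1 - (1 - s))), 1e-9)
  expect_identical(long_term_benefit(0, 0, p), 0)
  expect_equal(long_term_benefit(0.25, 1, p), 0.75)
  expect_equal(long_term_benefit(2 / 7, 0, p), -0.34747, tolerance = 1e-4)
  expect_true(all(long_term_benefit(s, 0, p) <= 0))
})

test_that("point feedback reproduces the worked example and its sign bounds", {
  p <- default_params
  expect_identical(compute_points(2 / 7, 1, p), 9L)
  expect_identical(compute_points(2 / 7, 0, p), -4L)
  expect_identical(compute_points(p$theta, 1, p), 0L)
  expect_identical(compute_points(0, 1, p), 13L)
  s <- seq(0, p$theta, length.out = 500)
  pe <- compute_points(s, 1, p)
  pf <- compute_points(s, 0, p)
  expect_true(all(diff(pe) <= 0)) # non-increasing in strength
  expect_true(all(pe >= 0) && all(pf <= 0))
  expect_true(all(abs(pe) <= p$max_points) && all(abs(pf) <= p$max_points))
})

test_that("points are invariant to the goal reward", {
  s <- seq(0, 0.9, length.out = 200)
  base <- compute_points(s, 0, habit_params(goal_reward = 0))
  for (r in c(1, 10)) {
    p <- habit_params(goal_reward = r)
    expect_identical(compute_points(s, 0, p), base)
    expect_identical(compute_points(s, 1, p),
                     compute_points(s, 1, habit_params()))
  }
})

test_that("rounding modes diverge on the failure penalty at 2/7", {
  # exact scaled benefit is ~ -4.517: truncation gives -4, nearest -5
  exact <- 13 * long_term_benefit(2 / 7, 0, default_params)
  expect_equal(exact, -4.517, tolerance = 1e-3)
  expect_identical(
    compute_points(2 / 7, 0, habit_params(rounding_mode = "truncate_toward_zero")),
    -4L)
  expect_identical(
    compute_points(2 / 7, 0, habit_params(rounding_mode = "nearest_half_away")),
    -5L)
  # both modes agree on the enactment reward there
  expect_identical(
    compute_points(2 / 7, 1, habit_params(rounding_mode = "nearest_half_away")),
    9L)
})

test_that("feedback_result obeys the per-action sign invariants", {
  p <- default_params
  for (s in c(0, 0.2, 2 / 7, 0.6, 0.89, 0.95)) {
    r1 <- feedback_result(s, 1, p)
    expect_gte(r1$points_delta, 0L)
    expect_gte(r1$strength_after, r1$strength_before)
    r0 <- feedback_result(s, 0, p)
    expect_lte(r0$points_delta, 0L)
    expect_lte(r0$strength_after, r0$strength_before)
  }
})

test_that("initial strength is the previous week's relative frequency", {
  expect_identical(init_strength(0), 0)
  expect_identical(init_strength(2), 2 / 7)
  expect_identical(init_strength(7), 1)
  expect_identical(init_strength(0:7), 0:7 / 7)
  expect_error(init_strength(8), "between 0 and 7")
  expect_error(init_strength(-1), "between 0 and 7")
  expect_error(init_strength(2.5), "between 0 and 7")
  # strength 1 from a 7/7 week yields 0-point feedback, not an error
  expect_identical(compute_points(init_strength(7), 1, default_params), 0L)
})

test_that("point curve spans [0, theta] with the documented shape", {
  curve <- point_curve(default_params, grid_step = 0.1)
  expect_s3_class(curve, "habit_point_curve")
  expect_identical(names(curve), c("strength", "points_enact", "points_fail"))
  expect_identical(curve$strength[1], 0)
  expect_equal(curve$strength[nrow(curve)], 0.9)
  expect_identical(curve$points_enact[1], 13L)
  expect_identical(curve$points_enact[nrow(curve)], 0L)
  expect_true(all(curve$points_enact >= 0 & curve$points_fail <= 0))
})

test_that("failure penalty is approximately linear with slope -M", {
  curve <- point_curve(default_params, grid_step = 0.01)
  slope <- unname(coef(lm(points_fail ~ strength, data = curve))["strength"])
  expect_lt(abs(slope - (-13)) / 13, 0.15)
})

test_that("point curve CSV uses the documented header and 6-decimal strengths", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_point_curve(point_curve(default_params, grid_step = 0.1), path)
  lines <- readLines(path)
  expect_identical(lines[1], "strength,points_enact,points_fail")
  expect_identical(lines[2], "0.000000,13,0")
  back <- read.csv(path)
  expect_equal(nrow(back), 10)
})

test_that("model parameters validate their domains and round-trip to disk", {
  expect_error(habit_params(alpha = 0), "alpha")
  expect_error(habit_params(alpha = 1), "alpha")
  expect_error(habit_params(theta = 1.2), "theta")
  expect_error(habit_params(max_points = 0), "max_points")
  expect_error(habit_params(max_points = 2.5), "max_points")
  expect_error(habit_params(goal_reward = -1), "goal_reward")
  expect_error(habit_params(rounding_mode = "banker"), "should be one of")

  p <- habit_params(alpha = 0.2, theta = 0.8, max_points = 10,
                    goal_reward = 5, rounding_mode = "nearest_half_away")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_habit_params(p, yml)
  expect_equal(read_habit_params(yml), p)
  jsn <- withr::local_tempfile(fileext = ".json")
  write_habit_params(p, jsn)
  expect_equal(read_habit_params(jsn), p)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("alpha: 0.1\nbogus: 3", bad)
  expect_error(read_habit_params(bad), "unknown config keys")
})
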