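#' Habit-strength update rule
#'
#' One step of the habit dynamics. Enacting the behavior closes a
#' fraction `alpha` of the remaining gap to full strength,
#' `s + alpha * (1 - s)`; failing to enact decays the strength
#' proportionally to `s * (1 - alpha)`. Both rules map `[0, 1]` into
#' itself, with fixed points at 1 (enactment) and 0 (failure).
#'
#' @param strength Habit strength in `[0, 1]`. Vectorized.
#' @param action 0 (not enacted) or 1 (enacted); recycled against
#'   `strength`.
#' @param params A [habit_params()] object.
#' @return Updated strength, same length as `strength`.
#' @examples
#' update_strength(2 / 7, action = 1)
#' update_strength(2 / 7, action = 0)
#' @export
update_strength <- function(strength, action, params = habit_params()) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  action <- check_action(action)
  n <- max(length(strength), length(action))
  strength <- rep_len(strength, n)
  action <- rep_len(action, n)
  out <- numeric(n)
  up <- action == 1L
  out[up] <- strength[up] + params$alpha * (1 - strength[up])
  out[!up] <- strength[!up] * (1 - params$alpha)
  out
}

# Strength after n successive enactments, in closed form:
# 1 - (1 - s) (1 - alpha)^n.
strength_after_n <- function(strength, n, alpha) {
  1 - (1 - strength) * (1 - alpha)^n
}

#' Number of enactments needed to reach the target strength
#'
#' The smallest `n >= 0` such that `n` successive enactment updates
#' starting from `strength` produce a value at least `theta - eps`.
#' Computed from the closed form
#' `ceiling(log((1 - theta) / (1 - s)) / log(1 - alpha))` with an
#' `eps` guard, then adjusted against the exact post-`n` strength so
#' that ties on the ceiling boundary resolve to the iterative
#' definition (see [brute_force_n()]).
#'
#' This count is what makes the failure penalty nonmonotone in
#' strength: a failure at 0.09 (with `alpha = 0.1`, `theta = 0.9`)
#' pushes the count from 21 to 22, while at 0.08 or 0.10 a failure
#' leaves it at 22 or 21.
#'
#' @inheritParams update_strength
#' @return Integer vector of enactment counts, 0 where
#'   `strength >= theta - eps`.
#' @examples
#' n_to_goal(0.09)
#' n_to_goal(update_strength(0.09, 0))
#' @export
n_to_goal <- function(strength, params = habit_params()) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  alpha <- params$alpha
  theta <- params$theta
  eps <- params$eps

  n <- integer(length(strength))
  todo <- strength < theta - eps
  if (!any(todo)) return(n)

  s <- strength[todo]
  raw <- log((1 - theta) / (1 - s)) / log(1 - alpha)
  cand <- pmax(as.integer(ceiling(raw - eps)), 0L)
  # settle boundary cases by the definitional criterion
  repeat {
    dec <- cand > 0L & strength_after_n(s, cand - 1L, alpha) >= theta - eps
    if (!any(dec)) break
    cand[dec] <- cand[dec] - 1L
  }
  repeat {
    inc <- strength_after_n(s, cand, alpha) < theta - eps
    if (!any(inc)) break
    cand[inc] <- cand[inc] + 1L
  }
  n[todo] <- cand
  n
}

#' Value-to-go of following through with habit building
#'
#' The total future reward of holding a habit of the given strength and
#' then enacting it on every remaining occasion until the strength
#' reaches `theta`: the goal reward minus the accumulated effort costs
#' `1 - s_k` along the enactment trajectory. With `n = n_to_goal(s)`
#' the geometric trajectory gives the closed form
#' `r_goal - (1 - s) * (1 - (1 - alpha)^n) / alpha`; at or above
#' `theta` the value is `r_goal` exactly.
#'
#' @inheritParams update_strength
#' @return Numeric vector of values.
#' @examples
#' value_to_go(2 / 7)
#' @export
value_to_go <- function(strength, params = habit_params()) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  n <- n_to_goal(strength, params)
  v <- params$goal_reward -
    (1 - strength) * (1 - (1 - params$alpha)^n) / params$alpha
  v[n == 0L] <- params$goal_reward
  v
}

#' Long-term benefit of an action
#'
#' The change in value-to-go induced by taking the action at the given
#' strength, `f(s, a) = V(update(s, a)) - V(s)`. For enactment below
#' the threshold this collapses analytically to `1 - s`; for failure it
#' is nonpositive, with `f(0, 0) = 0` (failure at zero strength is the
#' identity). This is the potential-based shaping term that, scaled by
#' the maximal point value, becomes the point feedback.
#'
#' @inheritParams update_strength
#' @return Numeric vector of value differences.
#' @examples
#' long_term_benefit(0.25, 1) # = 1 - 0.25
#' long_term_benefit(2 / 7, 0)
#' @export
long_term_benefit <- function(strength, action, params = habit_params()) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  action <- check_action(action)
  value_to_go(update_strength(strength, action, params), params) -
    value_to_go(strength, params)
}

integerize <- function(x, mode) {
  switch(mode,
    truncate_toward_zero = trunc(x),
    nearest_half_away = sign(x) * floor(abs(x) + 0.5),
    abort(sprintf("unknown rounding_mode: %s", mode))
  )
}

#' Optimized point feedback for a reported action
#'
#' The integer number of points awarded (enactment) or deducted
#' (failure) at the given habit strength: the long-term benefit
#' `f(s, a)` scaled by the maximal point value `M` and integerized
#' under the configured rounding mode. Points for enacting are
#' nonnegative and non-increasing in strength (from `M` at `s = 0` to
#' 0 at `theta`); points for failing are nonpositive. Because `|f|`
#' never exceeds 1 on `[0, theta]`, the magnitude is bounded by `M`.
#'
#' With the defaults (`alpha = 0.1`, `theta = 0.9`, `M = 13`) a user
#' initialized at 2/7 earns +9 points for enacting and loses 4 points
#' for failing.
#'
#' @inheritParams update_strength
#' @return Integer vector of point deltas.
#' @examples
#' compute_points(2 / 7, 1) # 9
#' compute_points(2 / 7, 0) # -4
#' @export
compute_points <- function(strength, action, params = habit_params()) {
  params <- as_habit_params(params)
  f <- long_term_benefit(strength, action, params)
  as.integer(integerize(params$max_points * f, params$rounding_mode))
}

#' Apply one report to a habit state
#'
#' Computes the point feedback on the pre-update strength (points are a
#' function of the state in which the action was taken), then applies
#' the strength update. Returns a one-row tibble describing the
#' transition.
#'
#' @param strength Habit strength before the report.
#' @param action 0 or 1.
#' @param params A [habit_params()] object.
#' @return A tibble with columns `action`, `points_delta`,
#'   `strength_before`, `strength_after`, and `benefit` (the value
#'   difference `f(s, a)` before scaling).
#' @export
feedback_result <- function(strength, action, params = habit_params()) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  action <- check_action(action)
  tibble::tibble(
    action = action,
    points_delta = compute_points(strength, action, params),
    strength_before = strength,
    strength_after = update_strength(strength, action, params),
    benefit = long_term_benefit(strength, action, params)
  )
}

#' Initial habit strength from last week's behavior
#'
#' Initializes the habit strength as the relative frequency of the
#' behavior over the previous 7 days, `days / 7`. A count of 7 yields
#' strength 1, which already exceeds the default threshold and simply
#' produces 0-point feedback; no capping is applied.
#'
#' @param days_enacted_last_week Integer count in `0..7`. Vectorized.
#' @return Numeric strength in `[0, 1]`.
#' @examples
#' init_strength(2) # 2/7
#' @export
init_strength <- function(days_enacted_last_week) {
  d <- days_enacted_last_week
  if (!is.numeric(d) || length(d) == 0L || anyNA(d) ||
      any(d != trunc(d)) || any(d < 0) || any(d > 7)) {
    abort("`days_enacted_last_week` must be an integer between 0 and 7.")
  }
  as.numeric(d) / 7
}

#' Tabulate point feedback over a strength grid
#'
#' Evaluates the point feedback for both actions on a uniform strength
#' grid over `[0, theta]`, the table behind the point-curve figure.
#' The enactment curve is non-increasing from `M` at strength 0 down
#' to 0 at `theta`; the failure curve is nonpositive and, although it
#' changes erratically where the enactments-to-goal count jumps, is
#' well approximated by a straight line of slope `-M` (the same slope
#' as the enactment curve).
#'
#' @param params A [habit_params()] object.
#' @param grid_step Grid spacing in `(0, 1)`.
#' @return A tibble of class `habit_point_curve` with columns
#'   `strength`, `points_enact`, `points_fail`.
#' @examples
#' point_curve(grid_step = 0.1)
#' @export
point_curve <- function(params = habit_params(), grid_step = 0.01) {
  params <- as_habit_params(params)
  if (!is.numeric(grid_step) || length(grid_step) != 1L ||
      is.na(grid_step) || grid_step <= 0 || grid_step >= 1) {
    abort("`grid_step` must be a single number in (0, 1).")
  }
  s <- seq(0, params$theta, by = grid_step)
  if (s[length(s)] < params$theta - params$eps) s <- c(s, params$theta)
  out <- tibble::tibble(
    strength = s,
    points_enact = compute_points(s, 1L, params),
    points_fail = compute_points(s, 0L, params)
  )
  class(out) <- c("habit_point_curve", class(out))
  out
}

#' Write a point curve as CSV
#'
#' Header `strength,points_enact,points_fail`; strength printed with 6
#' decimals.
#'
#' @param curve A [point_curve()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_point_curve <- function(curve, path) {
  stopifnot(all(c("strength", "points_enact", "points_fail") %in%
                  names(curve)))
  out <- data.frame(
    strength = sprintf("%.6f", curve$strength),
    points_enact = curve$points_enact,
    points_fail = curve$points_fail
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
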