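#' Model parameters for the habit-formation MDP
#'
#' Bundles the parameters of the habit-formation model and the numeric
#' policy knobs used when value differences are converted to integer
#' points. The defaults reproduce the example application: a learning
#' rate of 0.1, a target habit strength of 0.9, and a maximal point
#' value of 13.
#'
#' @param alpha Learning rate in (0, 1): the fraction of the remaining
#'   gap to full strength closed by one enactment, and the proportional
#'   decay applied on a failure.
#' @param theta Target habit strength in (0, 1) at which the habit
#'   counts as cultivated and the goal reward accrues.
#' @param max_points Maximal point value `M` (positive integer) used to
#'   scale long-term benefits into points.
#' @param goal_reward Reward attained when the habit strength crosses
#'   `theta`. It shifts every value-to-go by the same constant and
#'   therefore cancels out of all point computations; it is retained so
#'   values can be reported on an interpretable scale.
#' @param rounding_mode How `max_points * f(s, a)` is integerized:
#'   `"truncate_toward_zero"` (default) or `"nearest_half_away"`
#'   (round half away from zero).
#' @param eps Comparison tolerance used when testing whether the
#'   strength has reached `theta`, guarding against floating-point
#'   landings exactly on a ceiling boundary.
#'
#' @return An object of class `habit_params` (a named list).
#' @examples
#' p <- habit_params()
#' compute_points(2 / 7, action = 1, params = p)
#' @export
habit_params <- function(alpha = 0.1,
                         theta = 0.9,
                         max_points = 13L,
                         goal_reward = 0,
                         rounding_mode = c("truncate_toward_zero",
                                           "nearest_half_away"),
                         eps = 1e-12) {
  rounding_mode <- match.arg(rounding_mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta >= 1) {
    abort("`theta` must be a single number in (0, 1).")
  }
  if (!is.numeric(max_points) || length(max_points) != 1L ||
      is.na(max_points) || max_points < 1 ||
      max_points != trunc(max_points)) {
    abort("`max_points` must be a positive integer.")
  }
  if (!is.numeric(goal_reward) || length(goal_reward) != 1L ||
      is.na(goal_reward) || goal_reward < 0) {
    abort("`goal_reward` must be a single nonnegative number.")
  }
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) || eps <= 0) {
    abort("`eps` must be a small positive number.")
  }
  structure(
    list(alpha = as.numeric(alpha),
         theta = as.numeric(theta),
         max_points = as.integer(max_points),
         goal_reward = as.numeric(goal_reward),
         rounding_mode = rounding_mode,
         eps = as.numeric(eps)),
    class = "habit_params"
  )
}

#' @export
print.habit_params <- function(x, ...) {
  cat("<habit_params>\n")
  cat(sprintf("  alpha (learning rate):   %g\n", x$alpha))
  cat(sprintf("  theta (target strength): %g\n", x$theta))
  cat(sprintf("  max_points (M):          %d\n", x$max_points))
  cat(sprintf("  goal_reward:             %g\n", x$goal_reward))
  cat(sprintf("  rounding_mode:           %s\n", x$rounding_mode))
  cat(sprintf("  eps:                     %g\n", x$eps))
  invisible(x)
}

as_habit_params <- function(params) {
  if (inherits(params, "habit_params")) return(params)
  if (is.list(params)) return(do.call(habit_params, params))
  abort("`params` must be a `habit_params` object or a named list.")
}

#' Read or write model parameters as a YAML/JSON config block
#'
#' The on-disk representation is a flat mapping with keys `alpha`,
#' `theta`, `max_points`, `goal_reward`, `rounding_mode` (and optionally
#' `eps`). The format is inferred from the file extension: `.json` is
#' JSON, anything else is parsed as YAML (of which plain key: value
#' lines are a subset).
#'
#' @param path File path.
#' @param params A [habit_params()] object.
#' @return `read_habit_params()` returns a `habit_params` object;
#'   `write_habit_params()` returns `path` invisibly.
#' @export
read_habit_params <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("alpha", "theta", "max_points", "goal_reward",
             "rounding_mode", "eps")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(habit_params, raw)
}

#' @rdname read_habit_params
#' @export
write_habit_params <- function(params, path) {
  params <- as_habit_params(params)
  fields <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fields, path)
  }
  invisible(path)
}

check_strength <- function(strength, eps = 1e-9) {
  if (!is.numeric(strength) || length(strength) == 0L || anyNA(strength)) {
    abort("`strength` must be numeric in [0, 1] with no missing values.")
  }
  if (any(strength < -eps) || any(strength > 1 + eps)) {
    abort("`strength` must lie in [0, 1].")
  }
  pmin(pmax(strength, 0), 1)
}

check_action <- function(action) {
  if (!is.numeric(action) || length(action) == 0L || anyNA(action) ||
      !all(action %in% c(0, 1))) {
    abort("`action` must be 0 (not enacted) or 1 (enacted).")
  }
  as.integer(action)
}
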