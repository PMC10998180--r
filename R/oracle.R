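#' Brute-force enactment count
#'
#' Independent check of [n_to_goal()]: repeatedly applies the
#' enactment update `s <- s + alpha * (1 - s)` and counts steps until
#' the strength reaches `theta - eps`. Deliberately shares no code
#' with the closed form.
#'
#' @param strength Habit strength in `[0, 1]` (scalar).
#' @param params A [habit_params()] object.
#' @param max_iter Iteration cap; exceeded caps signal a parameter
#'   pathology (e.g. `alpha` near 0) rather than returning a count.
#' @return Integer count of enactments.
#' @export
brute_force_n <- function(strength, params = habit_params(),
                          max_iter = 1e6) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  stopifnot(length(strength) == 1L)
  s <- strength
  n <- 0L
  while (s < params$theta - params$eps) {
    s <- s + params$alpha * (1 - s)
    n <- n + 1L
    if (n > max_iter) {
      abort(sprintf(
        "brute_force_n exceeded %d iterations (alpha = %g, theta = %g)",
        as.integer(max_iter), params$alpha, params$theta))
    }
  }
  n
}

#' Brute-force value-to-go
#'
#' Independent check of [value_to_go()]: simulates the enact-always
#' trajectory step by step, accumulating the per-step reward
#' `-(1 - s_k)`, and adds the goal reward once the threshold is
#' crossed. No closed form is used anywhere.
#'
#' @inheritParams brute_force_n
#' @return The summed reward of following through from `strength`.
#' @export
brute_force_value <- function(strength, params = habit_params(),
                              max_iter = 1e6) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  stopifnot(length(strength) == 1L)
  s <- strength
  total <- 0
  n <- 0L
  while (s < params$theta - params$eps) {
    total <- total - (1 - s)
    s <- s + params$alpha * (1 - s)
    n <- n + 1L
    if (n > max_iter) {
      abort(sprintf(
        "brute_force_value exceeded %d iterations (alpha = %g, theta = %g)",
        as.integer(max_iter), params$alpha, params$theta))
    }
  }
  total + params$goal_reward
}

#' Verify the closed forms against brute force on a grid
#'
#' Compares the closed-form enactment count, value-to-go, and the
#' analytic identity `f(s, 1) = 1 - s` (for `s < theta`) against
#' brute-force iteration on a uniform strength grid over `[0, 1]`.
#' Mismatches are collected into the returned report rather than
#' raised, so a failing run can be inspected.
#'
#' @param params A [habit_params()] object.
#' @param grid_size Number of grid points (at least 2).
#' @param tol Absolute tolerance for the real-valued comparisons;
#'   counts must agree exactly.
#' @param closed_forms Optional named list of functions
#'   `n(strength, params)` and `value(strength, params)` to check in
#'   place of the package's own; used to confirm that the oracle
#'   detects deliberately perturbed closed forms.
#' @return An object of class `oracle_report`: a list with
#'   `grid_size`, `max_abs_error`, `mismatch_count`, and a `details`
#'   tibble of mismatching grid points (`quantity`, `strength`,
#'   `expected`, `got`).
#' @examples
#' verify_closed_forms(grid_size = 101)
#' @export
verify_closed_forms <- function(params = habit_params(),
                                grid_size = 1000L,
                                tol = 1e-9,
                                closed_forms = NULL) {
  params <- as_habit_params(params)
  if (!is.numeric(grid_size) || grid_size < 2) {
    abort("`grid_size` must be an integer >= 2.")
  }
  n_fun <- closed_forms$n %||% n_to_goal
  v_fun <- closed_forms$value %||% value_to_go

  grid <- seq(0, 1, length.out = as.integer(grid_size))
  rows <- list()
  max_err <- 0

  for (s in grid) {
    n_bf <- brute_force_n(s, params)
    n_cf <- n_fun(s, params)
    if (n_cf != n_bf) {
      rows[[length(rows) + 1L]] <- list(quantity = "n_to_goal",
                                        strength = s,
                                        expected = as.numeric(n_bf),
                                        got = as.numeric(n_cf))
    }
    v_bf <- brute_force_value(s, params)
    v_cf <- v_fun(s, params)
    err_v <- abs(v_cf - v_bf)
    max_err <- max(max_err, err_v)
    if (err_v > tol) {
      rows[[length(rows) + 1L]] <- list(quantity = "value_to_go",
                                        strength = s,
                                        expected = v_bf, got = v_cf)
    }
    if (s < params$theta - params$eps) {
      # f(s,1) via the value difference, against the analytic 1 - s
      s_up <- s + params$alpha * (1 - s)
      f_diff <- v_fun(s_up, params) - v_fun(s, params)
      err_f <- abs(f_diff - (1 - s))
      max_err <- max(max_err, err_f)
      if (err_f > tol) {
        rows[[length(rows) + 1L]] <- list(quantity = "benefit_identity",
                                          strength = s,
                                          expected = 1 - s, got = f_diff)
      }
    }
  }

  details <- if (length(rows) > 0) {
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    tibble::tibble(quantity = character(), strength = numeric(),
                   expected = numeric(), got = numeric())
  }
  structure(
    list(grid_size = as.integer(grid_size),
         max_abs_error = max_err,
         mismatch_count = nrow(details),
         details = details,
         params = params,
         tol = tol),
    class = "oracle_report"
  )
}

#' @export
print.oracle_report <- function(x, ...) {
  cat("<oracle_report>\n")
  cat(sprintf("  grid_size:      %d\n", x$grid_size))
  cat(sprintf("  max_abs_error:  %.3g\n", x$max_abs_error))
  cat(sprintf("  mismatch_count: %d\n", x$mismatch_count))
  if (x$mismatch_count > 0) {
    cat("  first mismatches:\n")
    print(utils::head(x$details, 5))
  }
  invisible(x)
}

#' @rdname verify_closed_forms
#' @param x An `oracle_report`.
#' @param ... Unused.
#' @export
tidy.oracle_report <- function(x, ...) {
  x$details
}

#' @rdname verify_closed_forms
#' @export
glance.oracle_report <- function(x, ...) {
  tibble::tibble(grid_size = x$grid_size,
                 max_abs_error = x$max_abs_error,
                 mismatch_count = x$mismatch_count,
                 passed = x$mismatch_count == 0L)
}

#' Serialize an oracle report to JSON
#'
#' @param report An `oracle_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oracle_report <- function(report, path) {
  stopifnot(inherits(report, "oracle_report"))
  jsonlite::write_json(
    list(grid_size = report$grid_size,
         max_abs_error = report$max_abs_error,
         mismatch_count = report$mismatch_count,
         details = report$details),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
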