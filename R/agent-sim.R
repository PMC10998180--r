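#' Behavioral profile of a simulated myopic user
#'
#' Parameterizes an agent who cares only about immediate outcomes:
#' the immediate utility of enacting is the effort cost
#' `-effort_weight * (1 - s)` plus `point_utility` times the points
#' the active condition awards, and the utility of skipping is
#' `point_utility` times the skip feedback. Choices are logistic in
#' the utility difference with slope `choice_sharpness` (`Inf` means
#' strict argmax). The utility model and its defaults are this
#' package's own construction for the simulator, not an empirical
#' model of any study population; the defaults are chosen so that all
#' three trial arms produce interior (non-degenerate) enactment rates.
#'
#' @param point_utility Utility per point, `v >= 0`.
#' @param effort_weight Scale of the immediate effort cost
#'   `1 - s`, `>= 0`.
#' @param choice_sharpness Logistic slope `beta >= 0`; `Inf` selects
#'   the higher-utility action deterministically (ties split 50/50).
#' @param text_bonus_positive Point-equivalent utility of a positive
#'   text message (text-feedback arm, enactment).
#' @param text_bonus_neutral Point-equivalent utility of the neutral
#'   message (text-feedback arm, failure).
#' @return An object of class `agent_profile`.
#' @export
agent_profile <- function(point_utility = 0.15,
                          effort_weight = 1,
                          choice_sharpness = 3,
                          text_bonus_positive = 1,
                          text_bonus_neutral = 0) {
  for (nm in c("point_utility", "effort_weight")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite nonnegative number.", nm))
    }
  }
  if (!is.numeric(choice_sharpness) || length(choice_sharpness) != 1L ||
      is.na(choice_sharpness) || choice_sharpness < 0) {
    abort("`choice_sharpness` must be a nonnegative number (Inf allowed).")
  }
  structure(
    list(point_utility = as.numeric(point_utility),
         effort_weight = as.numeric(effort_weight),
         choice_sharpness = as.numeric(choice_sharpness),
         text_bonus_positive = as.numeric(text_bonus_positive),
         text_bonus_neutral = as.numeric(text_bonus_neutral)),
    class = "agent_profile"
  )
}

trial_conditions <- c("optimized", "text_feedback", "baseline")

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% trial_conditions) {
    abort(sprintf("`condition` must be one of: %s",
                  paste(trial_conditions, collapse = ", ")))
  }
  condition
}

# Point-equivalent feedback an agent experiences in each arm.
condition_feedback <- function(strength, action, condition, profile, params) {
  switch(condition,
    optimized = as.numeric(compute_points(strength, action, params)),
    text_feedback = if (action == 1L) profile$text_bonus_positive
                    else profile$text_bonus_neutral,
    baseline = 0
  )
}

#' One myopic choice
#'
#' Computes the immediate utilities of enacting versus skipping under
#' the given arm's feedback and returns 1 (enact) with probability
#' `plogis(beta * (U1 - U0))`. With optimized point feedback the
#' utility difference is positive at every strength below the
#' threshold (for the default parameters), so even a strictly myopic
#' agent follows through — the incentive-alignment property the point
#' scheme is designed for. In the baseline arm feedback is absent, so
#' a myopic agent with any positive effort weight never enacts.
#'
#' @param strength Habit strength in `[0, 1]` (scalar).
#' @param condition One of `"optimized"`, `"text_feedback"`,
#'   `"baseline"`.
#' @param profile An [agent_profile()].
#' @param params A [habit_params()] object.
#' @return `enactment_probability()` returns the probability of
#'   enacting; `myopic_choice()` returns 0 or 1, drawing one uniform
#'   from the current RNG stream when the probability is interior.
#' @export
myopic_choice <- function(strength, condition, profile = agent_profile(),
                          params = habit_params()) {
  p <- enactment_probability(strength, condition, profile, params)
  as.integer(runif(1) < p)
}

#' @rdname myopic_choice
#' @export
enactment_probability <- function(strength, condition,
                                  profile = agent_profile(),
                                  params = habit_params()) {
  params <- as_habit_params(params)
  strength <- check_strength(strength)
  stopifnot(length(strength) == 1L)
  condition <- check_condition(condition)

  u1 <- -profile$effort_weight * (1 - strength) + profile$point_utility *
    condition_feedback(strength, 1L, condition, profile, params)
  u0 <- profile$point_utility *
    condition_feedback(strength, 0L, condition, profile, params)
  d <- u1 - u0
  if (is.infinite(profile$choice_sharpness)) {
    (d > 0) + 0.5 * (d == 0)
  } else {
    plogis(profile$choice_sharpness * d)
  }
}

# Run a block with a locally seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one participant-by-day trajectory
#'
#' Iterates the daily cycle for a simulated myopic user: choose via
#' [myopic_choice()], score the choice with the engine's points
#' (optimized arm only; other arms carry no points), then update the
#' habit strength. Points are computed on the pre-update strength.
#'
#' @param condition Arm label.
#' @param profile An [agent_profile()].
#' @param params A [habit_params()] object.
#' @param days Number of intervention days (default 21).
#' @param initial_strength Starting habit strength.
#' @param seed Optional integer; when given, the trajectory is
#'   reproducible bit-for-bit and the caller's RNG stream is left
#'   untouched.
#' @return A tibble with one row per day: `day`, `enacted`,
#'   `points_delta`, `strength_before`, `strength_after`,
#'   `score_after`.
#' @export
simulate_participant <- function(condition,
                                 profile = agent_profile(),
                                 params = habit_params(),
                                 days = 21L,
                                 initial_strength = 0,
                                 seed = NULL) {
  params <- as_habit_params(params)
  condition <- check_condition(condition)
  if (!is.numeric(days) || length(days) != 1L || days < 1) {
    abort("`days` must be a positive integer.")
  }
  days <- as.integer(days)
  s0 <- check_strength(initial_strength)

  with_local_seed(seed, {
    enacted <- integer(days)
    pts <- integer(days)
    s_before <- numeric(days)
    s_after <- numeric(days)
    score <- integer(days)
    s <- s0
    total <- 0L
    for (d in seq_len(days)) {
      a <- myopic_choice(s, condition, profile, params)
      p <- if (condition == "optimized") {
        compute_points(s, a, params)
      } else 0L
      s_before[d] <- s
      s <- update_strength(s, a, params)
      s_after[d] <- s
      enacted[d] <- a
      pts[d] <- p
      total <- total + p
      score[d] <- total
    }
    tibble::tibble(day = seq_len(days), enacted = enacted,
                   points_delta = pts, strength_before = s_before,
                   strength_after = s_after, score_after = score)
  })
}

#' Configuration of a synthetic three-arm trial
#'
#' Mirrors the study design being emulated: three arms (optimized
#' point feedback, text-only feedback, bare baseline), a 21-day
#' intervention, and initial strengths of `k/7` with `k` drawn
#' uniformly from `init_days_range` — the support of the onboarding
#' question about the previous week.
#'
#' @param arms Character vector of arm labels (subset of
#'   `"optimized"`, `"text_feedback"`, `"baseline"`).
#' @param n_per_arm Participants per arm.
#' @param days Intervention length in days.
#' @param params A [habit_params()] object.
#' @param agent An [agent_profile()].
#' @param init_days_range Inclusive integer range for the
#'   days-enacted-last-week draw behind the initial strength.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(arms = trial_conditions,
                         n_per_arm = 50L,
                         days = 21L,
                         params = habit_params(),
                         agent = agent_profile(),
                         init_days_range = c(0L, 4L)) {
  arms <- vapply(arms, check_condition, character(1), USE.NAMES = FALSE)
  if (n_per_arm < 1 || days < 1) {
    abort("`n_per_arm` and `days` must be at least 1.")
  }
  if (length(init_days_range) != 2L || init_days_range[1] > init_days_range[2] ||
      any(init_days_range < 0) || any(init_days_range > 7)) {
    abort("`init_days_range` must be an increasing pair within 0..7.")
  }
  structure(
    list(arms = arms, n_per_arm = as.integer(n_per_arm),
         days = as.integer(days), params = as_habit_params(params),
         agent = agent, init_days_range = as.integer(init_days_range)),
    class = "trial_config"
  )
}

# Deterministic per-participant substream: depends only on the root
# seed, the arm, and the participant index, so increasing n_per_arm
# never reshuffles earlier participants.
participant_seed <- function(seed, arm_index, index) {
  as.integer((abs(seed) * 1009 + arm_index * 97003 + index) %%
               .Machine$integer.max)
}

#' Simulate a three-arm synthetic trial
#'
#' Runs [simulate_participant()] for every participant in every arm of
#' the configuration, each on its own deterministic RNG substream
#' derived from `seed`, and summarizes enactment counts per arm.
#'
#' @param config A [trial_config()].
#' @param seed Integer root seed.
#' @return An object of class `habit_trial`: a list with
#'   `participants` (tibble: `participant`, `arm`, `days`,
#'   `enactments`, `final_strength`, `final_score`), `summary`
#'   (tibble: per-arm n, mean and SD of enactment counts, mean final
#'   strength), and the `config` and `seed` used. [tidy()] returns the
#'   participant table, [glance()] the per-arm summary.
#' @export
simulate_trial <- function(config = trial_config(), seed = 1L) {
  stopifnot(inherits(config, "trial_config"))
  rows <- purrr::map2_dfr(
    rep(config$arms, each = config$n_per_arm),
    rep(seq_len(config$n_per_arm), times = length(config$arms)),
    function(arm, i) {
      arm_index <- match(arm, trial_conditions)
      pseed <- participant_seed(seed, arm_index, i)
      lo <- config$init_days_range[1]
      hi <- config$init_days_range[2]
      traj <- with_local_seed(pseed, {
        k <- sample(lo:hi, 1L)
        s0 <- init_strength(k)
        simulate_participant(arm, config$agent, config$params,
                             config$days, s0, seed = NULL)
      })
      tibble::tibble(
        participant = sprintf("%s_%03d", arm, i),
        arm = arm,
        days = config$days,
        enactments = sum(traj$enacted),
        final_strength = traj$strength_after[config$days],
        final_score = traj$score_after[config$days]
      )
    })
  summary <- rows |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_enactments = mean(.data$enactments),
      sd_enactments = stats::sd(.data$enactments),
      mean_final_strength = mean(.data$final_strength),
      .groups = "drop"
    )
  structure(list(participants = rows, summary = summary,
                 config = config, seed = as.integer(seed)),
            class = "habit_trial")
}

#' @export
print.habit_trial <- function(x, ...) {
  cat(sprintf("<habit_trial> %d arms x %d participants, %d days, seed %d\n",
              length(x$config$arms), x$config$n_per_arm,
              x$config$days, x$seed))
  print(x$summary)
  invisible(x)
}

#' @rdname simulate_trial
#' @param x A `habit_trial`.
#' @param ... Unused.
#' @export
tidy.habit_trial <- function(x, ...) {
  x$participants
}

#' @rdname simulate_trial
#' @export
glance.habit_trial <- function(x, ...) {
  x$summary
}

#' Write trial outputs to disk
#'
#' @param trial A [simulate_trial()] result.
#' @param csv Optional path for the per-participant CSV (header
#'   `participant,arm,days,enactments,final_strength,final_score`).
#' @param summary_json Optional path for the per-arm summary JSON.
#' @param jsonl Optional path for the participant table as JSONL, one
#'   object per row.
#' @return `trial`, invisibly.
#' @export
write_trial <- function(trial, csv = NULL, summary_json = NULL,
                        jsonl = NULL) {
  stopifnot(inherits(trial, "habit_trial"))
  if (!is.null(csv)) {
    write.csv(trial$participants, csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_json)) {
    jsonlite::write_json(trial$summary, summary_json, digits = NA)
  }
  if (!is.null(jsonl)) {
    lines <- vapply(seq_len(nrow(trial$participants)), function(i) {
      jsonlite::toJSON(as.list(trial$participants[i, ]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, jsonl)
  }
  invisible(trial)
}

#' Read a trial configuration from YAML
#'
#' Top-level keys `arms`, `n_per_arm`, `days`, `init_days_range`, plus
#' nested `params` (see [read_habit_params()] for its keys) and
#' `agent` (keys matching [agent_profile()] arguments).
#'
#' @param path YAML file path.
#' @return A [trial_config()].
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("arms", "n_per_arm", "days", "init_days_range")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  if (!is.null(raw$params)) args$params <- do.call(habit_params, raw$params)
  if (!is.null(raw$agent)) args$agent <- do.call(agent_profile, raw$agent)
  do.call(trial_config, args)
}
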