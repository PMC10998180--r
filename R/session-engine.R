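#' Default trigger moments and message templates
#'
#' The onboarding dialogue offers 8 concrete, recurring daily moments
#' as triggers for the water-drinking habit. Two are the published
#' examples; the remaining six are this package's own placeholders
#' (the deployed bot's full list is not public). Likewise, of the 5
#' rotating congratulatory phrases only "That's wonderful!" is
#' published; the other four are placeholders.
#'
#' Message templates support the placeholders `{points}`, `{total}`,
#' `{amount}`, and `{trigger}`.
#'
#' @return `default_trigger_moments()`: a character vector of length
#'   8. `default_message_templates()`: a named character vector.
#' @export
default_trigger_moments <- function() {
  c("when my wake-up alarm rings",
    "when I have the first bite of my lunch",
    "when I sit down at my desk in the morning",
    "when I come home from work",
    "when I start preparing dinner",
    "when I brush my teeth in the evening",
    "when I take my morning break",
    "when I close my laptop for the day")
}

#' @rdname default_trigger_moments
#' @export
default_message_templates <- function() {
  c(positive_1 = "That's wonderful!",
    positive_2 = "Great job!",
    positive_3 = "Well done!",
    positive_4 = "Fantastic, keep it up!",
    positive_5 = "You are doing great!",
    failure = "Okay. Keep going tomorrow!",
    neutral = "OK",
    points_gain = "I am glad to grant you {points} points for keeping a good habit! Your total score is {total} points",
    points_loss = "You lost {points} points. Your total score is {total} points",
    reminder = "Remember your intention: {trigger}, I will drink {amount} glasses of water",
    checkin = "Did you accomplish your goal today to drink {amount} glasses of water?")
}

fill_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template,
                     fixed = TRUE)
  }
  template
}

#' Session configuration for the chatbot engine
#'
#' Transport-agnostic configuration of one chatbot deployment arm.
#' Time is modeled as a day index plus clock-time labels; no real
#' scheduler is attached. The condition decides which template
#' families are active: the optimized arm sends reminders, texts, and
#' points; the text-feedback arm sends reminders and texts only; the
#' baseline arm acknowledges every report with the neutral "OK" and
#' sends no reminders.
#'
#' @param condition `"optimized"`, `"text_feedback"`, or `"baseline"`.
#' @param trigger_moments Character vector of selectable trigger
#'   moments.
#' @param reminder_clock_time Clock-time label for the nightly
#'   reminder (default `"21:00"`, i.e. 9 PM).
#' @param checkin_window_hours Offsets (hours) after the trigger
#'   moment between which the check-in question is asked; default 30
#'   minutes to 2.5 hours.
#' @param starting_score Initial score (default 0; totals may go
#'   negative).
#' @param params A [habit_params()] object.
#' @param message_templates Named character vector of templates; see
#'   [default_message_templates()].
#' @return An object of class `session_config`.
#' @export
session_config <- function(condition = "optimized",
                           trigger_moments = default_trigger_moments(),
                           reminder_clock_time = "21:00",
                           checkin_window_hours = c(0.5, 2.5),
                           starting_score = 0L,
                           params = habit_params(),
                           message_templates = default_message_templates()) {
  condition <- check_condition(condition)
  if (length(checkin_window_hours) != 2L ||
      checkin_window_hours[1] >= checkin_window_hours[2]) {
    abort("`checkin_window_hours` must be an increasing pair of offsets.")
  }
  if (!is.numeric(starting_score) || length(starting_score) != 1L ||
      starting_score != trunc(starting_score)) {
    abort("`starting_score` must be an integer.")
  }
  templates <- default_message_templates()
  templates[names(message_templates)] <- message_templates
  structure(
    list(condition = condition,
         trigger_moments = trigger_moments,
         reminder_clock_time = reminder_clock_time,
         checkin_window_hours = as.numeric(checkin_window_hours),
         starting_score = as.integer(starting_score),
         params = as_habit_params(params),
         message_templates = templates),
    class = "session_config"
  )
}

event_kinds <- c(onboarded = 1L, checkin_asked = 2L, report = 3L,
                 feedback_sent = 4L, reminder_sent = 5L)

new_event <- function(participant, day, event_kind, enacted = NA_integer_,
                      points_delta = NA_integer_,
                      strength_before = NA_real_, strength_after = NA_real_,
                      score_after = NA_integer_,
                      message_key = NA_character_) {
  tibble::new_tibble(
    list(participant = participant, day = as.integer(day),
         event_kind = event_kind, enacted = as.integer(enacted),
         points_delta = as.integer(points_delta),
         strength_before = as.numeric(strength_before),
         strength_after = as.numeric(strength_after),
         score_after = as.integer(score_after),
         message_key = message_key),
    nrow = 1L)
}

#' Start a chatbot session (onboarding)
#'
#' Records the user's chosen trigger moment and amount, and
#' initializes the habit strength from how often they enacted the
#' behavior in the previous 7 days (see [init_strength()]). In
#' non-baseline conditions the first nightly reminder is sent the same
#' evening.
#'
#' @param trigger_choice One of `config$trigger_moments`.
#' @param amount Amount of water (glasses) per enactment; positive.
#' @param days_last_week Integer in `0..7`.
#' @param config A [session_config()].
#' @param participant Participant identifier for the log.
#' @return An object of class `habit_session`: a list with `state`
#'   (`strength`, `score`, `day`, `positive_count`), `log` (event
#'   tibble), `config`, `trigger_moment`, `amount`, `participant`,
#'   and `messages` (texts produced by the last step).
#' @export
onboard <- function(trigger_choice, amount, days_last_week,
                    config = session_config(), participant = "user") {
  stopifnot(inherits(config, "session_config"))
  if (!is.character(trigger_choice) || length(trigger_choice) != 1L ||
      !trigger_choice %in% config$trigger_moments) {
    abort("invalid_trigger: `trigger_choice` must be one of the configured trigger moments.")
  }
  if (!is.numeric(amount) || length(amount) != 1L || is.na(amount) ||
      amount <= 0) {
    abort("invalid_amount: `amount` must be a positive number of glasses.")
  }
  strength <- tryCatch(init_strength(days_last_week),
                       error = function(e) {
                         abort("invalid_count: `days_last_week` must be an integer between 0 and 7.")
                       })
  state <- list(strength = strength, score = config$starting_score,
                day = 0L, positive_count = 0L)
  log <- new_event(participant, 0L, "onboarded",
                   strength_after = strength,
                   score_after = config$starting_score)
  messages <- character()
  if (config$condition != "baseline") {
    log <- dplyr::bind_rows(
      log, new_event(participant, 0L, "reminder_sent",
                     message_key = "reminder"))
    messages <- fill_template(config$message_templates[["reminder"]],
                              list(trigger = trigger_choice,
                                   amount = format(amount)))
  }
  structure(list(state = state, log = log, config = config,
                 trigger_moment = trigger_choice, amount = amount,
                 participant = participant, messages = messages),
            class = "habit_session")
}

#' @export
print.habit_session <- function(x, ...) {
  cat(sprintf("<habit_session> %s arm, day %d, strength %.4f, score %d\n",
              x$config$condition, x$state$day, x$state$strength,
              x$state$score))
  cat(sprintf("  %d log events\n", nrow(x$log)))
  invisible(x)
}

#' Choose the feedback text for a report
#'
#' Positive messages cycle deterministically through the 5
#' congratulatory phrases (index = counter mod 5); the failure message
#' in feedback conditions is always `"Okay. Keep going tomorrow!"`;
#' the baseline condition acknowledges everything with the neutral
#' `"OK"`.
#'
#' @param report 0 or 1.
#' @param condition Arm label.
#' @param rotation_state Nonnegative counter of positive messages sent
#'   so far.
#' @return A message key into the template table.
#' @export
select_feedback_text <- function(report, condition, rotation_state = 0L) {
  condition <- check_condition(condition)
  report <- check_action(report)
  if (condition == "baseline") return("neutral")
  if (report == 1L) {
    paste0("positive_", (rotation_state %% 5L) + 1L)
  } else {
    "failure"
  }
}

#' Advance a session by one daily report
#'
#' Runs one day of the chatbot cycle: the check-in question, the
#' user's report, condition-specific feedback, and (outside the
#' baseline arm) the nightly reminder for the next day. In the
#' optimized arm the points are computed on the strength in which the
#' action was taken, applied to the score, and only then is the
#' strength updated. A missing report (`NA`) leaves the state
#' unchanged and logs an explicit gap.
#'
#' @param session A [onboard()] result.
#' @param report 1 (enacted), 0 (not enacted), or `NA` (no answer).
#' @return The updated `habit_session`; the texts produced this step
#'   are in `$messages`.
#' @export
daily_step <- function(session, report) {
  stopifnot(inherits(session, "habit_session"))
  if (!(length(report) == 1L && (is.na(report) || report %in% c(0, 1)))) {
    abort("`report` must be 0, 1, or NA (no answer).")
  }
  config <- session$config
  state <- session$state
  day <- state$day + 1L
  tpl <- config$message_templates
  messages <- character()
  events <- list(
    new_event(session$participant, day, "checkin_asked",
              message_key = "checkin")
  )
  messages <- c(messages, fill_template(tpl[["checkin"]],
                                        list(amount = format(session$amount))))

  if (is.na(report)) {
    events[[length(events) + 1L]] <-
      new_event(session$participant, day, "report")
  } else {
    report <- check_action(report)
    events[[length(events) + 1L]] <-
      new_event(session$participant, day, "report", enacted = report)

    key <- select_feedback_text(report, config$condition,
                                state$positive_count)
    if (config$condition == "optimized") {
      pts <- compute_points(state$strength, report, config$params)
      new_score <- state$score + pts
      events[[length(events) + 1L]] <-
        new_event(session$participant, day, "feedback_sent",
                  points_delta = pts, score_after = new_score,
                  message_key = key)
      messages <- c(messages, tpl[[key]])
      pts_key <- if (report == 1L) "points_gain" else "points_loss"
      messages <- c(messages, fill_template(
        tpl[[pts_key]], list(points = abs(pts), total = new_score)))
      state$score <- new_score
    } else {
      events[[length(events) + 1L]] <-
        new_event(session$participant, day, "feedback_sent",
                  message_key = key)
      messages <- c(messages, tpl[[key]])
    }
    if (report == 1L && config$condition != "baseline") {
      state$positive_count <- state$positive_count + 1L
    }
    state$strength <- update_strength(state$strength, report,
                                      config$params)
  }

  if (config$condition != "baseline") {
    events[[length(events) + 1L]] <-
      new_event(session$participant, day, "reminder_sent",
                message_key = "reminder")
    messages <- c(messages, fill_template(
      tpl[["reminder"]], list(trigger = session$trigger_moment,
                              amount = format(session$amount))))
  }

  state$day <- day
  session$state <- state
  session$log <- dplyr::bind_rows(c(list(session$log), events))
  session$messages <- messages
  session
}

#' Run a whole session from a report sequence
#'
#' Convenience wrapper: onboards and then applies [daily_step()] to
#' each element of `reports` in order.
#'
#' @param reports Vector of daily reports (0, 1, or `NA`).
#' @inheritParams onboard
#' @return A `habit_session`.
#' @export
run_session <- function(reports, trigger_choice, amount, days_last_week,
                        config = session_config(), participant = "user") {
  session <- onboard(trigger_choice, amount, days_last_week, config,
                     participant)
  for (r in reports) session <- daily_step(session, r)
  session
}

#' Rebuild the session state from its event log
#'
#' Event-sourcing consistency check: re-derives the final strength and
#' score from the onboarding event and the report events alone. For
#' any valid log produced by [onboard()] + [daily_step()], the result
#' equals the incrementally maintained state exactly.
#'
#' @param events An event-log tibble (the `$log` of a session, or one
#'   read back via [read_session_log()]).
#' @param config The [session_config()] the log was produced under.
#' @return A list with `strength`, `score`, `day`, `positive_count`.
#' @export
replay_log <- function(events, config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  req <- c("participant", "day", "event_kind", "enacted", "points_delta",
           "strength_before", "strength_after", "score_after",
           "message_key")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf("malformed log: missing columns %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(events) == 0L || events$event_kind[1] != "onboarded") {
    abort("malformed log: record 1 must be an `onboarded` event.")
  }
  rank <- unname(event_kinds[events$event_kind])
  if (anyNA(rank)) {
    abort(sprintf("malformed log: record %d has unknown event_kind `%s`.",
                  which(is.na(rank))[1],
                  events$event_kind[which(is.na(rank))[1]]))
  }
  key <- events$day * 10L + rank
  bad <- which(diff(key) <= 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed log: record %d out of order.", bad[1] + 1L))
  }

  strength <- events$strength_after[1]
  score <- events$score_after[1]
  positive_count <- 0L
  day <- 0L
  for (i in which(events$event_kind == "report")) {
    day <- events$day[i]
    a <- events$enacted[i]
    if (is.na(a)) next
    if (config$condition == "optimized") {
      score <- score + compute_points(strength, a, config$params)
    }
    if (a == 1L && config$condition != "baseline") {
      positive_count <- positive_count + 1L
    }
    strength <- update_strength(strength, a, config$params)
  }
  day <- max(day, events$day[nrow(events)])
  list(strength = strength, score = as.integer(score), day = day,
       positive_count = positive_count)
}

#' Read and write session logs as JSONL
#'
#' One event per line, keys matching the event-record field names;
#' missing optional fields are omitted from the line and read back as
#' `NA`.
#'
#' @param events An event-log tibble.
#' @param path File path.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns the event tibble.
#' @export
write_session_log <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    row <- as.list(events[i, ])
    row <- row[!vapply(row, is.na, logical(1))]
    jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) abort(sprintf("log file not found: %s", path))
  lines <- readLines(path)
  rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
  purrr::map_dfr(rows, function(r) {
    new_event(participant = r$participant %||% NA_character_,
              day = r$day %||% NA_integer_,
              event_kind = r$event_kind %||% NA_character_,
              enacted = r$enacted %||% NA_integer_,
              points_delta = r$points_delta %||% NA_integer_,
              strength_before = r$strength_before %||% NA_real_,
              strength_after = r$strength_after %||% NA_real_,
              score_after = r$score_after %||% NA_integer_,
              message_key = r$message_key %||% NA_character_)
  })
}
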