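Package: habitpoints
Title: Optimized Gamification of Habit Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models habit formation as a one-dimensional Markov decision
    process and converts differences in value-to-go into integer point
    rewards and penalties, so that a purely myopic user who maximizes
    immediate payoff chooses the actions that are best in the long run.
    Includes a brute-force verification oracle for every closed form, a
    myopic-agent simulator with a three-arm synthetic trial, and a
    transport-agnostic chatbot session engine (onboarding, nightly
    reminders, check-ins, condition-specific feedback, score ledger)
    with event-sourced JSONL logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
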