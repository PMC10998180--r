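#' Plot a point curve
#'
#' Point values for enacting versus failing to enact the habit as a
#' function of habit strength. The enactment curve steps down from
#' `M` at strength 0 to 0 at the target threshold; the failure curve
#' is nonpositive and roughly linear with the same slope.
#'
#' @param object A [point_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.habit_point_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("points_enact", "points_fail"),
    names_to = "action", values_to = "points")
  long$action <- ifelse(long$action == "points_enact",
                        "enact (a = 1)", "fail (a = 0)")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$strength, y = .data$points,
                               colour = .data$action)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "habit strength", y = "points",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-arm enactment counts of a synthetic trial
#'
#' @param object A [simulate_trial()] result.
#' @param ... Unused.
#' @return A ggplot object showing the distribution of per-participant
#'   enactment counts by arm.
#' @export
autoplot.habit_trial <- function(object, ...) {
  ggplot2::ggplot(object$participants,
                  ggplot2::aes(x = .data$arm, y = .data$enactments)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4) +
    ggplot2::labs(x = NULL,
                  y = sprintf("enactments in %d days",
                              object$config$days)) +
    ggplot2::theme_minimal()
}
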