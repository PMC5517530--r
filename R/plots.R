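#' @rdname choice_proportion_summary
#' @param object A `proportion_summary`.
#' @export
autoplot.proportion_summary <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$rule_set, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.15) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = object$statistic,
                  title = sprintf("Condition: %s", object$condition)) +
    ggplot2::theme_minimal()
}

#' @rdname decompose_interaction
#' @param object A `voi_decomposition`.
#' @export
autoplot.voi_decomposition <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue4", width = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "effect (outcome units)",
                  title = sprintf("(%s, %s) vs (%s, %s)",
                                  object$target[[1]], object$target[[2]],
                                  object$baseline[[1]], object$baseline[[2]])) +
    ggplot2::theme_minimal()
}

#' @rdname cluster_bootstrap
#' @param object A `bootstrap_result`.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(replicate = object$replicates),
                  ggplot2::aes(x = .data$replicate)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "red3") +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "replicate statistic", y = "count",
                  title = sprintf("Cluster bootstrap (B = %d, %d clusters)",
                                  object$B, object$n_clusters)) +
    ggplot2::theme_minimal()
}

#' Mean thermometer trajectories by attitude
#'
#' Plots the mean ratings I, II and III for retained accordance and
#' non-accordance cases — the up-then-down vs down-then-up signature of the
#' two attitudes.
#'
#' @param screen An `attitude_screen` from [apply_exclusions()].
#' @return A ggplot.
#' @export
plot_affect_trajectories <- function(screen) {
  stopifnot(inherits(screen, "attitude_screen"))
  long <- tidyr::pivot_longer(
    screen$retained, c("rating_I", "rating_II", "rating_III"),
    names_to = "stage", values_to = "rating")
  long$stage <- factor(long$stage,
                       levels = c("rating_I", "rating_II", "rating_III"),
                       labels = c("I", "II", "III"))
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$label, .data$stage),
    mean = mean(.data$rating),
    sem = sd(.data$rating) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$stage, y = .data$mean,
                               group = .data$label, colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = "affective feeling", y = "thermometer rating (degrees)",
                  colour = "attitude") +
    ggplot2::theme_minimal()
}
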