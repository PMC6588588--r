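#' Kaplan-Meier curves by stratification group
#'
#' @param clinical A clinical table.
#' @param groups A `pd_groups` tibble.
#' @return A ggplot object (step curves, one per group).
#' @export
plot_km <- function(clinical, groups) {
  clinical <- as_clinical(clinical)
  d <- inner_join(clinical, as_tibble(groups), by = "subject_id")
  curves <- d |>
    group_by(.data$group) |>
    group_modify(function(g, key) {
      km <- km_estimate(g$time_days, g$event)
      tibble(time = c(0, km$time), survival = c(1, km$survival))
    }) |>
    ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Summary plot of a threshold sweep
#'
#' Box plots of the log-rank p-values attained across the threshold grid,
#' one box per score type, on a -log10 scale.
#'
#' @param sweep Result of [threshold_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  d <- filter(sweep, !.data$skipped)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score_type,
                                  y = -log10(.data$p_value))) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6,
                         ggplot2::aes(colour = .data$beta)) +
    ggplot2::labs(x = "score", y = expression(-log[10]~p),
                  colour = expression(beta)) +
    ggplot2::theme_minimal()
}

#' Scatter of per-subject R vs M scores
#'
#' @param object A `pd_scores` tibble.
#' @param selection Optional `pd_selection` used to colour sub-cohorts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pd_scores
#' @export
autoplot.pd_scores <- function(object, selection = NULL, ...) {
  ss <- subject_scores(object)
  if (!is.null(selection)) {
    ss <- left_join(ss,
                    select(as_tibble(selection), "subject_id", "subcohort"),
                    by = "subject_id")
    p <- ggplot2::ggplot(ss, ggplot2::aes(x = .data$R, y = .data$M,
                                          colour = .data$subcohort))
  } else {
    p <- ggplot2::ggplot(ss, ggplot2::aes(x = .data$R, y = .data$M))
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "route propagation score R", y = "effect score M") +
    ggplot2::theme_minimal()
}
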