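#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a log-rank test
#'
#' @param x A `pd_logrank`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `n`.
#' @method tidy pd_logrank
#' @export
tidy.pd_logrank <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         n = x$n_total)
}

#' @rdname tidy.pd_logrank
#' @method glance pd_logrank
#' @export
glance.pd_logrank <- function(x, ...) tidy.pd_logrank(x)

#' Tidy a distillation result
#'
#' `tidy()` returns the per-candidate classification; `glance()` a one-row
#' summary with sub-cohort sizes, target counts and the CorC/CorC'
#' quality check.
#'
#' @param x A `pd_distill`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pd_distill
#' @export
tidy.pd_distill <- function(x, ...) as_tibble(x$targets)

#' @rdname tidy.pd_distill
#' @method glance pd_distill
#' @export
glance.pd_distill <- function(x, ...) {
  tibble(n_activated = sum(x$selection$subcohort == "activated"),
         n_suppressed = sum(x$selection$subcohort == "suppressed"),
         n_candidates = nrow(x$targets),
         n_up = length(x$extended$up_targets),
         n_down = length(x$extended$down_targets),
         cor_full = x$quality$cor_full,
         cor_selected = x$quality$cor_selected,
         improved = x$quality$improved)
}

#' Tidy a per-subject score table
#'
#' @param x A `pd_scores`.
#' @param ... Unused.
#' @return Per-subject tibble (`subject_id`, `R`, `M`).
#' @method tidy pd_scores
#' @export
tidy.pd_scores <- function(x, ...) subject_scores(x)

#' @rdname tidy.pd_scores
#' @method glance pd_scores
#' @export
glance.pd_scores <- function(x, ...) {
  ss <- subject_scores(x)
  tibble(n_subjects = nrow(ss),
         n_routes = length(unique(x$route_id)),
         mean_R = mean(ss$R), mean_M = mean(ss$M))
}
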