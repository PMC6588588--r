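#' Validate a clinical outcome table
#'
#' @param clinical Data frame with `subject_id`, `time_days` (> 0), `event`
#'   (1 = death/progression, 0 = censored) and optionally `stage`.
#' @return The validated tibble.
#' @export
as_clinical <- function(clinical) {
  clinical <- as_tibble(clinical)
  need <- c("subject_id", "time_days", "event")
  if (!all(need %in% names(clinical))) {
    pd_abort(sprintf("clinical table needs columns %s",
                     paste(need, collapse = ", ")), "pd_input_error")
  }
  if (nrow(clinical) == 0) {
    pd_abort("clinical table is empty", "pd_input_error")
  }
  if (any(clinical$time_days <= 0) || any(!clinical$event %in% c(0, 1))) {
    pd_abort("times must be > 0 and event must be 0/1", "pd_input_error")
  }
  clinical
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring, computed with
#' [survival::survfit()].
#'
#' @param times Positive follow-up times (days).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `pd_km` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (one row per distinct observed time), with the `survfit`
#'   object attached as attribute `fit`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival # 2/3, 1/3, 0
km_estimate <- function(times, events) {
  if (length(times) == 0 || length(times) != length(events)) {
    pd_abort("times/events must be nonempty and equal length",
             "pd_input_error")
  }
  if (any(times <= 0)) pd_abort("times must be positive", "pd_input_error")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  structure(out, class = c("pd_km", class(out)), fit = fit)
}

#' Log-rank test between stratified groups
#'
#' k-group log-rank test ([survival::survdiff()]) of the survival curves
#' of the groups, df = k - 1, p from the upper chi-square tail. Used as the
#' companion test to every KM comparison in the package.
#'
#' @param clinical A clinical table (see [as_clinical()]).
#' @param groups A `pd_groups` tibble (`subject_id`, `group`) from
#'   [stratify()] / [stratify_quadrant()], or a named character vector.
#' @return A `pd_logrank` list: `statistic`, `df`, `p_value`, `n` (per
#'   group), `n_total`.
#' @export
logrank_test <- function(clinical, groups) {
  clinical <- as_clinical(clinical)
  if (!is.data.frame(groups)) {
    groups <- tibble(subject_id = names(groups), group = unname(groups))
  }
  d <- inner_join(clinical, as_tibble(groups), by = "subject_id")
  tab <- table(d$group)
  if (length(tab) < 2) {
    pd_abort("log-rank needs >= 2 nonempty groups", "pd_group_error")
  }
  if (any(tab == 0)) {
    pd_abort("a stratification group has zero subjects", "pd_group_error")
  }
  fit <- survival::survdiff(
    survival::Surv(time_days, event) ~ group, data = d
  )
  df <- length(tab) - 1
  p <- pchisq(fit$chisq, df = df, lower.tail = FALSE)
  structure(list(statistic = unname(fit$chisq), df = df, p_value = p,
                 n = as.list(tab), n_total = nrow(d)),
            class = "pd_logrank")
}

#' @export
print.pd_logrank <- function(x, ...) {
  cat(sprintf("<log-rank> chi-square = %.4g on %d df, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n_total))
  invisible(x)
}

#' Binary stratification of a score
#'
#' `high`: score > beta; `low`: score < beta; subjects exactly at `beta`
#' are excluded. When either side is empty the result carries
#' `attr(, "flagged") = TRUE` so sweep callers can skip that threshold.
#'
#' @param scores A `pd_scores` tibble, or a per-subject tibble with
#'   `subject_id` and the score column.
#' @param score `"M"` (default) or `"R"`.
#' @param beta Threshold in [-1, 1].
#' @return A `pd_groups` tibble: `subject_id`, `group`.
#' @export
stratify <- function(scores, score = c("M", "R"), beta = 0) {
  score <- match.arg(score)
  check_threshold(beta, "beta")
  ss <- if (inherits(scores, "pd_scores")) subject_scores(scores) else
    as_tibble(scores)
  vals <- ss[[score]]
  if (is.null(vals)) {
    pd_abort(sprintf("score column `%s` not present", score),
             "pd_input_error")
  }
  out <- tibble(subject_id = ss$subject_id,
                group = ifelse(vals > beta, "high",
                               ifelse(vals < beta, "low", NA_character_)))
  out <- filter(out, !is.na(.data$group))
  flagged <- !all(c("high", "low") %in% out$group)
  structure(out, class = c("pd_groups", class(tibble())),
            rule = list(score = score, beta = beta), flagged = flagged)
}

#' Four-quadrant stratification on two pathways' M scores
#'
#' Crosses two binary M-score rules, e.g. Th1 x Th2: `high-low` means the
#' first pathway high and the second low (Th1 dominance). Subjects at
#' either threshold are excluded.
#'
#' @param scores_a,scores_b `pd_scores` (or per-subject tibbles) for the
#'   two pathways.
#' @param beta_a,beta_b Thresholds.
#' @param score Score column to cross, default `"M"`.
#' @return A `pd_groups` tibble with labels
#'   `high-high`, `high-low`, `low-high`, `low-low`.
#' @export
stratify_quadrant <- function(scores_a, scores_b, beta_a = 0, beta_b = 0,
                              score = "M") {
  ga <- stratify(scores_a, score = score, beta = beta_a)
  gb <- stratify(scores_b, score = score, beta = beta_b)
  d <- inner_join(as_tibble(ga), as_tibble(gb), by = "subject_id",
                  suffix = c("_a", "_b"))
  out <- tibble(subject_id = d$subject_id,
                group = paste(d$group_a, d$group_b, sep = "-"))
  flagged <- length(unique(out$group)) < 2
  structure(out, class = c("pd_groups", class(tibble())),
            rule = list(score = score, beta_a = beta_a, beta_b = beta_b,
                        quadrant = TRUE),
            flagged = flagged)
}

#' Exclude long-term event-free subjects
#'
#' Optional filter mirroring analyses that drop progression-free subjects
#' followed beyond a horizon (default 5 years = 1825 days), so that the
#' comparison focuses on subjects at risk within the clinical window.
#'
#' @param clinical A clinical table.
#' @param t_days Horizon in days.
#' @return The filtered tibble.
#' @export
exclude_longterm_eventfree <- function(clinical, t_days = 1825) {
  clinical <- as_clinical(clinical)
  filter(clinical, !(.data$event == 0 & .data$time_days > t_days))
}

#' Threshold sweep of survival separation
#'
#' For every threshold `beta` on the grid and each requested score type,
#' stratifies the cohort and runs the log-rank test; combinations where a
#' side has fewer than `min_group` subjects are recorded as skipped rather
#' than tested.
#'
#' @param scores A `pd_scores` tibble (M present for score type `"M"`).
#' @param clinical A clinical table.
#' @param grid Thresholds, default `seq(-1, 1, 0.1)`.
#' @param min_group Minimum subjects per side, default 10.
#' @param score_types Subset of `c("R", "M")`.
#' @return Tibble: `beta`, `score_type`, `n_high`, `n_low`, `statistic`,
#'   `p_value`, `skipped`.
#' @export
threshold_sweep <- function(scores, clinical, grid = seq(-1, 1, by = 0.1),
                            min_group = 10, score_types = c("R", "M")) {
  clinical <- as_clinical(clinical)
  score_types <- match.arg(score_types, c("R", "M"), several.ok = TRUE)
  rows <- list()
  for (st in score_types) {
    for (beta in grid) {
      g <- stratify(scores, score = st, beta = beta)
      d <- inner_join(as_tibble(g), clinical, by = "subject_id")
      n_high <- sum(d$group == "high"); n_low <- sum(d$group == "low")
      if (n_high < min_group || n_low < min_group) {
        rows[[length(rows) + 1]] <- tibble(
          beta = beta, score_type = st, n_high = n_high, n_low = n_low,
          statistic = NA_real_, p_value = NA_real_, skipped = TRUE)
        next
      }
      lr <- logrank_test(clinical, g)
      rows[[length(rows) + 1]] <- tibble(
        beta = beta, score_type = st, n_high = n_high, n_low = n_low,
        statistic = lr$statistic, p_value = lr$p_value, skipped = FALSE)
    }
  }
  bind_rows(rows)
}

#' Stage-stratified survival analysis
#'
#' Repeats a stratified log-rank comparison within each clinical stage.
#' Subjects with missing stage are excluded (count logged); stages where
#' fewer than two groups survive the restriction are reported untestable.
#'
#' @param groups A `pd_groups` tibble.
#' @param clinical A clinical table with a `stage` column.
#' @return Tibble: `stage`, `n`, `statistic`, `df`, `p_value`, `testable`.
#' @export
stage_stratified_analysis <- function(groups, clinical) {
  clinical <- as_clinical(clinical)
  if (!"stage" %in% names(clinical)) {
    pd_abort("clinical table has no `stage` column", "pd_input_error")
  }
  n_missing <- sum(is.na(clinical$stage))
  if (n_missing > 0) {
    inform(sprintf("excluding %d subject(s) with missing stage", n_missing))
  }
  clinical <- filter(clinical, !is.na(.data$stage))
  stages <- sort(unique(clinical$stage))
  bind_rows(map(stages, function(s) {
    cl <- filter(clinical, .data$stage == s)
    d <- inner_join(as_tibble(groups), cl, by = "subject_id")
    if (nrow(d) < 2 || length(unique(d$group)) < 2) {
      return(tibble(stage = s, n = nrow(d), statistic = NA_real_,
                    df = NA_integer_, p_value = NA_real_, testable = FALSE))
    }
    lr <- logrank_test(cl, groups)
    tibble(stage = s, n = lr$n_total, statistic = lr$statistic,
           df = as.integer(lr$df), p_value = lr$p_value, testable = TRUE)
  }))
}

# --- decoy pathways --------------------------------------------------------

#' Generate topology-preserving decoy pathways
#'
#' Each decoy replaces every non-process node's gene (routes, TF and Up/Down
#' targets included) with a distinct gene drawn without replacement from
#' `gene_universe`, keeping nodes, edges, edge signs, routes and the
#' Up/Down partition sizes identical. Genes of the original pathway are
#' removed from the universe first. Decoys are independent across `k` and
#' reproducible for a given `seed`.
#'
#' @param p A `pd_pathway` (possibly extended).
#' @param gene_universe Candidate replacement genes.
#' @param k Number of decoys, default 10.
#' @param seed Optional integer seed.
#' @return List of `k` pathways.
#' @export
generate_decoys <- function(p, gene_universe, k = 10, seed = NULL) {
  stopifnot(inherits(p, "pd_pathway"))
  own <- setdiff(unique(c(p$nodes$id, p$up_targets, p$down_targets)),
                 p$process)
  universe <- setdiff(unique(as.character(gene_universe)), c(own, p$process))
  if (length(universe) < length(own)) {
    pd_abort(sprintf("gene universe too small: %d genes to replace, %d available",
                     length(own), length(universe)), "pd_input_error")
  }
  make_one <- function(i) {
    repl <- sample(universe, length(own))
    lut <- setNames(repl, own)
    map_gene <- function(g) {
      hit <- g %in% own
      g[hit] <- unname(lut[g[hit]])
      g
    }
    q <- p
    q$name <- sprintf("%s_decoy%d", p$name, i)
    q$nodes$id <- map_gene(q$nodes$id)
    q$edges$src <- map_gene(q$edges$src)
    q$edges$dst <- map_gene(q$edges$dst)
    q$routes$gene <- map_gene(q$routes$gene)
    q$tf <- unname(map_gene(q$tf))
    q$up_targets <- unname(map_gene(q$up_targets))
    q$down_targets <- unname(map_gene(q$down_targets))
    q
  }
  if (is.null(seed)) {
    map(seq_len(k), make_one)
  } else {
    withr::with_seed(seed, map(seq_len(k), make_one))
  }
}

#' Two-of-three decoy significance test
#'
#' Compares the cohort's effect-score vector under the true (tailored)
#' pathway with the vector under one decoy. Criteria: (1) two-sample t-test
#' p < `alpha`; (2) Wilcoxon rank-sum p < `alpha`; (3) |Pearson
#' correlation| < `corr_cut` (low similarity is evidence of dissimilarity).
#' The decoy is called dissimilar ("significant") when at least two of the
#' three hold. An undefined correlation (constant vector) counts as a
#' criterion not met.
#'
#' @param true_scores,decoy_scores Numeric vectors of per-subject M scores
#'   (equal length >= 3).
#' @param alpha Test level, default 0.05.
#' @param corr_cut Correlation cut, default 0.3.
#' @return One-row tibble: `t_p`, `wilcox_p`, `correlation`,
#'   `criteria_met`, `significant`.
#' @export
decoy_significance <- function(true_scores, decoy_scores, alpha = 0.05,
                               corr_cut = 0.3) {
  if (length(true_scores) != length(decoy_scores) ||
      length(true_scores) < 3) {
    pd_abort("score vectors must be equal length >= 3", "pd_input_error")
  }
  same <- isTRUE(all.equal(true_scores, decoy_scores))
  t_p <- if (same) 1 else
    tryCatch(t.test(true_scores, decoy_scores)$p.value,
             error = function(e) 1)
  w_p <- if (same) 1 else
    suppressWarnings(wilcox.test(true_scores, decoy_scores,
                                 exact = FALSE)$p.value)
  rho <- tryCatch(pearson_cor(true_scores, decoy_scores),
                  pd_constant_error = function(e) NA_real_)
  crit <- c(t_p < alpha, w_p < alpha, !is.na(rho) && abs(rho) < corr_cut)
  tibble(t_p = t_p, wilcox_p = w_p, correlation = rho,
         criteria_met = sum(crit), significant = sum(crit) >= 2)
}

#' Decoy-pathway analysis of an extended pathway
#'
#' Generates `k` decoys, scores each over the cohort and applies the
#' two-of-three criterion against the true pathway's M scores.
#'
#' @param expr Gene-by-subject log2-ratio table containing the universe
#'   genes.
#' @param extended A scored `pd_extended_pathway`.
#' @param gene_universe Replacement gene pool (defaults to all expression
#'   genes outside the pathway).
#' @param k Number of decoys.
#' @param seed Integer seed (decoy construction is the only randomness).
#' @param t_pr,t_pm Scoring thresholds.
#' @param alpha,corr_cut Criteria parameters, see [decoy_significance()].
#' @return A `pd_decoy_report` tibble, one row per decoy.
#' @export
decoy_analysis <- function(expr, extended, gene_universe = NULL, k = 10,
                           seed = NULL, t_pr = 0.05, t_pm = 0.05,
                           alpha = 0.05, corr_cut = 0.3) {
  m <- as_expr_matrix(expr)
  gene_universe <- gene_universe %||%
    setdiff(rownames(m), c(extended$nodes$id, extended$up_targets,
                           extended$down_targets))
  true_m <- subject_scores(score_cohort(m, extended, t_pr, t_pm))$M
  decoys <- generate_decoys(extended, gene_universe, k = k, seed = seed)
  out <- imap(decoys, function(d, i) {
    dm <- subject_scores(score_cohort(m, d, t_pr, t_pm))$M
    row <- decoy_significance(true_m, dm, alpha = alpha,
                              corr_cut = corr_cut)
    mutate(row, decoy = d$name, .before = 1)
  })
  res <- bind_rows(out)
  structure(res, class = c("pd_decoy_report", class(tibble())),
            true_mean = mean(true_m))
}

# --- cross-cohort overlap --------------------------------------------------

#' Cross-cohort overlap of Up / Down target sets
#'
#' For Up and Down targets separately, counts every region of the Venn
#' partition over the cohorts and extracts the common core (genes present
#' in all cohorts), which can be exported for restricted-target effect
#' scoring.
#'
#' @param classifications Named list (>= 2 cohorts) of `pd_targets`
#'   tibbles, or of lists with `up` / `down` character vectors.
#' @return A `pd_overlap` list: `regions` (tibble `side`, `region`,
#'   `count`), `core_up`, `core_down`.
#' @export
overlap_analysis <- function(classifications) {
  if (length(classifications) < 2) {
    pd_abort("overlap analysis needs >= 2 cohorts", "pd_input_error")
  }
  if (is.null(names(classifications))) {
    names(classifications) <- paste0("cohort", seq_along(classifications))
  }
  sets <- imap(classifications, function(x, nm) {
    if (is.data.frame(x)) {
      list(up = x$gene[x$class == "up"], down = x$gene[x$class == "down"])
    } else {
      list(up = as.character(x$up %||% character()),
           down = as.character(x$down %||% character()))
    }
  })
  venn_side <- function(side) {
    gsets <- map(sets, side)
    genes <- unique(unlist(gsets))
    if (length(genes) == 0) {
      return(list(regions = tibble(side = side, region = character(),
                                   count = integer()),
                  core = character()))
    }
    member <- vapply(gsets, function(s) genes %in% s,
                     logical(length(genes)))
    member <- matrix(member, nrow = length(genes),
                     dimnames = list(genes, names(sets)))
    region <- apply(member, 1, function(r)
      paste(names(sets)[r], collapse = "&"))
    counts <- table(region)
    list(regions = tibble(side = side, region = names(counts),
                          count = as.integer(counts)),
         core = sort(genes[rowSums(member) == length(sets)]))
  }
  up <- venn_side("up"); down <- venn_side("down")
  structure(list(regions = bind_rows(up$regions, down$regions),
                 core_up = up$core, core_down = down$core,
                 cohorts = names(sets)),
            class = "pd_overlap")
}

#' @export
print.pd_overlap <- function(x, ...) {
  cat(sprintf("<overlap> %d cohorts: %s\n", length(x$cohorts),
              paste(x$cohorts, collapse = ", ")))
  cat(sprintf("  common core: %d Up, %d Down\n",
              length(x$core_up), length(x$core_down)))
  invisible(x)
}

#' Restrict an extended pathway to a core target set
#'
#' Keeps only the Up/Down targets present in `core`, the restricted-target
#' variant of effect scoring used to compare cohorts on a shared gene set.
#'
#' @param extended A `pd_extended_pathway`.
#' @param core Character vector of genes to retain.
#' @return A `pd_extended_pathway`.
#' @export
restrict_targets <- function(extended, core) {
  stopifnot(inherits(extended, "pd_extended_pathway"))
  extend_pathway(extended, intersect(extended$up_targets, core),
                 intersect(extended$down_targets, core))
}
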