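#' Empirical p-value of a log2 ratio against a population
#'
#' The null distribution for a gene is the empirical distribution of that
#' gene's log2 tumor/control ratios across the cohort; the p-value is the
#' tail area beyond the observed value, estimated by add-one counting
#' `(k + 1) / (n + 1)` so that p never reaches 0 and no density estimate is
#' needed. Tails: `up` counts values `>= y`, `down` counts `<= y`, `two` is
#' `min(1, 2 * min(up, down))`.
#'
#' @param y Observed log2 ratio (may be a vector).
#' @param population Numeric vector of the gene's cohort values (length
#'   >= 2).
#' @param tail `"up"`, `"down"` or `"two"`.
#' @return p-value(s) in (0, 1].
#' @export
#' @examples
#' empirical_pvalue(2, c(-2, -1, 0, 1, 2), "up") # 2/6
empirical_pvalue <- function(y, population, tail = c("up", "down", "two")) {
  tail <- match.arg(tail)
  population <- population[!is.na(population)]
  n <- length(population)
  if (n < 2) {
    pd_abort("population must have at least 2 values", "pd_input_error")
  }
  up <- (vapply(y, function(v) sum(population >= v), numeric(1)) + 1) / (n + 1)
  dn <- (vapply(y, function(v) sum(population <= v), numeric(1)) + 1) / (n + 1)
  switch(tail, up = up, down = dn, two = pmin(1, 2 * pmin(up, dn)))
}

#' Consistency of a gene with the transcription factor
#'
#' `v = net_sign * sign(g_i) * sign(g_t)`: +1 when the gene's observed
#' direction agrees with what its (net) regulatory relation to the TF
#' predicts from the TF's direction, -1 when it contradicts it, and 0 when
#' either log2 ratio is exactly zero (such genes count in neither sum).
#'
#' @param gi_value,gt_value Log2 ratios of the gene and the TF.
#' @param net_sign +1 (net activation) or -1 (net inhibition).
#' @return -1, 0 or +1 (vectorized).
#' @export
consistency <- function(gi_value, gt_value, net_sign) {
  if (!all(net_sign %in% c(-1, 1))) {
    pd_abort("`net_sign` must be +1 or -1", "pd_input_error")
  }
  net_sign * .sgn(gi_value) * .sgn(gt_value)
}

#' Plug-in FDR for a thresholded gene set
#'
#' With `n_genes` genes tested at p-value threshold `t_p`, about
#' `n_genes * t_p` are expected to pass by chance; the ratio to the number
#' actually passing estimates the false discovery rate. Clamped to [0, 1];
#' when nothing passes the FDR is taken as 1 (the associated score then
#' collapses to 0).
#'
#' @param n_genes Number of genes considered (>= 1).
#' @param t_p P-value threshold in (0, 1].
#' @param n_passing Number of genes with p below `t_p`.
#' @return FDR in [0, 1].
#' @export
fdr_estimate <- function(n_genes, t_p, n_passing) {
  stopifnot(n_genes >= 1)
  check_threshold(t_p, "t_p", lo = 0, hi = 1, open_lo = TRUE)
  ifelse(n_passing <= 0, 1, pmin(1, n_genes * t_p / n_passing))
}

# per-gene tail choice: up-regulated genes use the upper tail, down-regulated
# the lower, exactly-zero values the two-sided tail
tail_pvalue <- function(y, population) {
  up <- empirical_pvalue(y, population, "up")
  dn <- empirical_pvalue(y, population, "down")
  ifelse(y > 0, up, ifelse(y < 0, dn, pmin(1, 2 * pmin(up, dn))))
}

#' Route propagation score R for one subject
#'
#' For a route with genes `g_1, ..., g_ng` upstream of the TF,
#' `R = ((#consistent - #inconsistent) / n_g) * (1 - FDR)` where consistency
#' is taken per gene against the TF via [consistency()] with the gene's net
#' route sign, and the FDR is [fdr_estimate()] over the route genes'
#' empirical p-values at threshold `t_pr`. The TF itself is excluded from
#' the counts. R lies in [-1, 1]; positive values mean the upstream route is
#' transmitting a signal consistent with the TF's observed direction.
#'
#' @param subject Named numeric vector (or single-subject mapping) of log2
#'   ratios, names are genes.
#' @param route Data frame with columns `gene` and `net_sign` (TF row
#'   optional, ignored), e.g. one route of `pathway()$routes`.
#' @param populations Named list or gene-by-subject matrix giving each
#'   gene's cohort distribution.
#' @param tf TF gene symbol.
#' @param t_pr P-value threshold for the route FDR, default 0.05.
#' @param fdr Optional externally supplied FDR in [0, 1]; when given, the
#'   empirical p-value stage is bypassed and `populations` may be `NULL`.
#' @return R in [-1, 1].
#' @export
route_score <- function(subject, route, populations = NULL, tf, t_pr = 0.05,
                        fdr = NULL) {
  check_threshold(t_pr, "t_pr", lo = 0, hi = 1, open_lo = TRUE)
  route <- route[route$gene != tf, , drop = FALSE]
  genes <- route$gene
  missing <- setdiff(c(genes, tf), names(subject))
  if (length(missing) > 0) {
    pd_abort(sprintf("subject lacks expression for gene(s): %s",
                     paste(missing, collapse = ", ")), "pd_missing_gene_error")
  }
  v <- consistency(unname(subject[genes]), unname(subject[tf]),
                   route$net_sign)
  n_g <- length(genes)
  if (is.null(fdr)) {
    p <- vapply(genes, function(g) {
      tail_pvalue(unname(subject[g]), gene_population(populations, g))
    }, numeric(1))
    fdr <- fdr_estimate(n_g, t_pr, sum(p < t_pr))
  } else {
    check_threshold(fdr, "fdr", lo = 0, hi = 1)
  }
  ((sum(v > 0) - sum(v < 0)) / n_g) * (1 - fdr)
}

gene_population <- function(populations, g) {
  pop <- if (is.matrix(populations)) {
    if (!g %in% rownames(populations)) NULL else populations[g, ]
  } else {
    populations[[g]]
  }
  if (is.null(pop)) {
    pd_abort(sprintf("no population distribution for gene %s", g),
             "pd_missing_gene_error")
  }
  pop
}

#' Effect score M for one subject
#'
#' The biological-process direction is estimated by the TF's log2 ratio.
#' Each Up target is consistent when its sign matches the TF's, each Down
#' target when it opposes it. With `n_m = |G_u| + |G_d|` targets,
#' `M = ((#consistent - #inconsistent) / n_m) * (1 - FDR)`, the FDR taken
#' over the targets' empirical p-values at `t_pm`. Equivalently, when every
#' consistent target is also significant, `M = A_k * (1 - FDR) / (n + m)`
#' with `A_k` the count of consistent significant targets.
#'
#' @param subject Named numeric vector of log2 ratios.
#' @param extended A `pd_extended_pathway` (nonempty target sets).
#' @param populations As in [route_score()].
#' @param t_pm P-value threshold for the effect FDR, default 0.05.
#' @param fdr Optional externally supplied FDR in [0, 1], bypassing the
#'   empirical p-value stage (`populations` may then be `NULL`).
#' @return M in [-1, 1].
#' @export
effect_score <- function(subject, extended, populations = NULL, t_pm = 0.05,
                         fdr = NULL) {
  check_threshold(t_pm, "t_pm", lo = 0, hi = 1, open_lo = TRUE)
  if (!inherits(extended, "pd_extended_pathway") ||
      (length(extended$up_targets) + length(extended$down_targets)) == 0) {
    pd_abort(paste0("effect score needs an extended pathway with a nonempty ",
                    "target set; use route scores (R) alone otherwise"),
             "pd_empty_targets_error")
  }
  tf <- extended$tf
  genes <- c(extended$up_targets, extended$down_targets)
  rel <- c(rep(1, length(extended$up_targets)),
           rep(-1, length(extended$down_targets)))
  missing <- setdiff(c(genes, tf), names(subject))
  if (length(missing) > 0) {
    pd_abort(sprintf("subject lacks expression for gene(s): %s",
                     paste(missing, collapse = ", ")), "pd_missing_gene_error")
  }
  v <- consistency(unname(subject[genes]), unname(subject[tf]), rel)
  n_m <- length(genes)
  if (is.null(fdr)) {
    p <- vapply(genes, function(g) {
      tail_pvalue(unname(subject[g]), gene_population(populations, g))
    }, numeric(1))
    fdr <- fdr_estimate(n_m, t_pm, sum(p < t_pm))
  } else {
    check_threshold(fdr, "fdr", lo = 0, hi = 1)
  }
  ((sum(v > 0) - sum(v < 0)) / n_m) * (1 - fdr)
}

# --- cohort-level vectorized scoring ---------------------------------------

# per-gene matrix of tail-selected empirical p-values, each row's population
# being the row itself (cohort-internal null)
cohort_tail_pvalues <- function(m) {
  n <- ncol(m)
  t(apply(m, 1, function(x) {
    ge <- n - rank(x, ties.method = "min") + 1 # #{>= x_k}
    le <- rank(x, ties.method = "max")         # #{<= x_k}
    up <- (ge + 1) / (n + 1)
    dn <- (le + 1) / (n + 1)
    ifelse(x > 0, up, ifelse(x < 0, dn, pmin(1, 2 * pmin(up, dn))))
  }))
}

#' Score a cohort: per-route R and (for extended pathways) M
#'
#' Computes the route propagation score for every subject and route, the
#' per-subject scalar `R_subject` (the route score of maximal absolute
#' value, ties broken by route order), and, when `p` carries Up/Down
#' targets, the effect score `M`. Per-gene null distributions are the
#' cohort's own rows.
#'
#' @param expr Gene-by-subject table of log2 tumor/control ratios: a data
#'   frame with a `gene` column plus one numeric column per subject, or a
#'   matrix with gene rownames.
#' @param p A `pd_pathway` or `pd_extended_pathway` with routes.
#' @param t_pr,t_pm P-value thresholds for the route and effect FDRs.
#' @return A `pd_scores` tibble, one row per subject x route: `subject_id`,
#'   `route_id`, `R`, `R_subject`, and `M` (NA for plain pathways).
#' @export
score_cohort <- function(expr, p, t_pr = 0.05, t_pm = 0.05) {
  stopifnot(inherits(p, "pd_pathway"))
  m <- as_expr_matrix(expr)
  if (nrow(p$routes) == 0) {
    pd_abort("pathway has no routes; call enumerate_routes() first",
             "pd_pathway_error")
  }
  needed <- unique(c(p$routes$gene, p$tf, p$up_targets, p$down_targets))
  missing <- setdiff(needed, rownames(m))
  if (length(missing) > 0) {
    pd_abort(sprintf("expression table lacks pathway gene(s): %s",
                     paste(missing, collapse = ", ")),
             "pd_missing_gene_error")
  }
  subjects <- colnames(m)
  pmat <- cohort_tail_pvalues(m[needed, , drop = FALSE])
  tf_sign <- .sgn(m[p$tf, ])

  route_ids <- unique(p$routes$route_id)
  per_route <- map(route_ids, function(rid) {
    rt <- filter(p$routes, .data$route_id == rid, .data$gene != p$tf)
    vals <- m[rt$gene, , drop = FALSE]
    v <- rt$net_sign * .sgn(vals) * rep(tf_sign, each = nrow(rt))
    npass <- colSums(pmat[rt$gene, , drop = FALSE] < t_pr)
    fdr <- fdr_estimate(nrow(rt), t_pr, npass)
    r <- ((colSums(v > 0) - colSums(v < 0)) / nrow(rt)) * (1 - fdr)
    tibble(subject_id = subjects, route_id = rid, R = unname(r))
  })
  scores <- bind_rows(per_route)

  # subject scalar: the route score of maximal |R| (first route on ties)
  scalar <- scores |>
    group_by(.data$subject_id) |>
    summarise(R_subject = .data$R[which.max(abs(.data$R))], .groups = "drop")
  scores <- left_join(scores, scalar, by = "subject_id")

  if (inherits(p, "pd_extended_pathway") &&
      length(c(p$up_targets, p$down_targets)) > 0) {
    tg <- c(p$up_targets, p$down_targets)
    rel <- c(rep(1, length(p$up_targets)), rep(-1, length(p$down_targets)))
    vals <- m[tg, , drop = FALSE]
    v <- rel * .sgn(vals) * rep(tf_sign, each = length(tg))
    npass <- colSums(pmat[tg, , drop = FALSE] < t_pm)
    fdr <- fdr_estimate(length(tg), t_pm, npass)
    mm <- ((colSums(v > 0) - colSums(v < 0)) / length(tg)) * (1 - fdr)
    scores <- left_join(scores,
                        tibble(subject_id = subjects, M = unname(mm)),
                        by = "subject_id")
  } else {
    scores$M <- NA_real_
  }
  structure(scores,
            class = c("pd_scores", class(scores)),
            thresholds = list(t_pr = t_pr, t_pm = t_pm),
            tf = p$tf, pathway = p$name)
}

#' Per-subject score summary
#'
#' Collapses a `pd_scores` table to one row per subject (`subject_id`,
#' `R` = the max-|R| route score, `M`).
#'
#' @param scores A `pd_scores` tibble from [score_cohort()].
#' @return A tibble with one row per subject.
#' @export
subject_scores <- function(scores) {
  distinct(as_tibble(scores), .data$subject_id, .keep_all = TRUE) |>
    select("subject_id", R = "R_subject", "M")
}
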