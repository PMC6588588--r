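#' Select activated and suppressed sub-cohorts by R score
#'
#' Subjects whose scalar route score exceeds `t_cu` form the activated
#' sub-cohort `C_u`; those below `t_cd` form the suppressed sub-cohort
#' `C_d`. Comparisons are strict, so ties at a threshold are excluded, and
#' `t_cu >= t_cd` guarantees the two sub-cohorts are disjoint. Their union
#' `C'` is the selected cohort over which target correlations are computed.
#'
#' @param scores A `pd_scores` tibble or a per-subject tibble with columns
#'   `subject_id` and `R` (e.g. [subject_scores()]), or a named numeric
#'   vector of R values.
#' @param t_cu,t_cd Upper and lower R thresholds, `t_cu >= t_cd`.
#' @return A `pd_selection` tibble: `subject_id`, `R`, `subcohort`
#'   (`"activated"`, `"suppressed"`, `"unselected"`).
#' @export
select_subcohorts <- function(scores, t_cu = 0.5, t_cd = -0.5) {
  check_threshold(t_cu, "t_cu"); check_threshold(t_cd, "t_cd")
  if (t_cu < t_cd) {
    pd_abort("`t_cu` must be >= `t_cd` (sub-cohorts must be disjoint)",
             "pd_threshold_error")
  }
  tab <- scores_to_subject_r(scores)
  tab <- mutate(tab, subcohort = ifelse(.data$R > t_cu, "activated",
                                        ifelse(.data$R < t_cd, "suppressed",
                                               "unselected")))
  n_sel <- sum(tab$subcohort != "unselected")
  if (n_sel == 0) {
    pd_abort("no subject passes the R thresholds; loosen t_cu / t_cd",
             "pd_selection_error")
  }
  if (n_sel < 3) {
    warn(sprintf("only %d subject(s) selected; correlations over C' need >= 3",
                 n_sel))
  }
  inform(sprintf("selected cohort C': %d activated + %d suppressed of %d",
                 sum(tab$subcohort == "activated"),
                 sum(tab$subcohort == "suppressed"), nrow(tab)))
  structure(tab, class = c("pd_selection", class(tibble())),
            thresholds = list(t_cu = t_cu, t_cd = t_cd))
}

scores_to_subject_r <- function(scores) {
  if (inherits(scores, "pd_scores")) {
    ss <- subject_scores(scores)
    return(tibble(subject_id = ss$subject_id, R = ss$R))
  }
  if (is.data.frame(scores)) {
    stopifnot(all(c("subject_id", "R") %in% names(scores)))
    return(as_tibble(scores)[, c("subject_id", "R")])
  }
  tibble(subject_id = names(scores), R = unname(scores))
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper used for target classification and the quality
#' check: requires equal lengths >= 3 and non-constant vectors.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in [-1, 1].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    pd_abort("vectors must have equal length", "pd_input_error")
  }
  if (length(x) < 3) {
    pd_abort("correlation needs at least 3 observations", "pd_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    pd_abort("correlation undefined for a constant vector",
             "pd_constant_error")
  }
  cor(x, y)
}

#' Classify candidate targets by TF correlation over the selected cohort
#'
#' For every candidate gene, the Pearson correlation `rho` with the TF is
#' computed over the selected cohort `C'` only. Genes with `rho > t_gu`
#' become Up targets, `rho < t_gd` Down targets, the rest are unclassified.
#' Candidates absent from the expression table, and candidates constant
#' over `C'`, are skipped with a warning; the TF itself is never a
#' candidate.
#'
#' @param expr Gene-by-subject log2-ratio table (see [score_cohort()]).
#' @param ptg Candidate genes: a `pd_gene_set` or character vector.
#' @param tf TF gene symbol.
#' @param selection A `pd_selection` from [select_subcohorts()].
#' @param t_gu,t_gd Correlation thresholds, `t_gu >= t_gd`.
#' @return A `pd_targets` tibble: `gene`, `rho`, `class`
#'   (`"up"` / `"down"` / `"none"`).
#' @export
classify_targets <- function(expr, ptg, tf, selection, t_gu = 0.3,
                             t_gd = -0.3) {
  check_threshold(t_gu, "t_gu"); check_threshold(t_gd, "t_gd")
  if (t_gu < t_gd) {
    pd_abort("`t_gu` must be >= `t_gd`", "pd_threshold_error")
  }
  m <- as_expr_matrix(expr)
  genes <- if (inherits(ptg, "pd_gene_set")) ptg$genes else
    unique(as.character(ptg))
  genes <- setdiff(genes, tf)
  sel_ids <- selection$subject_id[selection$subcohort != "unselected"]
  sel_ids <- intersect(colnames(m), sel_ids)
  if (length(sel_ids) < 3) {
    pd_abort("selected cohort has < 3 subjects with expression",
             "pd_selection_error")
  }
  if (!tf %in% rownames(m)) {
    pd_abort(sprintf("TF %s missing from expression table", tf),
             "pd_missing_gene_error")
  }
  tf_vec <- m[tf, sel_ids]
  if (sd(tf_vec) == 0) {
    pd_abort("TF expression is constant over the selected cohort",
             "pd_constant_error")
  }
  absent <- setdiff(genes, rownames(m))
  if (length(absent) > 0) {
    warn(sprintf("%d candidate gene(s) absent from expression table, skipped",
                 length(absent)))
    genes <- setdiff(genes, absent)
  }
  keep <- genes[apply(m[genes, sel_ids, drop = FALSE], 1, sd) > 0]
  if (length(keep) < length(genes)) {
    warn(sprintf("%d candidate gene(s) constant over C', skipped",
                 length(genes) - length(keep)))
  }
  rho <- as.numeric(cor(t(m[keep, sel_ids, drop = FALSE]), tf_vec))
  out <- tibble(gene = keep, rho = rho,
                class = ifelse(rho > t_gu, "up",
                               ifelse(rho < t_gd, "down", "none")))
  structure(out, class = c("pd_targets", class(tibble())),
            thresholds = list(t_gu = t_gu, t_gd = t_gd),
            n_selected = length(sel_ids))
}

#' Optional FDR-style size cap for selections and classifications
#'
#' Retains the top `k = ceiling((1 - fdr) * size)` entries by absolute
#' score, a coarse way to let an FDR target further shrink a sub-cohort or
#' target set. Off by default throughout the pipeline.
#'
#' @param x A `pd_selection` or `pd_targets`.
#' @param fdr Fraction to trim, in [0, 1).
#' @return `x` with the weakest members demoted to
#'   `"unselected"` / `"none"`.
#' @export
cap_by_fdr <- function(x, fdr) {
  check_threshold(fdr, "fdr", lo = 0, hi = 1, open_hi = TRUE)
  if (inherits(x, "pd_selection")) {
    for (grp in c("activated", "suppressed")) {
      idx <- which(x$subcohort == grp)
      k <- ceiling((1 - fdr) * length(idx))
      drop <- idx[order(-abs(x$R[idx]))][-seq_len(k)]
      if (length(drop) > 0) x$subcohort[drop] <- "unselected"
    }
  } else if (inherits(x, "pd_targets")) {
    for (grp in c("up", "down")) {
      idx <- which(x$class == grp)
      k <- ceiling((1 - fdr) * length(idx))
      drop <- idx[order(-abs(x$rho[idx]))][-seq_len(k)]
      if (length(drop) > 0) x$class[drop] <- "none"
    }
  } else {
    pd_abort("`x` must be a pd_selection or pd_targets", "pd_input_error")
  }
  x
}

#' Quantile-based threshold helper
#'
#' Converts quantile levels into absolute thresholds on a score or
#' correlation vector, supporting quantile thresholding as an alternative
#' to fixed cutoffs.
#'
#' @param values Numeric vector (R scores or correlations).
#' @param upper,lower Quantile levels in (0, 1), e.g. 0.9 / 0.1.
#' @return Named list with `t_upper` and `t_lower`.
#' @export
quantile_thresholds <- function(values, upper = 0.9, lower = 0.1) {
  check_threshold(upper, "upper", lo = 0, hi = 1, open_lo = TRUE,
                  open_hi = TRUE)
  check_threshold(lower, "lower", lo = 0, hi = 1, open_lo = TRUE,
                  open_hi = TRUE)
  q <- quantile(values, c(lower, upper), na.rm = TRUE, names = FALSE)
  list(t_upper = q[2], t_lower = q[1])
}

#' Distill cohort-specific targets and extend the pathway
#'
#' Runs the six-step distillation: (1) score every subject's routes (R);
#' (2) select the activated / suppressed sub-cohorts by `t_cu` / `t_cd`;
#' (3) correlate every candidate with the TF over the selected cohort;
#' (4) classify candidates into Up (`rho > t_gu`) and Down (`rho < t_gd`)
#' targets; (5) extend the pathway with the classified sets; (6) score the
#' extended pathway (M). All intermediates are returned for audit; the
#' computation is deterministic.
#'
#' @param p A `pd_pathway` with routes (use [enumerate_routes()] first if
#'   needed).
#' @param expr Gene-by-subject log2-ratio table.
#' @param ptg Candidate target genes (`pd_gene_set` or character vector).
#' @param t_pr,t_pm Route / effect p-value thresholds.
#' @param t_cu,t_cd R-score selection thresholds.
#' @param t_gu,t_gd Correlation classification thresholds.
#' @return A `pd_distill` list: `extended` (the extended pathway), `scores`
#'   (a `pd_scores` over the extended pathway), `base_scores`, `selection`,
#'   `targets`, `quality` (the [correlation_check()] result) and the
#'   thresholds used.
#' @export
distill <- function(p, expr, ptg, t_pr = 0.05, t_pm = 0.05,
                    t_cu = 0.5, t_cd = -0.5, t_gu = 0.3, t_gd = -0.3) {
  if (t_gu < t_gd) {
    pd_abort("`t_gu` must be >= `t_gd`", "pd_threshold_error")
  }
  if (t_cu < t_cd) {
    pd_abort("`t_cu` must be >= `t_cd`", "pd_threshold_error")
  }
  base_scores <- score_cohort(expr, p, t_pr = t_pr, t_pm = t_pm)
  selection <- select_subcohorts(base_scores, t_cu = t_cu, t_cd = t_cd)
  targets <- classify_targets(expr, ptg, p$tf, selection,
                              t_gu = t_gu, t_gd = t_gd)
  extended <- extend_pathway(p,
                             up = targets$gene[targets$class == "up"],
                             down = targets$gene[targets$class == "down"])
  scores <- score_cohort(expr, extended, t_pr = t_pr, t_pm = t_pm)
  quality <- correlation_check(scores, selection)
  structure(list(extended = extended, scores = scores,
                 base_scores = base_scores, selection = selection,
                 targets = targets, quality = quality,
                 thresholds = list(t_pr = t_pr, t_pm = t_pm, t_cu = t_cu,
                                   t_cd = t_cd, t_gu = t_gu, t_gd = t_gd)),
            class = "pd_distill")
}

#' @export
print.pd_distill <- function(x, ...) {
  cat(sprintf("<distillation> %s\n", x$extended$name))
  cat(sprintf("  C': %d subjects (%d activated, %d suppressed)\n",
              sum(x$selection$subcohort != "unselected"),
              sum(x$selection$subcohort == "activated"),
              sum(x$selection$subcohort == "suppressed")))
  cat(sprintf("  targets: %d Up, %d Down of %d candidates\n",
              length(x$extended$up_targets), length(x$extended$down_targets),
              nrow(x$targets)))
  cat(sprintf("  CorC = %.3f, CorC' = %.3f (%simproved)\n",
              x$quality$cor_full, x$quality$cor_selected,
              if (isTRUE(x$quality$improved)) "" else "not "))
  invisible(x)
}

#' Quality check: R-M correlation over full vs selected cohort
#'
#' A sound extension should make R and M more coherent over the selected
#' cohort `C'` than over the full cohort: `CorC' > CorC`, where both are
#' Pearson correlations between the per-subject scalar R and M.
#'
#' @param scores A `pd_scores` over an extended pathway (M present).
#' @param selection A `pd_selection`.
#' @return Tibble with `cor_full` (CorC), `cor_selected` (CorC') and
#'   `improved` (CorC' > CorC).
#' @export
correlation_check <- function(scores, selection) {
  ss <- subject_scores(scores)
  if (all(is.na(ss$M))) {
    pd_abort("scores carry no M; run on an extended pathway",
             "pd_input_error")
  }
  sel_ids <- selection$subject_id[selection$subcohort != "unselected"]
  if (length(sel_ids) < 3) {
    pd_abort("selected cohort has < 3 subjects", "pd_selection_error")
  }
  sub <- filter(ss, .data$subject_id %in% sel_ids)
  cor_full <- tryCatch(pearson_cor(ss$R, ss$M),
                       pd_constant_error = function(e) NA_real_)
  cor_sel <- tryCatch(pearson_cor(sub$R, sub$M),
                      pd_constant_error = function(e) NA_real_)
  # strictly greater, beyond floating-point jitter
  tibble(cor_full = cor_full, cor_selected = cor_sel,
         improved = !is.na(cor_full) && !is.na(cor_sel) &&
           cor_sel - cor_full > 1e-12)
}
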