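test_that("sub-cohort selection uses strict thresholds", {
  r <- c(a = 0.8, b = 0.1, c = -0.6)
  sel <- suppressWarnings(
    suppressMessages(select_subcohorts(r, t_cu = 0.5, t_cd = -0.5)))
  expect_equal(sel$subcohort[match(c("a", "b", "c"), sel$subject_id)],
               c("activated", "unselected", "suppressed"))

  # everything strictly inside the thresholds: nothing selected
  expect_error(
    suppressMessages(select_subcohorts(c(a = 0.1, b = -0.2, c = 0),
                                       0.5, -0.5)),
    class = "pd_selection_error")
  # boundary: t_cu = t_cd = 0 selects every subject with R != 0
  sel0 <- suppressMessages(
    select_subcohorts(c(a = 0.3, b = -0.1, c = 0, d = 0.2), 0, 0))
  expect_equal(sum(sel0$subcohort != "unselected"), 3)
  # fewer than 3 selected: selection warns; correlation refuses later
  expect_warning(
    suppressMessages(small <- select_subcohorts(c(a = 0.9, b = 0.8,
                                                  c = 0.1), 0.5, -0.5)),
    ">= 3")
  expect_error(
    classify_targets(toy_cohort(), "X1", "TBX21", small, 0.3, -0.3),
    class = "pd_selection_error")
  expect_error(select_subcohorts(r, t_cu = -0.5, t_cd = 0.5),
               class = "pd_threshold_error")
})

test_that("pearson_cor matches the direct product-moment formula", {
  expect_equal(pearson_cor(1:5, 1:5), 1)
  expect_equal(pearson_cor(1:5, -(1:5)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 2, 4)), 0.98198,
               tolerance = 1e-5)
  direct <- function(x, y) { # independent oracle, no stats::cor
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_cor(x, y), direct(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_cor(1:3, 1:4), class = "pd_input_error")
  expect_error(pearson_cor(1:2, 1:2), class = "pd_input_error")
  expect_error(pearson_cor(rep(1, 5), 1:5), class = "pd_constant_error")
})

make_selection <- function(ids) {
  structure(tibble::tibble(subject_id = ids, R = 1,
                           subcohort = "activated"),
            class = c("pd_selection", class(tibble::tibble())))
}

test_that("candidate classification applies strict correlation cutoffs", {
  ids <- sprintf("P%d", 1:6)
  tf <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(TF = tf,
             POS = tf * 2 + 0.001 * c(1, -1, 1, -1, 1, -1), # rho ~ 1
             NEG = -tf,                                     # rho = -1
             MID = c(2, 1, 4, 3, 6, 5),                     # rho ~ 0.77
             FLAT = rep(1, 6))
  colnames(m) <- ids
  sel <- make_selection(ids)
  cls <- suppressWarnings(
    classify_targets(m, c("POS", "NEG", "MID", "FLAT", "TF"), "TF", sel,
                     t_gu = 0.9, t_gd = -0.9))
  expect_equal(cls$class[cls$gene == "POS"], "up")
  expect_equal(cls$class[cls$gene == "NEG"], "down")
  expect_equal(cls$class[cls$gene == "MID"], "none")
  expect_false("TF" %in% cls$gene)    # TF never a candidate
  expect_false("FLAT" %in% cls$gene)  # constant gene skipped
  # rho below t_gu but above t_gd is unclassified
  cls2 <- classify_targets(m[1:4, ], "MID", "TF", sel,
                           t_gu = 0.9, t_gd = -0.3)
  expect_equal(cls2$class, "none")
  # absent candidates are skipped with a warning, not an error
  expect_warning(
    classify_targets(m[1:4, ], c("POS", "GHOST"), "TF", sel, 0.5, -0.5),
    "absent")
})

test_that("classification is order-invariant and threshold-monotone", {
  set.seed(31)
  ids <- sprintf("P%d", 1:30)
  m <- rbind(TF = rnorm(30),
             matrix(rnorm(20 * 30), nrow = 20,
                    dimnames = list(sprintf("G%d", 1:20), NULL)))
  colnames(m) <- ids
  sel <- make_selection(ids)
  cand <- sprintf("G%d", 1:20)
  a <- classify_targets(m, cand, "TF", sel, 0.2, -0.2)
  b <- classify_targets(m[, sample(30)], sample(cand), "TF", sel, 0.2, -0.2)
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$rho, b$rho)
  expect_equal(a$class, b$class)
  # raising t_gu shrinks G_u; lowering t_gd shrinks G_d
  strict <- classify_targets(m, cand, "TF", sel, 0.5, -0.5)
  expect_true(all(strict$gene[strict$class == "up"] %in%
                    a$gene[a$class == "up"]))
  expect_true(all(strict$gene[strict$class == "down"] %in%
                    a$gene[a$class == "down"]))
  expect_true(all(a$rho[a$class == "up"] > 0.2))
  expect_true(all(a$rho[a$class == "down"] < -0.2))
})

test_that("G_u and G_d never overlap when t_gu >= t_gd", {
  set.seed(37)
  ids <- sprintf("P%d", 1:20)
  sel <- make_selection(ids)
  for (i in 1:10) {
    m <- rbind(TF = rnorm(20),
               matrix(rnorm(10 * 20), nrow = 10,
                      dimnames = list(sprintf("G%d", 1:10), NULL)))
    colnames(m) <- ids
    th <- sort(runif(2, -1, 1))
    cls <- classify_targets(m, sprintf("G%d", 1:10), "TF", sel,
                            t_gu = th[2], t_gd = th[1])
    expect_length(intersect(cls$gene[cls$class == "up"],
                            cls$gene[cls$class == "down"]), 0)
  }
})

test_that("distillation recovers planted targets on a synthetic cohort", {
  co <- simulate_cohort(simulation_config(seed = 3))
  d <- suppressMessages(distill(co$pathway, co$expr, co$ptg))
  expect_setequal(d$extended$up_targets, co$planted_up)
  expect_setequal(d$extended$down_targets, co$planted_down)
  # intermediates are all returned for audit
  expect_s3_class(d$base_scores, "pd_scores")
  expect_s3_class(d$selection, "pd_selection")
  expect_s3_class(d$targets, "pd_targets")
  expect_true(all(c("cor_full", "cor_selected") %in% names(d$quality)))
  # deterministic given inputs
  d2 <- suppressMessages(distill(co$pathway, co$expr, co$ptg))
  expect_equal(tibble::as_tibble(d2$scores), tibble::as_tibble(d$scores))
  # threshold sanity precedes any computation
  expect_error(distill(co$pathway, co$expr, co$ptg, t_gu = -0.5,
                       t_gd = 0.5),
               class = "pd_threshold_error")
})

test_that("the correlation quality check compares C' against the cohort", {
  ids <- sprintf("P%d", 1:10)
  sc <- structure(
    tibble::tibble(subject_id = ids, route_id = "r1",
                   R = seq(-0.9, 0.9, length.out = 10),
                   R_subject = seq(-0.9, 0.9, length.out = 10),
                   M = seq(-0.9, 0.9, length.out = 10)),
    class = c("pd_scores", class(tibble::tibble())))
  sel <- suppressMessages(select_subcohorts(sc, 0.3, -0.3))
  q <- correlation_check(sc, sel)
  expect_equal(q$cor_full, 1)      # M identical to R
  expect_equal(q$cor_selected, 1)
  expect_false(q$improved)         # equal, not strictly greater
  expect_error(correlation_check(dplyr::mutate(sc, M = NA_real_), sel),
               class = "pd_input_error")
})

test_that("FDR-based size caps trim the weakest members", {
  sel <- make_selection(sprintf("P%d", 1:10))
  sel$R <- seq(0.1, 1, by = 0.1)
  capped <- cap_by_fdr(sel, 0.3)
  expect_equal(sum(capped$subcohort == "activated"), 7)
  expect_true(all(capped$R[capped$subcohort == "activated"] > 0.3))

  cls <- structure(tibble::tibble(gene = sprintf("G%d", 1:4),
                                  rho = c(0.9, 0.5, -0.8, -0.4),
                                  class = c("up", "up", "down", "down")),
                   class = c("pd_targets", class(tibble::tibble())))
  capped2 <- cap_by_fdr(cls, 0.5)
  expect_equal(capped2$class, c("up", "none", "down", "none"))
})

test_that("quantile thresholds translate levels into cutoffs", {
  v <- 1:100
  th <- quantile_thresholds(v, upper = 0.9, lower = 0.1)
  expect_equal(th$t_upper, quantile(v, 0.9, names = FALSE))
  expect_equal(th$t_lower, quantile(v, 0.1, names = FALSE))
})
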