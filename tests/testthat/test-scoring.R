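test_that("empirical p-values equal add-one tail counts", {
  pop <- c(-2, -1, 0, 1, 2)
  expect_equal(empirical_pvalue(2, pop, "up"), 2 / 6)
  expect_equal(empirical_pvalue(3, pop, "up"), 1 / 6) # beyond the maximum
  expect_equal(empirical_pvalue(0, pop, "two"), 1)    # capped at the median
  expect_error(empirical_pvalue(1, numeric(1)), class = "pd_input_error")
})

test_that("empirical p-values agree with exhaustive counting, any input", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    pop <- round(rnorm(n), 1)
    y <- round(rnorm(1), 1)
    k_up <- 0; k_dn <- 0
    for (s in pop) { # independent oracle: explicit loop counts
      if (s >= y) k_up <- k_up + 1
      if (s <= y) k_dn <- k_dn + 1
    }
    expect_equal(empirical_pvalue(y, pop, "up"), (k_up + 1) / (n + 1))
    expect_equal(empirical_pvalue(y, pop, "down"), (k_dn + 1) / (n + 1))
    expect_equal(empirical_pvalue(y, pop, "two"),
                 min(1, 2 * min((k_up + 1) / (n + 1), (k_dn + 1) / (n + 1))))
  }
})

test_that("consistency follows the activation/inhibition sign rules", {
  expect_equal(consistency(1.2, 0.8, 1), 1)   # same sign, activation
  expect_equal(consistency(1.2, 0.8, -1), -1) # same sign, inhibition
  expect_equal(consistency(-1.2, 0.8, -1), 1)
  expect_equal(consistency(0, 0.8, 1), 0)     # zero fold-change is neutral
  expect_error(consistency(1, 1, 0), class = "pd_input_error")
})

test_that("the plug-in FDR is clamped and degenerate-safe", {
  expect_equal(fdr_estimate(10, 0.05, 5), 0.1)
  expect_equal(fdr_estimate(10, 0.05, 0), 1)
  expect_equal(fdr_estimate(10, 1, 10), 1)
  expect_error(fdr_estimate(10, 0, 5), class = "pd_threshold_error")
})

test_that("route scores reproduce hand-evaluated formula cases", {
  rt <- data.frame(gene = c("A", "B", "C", "D"), net_sign = 1)
  tfv <- c(TF = 1)
  all_cons <- c(A = 1, B = 0.5, C = 2, D = 0.1, tfv)
  expect_equal(route_score(all_cons, rt, tf = "TF", fdr = 0), 1)
  three_one <- c(A = 1, B = 0.5, C = 2, D = -0.1, tfv)
  expect_equal(route_score(three_one, rt, tf = "TF", fdr = 0), 0.5)
  all_incons <- c(A = -1, B = -0.5, C = -2, D = -0.1, tfv)
  expect_equal(route_score(all_incons, rt, tf = "TF", fdr = 0.2), -0.8)
  # missing gene names the offender
  expect_error(route_score(tfv, rt, tf = "TF", fdr = 0),
               class = "pd_missing_gene_error")
})

test_that("route scores compute their FDR from cohort populations", {
  # population of 9 per gene; each subject value exceeds its whole
  # population, so p = 1/10; at t_pr = 0.2 all 4 pass: FDR = 4*0.2/4 = 0.2
  rt <- data.frame(gene = c("A", "B", "C", "D"), net_sign = 1)
  subj <- c(A = 10, B = 10, C = 10, D = 10, TF = 1)
  pops <- list(A = 1:9, B = 1:9, C = 1:9, D = 1:9)
  expect_equal(route_score(subj, rt, pops, tf = "TF", t_pr = 0.2),
               1 * (1 - 0.2))
  # at t_pr = 0.05 nothing passes: FDR = 1, score collapses to 0
  expect_equal(route_score(subj, rt, pops, tf = "TF", t_pr = 0.05), 0)
})

test_that("effect scores reproduce hand-evaluated formula cases", {
  mk_ext <- function(n_up, n_dn) {
    extend_pathway(toy_pathway(), up = sprintf("U%d", seq_len(n_up)),
                   down = sprintf("D%d", seq_len(n_dn)))
  }
  ext <- mk_ext(4, 4)
  tfv <- c(TBX21 = 1)
  # all Up with the TF, all Down against: M = 1
  s1 <- c(setNames(rep(1, 4), sprintf("U%d", 1:4)),
          setNames(rep(-1, 4), sprintf("D%d", 1:4)), tfv)
  expect_equal(effect_score(s1, ext, fdr = 0), 1)
  # half consistent: M = 0
  s2 <- c(setNames(c(1, 1, -1, -1), sprintf("U%d", 1:4)),
          setNames(c(-1, -1, 1, 1), sprintf("D%d", 1:4)), tfv)
  expect_equal(effect_score(s2, ext, fdr = 0), 0)
  # 6 consistent, 2 inconsistent of 8 at FDR 0.1: (4/8) * 0.9 = 0.45
  s3 <- c(setNames(c(1, 1, 1, -1), sprintf("U%d", 1:4)),
          setNames(c(-1, -1, -1, 1), sprintf("D%d", 1:4)), tfv)
  expect_equal(effect_score(s3, ext, fdr = 0.1), 0.45)
  # empty target set directs to R-only scoring
  expect_error(effect_score(s1, toy_pathway(), fdr = 0),
               class = "pd_empty_targets_error")
})

test_that("effect score equals the patient-level form A_k(1-FDR)/(n+m)
           when every consistent target is significant", {
  # 3 Up with the TF, 1 Down against it: all 4 consistent, all at the
  # extreme of their population (p = 1/10), so A_k = n + m = 4
  ext <- extend_pathway(toy_pathway(), up = c("U1", "U2", "U3"),
                        down = "D1")
  subj <- c(U1 = 10, U2 = 10, U3 = 10, D1 = -10, TBX21 = 1)
  pops <- list(U1 = 1:9, U2 = 1:9, U3 = 1:9, D1 = -(1:9))
  t_pm <- 0.2
  fdr <- fdr_estimate(4, t_pm, 4)
  a_k <- 4
  expect_equal(effect_score(subj, ext, pops, t_pm = t_pm),
               a_k * (1 - fdr) / 4)
})

test_that("R and M stay in [-1, 1] on random fixtures and R is
           antisymmetric under a global edge-sign flip", {
  set.seed(99)
  rt <- data.frame(gene = c("A", "B", "C"), net_sign = c(1, -1, 1))
  rt_flip <- transform(rt, net_sign = -net_sign)
  ext <- extend_pathway(toy_pathway(), up = c("A", "B"), down = "C")
  for (i in 1:1000) {
    vals <- round(rnorm(4, sd = 2), 2)
    subj <- c(A = vals[1], B = vals[2], C = vals[3], TF = vals[4],
              TBX21 = vals[4])
    fdr <- runif(1)
    r <- route_score(subj, rt, tf = "TF", fdr = fdr)
    m <- effect_score(subj, ext, fdr = fdr)
    expect_true(r >= -1 && r <= 1)
    expect_true(m >= -1 && m <= 1)
    expect_equal(route_score(subj, rt_flip, tf = "TF", fdr = fdr), -r)
  }
})

test_that("cohort scoring composes the per-subject primitives", {
  m <- toy_cohort()
  p <- toy_pathway()
  sc <- score_cohort(m, p, t_pr = 0.3)
  expect_s3_class(sc, "pd_scores")
  expect_equal(nrow(sc), ncol(m)) # one route
  rt <- p$routes[p$routes$gene != "TBX21", ]
  for (s in colnames(m)) {
    expect_equal(sc$R[sc$subject_id == s],
                 route_score(m[, s], rt, m, tf = "TBX21", t_pr = 0.3))
  }
  expect_true(all(is.na(sc$M)))

  ext <- extend_pathway(p, up = "X1", down = "X2")
  sc2 <- score_cohort(m, ext, t_pr = 0.3, t_pm = 0.3)
  for (s in colnames(m)) {
    expect_equal(sc2$M[sc2$subject_id == s],
                 effect_score(m[, s], ext, m, t_pm = 0.3))
  }
})

test_that("the subject scalar R is the route score of maximal magnitude", {
  p2 <- pathway(
    nodes = data.frame(id = c("A", "B", "TF", "BP"),
                       role = c("kinase", "kinase", "tf", "process")),
    edges = data.frame(src = c("A", "B"), dst = "TF", sign = c(1, -1)),
    routes = list(ra = c("A", "TF"), rb = c("B", "TF")))
  set.seed(1)
  m <- matrix(rnorm(4 * 12), nrow = 4,
              dimnames = list(c("A", "B", "TF", "Z"),
                              sprintf("P%02d", 1:12)))
  sc <- score_cohort(m, p2, t_pr = 0.5)
  per <- tidyr::pivot_wider(tibble::as_tibble(sc[, 1:3]),
                            names_from = "route_id", values_from = "R")
  ss <- subject_scores(sc)
  for (i in seq_len(nrow(per))) {
    rs <- c(per$ra[i], per$rb[i])
    expect_equal(ss$R[ss$subject_id == per$subject_id[i]],
                 rs[which.max(abs(rs))])
  }
})

test_that("scoring errors identify missing pathway genes", {
  m <- toy_cohort()
  p <- toy_pathway()
  expect_error(score_cohort(m[-1, ], p), "IFNG",
               class = "pd_missing_gene_error")
})
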