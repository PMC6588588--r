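test_that("KM estimates match the closed-form product-limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  allc <- km_estimate(c(4, 9, 2), c(0, 0, 0))
  expect_true(all(allc$survival == 1))

  one <- km_estimate(5, 1)
  expect_equal(one$survival, 0)

  # random uncensored fixtures vs an explicit product-limit loop
  set.seed(17)
  for (i in 1:20) {
    t <- sample(1:50, sample(3:12, 1), replace = TRUE)
    km <- km_estimate(t, rep(1, length(t)))
    n <- length(t)
    surv <- 1
    expected <- numeric(0)
    for (tt in sort(unique(t))) {
      d <- sum(t == tt); at_risk <- sum(t >= tt)
      surv <- surv * (1 - d / at_risk)
      expected <- c(expected, surv)
    }
    expect_equal(km$survival, expected)
  }
  expect_error(km_estimate(numeric(0), numeric(0)),
               class = "pd_input_error")
})

test_that("censored KM and log-rank match the frozen independent oracle", {
  fx <- survival_fixture()
  # oracle: lifelines KaplanMeierFitter on group a, values frozen
  km <- km_estimate(fx$time[1:10], fx$event[1:10])
  oracle_surv <- c(0.9, 0.9, 0.7875, 0.675, 0.675, 0.54, 0.405, 0.405,
                   0.2025, 0.0)
  expect_equal(km$survival, oracle_surv, tolerance = 1e-6)

  clin <- clinical_from_fixture(fx)
  lr2 <- logrank_test(clin, setNames(fx$group2, fx$ids))
  # oracle: lifelines multivariate_logrank_test, frozen
  expect_equal(lr2$statistic, 3.026462887526661, tolerance = 1e-6)
  expect_equal(lr2$p_value, 0.08191641552789475, tolerance = 1e-6)
  expect_equal(lr2$df, 1)

  lr4 <- logrank_test(clin, setNames(fx$group4, fx$ids))
  expect_equal(lr4$statistic, 18.570865463453917, tolerance = 1e-6)
  expect_equal(lr4$df, 3)

  td <- tidy(lr2)
  expect_equal(td$p.value, lr2$p_value)
})

test_that("log-rank is null on identical groups and label/order invariant", {
  clin <- tibble::tibble(subject_id = sprintf("S%d", 1:10),
                         time_days = rep(c(3, 5, 8, 12, 20), 2),
                         event = rep(c(1, 1, 0, 1, 1), 2))
  g <- setNames(rep(c("x", "y"), each = 5), clin$subject_id)
  lr <- logrank_test(clin, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  fx <- survival_fixture()
  clin2 <- clinical_from_fixture(fx)
  base <- logrank_test(clin2, setNames(fx$group2, fx$ids))
  relabel <- setNames(ifelse(fx$group2 == "a", "z", "q"), fx$ids)
  expect_equal(logrank_test(clin2, relabel)$statistic, base$statistic)
  shuf <- sample(20)
  expect_equal(
    logrank_test(clin2[shuf, ], setNames(fx$group2, fx$ids)[shuf])$statistic,
    base$statistic)

  expect_error(logrank_test(clin2, setNames(rep("a", 20), fx$ids)),
               class = "pd_group_error")
})

test_that("binary and quadrant stratification follow the strict rules", {
  ss <- tibble::tibble(subject_id = c("a", "b", "c"),
                       R = c(0.2, -0.3, 0), M = c(0.4, -0.2, 0))
  g <- stratify(ss, "M", beta = 0)
  expect_equal(g$group[match(c("a", "b"), g$subject_id)], c("high", "low"))
  expect_false("c" %in% g$subject_id) # score == beta excluded
  expect_false(attr(g, "flagged"))

  flat <- stratify(tibble::tibble(subject_id = c("a", "b"), M = c(0, 0)),
                   "M", 0)
  expect_true(attr(flat, "flagged"))

  th1 <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                        M = c(0.5, 0.5, -0.5, -0.5))
  th2 <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                        M = c(0.5, -0.5, 0.5, -0.5))
  q <- stratify_quadrant(th1, th2)
  expect_equal(q$group[match(c("a", "b", "c", "d"), q$subject_id)],
               c("high-high", "high-low", "low-high", "low-low"))
})

test_that("the threshold sweep records skipped cells and is deterministic", {
  set.seed(23)
  n <- 60
  ss <- structure(
    tibble::tibble(subject_id = sprintf("S%02d", 1:n), route_id = "r",
                   R = runif(n, -0.8, 0.8), R_subject = 0, M = 0),
    class = c("pd_scores", class(tibble::tibble())))
  ss$R_subject <- ss$R
  ss$M <- ss$R + rnorm(n, 0, 0.2)
  clin <- tibble::tibble(subject_id = ss$subject_id,
                         time_days = rexp(n, 1 / 500) + 1,
                         event = rbinom(n, 1, 0.7))
  sw <- threshold_sweep(ss, clin)
  expect_true(all(sw$skipped[abs(sw$beta - 1) < 1e-9]))
  expect_true(all(sw$skipped[abs(sw$beta + 1) < 1e-9]))
  expect_true(any(!sw$skipped))
  expect_true(all(sw$n_high[!sw$skipped] >= 10))
  expect_identical(sw, threshold_sweep(ss, clin))
})

test_that("stage-stratified analysis tests each stage separately", {
  fx <- survival_fixture()
  clin <- clinical_from_fixture(fx)
  groups <- tibble::tibble(subject_id = fx$ids, group = fx$group2)

  clin$stage <- rep(c("I", "II"), 10)
  res <- stage_stratified_analysis(groups, clin)
  expect_equal(res$stage, c("I", "II"))
  expect_true(all(res$testable))

  # a stage with a single subject is untestable
  clin$stage <- c(rep("I", 19), "III")
  res2 <- stage_stratified_analysis(groups, clin)
  expect_false(res2$testable[res2$stage == "III"])
  expect_true(res2$testable[res2$stage == "I"])

  expect_error(stage_stratified_analysis(groups, clin[, 1:3]),
               class = "pd_input_error")
})

test_that("decoys preserve topology and never reuse pathway genes", {
  p <- extend_pathway(toy_pathway(), up = c("U1", "U2"), down = "D1")
  universe <- sprintf("N%03d", 1:50)
  d1 <- generate_decoys(p, universe, k = 10, seed = 7)
  d2 <- generate_decoys(p, universe, k = 10, seed = 7)
  expect_equal(d1, d2) # seeded reproducibility
  own <- setdiff(c(p$nodes$id, p$up_targets, p$down_targets), p$process)
  for (d in d1) {
    expect_equal(nrow(d$nodes), nrow(p$nodes))
    expect_equal(d$edges$sign, p$edges$sign)
    expect_equal(nrow(d$routes), nrow(p$routes))
    expect_equal(length(d$up_targets), length(p$up_targets))
    expect_equal(length(d$down_targets), length(p$down_targets))
    expect_equal(d$nodes$id[d$nodes$role == "process"], p$process)
    replaced <- setdiff(c(d$nodes$id, d$up_targets, d$down_targets),
                        d$process)
    expect_length(intersect(replaced, own), 0)
    expect_false(anyDuplicated(replaced) > 0) # without replacement
  }
  expect_error(generate_decoys(p, universe[1:4], k = 1),
               class = "pd_input_error")
})

test_that("decoy gene replacement is marginally uniform over the universe", {
  p <- toy_pathway()
  universe <- sprintf("N%02d", 1:20)
  decoys <- generate_decoys(p, universe, k = 5000, seed = 11)
  # the gene replacing IFNG across decoys should be ~uniform over 20 genes
  repl <- vapply(decoys, function(d) d$nodes$id[1], "")
  tab <- table(factor(repl, levels = universe))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("the 2-of-3 decoy criterion behaves at its edges", {
  x <- seq(-0.5, 0.9, length.out = 100)
  same <- decoy_significance(x, x)
  expect_false(same$significant)
  expect_equal(same$criteria_met, 0)
  expect_equal(same$correlation, 1)

  set.seed(19)
  truev <- rnorm(200, 0.5, 0.1)
  decoy <- rnorm(200, -0.3, 0.1)
  far <- decoy_significance(truev, decoy)
  expect_true(far$significant)
  expect_equal(far$criteria_met, 3)

  # shifted but strongly correlated: only the two difference tests fire
  shifted <- decoy_significance(x, x - 0.4)
  expect_equal(shifted$criteria_met, 2)
  expect_true(shifted$significant)

  # same distribution, uncorrelated: only the correlation criterion fires
  a <- rnorm(500); b <- rnorm(500)
  null_case <- decoy_significance(a, b)
  expect_false(null_case$significant)

  expect_error(decoy_significance(1:2, 1:2), class = "pd_input_error")
})

test_that("overlap analysis enumerates Venn regions and common cores", {
  cls <- list(
    stad = list(up = c("A", "B", "C"), down = c("X")),
    brca = list(up = c("B", "C", "D"), down = c("Y")),
    coad = list(up = c("B", "C"), down = c("Z")))
  ov <- overlap_analysis(cls)
  expect_equal(ov$core_up, c("B", "C"))
  expect_length(ov$core_down, 0) # disjoint Down sets
  up_regions <- ov$regions[ov$regions$side == "up", ]
  expect_equal(up_regions$count[up_regions$region == "stad&brca&coad"], 2)
  expect_equal(up_regions$count[up_regions$region == "stad"], 1)

  # identical single-gene sets across 5 cohorts
  five <- replicate(5, list(up = "G", down = character()), simplify = FALSE)
  names(five) <- paste0("c", 1:5)
  expect_equal(overlap_analysis(five)$core_up, "G")
  expect_error(overlap_analysis(cls[1]), class = "pd_input_error")
})

test_that("restricting targets to a core keeps only core genes", {
  ext <- extend_pathway(toy_pathway(), up = c("U1", "U2"),
                        down = c("D1", "D2"))
  r <- restrict_targets(ext, c("U1", "D2", "Q"))
  expect_equal(r$up_targets, "U1")
  expect_equal(r$down_targets, "D2")
})

test_that("long-term event-free subjects can be excluded", {
  clin <- tibble::tibble(subject_id = c("a", "b", "c"),
                         time_days = c(2000, 2000, 100),
                         event = c(0, 1, 0))
  kept <- exclude_longterm_eventfree(clin)
  expect_equal(kept$subject_id, c("b", "c"))
})
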