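test_that("rank-based AUC matches the pair-counting oracle", {
  lab <- factor(rep(c("neg", "pos"), each = 3), c("neg", "pos"))
  # perfectly separated
  expect_equal(as.numeric(univariate_auc(c(1, 2, 3, 7, 8, 9), lab)), 1)
  # identical distributions
  expect_equal(as.numeric(univariate_auc(c(1, 2, 3, 1, 2, 3), lab)), 0.5)
  # orientation: lower-in-positives still reports >= 0.5 with direction
  a <- univariate_auc(c(7, 8, 9, 1, 2, 3), lab)
  expect_equal(as.numeric(a), 1)
  expect_identical(attr(a, "direction"), "<")
  set.seed(61)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    v <- sample(round(rnorm(n), 1))  # ties likely
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    auc <- univariate_auc(v, factor(pos, c(FALSE, TRUE)), TRUE)
    oracle <- pair_count_auc(v, pos)
    expect_equal(as.numeric(auc), max(oracle, 1 - oracle), tolerance = 1e-12)
  }
  expect_error(univariate_auc(1:3, factor(rep("a", 3), c("a", "b"))),
               "both classes")
})

test_that("univariate panel statistics behave on constructed panels", {
  set.seed(67)
  n <- 40
  lab <- factor(rep(c("oral", "IM"), each = n / 2), c("oral", "IM"))
  base <- rnorm(n)
  d <- tibble::tibble(
    a = 2^(base + (lab == "IM") * 2 + rnorm(n, 0, 0.1)) * 100,
    b = 2^(base + (lab == "IM") * 2 + rnorm(n, 0, 0.1)) * 50,   # tracks a
    c = 2^(-base + rnorm(n, 0, 0.1)) * 10,                       # anti-tracks
    d = 2^rnorm(n) * 1000                                        # independent
  )
  res <- univariate_stats(d, lab, positive = "IM", n_clusters = 2)
  expect_equal(res$feature[1], res$feature[res$auc == max(res$auc)][1])
  ra <- res[match(c("a", "b", "c", "d"), res$feature), ]
  # duplicated/correlated features share a cluster; |rho| co-clusters the
  # anticorrelated partner too
  expect_equal(ra$cluster[1], ra$cluster[2])
  expect_equal(ra$cluster[1], ra$cluster[3])
  expect_false(ra$cluster[4] == ra$cluster[1])
  expect_gt(ra$log2fc[1], 1.5)
  expect_lt(ra$p[1], 1e-6)
  # constant feature degrades gracefully
  res2 <- univariate_stats(tibble::tibble(k = rep(2, n), a = d$a), lab)
  expect_equal(res2$auc[res2$feature == "k"], 0.5)
  expect_equal(res2$p[res2$feature == "k"], 1)
})

test_that("confusion-matrix percentages match the reference arithmetic", {
  ss <- sensitivity_specificity(tp = 83, fn = 10, fp = 15, tn = 75)
  expect_equal(ss$sensitivity_pct, 89)
  expect_equal(ss$specificity_pct, 83)
  expect_equal(ss$sensitivity, 100 * 83 / 93)
  expect_equal(ss$accuracy, 100 * (83 + 75) / 183)
  perfect <- sensitivity_specificity(10, 0, 0, 12)
  expect_equal(c(perfect$sensitivity, perfect$specificity), c(100, 100))
  even <- sensitivity_specificity(1, 1, 1, 1)
  expect_equal(c(even$sensitivity, even$specificity, even$accuracy),
               c(50, 50, 50))
  expect_error(sensitivity_specificity(0, 0, 1, 1), "at least one")
})

test_that("a perfectly separating feature yields a perfect MCCV report", {
  set.seed(71)
  lab <- factor(rep(c("oral", "IM"), each = 12), c("oral", "IM"))
  d <- tibble::tibble(x = c(rnorm(12, 0, 0.1), rnorm(12, 10, 0.1)))
  rep <- mccv_rf(d, lab, positive = "IM", runs = 10, trees = 50, seed = 2)
  expect_equal(rep$auc, 1)
  cm <- rep$confusion
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(12, 0, 0, 12))
})

test_that("MCCV report is deterministic and internally consistent", {
  panel <- fix_panel()
  r1 <- suppressWarnings(mccv_rf(panel$data, panel$labels, positive = "IM",
                                 runs = 5, trees = 100, seed = 9))
  r2 <- suppressWarnings(mccv_rf(panel$data, panel$labels, positive = "IM",
                                 runs = 5, trees = 100, seed = 9))
  expect_identical(r1$roc, r2$roc)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$importance, r2$importance)
  # pooled AUC equals the trapezoidal area and the pair-count of scores
  held <- r1$votes$times_held_out > 0
  expect_equal(sum(r1$confusion$tp + r1$confusion$fn),
               sum(panel$labels[held] == "IM"))
  expect_equal(sum(r1$confusion$fp + r1$confusion$tn),
               sum(panel$labels[held] == "oral"))
  expect_true(r1$ci[["lower"]] <= r1$ci[["upper"]])
  expect_gte(min(r1$roc$tpr), 0); expect_lte(max(r1$roc$tpr), 1)
  expect_equal(r1$roc$tpr[1], 0); expect_equal(max(r1$roc$fpr), 1)
})

test_that("pooled trapezoidal AUC equals the rank statistic of pooled scores", {
  set.seed(73)
  lab <- factor(rep(c("n", "p"), 15), c("n", "p"))
  d <- tibble::tibble(x = rnorm(30) + (lab == "p") * 1,
                      y = rnorm(30))
  rep <- mccv_rf(d, lab, positive = "p", runs = 6, trees = 60, seed = 4)
  # reconstruct pooled scores from the ROC invariant instead: the
  # trapezoid area must match a direct pair-count on the curve steps
  auc_steps <- sum(diff(rep$roc$fpr) *
                     (head(rep$roc$tpr, -1) + tail(rep$roc$tpr, -1)) / 2)
  expect_equal(rep$auc, auc_steps, tolerance = 1e-9)
})

test_that("label permutation gives chance-level pooled AUC", {
  panel <- fix_panel()
  set.seed(79)
  perm <- sample(panel$labels)
  rep <- mccv_rf(panel$data, perm, positive = "IM", runs = 30, trees = 300,
                 seed = 6)
  expect_gte(rep$auc, 0.35)
  expect_lte(rep$auc, 0.65)
})

test_that("tidiers summarize the report", {
  panel <- fix_panel()
  rep <- suppressWarnings(mccv_rf(panel$data, panel$labels, positive = "IM",
                                  runs = 5, trees = 100, seed = 9))
  g <- glance(rep)
  held <- rep$votes$times_held_out > 0
  expect_equal(g$tp + g$fn, sum(panel$labels[held] == "IM"))
  expect_equal(g$fp + g$tn, sum(panel$labels[held] == "oral"))
  expect_equal(nrow(tidy(rep)), 5)
  expect_true(all(diff(tidy(rep)$mean_decrease_accuracy) <= 1e-12))
})
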