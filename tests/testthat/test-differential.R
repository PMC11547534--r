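two_group_table <- function(log2_baseline, log2_post) {
  n1 <- length(log2_baseline); n2 <- length(log2_post)
  areas <- matrix(2^c(log2_baseline, log2_post), nrow = 1)
  feature_table(
    tibble::tibble(feature_id = "F1", mz = 300, rt = 5),
    tibble::tibble(sample_id = paste0("s", seq_len(n1 + n2)),
                   role = "sample", group = "oral",
                   time_h = rep(c(0, 24), c(n1, n2))),
    areas
  )
}

test_that("two-group fits match hand-computed pooled-variance inputs", {
  # baseline log2 (2,3,4), post (5,6,10): means 3 and 7, SS 2 and 14
  t <- two_group_table(c(2, 3, 4), c(5, 6, 10))
  fit <- fit_feature_models(t, c("baseline", "baseline", "baseline",
                                 "post", "post", "post"))
  expect_equal(fit$log2fc, 4)
  expect_equal(fit$s2, (2 + 14) / 4)
  expect_equal(fit$df, 4)
  # identical groups: zero fold change
  t0 <- two_group_table(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fit_feature_models(t0, rep(c("a", "b"), each = 3))$log2fc, 0)
  # doubling all post values shifts log2FC by exactly +1
  t2 <- two_group_table(c(2, 3, 4), c(5, 6, 10) + 1)
  fit2 <- fit_feature_models(t2, rep(c("baseline", "post"), each = 3))
  expect_equal(fit2$log2fc, fit$log2fc + 1)
  expect_equal(fit2$s2, fit$s2)
  expect_error(fit_feature_models(t, c("a", "a", "a", "a", "a", "b")),
               "at least 2")
  expect_error(fit_feature_models(t, rep("a", 6)), "2 levels")
})

test_that("empirical-Bayes prior recovery and degenerate behavior", {
  # simulated scaled-inverse-chi-square prior is recovered within 10%
  set.seed(19)
  d0 <- 4; s0_2 <- 2; df <- 10; n <- 5000
  sigma2 <- s0_2 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  eb <- eb_moderate(s2, df)
  expect_lt(abs(eb$d0 - d0) / d0, 0.1)
  expect_lt(abs(eb$s0_2 - s0_2) / s0_2, 0.1)
  expect_equal(eb$s2_post, (eb$d0 * eb$s0_2 + df * s2) / (eb$d0 + df))
  # homogeneous variances: infinite prior df; every posterior collapses
  # to the prior variance (the log-scale moment estimator applies the
  # chi-square bias correction exp(log(df/2) - digamma(df/2)), as the
  # reference empirical-Bayes implementation does)
  s2c <- rep(3, 100)
  ebc <- suppressWarnings(eb_moderate(s2c, 10))
  expect_identical(ebc$d0, Inf)
  expect_equal(ebc$s2_post, rep(ebc$s0_2, 100))
  expect_equal(ebc$s0_2, 3 * exp(log(5) - digamma(5)), tolerance = 1e-9)
  expect_equal(var(ebc$s2_post), 0)
  expect_error(eb_moderate(rep(0, 20), 10), "zero")
})

test_that("moderation agrees with the established empirical-Bayes reference", {
  skip_if_not_installed("limma")
  set.seed(23)
  s2 <- rlnorm(2000, -1, 0.8)
  eb <- eb_moderate(s2, 8)
  sq <- limma::squeezeVar(s2, 8)
  expect_equal(eb$d0, sq$df.prior, tolerance = 0.02)
  expect_equal(eb$s0_2, sq$var.prior, tolerance = 0.02)
  expect_equal(eb$s2_post, sq$var.post, tolerance = 0.05)
})

test_that("moderated t reduces to classical pooled t when d0 = 0", {
  set.seed(29)
  x <- rnorm(5, 0); y <- rnorm(6, 1)
  fc <- mean(y) - mean(x)
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 9
  tp <- moderated_t_and_p(fc, s2, df = 9, d0 = 0, n1 = 5, n2 = 6)
  ref <- t.test(y, x, var.equal = TRUE)
  expect_equal(tp$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tp$p, ref$p.value, tolerance = 1e-12)
  # infinite prior df: normal reference
  tpz <- moderated_t_and_p(1, 0.5, df = 9, d0 = Inf, n1 = 5, n2 = 6)
  se <- sqrt(0.5 * (1 / 5 + 1 / 6))
  expect_equal(tpz$p, 2 * pnorm(-1 / se), tolerance = 1e-12)
  # zero effect, zero variance: p = 1 by convention
  expect_equal(moderated_t_and_p(0, 0, 9, 0, 5, 6)$p, 1)
  expect_equal(moderated_t_and_p(0, 1, 9, 0, 5, 6)$t, 0)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(37)
  for (i in 1:25) {
    p <- round(runif(sample(1:40, 1)), 3)  # rounding forces ties
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("volcano categorization follows the three-tier rule set", {
  # p fails -> grey no matter the fold change
  v <- volcano_classify(c(0.5, 0.01, 0.01, 0.1, 0.1),
                        c(5, 2, -3.5, 3, 0))
  expect_equal(as.character(v$class),
               c("non-significant", "mid-significant", "significant",
                 "significant", "mid-significant"))
  expect_equal(as.character(v$direction), c("up", "up", "down", "up", "none"))
  # boundaries count as passing: adj p = 0.1 and |log2FC| = 3
  b <- volcano_classify(0.1, 3)
  expect_equal(as.character(b$class), "significant")
  # partition is exhaustive and exclusive over a grid
  grid <- expand.grid(p = c(1e-6, 0.05, 0.1, 0.2, 1),
                      fc = c(-5, -3, -1, 0, 1, 3, 5))
  cls <- volcano_classify(grid$p, grid$fc)$class
  expect_false(anyNA(cls))
  expect_error(volcano_classify(0, 1), "\\(0, 1\\]")
})

test_that("null data keeps the false-positive rate controlled", {
  set.seed(41)
  frac <- replicate(20, {
    a <- matrix(2^rnorm(50 * 12, 10, 0.5), 50, 12)
    t <- feature_table(
      tibble::tibble(feature_id = sprintf("F%02d", 1:50),
                     mz = runif(50, 100, 500), rt = runif(50, 1, 20)),
      tibble::tibble(sample_id = paste0("s", 1:12), role = "sample",
                     group = "oral", time_h = rep(c(0, 24), each = 6)),
      a
    )
    res <- differential_analysis(t, rep(c("baseline", "post"), each = 6))
    mean(res$adj_p < 0.1)
  })
  se <- sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), 0.1 + 3 * se + 1e-9)
})

test_that("differential_analysis output is internally consistent", {
  st <- fix_study()
  norm <- fix_normalized()
  cond <- ifelse(norm$samples$role != "sample", NA,
                 ifelse(norm$samples$time_h == 0, "baseline", "post"))
  res <- differential_analysis(norm, cond)
  expect_s3_class(res, "sulfo_diff")
  expect_true(all(res$adj_p >= res$p - 1e-12))
  g <- glance(res)
  expect_equal(g$n_non_significant + g$n_mid_significant + g$n_significant,
               nrow(res))
  expect_equal(g$n_baseline, 6)   # 2 horses x 3 replicates at 0 h
  expect_equal(g$n_post, 183)
  # markers planted with a post-administration shift stand out; with only
  # six baseline injections (two biological draws) BH adjustment across
  # 305 mostly-null features is conservative, so assert raw evidence plus
  # the strongest, least group-confounded marker clearing the volcano
  truth <- st$truth[!is.na(st$truth$name), ]
  mk <- res[match(truth$feature_id, res$feature_id), ]
  expect_gte(sum(mk$p < 0.05), 3)
  best <- mk[truth$name == "2-methoxyestradiol sulfate", ]
  expect_false(best$class == "non-significant")
  expect_equal(as.character(best$direction), "up")
})
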