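test_that("fill filtering keeps and drops the right features", {
  t <- toy_table()
  expect_equal(dim(filter_features(t, min_fill = 0))[1], 3)
  # F002 is missing in 2 of 10 samples: dropped at Fill% = 1
  kept <- filter_features(t, min_fill = 1)
  expect_equal(kept$features$feature_id, c("F001", "F003"))
  # threshold between 0.8 and 1 keeps exactly F002 too
  expect_equal(dim(filter_features(t, min_fill = 0.8))[1], 3)
  # S/N filter engages only when an sn column exists
  t_sn <- t
  t_sn$features$sn <- c(10, 3, 50)
  expect_equal(filter_features(t_sn, min_sn = 5)$features$feature_id,
               c("F001", "F003"))
  expect_equal(dim(filter_features(t, min_sn = 5))[1], 3)
  # MS2 requirement
  expect_equal(filter_features(t, require_ms2 = TRUE,
                               ms2_feature_ids = "F003")$features$feature_id,
               "F003")
  expect_error(filter_features(t, min_fill = 2), "min_fill")
})

test_that("missing cells are imputed as 20% of the feature minimum", {
  t <- toy_table()
  imp <- impute_missing(t)
  expect_false(anyNA(imp$areas))
  # F002 minimum observed is 900 -> imputed 180, independently per feature
  expect_equal(unname(imp$areas["F002", c("a1", "b3")]), c(180, 180))
  # observed values untouched
  expect_equal(imp$areas["F001", ], t$areas["F001", ])
  # no-missing table passes through identically
  expect_identical(impute_missing(imp)$areas, imp$areas)
  # all-missing feature cannot be imputed
  bad <- t
  bad$areas[1, ] <- NA
  expect_error(impute_missing(bad), "F001")
})

test_that("imputation and fill-filtering commute when thresholds ignore imputed cells", {
  t <- toy_table()
  a <- impute_missing(filter_features(t, min_fill = 0.5))
  b <- filter_features(impute_missing(t), min_fill = 0)  # post-imputation fill is 1
  expect_identical(a$areas, b$areas[rownames(a$areas), ])
})

test_that("LOWESS normalization is a no-op on drift-free features", {
  t <- impute_missing(toy_table())
  t$areas[1, ] <- 500  # constant feature
  norm <- lowess_normalize(t)
  expect_equal(norm$areas[1, ], t$areas[1, ], tolerance = 1e-9)
})

test_that("LOWESS normalization removes injected monotone drift", {
  set.seed(21)
  n_feat <- 60
  design <- study_design()
  st <- generate_study(design, n_background = n_feat,
                       drift = drift_model(0.8, 1.2, 0), missing_rate = 0,
                       seed = 21)
  norm <- lowess_normalize(impute_missing(st$table))
  rep <- normalization_report(norm)
  expect_true(all(rep$normalized))
  # QC CV shrinks for essentially every feature
  expect_gte(mean(rep$qc_cv_after < rep$qc_cv_before), 0.95)
  # residual QC trend (average over features, so technical noise cancels)
  # is flattened to below 10% of the injected slope
  qc <- norm$samples$role == "QC"
  x <- norm$samples$injection_order[qc] / max(norm$samples$injection_order)
  mean_qc_profile <- function(tab) {
    scaled <- sweep(tab$areas[, qc], 1, rowMeans(tab$areas[, qc]), `/`)
    colMeans(scaled)
  }
  slope <- function(y) unname(stats::coef(stats::lm(y ~ x))[2])
  pre <- slope(mean_qc_profile(impute_missing(st$table)))
  post <- slope(mean_qc_profile(norm))
  expect_gt(abs(pre), 0.2)            # the injected drift is visible
  expect_lt(abs(post), 0.1 * abs(pre))
  # QC median per feature is preserved
  f1_before <- stats::median(impute_missing(st$table)$areas[1, qc])
  expect_equal(stats::median(norm$areas[1, qc]), f1_before,
               tolerance = 0.05)
})

test_that("normalization needs at least 4 QC anchors", {
  t <- toy_table()
  t2 <- feature_table(t$features, t$samples[2:8, ], t$areas[, 2:8])
  expect_error(lowess_normalize(impute_missing(t2)), "4 QC")
})

test_that("PCA scores are deterministic and separate constructed clusters", {
  set.seed(8)
  base <- matrix(rlnorm(40 * 6, 10, 0.1), 40, 6)
  base[1:20, 4:6] <- base[1:20, 4:6] * 50   # block structure
  t <- feature_table(
    tibble::tibble(feature_id = sprintf("F%02d", 1:40), mz = runif(40, 100, 500),
                   rt = runif(40, 1, 20)),
    tibble::tibble(sample_id = paste0("s", 1:6), role = "sample",
                   group = rep(c("oral", "IM"), each = 3), time_h = 0),
    base
  )
  sc <- pca_scores(t, k = 2)
  # PC1 separates the constructed clusters
  expect_true(all(sc$PC1[1:3] * sc$PC1[4:6] < 0))
  ve <- attr(sc, "var_explained")
  expect_lte(sum(ve), 1)
  expect_true(all(diff(ve) <= 1e-12))
  # duplicated samples give identical scores
  t2 <- feature_table(t$features,
                      dplyr::mutate(t$samples[c(1, 1, 2, 3), ],
                                    sample_id = paste0("d", 1:4)),
                      t$areas[, c(1, 1, 2, 3)])
  sc2 <- pca_scores(t2, k = 2)
  expect_equal(sc2$PC1[1], sc2$PC1[2], tolerance = 1e-12)
  # constant matrix is degenerate
  t3 <- feature_table(t$features[1:2, ],
                      t$samples[1:2, c("sample_id", "role", "group", "time_h")],
                      matrix(7, 2, 2))
  expect_error(pca_scores(t3), "degenerate")
})
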