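test_that("collection schedules have 32 points with the route-specific frequent days", {
  oral <- administration_schedule("oral")
  im <- administration_schedule("IM")
  expect_length(oral, 32)
  expect_length(im, 32)
  expect_equal(oral[1], 0)
  expect_true(all(diff(oral) > 0))
  expect_true(all(c(2, 4, 6, 8, 12, 336 + c(2, 4, 6, 8, 12)) %in% oral))
  expect_true(all((168 + c(2, 4, 6, 8, 12)) %in% im))
  expect_false(any((336 + c(2, 4)) %in% im))
})

test_that("the default design reproduces the modeling dataset shape", {
  d <- study_design()
  # one oral horse (480 h missing -> 30 post-admin times) + one IM horse
  # (31), technical triplicates: 61 x 3 = 183 points with time zero removed
  expect_equal(n_post_admin_points(d), 183)
  expect_equal(sum(d$samples$role == "sample"), 189)  # + 2 x 3 baselines
  expect_gte(sum(d$samples$role == "QC"), 4)
  expect_equal(sum(d$samples$role == "control"), 2)
  expect_false(any(d$samples$sample_id == "oral_1_t480_r1"))
  # injection order is a permutation over the whole sheet
  expect_equal(sort(d$samples$sample_id), unique(sort(d$samples$sample_id)))
})

test_that("generation is byte-identical for a fixed seed", {
  a <- generate_study(n_background = 20, seed = 5)
  b <- generate_study(n_background = 20, seed = 5)
  expect_identical(a$table$areas, b$table$areas)
  expect_identical(a$truth, b$truth)
  expect_identical(a$spectra[[7]]$peaks, b$spectra[[7]]$peaks)
  c <- generate_study(n_background = 20, seed = 6)
  expect_false(identical(a$table$areas, c$table$areas))
})

test_that("generator rejects invalid specifications", {
  mk <- marker_specs()
  mk$rt[1] <- 30
  expect_error(generate_study(markers = mk), "gradient window")
  mk2 <- marker_specs()
  mk2$name[2] <- mk2$name[1]
  expect_error(generate_study(markers = mk2), "duplicate")
})

test_that("technical replicates share the biological draw", {
  st <- generate_study(n_background = 10, missing_rate = 0,
                       drift = drift_model(1, 1, 0), seed = 13)
  tab <- st$table
  long <- tibble::as_tibble(tab)
  study <- long[long$role == "sample", ]
  # within (feature, horse-time) triplet spread is technical (~10% CV);
  # across times the biological CV (~30-40%) dominates
  spread <- dplyr::summarise(
    dplyr::group_by(study, .data$feature_id, .data$group, .data$time_h),
    cv = sd(.data$area) / mean(.data$area), .groups = "drop"
  )
  expect_lt(stats::median(spread$cv), 0.15)
  across <- dplyr::summarise(
    dplyr::group_by(study, .data$feature_id, .data$group),
    cv = sd(.data$area) / mean(.data$area), .groups = "drop"
  )
  expect_gt(stats::median(across$cv), stats::median(spread$cv) * 1.5)
})

test_that("null planted effects give near-zero empirical group contrasts", {
  mk <- marker_specs()
  mk$group_log2fc <- 0
  mk$admin_log2fc <- 0
  st <- generate_study(markers = mk, n_background = 10, missing_rate = 0,
                       seed = 17)
  norm <- lowess_normalize(impute_missing(st$table))
  cond <- ifelse(norm$samples$role != "sample" | norm$samples$time_h == 0,
                 NA, norm$samples$group)
  fit <- fit_feature_models(norm, factor(cond, c("oral", "IM")))
  mk_fit <- fit[fit$feature_id %in% st$truth$feature_id[!is.na(st$truth$name)], ]
  # technical replicates share a biological draw, so the standard error
  # is taken over biological units (30 oral + 31 IM collections)
  se <- sqrt(mk_fit$s2 * (1 / 30 + 1 / 31))
  expect_true(all(abs(mk_fit$log2fc) < 3 * se))
})

test_that("planted group effects are recovered by the differential stage", {
  st <- fix_study()
  norm <- fix_normalized()
  cond <- ifelse(norm$samples$role != "sample" | norm$samples$time_h == 0,
                 NA, norm$samples$group)
  fit <- fit_feature_models(norm, factor(cond, c("oral", "IM")))
  truth <- st$truth[!is.na(st$truth$name), ]
  est <- fit$log2fc[match(truth$feature_id, fit$feature_id)]
  # includes the 2-ME2S-scale +1.15 effect at n = 90 + 93
  expect_true(all(abs(est - truth$group_log2fc) < 0.3))
})

test_that("planted effects are recovered without bias across replicates", {
  set.seed(83)
  effects <- c(0, 1, -1, 3, -3)
  est <- matrix(NA_real_, 10, length(effects))
  for (r in 1:10) {
    mk <- marker_specs()
    mk$group_log2fc <- effects
    st <- generate_study(markers = mk, n_background = 5, missing_rate = 0,
                         seed = 100 + r)
    tab <- lowess_normalize(impute_missing(st$table))
    cond <- ifelse(tab$samples$role != "sample" | tab$samples$time_h == 0,
                   NA, tab$samples$group)
    fit <- fit_feature_models(tab, factor(cond, c("oral", "IM")))
    truth <- st$truth[!is.na(st$truth$name), ]
    est[r, ] <- fit$log2fc[match(truth$feature_id[order(truth$group_log2fc)],
                                 fit$feature_id)] -
      sort(truth$group_log2fc)
  }
  expect_true(all(abs(colMeans(est)) <= 0.1))
})

test_that("QC injections cluster tighter than study samples in PCA space", {
  norm <- fix_normalized()
  sc <- pca_scores(norm, k = 2)
  mean_pair_dist <- function(m) mean(dist(m))
  qc_d <- mean_pair_dist(sc[sc$role == "QC", c("PC1", "PC2")])
  study_d <- min(
    mean_pair_dist(sc[sc$role == "sample" & sc$group == "oral",
                      c("PC1", "PC2")]),
    mean_pair_dist(sc[sc$role == "sample" & sc$group == "IM",
                      c("PC1", "PC2")])
  )
  expect_lt(qc_d, study_d)
})

test_that("sulfated ground truth carries stochastically larger IR and MA", {
  st <- fix_study()
  pr <- fix_profiles()
  tr <- dplyr::left_join(st$truth, pr, by = "feature_id")
  tr$ir[is.na(tr$ir)] <- 0
  tr$ma[is.na(tr$ma)] <- 0
  expect_lt(wilcox.test(tr$ir[tr$sulfated], tr$ir[!tr$sulfated],
                        alternative = "greater")$p.value, 0.01)
  expect_lt(wilcox.test(tr$ma[tr$sulfated], tr$ma[!tr$sulfated],
                        alternative = "greater")$p.value, 0.01)
})

test_that("sulfated features receive nonzero IR with high sensitivity", {
  st <- fix_study()
  pr <- fix_profiles()
  sulf <- st$truth$feature_id[st$truth$sulfated]
  got <- pr$feature_id[pr$ir > 0]
  expect_gte(mean(sulf %in% got), 0.99)
})
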