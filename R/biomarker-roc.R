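#' Univariate ROC area by rank statistic
#'
#' AUC as the Mann-Whitney U statistic divided by `n1 * n2` (midranks,
#' so ties count one half), oriented so the reported value is at least
#' 0.5; the attribute `"direction"` records whether higher values
#' indicate the positive class (`">"`) or the negative (`"<"`).
#'
#' @param values Numeric marker values, one per sample.
#' @param labels Class labels, two levels.
#' @param positive The positive-class label (default: the second factor
#'   level).
#' @return AUC in \[0.5, 1\] with attribute `"direction"`.
#' @export
univariate_auc <- function(values, labels, positive = NULL) {
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("`labels` must have exactly two levels", call. = FALSE)
  }
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(values)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (auc >= 0.5) {
    structure(auc, direction = ">")
  } else {
    structure(1 - auc, direction = "<")
  }
}

#' Table-style univariate biomarker statistics
#'
#' Per-feature classical univariate screen of a candidate panel: ROC
#' AUC (oriented, rank-based), two-sided Welch t-test p-value on log2
#' areas, log2 fold change `log2(mean positive) - log2(mean negative)`,
#' and a cluster id grouping features that behave alike — average-linkage
#' hierarchical clustering of `1 - |Spearman correlation|` cut at
#' `n_clusters` (anticorrelated features co-cluster, since either
#' direction carries the same classification information). A constant
#' feature gets AUC 0.5 and p 1.
#'
#' @param data Data frame/tibble of numeric feature columns, one row per
#'   sample.
#' @param labels Class labels (two levels).
#' @param positive Positive-class label (default second level).
#' @param n_clusters Number of behavior clusters (default
#'   `min(4, n features)`).
#' @return A tibble `feature`, `auc`, `p`, `log2fc`, `cluster`, sorted
#'   by decreasing AUC.
#' @export
univariate_stats <- function(data, labels, positive = NULL,
                             n_clusters = NULL) {
  data <- as.data.frame(data)
  stopifnot(all(vapply(data, is.numeric, logical(1))))
  if (!is.factor(labels)) labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  if (is.null(n_clusters)) n_clusters <- min(4L, ncol(data))
  pos <- labels == positive
  stats_one <- function(v) {
    if (stats::sd(v) == 0) {
      return(tibble::tibble(auc = 0.5, p = 1,
                            log2fc = 0))
    }
    tt <- stats::t.test(log2(v[pos]), log2(v[!pos]))
    tibble::tibble(
      auc = as.numeric(univariate_auc(v, labels, positive)),
      p = tt$p.value,
      log2fc = log2(mean(v[pos])) - log2(mean(v[!pos]))
    )
  }
  res <- purrr::map_dfr(data, stats_one)
  res <- dplyr::bind_cols(tibble::tibble(feature = names(data)), res)
  if (ncol(data) >= 2) {
    rho <- suppressWarnings(stats::cor(data, method = "spearman"))
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
    d <- stats::as.dist(1 - abs(rho))
    hc <- stats::hclust(d, method = "average")
    res$cluster <- unname(stats::cutree(hc, k = min(n_clusters, ncol(data))))
  } else {
    res$cluster <- 1L
  }
  dplyr::arrange(res, dplyr::desc(.data$auc))
}

# Empirical ROC curve of scores (higher score = more positive):
# points ordered from (0,0) to (1,1), tied scores collapsed.
roc_curve_points <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble::tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / sum(pos)),
    fpr = c(0, fp[last] / sum(!pos))
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Monte-Carlo cross-validated random-forest biomarker evaluation
#'
#' Repeated stratified splitting (default 30 runs, 2/3 train) of the
#' labeled panel; each run fits a random forest (default 300 trees,
#' library defaults otherwise) on the training portion and scores the
#' holdout. Reported are:
#' * the pooled ROC over all holdout class-probability scores across
#'   runs, with its trapezoidal AUC;
#' * a 95% band given by the 2.5/97.5 percentiles of the per-run holdout
#'   AUCs;
#' * a confusion matrix from per-sample majority vote over the runs in
#'   which the sample was held out (a run votes positive when the
#'   positive-class probability is at least 0.5; a tied vote count
#'   resolves positive);
#' * permutation importance (mean decrease in accuracy) averaged over
#'   runs.
#'
#' @param data Data frame/tibble of numeric feature columns, one row per
#'   sample; no missing values.
#' @param labels Class labels (two levels).
#' @param positive Positive-class label (default second level).
#' @param runs Number of MCCV runs (default 30).
#' @param train_frac Training fraction (default 2/3).
#' @param trees Trees per forest (default 300).
#' @param seed RNG seed; fixed seed gives identical reports (default 1).
#' @return An object of class `mccv_report`: list with `roc`, `auc`,
#'   `ci` (lower/upper), `confusion` (tp, fn, fp, tn), `importance`,
#'   `run_aucs`, `votes` and `config`. See [glance.mccv_report()] and
#'   [tidy.mccv_report()].
#' @export
mccv_rf <- function(data, labels, positive = NULL, runs = 30,
                    train_frac = 2 / 3, trees = 300, seed = 1) {
  data <- as.data.frame(data)
  stopifnot(all(vapply(data, is.numeric, logical(1))), !anyNA(data),
            runs >= 1, train_frac > 0, train_frac < 1)
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("`labels` must have exactly two levels", call. = FALSE)
  }
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n <- nrow(data)
  if (min(table(labels)) < 3) {
    stop("need at least 3 samples per class", call. = FALSE)
  }
  withr_seed(seed, {
    scores_all <- numeric(0); pos_all <- logical(0); run_of <- integer(0)
    votes_pos <- integer(n); votes_tot <- integer(n)
    imp_sum <- stats::setNames(numeric(ncol(data)), names(data))
    run_aucs <- numeric(runs)
    for (r in seq_len(runs)) {
      train <- logical(n)
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        train[sample(idx, round(length(idx) * train_frac))] <- TRUE
      }
      hold <- which(!train)
      attempts <- 0
      while (length(unique(labels[hold])) < 2 && attempts < 100) {
        train <- logical(n)
        for (lv in levels(labels)) {
          idx <- which(labels == lv)
          train[sample(idx, round(length(idx) * train_frac))] <- TRUE
        }
        hold <- which(!train)
        attempts <- attempts + 1
      }
      if (length(unique(labels[hold])) < 2) {
        stop("could not obtain a holdout containing both classes",
             call. = FALSE)
      }
      rf <- randomForest::randomForest(
        x = data[train, , drop = FALSE], y = droplevels(labels[train]),
        ntree = trees, importance = TRUE
      )
      prob <- stats::predict(rf, data[hold, , drop = FALSE],
                             type = "prob")[, positive]
      scores_all <- c(scores_all, prob)
      pos_all <- c(pos_all, pos[hold])
      run_of <- c(run_of, rep(r, length(hold)))
      votes_pos[hold] <- votes_pos[hold] + (prob >= 0.5)
      votes_tot[hold] <- votes_tot[hold] + 1L
      imp_sum <- imp_sum +
        randomForest::importance(rf, type = 1)[names(data), 1]
      # per-run holdout AUC, unoriented (score = positive-class probability)
      raw <- (sum(rank(prob)[pos[hold]]) -
                sum(pos[hold]) * (sum(pos[hold]) + 1) / 2) /
        (sum(pos[hold]) * sum(!pos[hold]))
      run_aucs[r] <- raw
    }
    roc <- roc_curve_points(scores_all, pos_all)
    auc <- trapezoid_auc(roc$fpr, roc$tpr)
    ci <- stats::quantile(run_aucs, c(0.025, 0.975), names = FALSE)
    never_held <- votes_tot == 0
    if (any(never_held)) {
      warning(sum(never_held), " sample(s) never held out; excluded from ",
              "the confusion matrix", call. = FALSE)
    }
    pred_pos <- votes_pos / pmax(votes_tot, 1L) >= 0.5
    use <- !never_held
    confusion <- tibble::tibble(
      tp = sum(pred_pos & pos & use), fn = sum(!pred_pos & pos & use),
      fp = sum(pred_pos & !pos & use), tn = sum(!pred_pos & !pos & use)
    )
    structure(list(
      roc = roc,
      auc = auc,
      ci = c(lower = ci[1], upper = ci[2]),
      confusion = confusion,
      importance = dplyr::arrange(
        tibble::tibble(feature = names(data),
                       mean_decrease_accuracy = imp_sum / runs),
        dplyr::desc(.data$mean_decrease_accuracy)
      ),
      run_aucs = run_aucs,
      votes = tibble::tibble(sample = seq_len(n), positive = pos,
                             votes_positive = votes_pos,
                             times_held_out = votes_tot),
      config = list(runs = runs, train_frac = train_frac, trees = trees,
                    seed = seed, positive = positive, n = n)
    ), class = "mccv_report")
  })
}

#' @export
print.mccv_report <- function(x, ...) {
  cm <- x$confusion
  ss <- sensitivity_specificity(cm$tp, cm$fn, cm$fp, cm$tn)
  cat(sprintf(
    paste0("<mccv_report> %d runs x %d trees on %d samples\n",
           "  pooled AUC %.3f (95%% band %.3f-%.3f)\n",
           "  confusion TP %d FN %d FP %d TN %d ",
           "(sens %d%%, spec %d%%, acc %d%%)\n"),
    x$config$runs, x$config$trees, x$config$n,
    x$auc, x$ci[["lower"]], x$ci[["upper"]],
    cm$tp, cm$fn, cm$fp, cm$tn,
    ss$sensitivity_pct, ss$specificity_pct, ss$accuracy_pct
  ))
  invisible(x)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Percentages computed exactly and rounded to the nearest integer for
#' reporting: sensitivity `100 * TP / (TP + FN)`, specificity
#' `100 * TN / (TN + FP)`, accuracy `100 * (TP + TN) / total`.
#'
#' @param tp,fn,fp,tn Confusion-matrix cell counts (actual positive
#'   predicted positive / negative; actual negative predicted positive /
#'   negative).
#' @return A one-row tibble with exact (`sensitivity`, `specificity`,
#'   `accuracy`) and rounded integer (`*_pct`) percentages.
#' @export
sensitivity_specificity <- function(tp, fn, fp, tn) {
  if (tp + fn == 0 || tn + fp == 0) {
    stop("each actual class must have at least one sample", call. = FALSE)
  }
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + fn + fp + tn)
  tibble::tibble(
    sensitivity = sens, specificity = spec, accuracy = acc,
    sensitivity_pct = round(sens), specificity_pct = round(spec),
    accuracy_pct = round(acc)
  )
}
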