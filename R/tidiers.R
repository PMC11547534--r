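#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential result
#'
#' @param x A `sulfo_diff` from [differential_analysis()].
#' @param ... Unused.
#' @return A plain tibble, one row per feature.
#' @method tidy sulfo_diff
#' @export
tidy.sulfo_diff <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "sulfo_diff")
  out
}

#' One-row summary of a differential result
#'
#' @param x A `sulfo_diff`.
#' @param ... Unused.
#' @return A tibble with the empirical-Bayes prior (`d0`, `s0_2`), group
#'   sizes, and the volcano class counts.
#' @method glance sulfo_diff
#' @export
glance.sulfo_diff <- function(x, ...) {
  counts <- table(x$class)
  tibble::tibble(
    n_features = nrow(x),
    n_baseline = attr(x, "n1"),
    n_post = attr(x, "n2"),
    d0 = attr(x, "d0"),
    s0_2 = attr(x, "s0_2"),
    n_non_significant = as.integer(counts[["non-significant"]]),
    n_mid_significant = as.integer(counts[["mid-significant"]]),
    n_significant = as.integer(counts[["significant"]])
  )
}

#' Tidy an MCCV report: feature importances
#'
#' @param x An `mccv_report` from [mccv_rf()].
#' @param ... Unused.
#' @return Tibble `feature`, `mean_decrease_accuracy`, sorted by
#'   decreasing importance.
#' @method tidy mccv_report
#' @export
tidy.mccv_report <- function(x, ...) x$importance

#' One-row summary of an MCCV report
#'
#' @param x An `mccv_report`.
#' @param ... Unused.
#' @return A tibble with pooled AUC, the 95% band, confusion counts and
#'   the derived sensitivity/specificity/accuracy percentages.
#' @method glance mccv_report
#' @export
glance.mccv_report <- function(x, ...) {
  cm <- x$confusion
  ss <- sensitivity_specificity(cm$tp, cm$fn, cm$fp, cm$tn)
  tibble::tibble(
    auc = x$auc, ci_lower = x$ci[["lower"]], ci_upper = x$ci[["upper"]],
    tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
    sensitivity = ss$sensitivity, specificity = ss$specificity,
    accuracy = ss$accuracy,
    runs = x$config$runs, trees = x$config$trees, seed = x$config$seed
  )
}
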