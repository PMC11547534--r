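#' Filter features by presence, signal-to-noise and MS/MS coverage
#'
#' Mirrors the manual refinement step applied to an alignment export:
#' keep features detected in at least a given fraction of samples
#' (Fill%), optionally above a signal-to-noise floor (uses a `sn` column
#' in the feature metadata when present; silently skipped otherwise), and
#' optionally restricted to features with a collected MS/MS spectrum.
#' Feature order is preserved.
#'
#' @param x A [feature_table()].
#' @param min_fill Minimum fraction of samples in which a feature must be
#'   present (0 disables; 1 requires presence everywhere).
#' @param min_sn Minimum signal-to-noise; applied only when the feature
#'   metadata has an `sn` column.
#' @param require_ms2 If `TRUE`, keep only features listed in
#'   `ms2_feature_ids`.
#' @param ms2_feature_ids Character vector of feature IDs with MS/MS
#'   coverage (e.g. from [align_spectra_to_features()]).
#' @return A filtered `feature_table`.
#' @export
filter_features <- function(x, min_fill = 0, min_sn = NULL,
                            require_ms2 = FALSE, ms2_feature_ids = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (min_fill < 0 || min_fill > 1) {
    stop("`min_fill` must be in [0, 1]", call. = FALSE)
  }
  fill <- rowMeans(!is.na(x$areas))
  keep <- fill >= min_fill
  if (!is.null(min_sn) && "sn" %in% names(x$features)) {
    keep <- keep & !is.na(x$features$sn) & x$features$sn >= min_sn
  }
  if (isTRUE(require_ms2)) {
    if (is.null(ms2_feature_ids)) {
      stop("`require_ms2 = TRUE` needs `ms2_feature_ids`", call. = FALSE)
    }
    keep <- keep & x$features$feature_id %in% ms2_feature_ids
  }
  feature_table(x$features[keep, , drop = FALSE], x$samples,
                x$areas[keep, , drop = FALSE])
}

#' Impute missing areas as 20% of the feature minimum
#'
#' Each missing cell is replaced by one fifth of the smallest positive
#' area observed for that feature — the standard small-value substitution
#' for left-censored peak areas. A feature with no observed positive
#' value cannot be imputed and raises an error.
#'
#' @param x A [feature_table()].
#' @param fraction Fraction of the feature minimum to substitute
#'   (default 0.2).
#' @return A `feature_table` with no missing cells.
#' @export
impute_missing <- function(x, fraction = 0.2) {
  stopifnot(inherits(x, "feature_table"))
  areas <- x$areas
  for (i in seq_len(nrow(areas))) {
    row <- areas[i, ]
    obs <- row[!is.na(row) & row > 0]
    if (anyNA(row)) {
      if (length(obs) == 0) {
        stop("feature ", x$features$feature_id[i],
             " has no observed positive value to impute from", call. = FALSE)
      }
      areas[i, is.na(row)] <- fraction * min(obs)
    }
  }
  feature_table(x$features, x$samples, areas)
}

#' QC-anchored LOWESS drift normalization
#'
#' Removes smooth injection-order intensity drift using the pooled-QC
#' injections as anchors. Per feature, a LOWESS curve is fitted to QC
#' intensity versus injection order; every sample's value is divided by
#' the curve evaluated at its own injection position and rescaled so the
#' feature's QC median is preserved. Features whose QC signal cannot
#' support a fit (fewer than 4 observed QC values, or a zero/degenerate
#' QC median) pass through unchanged and are flagged in the report.
#'
#' @param x A [feature_table()]; normally imputed first.
#' @param span LOWESS smoother span (fraction of QC points; default 0.5).
#' @param iter Robustifying iterations (default 2).
#' @return The normalized `feature_table`. A per-feature report (QC CV
#'   before/after, whether the feature was normalized) is attached as
#'   attribute `"norm_report"`; retrieve it with [normalization_report()].
#' @export
lowess_normalize <- function(x, span = 0.5, iter = 2) {
  stopifnot(inherits(x, "feature_table"))
  qc <- which(x$samples$role == "QC")
  if (length(qc) < 4) {
    stop("need at least 4 QC injections for LOWESS normalization; ",
         "rerun without normalization instead", call. = FALSE)
  }
  ord <- x$samples$injection_order
  areas <- x$areas
  cv <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  }
  report <- tibble::tibble(
    feature_id = x$features$feature_id,
    qc_cv_before = apply(areas[, qc, drop = FALSE], 1, cv),
    qc_cv_after = NA_real_,
    normalized = FALSE
  )
  for (i in seq_len(nrow(areas))) {
    y <- areas[i, qc]
    ok <- !is.na(y) & y > 0
    if (sum(ok) < 4) next
    qc_med <- stats::median(y[ok])
    if (qc_med <= 0) next
    fit <- stats::lowess(ord[qc][ok], y[ok], f = span, iter = iter)
    curve <- stats::approx(fit$x, fit$y, xout = ord, rule = 2, ties = mean)$y
    if (any(curve <= 0)) next
    areas[i, ] <- areas[i, ] / curve * qc_med
    report$normalized[i] <- TRUE
  }
  report$qc_cv_after <- apply(areas[, qc, drop = FALSE], 1, cv)
  out <- feature_table(x$features, x$samples, areas)
  attr(out, "norm_report") <- report
  out
}

#' Per-feature normalization report
#'
#' @param x A `feature_table` returned by [lowess_normalize()].
#' @return Tibble with `feature_id`, `qc_cv_before`, `qc_cv_after`,
#'   `normalized`.
#' @export
normalization_report <- function(x) {
  rep <- attr(x, "norm_report")
  if (is.null(rep)) {
    stop("no normalization report attached; run lowess_normalize() first",
         call. = FALSE)
  }
  rep
}

#' PCA sample scores for QC assessment
#'
#' Areas are log10(x + 1) transformed and feature-centered, then sample
#' scores for the leading components are computed. Component signs follow
#' a fixed convention (the largest-magnitude loading of each component is
#' positive) so repeated runs and duplicated samples give identical
#' scores.
#'
#' @param x A [feature_table()] with no missing values (impute first).
#' @param k Number of components (default 2).
#' @return A tibble of sample metadata plus score columns `PC1..PCk`,
#'   with the explained-variance fractions in attribute
#'   `"var_explained"`.
#' @export
pca_scores <- function(x, k = 2) {
  stopifnot(inherits(x, "feature_table"))
  if (nrow(x$features) < 2 || nrow(x$samples) < 2) {
    stop("PCA needs at least 2 features and 2 samples", call. = FALSE)
  }
  if (anyNA(x$areas)) {
    stop("areas contain missing values; impute before PCA", call. = FALSE)
  }
  m <- t(log10(x$areas + 1))          # samples x features
  m <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(m) < 1e-12)) {
    stop("degenerate (constant) matrix: PCA undefined", call. = FALSE)
  }
  k <- min(k, nrow(m) - 1L, ncol(m))
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(x$samples, tibble::as_tibble(scores))
  attr(out, "var_explained") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}
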