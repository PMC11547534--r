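#' Per-feature two-group linear fits on log2 areas
#'
#' Ordinary two-group model per feature on log2-transformed areas:
#' the effect is `mean(log2 group2) - mean(log2 group1)` and the residual
#' variance is pooled with `n - 2` degrees of freedom. The default
#' contrast of the workflow is pre-administration (0 h) baseline against
#' post-administration samples, but any two-level condition works (e.g.
#' oral vs IM).
#'
#' @param x A [feature_table()] with no missing values (impute first).
#' @param condition Character/factor of length `ncol(x)` giving each
#'   sample's condition, `NA` for samples to exclude; exactly two levels
#'   must remain, each with at least 2 samples. The *second* level (by
#'   factor order) is the numerator of the fold change.
#' @return A tibble `feature_id`, `log2fc`, `s2` (pooled residual
#'   variance), `df`; group sizes in attributes `"n1"`/`"n2"` and level
#'   names in `"levels"`.
#' @export
fit_feature_models <- function(x, condition) {
  stopifnot(inherits(x, "feature_table"))
  if (length(condition) != ncol(x$areas)) {
    stop("`condition` must have one entry per sample", call. = FALSE)
  }
  if (anyNA(x$areas)) {
    stop("areas contain missing values; impute first", call. = FALSE)
  }
  keep <- !is.na(condition)
  cond <- factor(condition[keep])
  if (nlevels(cond) != 2) {
    stop("`condition` must have exactly 2 levels, got ", nlevels(cond),
         call. = FALSE)
  }
  if (any(table(cond) < 2)) {
    stop("each condition needs at least 2 samples", call. = FALSE)
  }
  a <- log2(x$areas[, keep, drop = FALSE])
  if (any(!is.finite(a))) {
    stop("areas must be strictly positive for the log2 transform",
         call. = FALSE)
  }
  g1 <- cond == levels(cond)[1]
  g2 <- cond == levels(cond)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(a[, g1, drop = FALSE])
  m2 <- rowMeans(a[, g2, drop = FALSE])
  ss1 <- rowSums((a[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((a[, g2, drop = FALSE] - m2)^2)
  out <- tibble::tibble(
    feature_id = x$features$feature_id,
    log2fc = unname(m2 - m1),
    s2 = unname(ss1 + ss2) / (n1 + n2 - 2),
    df = n1 + n2 - 2
  )
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  attr(out, "levels") <- levels(cond)
  out
}

# Invert the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)); used by the empirical-Bayes moment estimator.
trigamma_inverse <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v <= 0) return(Inf)
    if (v > 1e7) return(1 / sqrt(v))
    if (v < 1e-6) return(1 / v)
    y <- 0.5 + 1 / v
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / v) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of feature variances
#'
#' Estimates a scaled inverse-chi-square prior for the per-feature
#' residual variances by the method of moments on `log(s2)`: the spread
#' of `log(s2)` beyond what the sampling chi-square distribution explains
#' determines the prior degrees of freedom `d0` (via trigamma inversion),
#' and the location determines the prior variance `s0_2`. Posterior
#' variances shrink each feature's `s2` toward `s0_2`:
#' `s2_post = (d0 * s0_2 + df * s2) / (d0 + df)`. When the observed
#' spread is no wider than the sampling distribution, `d0` is infinite
#' and every posterior variance equals `s0_2`.
#'
#' @param s2 Per-feature residual variances.
#' @param df Residual degrees of freedom (scalar or per-feature).
#' @return A list: `d0`, `s0_2`, and per-feature `s2_post`.
#' @export
eb_moderate <- function(s2, df) {
  if (all(s2 == 0)) stop("all variances are zero", call. = FALSE)
  if (length(s2) < 10) {
    warning("fewer than 10 features: prior estimates will be unstable",
            call. = FALSE)
  }
  df <- rep_len(df, length(s2))
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e)  # population moment
  excess <- evar - mean(trigamma(df[ok] / 2))
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s0_2 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, length(s2))
  } else {
    (d0 * s0_2 + df * s2) / (d0 + df)
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Moderated t-statistics and two-sided p-values
#'
#' `t = log2fc / sqrt(s2_post * (1/n1 + 1/n2))` referred to a
#' t-distribution with `d0 + df` degrees of freedom (normal when `d0` is
#' infinite; ordinary pooled t when `d0 = 0`). A feature with zero
#' posterior variance and zero fold change gets `t = 0`, `p = 1` by
#' convention.
#'
#' @param log2fc Effect estimates.
#' @param s2_post Posterior variances from [eb_moderate()].
#' @param df Residual degrees of freedom.
#' @param d0 Prior degrees of freedom.
#' @param n1,n2 Group sizes.
#' @return A tibble `t`, `p`.
#' @export
moderated_t_and_p <- function(log2fc, s2_post, df, d0, n1, n2) {
  if (any(d0 + df <= 0)) stop("d0 + df must be positive", call. = FALSE)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- ifelse(se == 0, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
              log2fc / se)
  dft <- d0 + df
  p <- ifelse(is.finite(dft), 2 * stats::pt(-abs(t), df = dft),
              2 * stats::pnorm(-abs(t)))
  p[se == 0 & log2fc == 0] <- 1
  tibble::tibble(t = t, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (with monotonicity enforcement), validating
#' that inputs are probabilities.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Three-tier volcano categorization
#'
#' The workflow's volcano rule set:
#' * non-significant: `-log10(adjusted p) < 1`;
#' * mid-significant: `-log10(adjusted p) >= 1` and `|log2FC| < 3`
#'   (fold change within +/- 8);
#' * significant: `-log10(adjusted p) >= 1` and `|log2FC| >= 3`
#'   (fold change beyond +/- 8).
#' Boundary values count as passing. Direction is `up` for positive
#' log2FC, `down` for negative, `none` at exactly zero.
#'
#' @param adj_p Adjusted p-values in (0, 1].
#' @param log2fc log2 fold changes.
#' @param neg_log_p_thresh Threshold on `-log10(adjusted p)` (default 1).
#' @param lfc_thresh Threshold on `|log2FC|` (default 3).
#' @return A tibble `class` (factor: non-significant, mid-significant,
#'   significant), `direction` (factor: down, none, up).
#' @export
volcano_classify <- function(adj_p, log2fc, neg_log_p_thresh = 1,
                             lfc_thresh = 3) {
  if (any(adj_p <= 0) || any(adj_p > 1)) {
    stop("adjusted p-values must lie in (0, 1]", call. = FALSE)
  }
  sig_p <- -log10(adj_p) >= neg_log_p_thresh
  cls <- ifelse(!sig_p, "non-significant",
                ifelse(abs(log2fc) >= lfc_thresh, "significant",
                       "mid-significant"))
  dir <- ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "none"))
  tibble::tibble(
    class = factor(cls, levels = c("non-significant", "mid-significant",
                                   "significant")),
    direction = factor(dir, levels = c("down", "none", "up"))
  )
}

#' Moderated differential analysis with volcano categorization
#'
#' End-to-end differential stage: per-feature two-group fits on log2
#' areas, empirical-Bayes variance moderation, moderated t-tests, BH
#' adjustment and the three-tier volcano categorization.
#'
#' @inheritParams fit_feature_models
#' @inheritParams volcano_classify
#' @return A tibble of class `sulfo_diff`: `feature_id`, `log2fc`, `s2`,
#'   `df`, `s2_post`, `t`, `p`, `adj_p`, `class`, `direction`. The prior
#'   (`d0`, `s0_2`), group sizes and contrast levels are attached as
#'   attributes; see [glance.sulfo_diff()].
#' @export
differential_analysis <- function(x, condition, neg_log_p_thresh = 1,
                                  lfc_thresh = 3) {
  fits <- fit_feature_models(x, condition)
  eb <- eb_moderate(fits$s2, fits$df)
  tp <- moderated_t_and_p(fits$log2fc, eb$s2_post, fits$df, eb$d0,
                          attr(fits, "n1"), attr(fits, "n2"))
  adj <- bh_adjust(tp$p)
  vc <- volcano_classify(pmax(adj, .Machine$double.xmin), fits$log2fc,
                         neg_log_p_thresh, lfc_thresh)
  out <- dplyr::bind_cols(
    fits,
    tibble::tibble(s2_post = eb$s2_post),
    tp,
    tibble::tibble(adj_p = adj),
    vc
  )
  class(out) <- c("sulfo_diff", class(out))
  attr(out, "d0") <- eb$d0
  attr(out, "s0_2") <- eb$s0_2
  attr(out, "n1") <- attr(fits, "n1")
  attr(out, "n2") <- attr(fits, "n2")
  attr(out, "levels") <- attr(fits, "levels")
  out
}
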