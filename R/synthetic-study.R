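#' Urine collection schedule for one administration route
#'
#' Reproduces the administration-study sampling scheme: daily 8 am
#' collections over 21 days (0-504 h) plus two frequent-sampling days
#' (2, 4, 6, 8 and 12 h after dosing) — the first and last administration
#' day of each route, i.e. days 0 and 14 for oral dosing and days 0 and
#' 7 for the two long-acting IM injections. Each route yields 32 time
#' points including time zero.
#'
#' @param route `"oral"` or `"IM"`.
#' @return Strictly increasing numeric vector of collection times in
#'   hours, starting at 0.
#' @export
administration_schedule <- function(route = c("oral", "IM")) {
  route <- match.arg(route)
  daily <- seq(0, 504, by = 24)
  frequent <- c(2, 4, 6, 8, 12)
  last_dose_day <- if (route == "oral") 14 else 7
  sort(unique(c(daily, frequent, last_dose_day * 24 + frequent)))
}

#' Design of a synthetic administration study
#'
#' Lays out the full injection sequence of an in-silico study: study
#' samples (per horse, collection time and technical replicate, ordered
#' by horse then time), pooled-QC injections interleaved every
#' `qc_every` study injections (plus one at the start), and external
#' control samples at the head of the sequence. Injection order is the
#' row order of the returned sheet.
#'
#' The default design mirrors the dataset used for classification
#' modeling: one oral and one IM horse, technical triplicates, and the
#' oral horse's 480 h collection missing — 61 post-administration
#' samples, 183 data points once time zero is removed.
#'
#' @param oral_horses,im_horses Number of horses per route.
#' @param replicates Technical replicates per collected sample.
#' @param qc_every Interleave one pooled-QC injection after this many
#'   study injections.
#' @param n_controls External control samples (pre-administration urine
#'   from unrelated horses) at the start of the sequence.
#' @param missing Tibble with columns `horse`, `time_h` listing
#'   collections that were never obtained. Default: the first oral
#'   horse's 480 h time point.
#' @return An object of class `study_design`: list with the injection
#'   sheet `samples` (tibble: `sample_id`, `role`, `group`, `horse`,
#'   `time_h`, `replicate`) and the design parameters.
#' @export
study_design <- function(oral_horses = 1, im_horses = 1, replicates = 3,
                         qc_every = 10, n_controls = 2,
                         missing = NULL) {
  stopifnot(oral_horses >= 0, im_horses >= 0, oral_horses + im_horses >= 1,
            replicates >= 1, qc_every >= 1, n_controls >= 0)
  if (is.null(missing)) {
    missing <- if (oral_horses >= 1) {
      tibble::tibble(horse = "oral_1", time_h = 480)
    } else {
      tibble::tibble(horse = character(0), time_h = numeric(0))
    }
  }
  horses <- tibble::tibble(
    horse = c(sprintf("oral_%d", seq_len(oral_horses)),
              sprintf("IM_%d", seq_len(im_horses))),
    group = c(rep("oral", oral_horses), rep("IM", im_horses))
  )
  study <- purrr::pmap_dfr(horses, function(horse, group) {
    tt <- administration_schedule(group)
    drop <- missing$time_h[missing$horse == horse]
    tt <- setdiff(tt, drop)
    tidyr::expand_grid(horse = horse, group = group, time_h = tt,
                       replicate = seq_len(replicates))
  })
  study$sample_id <- sprintf("%s_t%03d_r%d", study$horse,
                             as.integer(study$time_h), study$replicate)
  study$role <- "sample"

  # weave pooled QCs into the study block
  n_study <- nrow(study)
  rows <- list()
  qc_i <- 0L
  add_qc <- function() {
    qc_i <<- qc_i + 1L
    tibble::tibble(sample_id = sprintf("QC_%02d", qc_i), role = "QC",
                   group = "none", horse = NA_character_,
                   time_h = NA_real_, replicate = NA_integer_)
  }
  rows[[1]] <- add_qc()
  for (i in seq_len(n_study)) {
    rows[[length(rows) + 1L]] <- study[i, c("sample_id", "role", "group",
                                            "horse", "time_h", "replicate")]
    if (i %% qc_every == 0 || i == n_study) {
      rows[[length(rows) + 1L]] <- add_qc()
    }
  }
  controls <- if (n_controls > 0) {
    tibble::tibble(sample_id = sprintf("control_%d", seq_len(n_controls)),
                   role = "control", group = "none", horse = NA_character_,
                   time_h = 0, replicate = NA_integer_)
  } else NULL
  samples <- dplyr::bind_rows(controls, dplyr::bind_rows(rows))
  structure(
    list(samples = samples, oral_horses = oral_horses,
         im_horses = im_horses, replicates = replicates,
         qc_every = qc_every, n_controls = n_controls, missing = missing),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(x$samples$role)
  cat(sprintf(
    "<study_design> %d oral + %d IM horse(s), %d replicates: %d study, %d QC, %d control injections\n",
    x$oral_horses, x$im_horses, x$replicates,
    tab[["sample"]], tab[["QC"]],
    if ("control" %in% names(tab)) tab[["control"]] else 0L
  ))
  invisible(x)
}

#' Count post-administration data points in a design
#'
#' Study injections with time > 0 h — the data points entering the
#' classification model once pre-administration samples are removed.
#'
#' @param design A [study_design()].
#' @return Integer count.
#' @export
n_post_admin_points <- function(design) {
  stopifnot(inherits(design, "study_design"))
  sum(design$samples$role == "sample" & design$samples$time_h > 0)
}

#' Default marker panel for the synthetic study
#'
#' The five steroid sulfates the administration work identified, planted
#' with their reported route effects: `group_log2fc` is the IM-vs-oral
#' log2 fold change among post-administration samples (2-ME2S +1.15,
#' TS -0.936, E1S -3.35, CS +0.109, PregS -3.05) and `rt` the observed
#' retention times. `admin_log2fc` (shared post-administration shift
#' from baseline), base abundances and the biological/technical CVs are
#' generator choices, not reported quantities.
#'
#' @return A tibble of marker specifications, one row per compound.
#' @export
marker_specs <- function() {
  tibble::tibble(
    name = c("estrone sulfate", "testosterone sulfate",
             "2-methoxyestradiol sulfate", "pregnenolone sulfate",
             "cortisol sulfate"),
    formula = c("C18H22O5S", "C19H28O5S", "C19H26O6S", "C21H32O5S",
                "C21H30O8S"),
    rt = c(9.333, 10.108, 8.462, 12.454, 4.963),
    base_abundance = c(5e5, 8e5, 3e5, 2e5, 1e6),
    group_log2fc = c(-3.35, -0.936, 1.15, -3.05, 0.109),
    admin_log2fc = c(2, 1, 2, 1.5, 0.5),
    bio_cv = 0.4,
    tech_cv = 0.1,
    sulfated = TRUE
  )
}

#' Injection-order drift model
#'
#' Smooth multiplicative intensity drift over the acquisition sequence —
#' the signal decay/variation that pooled-QC LOWESS normalization is
#' meant to remove — plus small per-injection lognormal noise. The
#' default drifts monotonically from 0.8 at the first injection to 1.2
#' at the last.
#'
#' @param start,end Multipliers at the first and last injection; must be
#'   positive.
#' @param noise_sd Standard deviation of per-injection lognormal noise.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(start = 0.8, end = 1.2, noise_sd = 0.02) {
  stopifnot(start > 0, end > 0, noise_sd >= 0)
  structure(list(start = start, end = end, noise_sd = noise_sd),
            class = "drift_model")
}

drift_multiplier <- function(drift, order, n) {
  if (n == 1) return(rep(drift$start, length(order)))
  drift$start + (drift$end - drift$start) * (order - 1) / (n - 1)
}

# lognormal sdlog giving a multiplicative coefficient of variation cv
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate a complete synthetic administration study
#'
#' Produces an aligned feature table, one DDA MS/MS spectrum per
#' feature, and ground-truth labels, with the statistical structure the
#' downstream analysis assumes:
#' * per-feature abundances are log-normal around group means; markers
#'   shift by `admin_log2fc` after administration and by +/- half of
#'   `group_log2fc` between the IM and oral routes;
#' * technical replicates share one biological draw and differ only by
#'   technical CV;
#' * pooled QCs are the per-feature mean over the first horse's study
#'   samples, plus technical noise; external controls are baseline-level
#'   draws;
#' * every injection is multiplied by the injection-order drift;
#' * study cells are censored missing at random at `missing_rate`;
#' * sulfated features' spectra carry the diagnostic fragment/neutral-
#'   loss peaks with Poisson intensity jitter; all features carry decoy
#'   fragments drawn away (>= 0.05 Da) from any diagnostic window, and
#'   background feature m/z are drawn away (>= 0.05 Da) from every entry
#'   of the default steroid sulfate reference list.
#'
#' Fixed `seed` gives byte-identical output.
#'
#' @param design A [study_design()].
#' @param markers Marker panel, default [marker_specs()].
#' @param n_background Number of background (non-marker) features
#'   (default 300).
#' @param sulfated_frac Fraction of background features that are
#'   sulfated (default 0.18, the approximate sulfated share of aligned
#'   features in equine urine screens).
#' @param drift A [drift_model()].
#' @param missing_rate Missing-at-random rate for study cells
#'   (default 0.02).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_study`: list with `table`
#'   (a [feature_table()]), `spectra` (list of [product_spectrum()]),
#'   `truth` (tibble of ground-truth labels), `design`, `markers`,
#'   `seed`.
#' @export
generate_study <- function(design = study_design(), markers = marker_specs(),
                           n_background = 300, sulfated_frac = 0.18,
                           drift = drift_model(), missing_rate = 0.02,
                           seed = 1) {
  stopifnot(inherits(design, "study_design"), n_background >= 0,
            sulfated_frac >= 0, sulfated_frac <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (anyDuplicated(markers$name)) {
    stop("duplicate marker names", call. = FALSE)
  }
  if (any(markers$rt < 0 | markers$rt > 27.5)) {
    stop("marker RT outside the 0-27.5 min gradient window", call. = FALSE)
  }
  withr_seed(seed, generate_study_impl(design, markers, n_background,
                                       sulfated_frac, drift, missing_rate,
                                       seed))
}

generate_study_impl <- function(design, markers, n_background,
                                sulfated_frac, drift, missing_rate, seed) {
  ref_mz <- steroid_sulfate_list()$mz
  draw_background_mz <- function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        m <- stats::runif(1, 150, 600)
        if (all(abs(m - ref_mz) > 0.05)) break
      }
      out[i] <- m
    }
    out
  }
  n_mark <- nrow(markers)
  marker_theo <- vapply(markers$formula, ion_mz, numeric(1),
                        kind = "deprotonated")
  # observed feature m/z: small mass error, well inside the 5 ppm window
  marker_mz <- marker_theo * (1 + stats::rnorm(n_mark, 0, 1e-6))
  n_sulf_bg <- round(sulfated_frac * n_background)
  truth <- tibble::tibble(
    name = c(markers$name, rep(NA_character_, n_background)),
    mz = c(marker_mz, draw_background_mz(n_background)),
    rt = c(markers$rt, stats::runif(n_background, 0.5, 25)),
    base_abundance = c(markers$base_abundance,
                       stats::rlnorm(n_background, log(2e5), 1.2)),
    group_log2fc = c(markers$group_log2fc, rep(0, n_background)),
    admin_log2fc = c(markers$admin_log2fc, rep(0, n_background)),
    bio_cv = c(markers$bio_cv, rep(0.3, n_background)),
    tech_cv = c(markers$tech_cv, rep(0.1, n_background)),
    sulfated = c(markers$sulfated,
                 sample(rep(c(TRUE, FALSE),
                            c(n_sulf_bg, n_background - n_sulf_bg))))
  )
  ord <- order(truth$mz)
  truth <- truth[ord, ]
  truth$feature_id <- sprintf("F%04d", seq_len(nrow(truth)))
  truth <- dplyr::select(truth, "feature_id", dplyr::everything())
  nf <- nrow(truth)

  sheet <- design$samples
  ns <- nrow(sheet)
  study_idx <- which(sheet$role == "sample")
  qc_idx <- which(sheet$role == "QC")
  ctl_idx <- which(sheet$role == "control")

  # expected log2 level per feature x study sample
  areas <- matrix(NA_real_, nf, ns,
                  dimnames = list(truth$feature_id, sheet$sample_id))
  post <- sheet$time_h[study_idx] > 0
  im <- sheet$group[study_idx] == "IM"
  group_sign <- ifelse(im, +0.5, -0.5)
  # one biological draw per (feature, horse x time); replicates share it
  bio_key <- paste(sheet$horse[study_idx], sheet$time_h[study_idx])
  uniq_bio <- unique(bio_key)
  bio_col <- match(bio_key, uniq_bio)
  for (f in seq_len(nf)) {
    mu <- log2(truth$base_abundance[f]) +
      truth$admin_log2fc[f] * post +
      truth$group_log2fc[f] * group_sign * post
    bio_draw <- stats::rnorm(length(uniq_bio), 0,
                             cv_to_sdlog(truth$bio_cv[f]) / log(2))
    tech <- stats::rnorm(length(study_idx), 0,
                         cv_to_sdlog(truth$tech_cv[f]) / log(2))
    areas[f, study_idx] <- 2^(mu + bio_draw[bio_col] + tech)
  }
  # pooled QC: per-feature mean over the first horse's study samples
  first_horse <- sheet$horse[study_idx][1]
  pool_cols <- study_idx[sheet$horse[study_idx] == first_horse]
  qc_base <- rowMeans(areas[, pool_cols, drop = FALSE])
  for (j in qc_idx) {
    areas[, j] <- qc_base *
      2^stats::rnorm(nf, 0, cv_to_sdlog(truth$tech_cv) / log(2))
  }
  # external controls: baseline-level draws from unrelated horses
  for (j in ctl_idx) {
    areas[, j] <- truth$base_abundance *
      2^stats::rnorm(nf, 0, cv_to_sdlog(pmax(truth$bio_cv, 0.2)) / log(2))
  }
  # injection-order drift multiplies everything
  mult <- drift_multiplier(drift, seq_len(ns), ns) *
    stats::rlnorm(ns, 0, drift$noise_sd)
  areas <- sweep(areas, 2, mult, `*`)
  # missing-at-random censoring of study cells
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(nf * length(study_idx)) < missing_rate,
                   nf, length(study_idx))
    # never censor a whole feature
    all_gone <- rowSums(!drop) == 0
    drop[all_gone, 1] <- FALSE
    areas[, study_idx][drop] <- NA_real_
  }

  tab <- feature_table(
    features = tibble::tibble(feature_id = truth$feature_id,
                              mz = truth$mz, rt = truth$rt),
    samples = tibble::tibble(sample_id = sheet$sample_id, role = sheet$role,
                             group = sheet$group, time_h = sheet$time_h),
    areas = areas
  )
  spectra <- synthesize_spectra(truth)
  structure(list(table = tab, spectra = spectra, truth = truth,
                 design = design, markers = markers, seed = seed),
            class = "synthetic_study")
}

# One DDA spectrum per feature: diagnostic peaks per the sulfated flag,
# plus decoy fragments kept >= 0.05 Da away from every diagnostic
# fragment m/z and neutral-loss position.
synthesize_spectra <- function(truth) {
  ions <- diagnostic_ions()
  frag_ref <- ions$ref_mz[ions$kind == "fragment"]
  loss_ref <- ions$ref_mz[ions$kind == "neutral_loss"]
  lapply(seq_len(nrow(truth)), function(f) {
    prec <- truth$mz[f]
    forbidden <- c(frag_ref, prec - loss_ref)
    n_decoy <- sample(5:12, 1)
    decoy_mz <- numeric(n_decoy)
    for (i in seq_len(n_decoy)) {
      repeat {
        m <- stats::runif(1, 100, min(400, prec - 1))
        if (all(abs(m - forbidden) > 0.05)) break
      }
      decoy_mz[i] <- m
    }
    decoy_int <- stats::rlnorm(n_decoy, log(200), 0.6)
    mzs <- decoy_mz
    ints <- decoy_int
    if (truth$sulfated[f]) {
      if (is.na(truth$name[f])) {
        # background sulfate: 2-4 active channels at moderate intensity
        active <- sample(6, sample(2:4, 1))
        rel <- stats::runif(6, 0.2, 1) * (seq_len(6) %in% active)
      } else {
        # marker: all six channels, strong
        rel <- stats::runif(6, 0.6, 1)
      }
      for (k in which(rel > 0)) {
        pos <- if (ions$kind[k] == "fragment") ions$ref_mz[k]
               else prec - ions$ref_mz[k]
        mzs <- c(mzs, pos + stats::rnorm(1, 0, 0.001))
        ints <- c(ints, stats::rpois(1, rel[k] * 1500) + 1)
      }
    }
    product_spectrum(
      precursor_mz = prec,
      rt_min = truth$rt[f] + stats::runif(1, -1.5, 1.5) / 60,
      peaks = tibble::tibble(mz = mzs, intensity = ints),
      title = sprintf("feature=%s sample=QC_01", truth$feature_id[f])
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> seed %d: %d features (%d sulfated, %d markers), %d injections, %d spectra\n",
    x$seed, nrow(x$truth), sum(x$truth$sulfated),
    sum(!is.na(x$truth$name)), ncol(x$table$areas), length(x$spectra)
  ))
  invisible(x)
}
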