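#' Pipeline configuration
#'
#' Assembles (and validates) the full parameter set of an end-to-end
#' run. Every argument has the package default, so
#' `pipeline_config()` is a complete configuration; pass a nested list
#' (e.g. from YAML via [read_pipeline_config()]) to override parts.
#'
#' @param seed Integer seed used for every stochastic stage.
#' @param design List: `oral_horses`, `im_horses`, `replicates`,
#'   `qc_every`, `n_controls`.
#' @param simulate List: `n_background`, `sulfated_frac`,
#'   `missing_rate`, `drift_start`, `drift_end`, `drift_noise_sd`.
#' @param annotate List: `rt_tol_s`, `mz_tol_ppm`, `frag_tol`.
#' @param normalize List: `span`, `iter`.
#' @param cluster List: `restarts`.
#' @param differential List: `neg_log_p_thresh`, `lfc_thresh`.
#' @param search List: `tol_ppm`.
#' @param biomarker List: `runs`, `train_frac`, `trees`.
#' @return An object of class `pipeline_config` (a named nested list).
#' @export
pipeline_config <- function(seed = 1,
                            design = list(),
                            simulate = list(),
                            annotate = list(),
                            normalize = list(),
                            cluster = list(),
                            differential = list(),
                            search = list(),
                            biomarker = list()) {
  defaults <- list(
    seed = 1,
    design = list(oral_horses = 1, im_horses = 1, replicates = 3,
                  qc_every = 10, n_controls = 2),
    simulate = list(n_background = 300, sulfated_frac = 0.18,
                    missing_rate = 0.02, drift_start = 0.8,
                    drift_end = 1.2, drift_noise_sd = 0.02),
    annotate = list(rt_tol_s = 3, mz_tol_ppm = 5, frag_tol = 0.005),
    normalize = list(span = 0.5, iter = 2),
    cluster = list(restarts = 10),
    differential = list(neg_log_p_thresh = 1, lfc_thresh = 3),
    search = list(tol_ppm = 5),
    biomarker = list(runs = 30, train_frac = 2 / 3, trees = 300)
  )
  user <- list(seed = seed, design = design, simulate = simulate,
               annotate = annotate, normalize = normalize,
               cluster = cluster, differential = differential,
               search = search, biomarker = biomarker)
  cfg <- merge_config(defaults, user)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    }
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]])) {
        stop("configuration key '", full, "' must be a list", call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else if (length(user[[key]]) > 0) {
      if (!is.numeric(user[[key]]) || length(user[[key]]) != 1) {
        stop("configuration key '", full, "' must be a single number",
             call. = FALSE)
      }
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and validate a YAML pipeline configuration
#'
#' Parses a YAML file of (possibly partial) pipeline settings, fills in
#' the package defaults, and rejects unknown keys by name.
#'
#' @param path Path to a YAML file whose top-level keys match the
#'   arguments of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

write_report <- function(df, path, seed) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# sulfoscreen %s seed=%d",
                     as.character(utils::packageVersion("sulfoscreen")),
                     as.integer(seed)), con)
  utils::write.table(as.data.frame(df), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full workflow end to end
#'
#' Executes simulate -> annotate -> impute/normalize -> cluster ->
#' differential -> search -> biomarker on a synthetic administration
#' study and writes every stage's output, plus a machine-readable run
#' manifest, into `out_dir`. Report files carry a one-line provenance
#' header (package version and seed); the feature table and MGF keep
#' their interchange formats unadorned, with their provenance recorded
#' in the manifest. With a fixed seed a rerun into a clean directory is
#' byte-identical.
#'
#' The biomarker stage selects its panel from the search hits: for each
#' reference compound hit, the feature with the smallest absolute ppm
#' deviation; the per-sample data are the normalized, imputed areas of
#' post-administration study samples, with IM as the positive class.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with every stage's in-memory result
#'   (`study`, `profiles`, `normalized`, `clusters`, `differential`,
#'   `hits`, `univariate`, `mccv`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)

  sim <- run_stage("simulate", {
    d <- config$design
    s <- config$simulate
    generate_study(
      design = study_design(d$oral_horses, d$im_horses, d$replicates,
                            d$qc_every, d$n_controls),
      n_background = s$n_background, sulfated_frac = s$sulfated_frac,
      drift = drift_model(s$drift_start, s$drift_end, s$drift_noise_sd),
      missing_rate = s$missing_rate, seed = seed
    )
  })
  write_feature_table(sim$table, file.path(out_dir, "feature_table.csv"))
  write_mgf(sim$spectra, file.path(out_dir, "spectra.mgf"))

  # round-trip through the interchange formats, as a user run would
  tab <- run_stage("read", read_feature_table(
    file.path(out_dir, "feature_table.csv")))
  spectra <- run_stage("read", read_mgf(file.path(out_dir, "spectra.mgf")))

  profiles <- run_stage("annotate", {
    a <- config$annotate
    align_spectra_to_features(spectra, tab, rt_tol_s = a$rt_tol_s,
                              mz_tol_ppm = a$mz_tol_ppm,
                              frag_tol = a$frag_tol)
  })
  write_report(profiles, file.path(out_dir, "sulfate_profiles.csv"), seed)

  norm <- run_stage("normalize", {
    n <- config$normalize
    lowess_normalize(impute_missing(tab), span = n$span, iter = n$iter)
  })
  write_feature_table(norm, file.path(out_dir, "normalized_table.csv"))
  write_report(normalization_report(norm),
               file.path(out_dir, "normalization_report.csv"), seed)

  clusters <- run_stage("cluster", classify_sulfates(
    norm, profiles, seed = seed, restarts = config$cluster$restarts))
  write_report(clusters, file.path(out_dir, "sulfate_clusters.csv"), seed)

  diff <- run_stage("differential", {
    cond <- ifelse(norm$samples$role != "sample", NA,
                   ifelse(norm$samples$time_h == 0, "baseline", "post"))
    differential_analysis(norm, cond,
                          neg_log_p_thresh = config$differential$neg_log_p_thresh,
                          lfc_thresh = config$differential$lfc_thresh)
  })
  write_report(diff, file.path(out_dir, "differential.csv"), seed)

  hits <- run_stage("search", {
    sulf_ids <- clusters$feature_id[clusters$label == "sulfated"]
    feats <- dplyr::filter(norm$features, .data$feature_id %in% sulf_ids)
    search_sulfates(feats, tol_ppm = config$search$tol_ppm)
  })
  write_report(hits, file.path(out_dir, "search_hits.csv"), seed)

  panel <- run_stage("biomarker", {
    best <- dplyr::slice_min(dplyr::group_by(hits, .data$name),
                             order_by = abs(.data$ppm), n = 1,
                             with_ties = FALSE)
    sort(unique(best$feature_id))
  })
  is_post <- norm$samples$role == "sample" & norm$samples$time_h > 0
  labeled <- t(norm$areas[panel, is_post, drop = FALSE])
  labels <- factor(norm$samples$group[is_post], levels = c("oral", "IM"))

  uni <- run_stage("biomarker", univariate_stats(
    as.data.frame(labeled), labels, positive = "IM"))
  write_report(uni, file.path(out_dir, "univariate_stats.csv"), seed)

  mccv <- run_stage("biomarker", {
    b <- config$biomarker
    mccv_rf(as.data.frame(labeled), labels, positive = "IM",
            runs = b$runs, train_frac = b$train_frac, trees = b$trees,
            seed = seed)
  })
  write_report(mccv$roc, file.path(out_dir, "roc_points.csv"), seed)
  write_report(mccv$confusion, file.path(out_dir, "confusion.csv"), seed)
  write_report(mccv$importance, file.path(out_dir, "importance.csv"), seed)

  manifest <- list(
    package = "sulfoscreen",
    version = as.character(utils::packageVersion("sulfoscreen")),
    seed = seed,
    config = unclass(config),
    stages = list(
      features = nrow(tab$features),
      injections = nrow(tab$samples),
      spectra = length(spectra),
      profiled_features = nrow(profiles),
      normalized_features = sum(normalization_report(norm)$normalized),
      sulfated_features = sum(clusters$cluster == 1L),
      volcano_counts = as.list(table(diff$class)),
      search_hits = nrow(hits),
      panel_size = length(panel),
      modeled_samples = sum(is_post),
      pooled_auc = mccv$auc
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = sim, profiles = profiles, normalized = norm,
                 clusters = clusters, differential = diff, hits = hits,
                 panel = panel, univariate = uni, mccv = mccv,
                 manifest = manifest))
}
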