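#' Eight-parameter matrix for sulfate classification
#'
#' Builds the per-feature parameter matrix the sulfate classifier runs
#' on: the six diagnostic channel intensities plus IR and MA. Features
#' with no MS/MS profile (no spectrum was collected or assigned) get
#' all-zero rows, so every aligned feature receives a class downstream.
#' Columns are z-scored (constant columns are left at 0); the column
#' order is fixed: the six channels in [diagnostic_ions()] order, then
#' `ir`, then `ma`.
#'
#' @param profiles Tibble from [align_spectra_to_features()] (or
#'   compatible: `feature_id` plus the eight parameter columns).
#' @param feature_ids Character vector of all feature IDs to include.
#' @return A numeric matrix (features x 8) with feature IDs as row
#'   names and the pre-standardization column means/sds in attributes
#'   `"center"`/`"scale"`.
#' @export
build_parameter_matrix <- function(profiles, feature_ids) {
  cols <- c(diagnostic_ions()$label, "ir", "ma")
  m <- matrix(0, nrow = length(feature_ids), ncol = length(cols),
              dimnames = list(feature_ids, cols))
  if (nrow(profiles) > 0) {
    stopifnot(all(cols %in% names(profiles)))
    idx <- match(profiles$feature_id, feature_ids)
    if (anyNA(idx)) {
      stop("profiles contain feature IDs absent from `feature_ids`",
           call. = FALSE)
    }
    m[idx, ] <- as.matrix(profiles[, cols])
  }
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  scl_safe <- ifelse(is.na(scl) | scl == 0, 1, scl)
  z <- sweep(sweep(m, 2, ctr), 2, scl_safe, `/`)
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Two-class k-means separation of sulfated features
#'
#' Runs Lloyd's k-means with k = 2 on the standardized eight-parameter
#' matrix, keeping the best of `restarts` random initializations by
#' within-cluster sum of squares. The cluster whose centroid has the
#' larger mean of the standardized IR and MA coordinates is labeled
#' `sulfated` and assigned cluster id 1; the other is `non-sulfated`,
#' id 2 — sulfate fragmentation is abundant, so high IR/MA marks the
#' sulfated class regardless of which cluster k-means numbered first.
#'
#' @param m Matrix from [build_parameter_matrix()].
#' @param seed Integer seed making the restarts reproducible (default 1).
#' @param restarts Number of random initializations (default 10).
#' @return A tibble `feature_id`, `cluster` (1 = sulfated,
#'   2 = non-sulfated), `label`; centroids (standardized space) in
#'   attribute `"centroids"` and the winning within-cluster sum of
#'   squares in `"wcss"`.
#' @export
kmeans_two <- function(m, seed = 1, restarts = 10) {
  if (nrow(unique(m)) < 2) {
    stop("k-means with k = 2 needs at least 2 distinct rows", call. = FALSE)
  }
  km <- withr_seed(seed, stats::kmeans(m, centers = 2, nstart = restarts,
                                       iter.max = 100, algorithm = "Lloyd"))
  ir_ma <- match(c("ir", "ma"), colnames(m))
  score <- rowMeans(km$centers[, ir_ma, drop = FALSE])
  sulf_cluster <- which.max(score)
  cluster <- unname(ifelse(km$cluster == sulf_cluster, 1L, 2L))
  out <- tibble::tibble(
    feature_id = rownames(m),
    cluster = cluster,
    label = ifelse(cluster == 1L, "sulfated", "non-sulfated")
  )
  centroids <- km$centers[c(sulf_cluster, setdiff(1:2, sulf_cluster)), ,
                          drop = FALSE]
  rownames(centroids) <- c("sulfated", "non-sulfated")
  attr(out, "centroids") <- centroids
  attr(out, "wcss") <- km$tot.withinss
  out
}

# Evaluate `code` under a local RNG seed without disturbing the caller's
# RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Classify features as sulfated / non-sulfated
#'
#' Convenience wrapper: builds the eight-parameter matrix for every
#' feature in `table` from the MS/MS `profiles` and clusters it with
#' [kmeans_two()].
#'
#' @param table A [feature_table()].
#' @param profiles Output of [align_spectra_to_features()].
#' @inheritParams kmeans_two
#' @return The [kmeans_two()] assignment tibble, with the unstandardized
#'   `ir`/`ma` values joined on for plotting.
#' @export
classify_sulfates <- function(table, profiles, seed = 1, restarts = 10) {
  stopifnot(inherits(table, "feature_table"))
  m <- build_parameter_matrix(profiles, table$features$feature_id)
  out <- kmeans_two(m, seed = seed, restarts = restarts)
  raw <- tibble::tibble(feature_id = rownames(m))
  raw$ir <- 0
  raw$ma <- 0
  if (nrow(profiles) > 0) {
    idx <- match(profiles$feature_id, raw$feature_id)
    raw$ir[idx] <- profiles$ir
    raw$ma[idx] <- profiles$ma
  }
  res <- dplyr::left_join(out, raw, by = "feature_id")
  attr(res, "centroids") <- attr(out, "centroids")
  attr(res, "wcss") <- attr(out, "wcss")
  res
}
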