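# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# default synthetic administration study and derived stage outputs
fix_study <- function(seed = 42) {
  memo(paste0("study_", seed), generate_study(seed = seed))
}

fix_profiles <- function(seed = 42) {
  memo(paste0("profiles_", seed),
       align_spectra_to_features(fix_study(seed)$spectra,
                                 fix_study(seed)$table))
}

fix_normalized <- function(seed = 42) {
  memo(paste0("norm_", seed),
       lowess_normalize(impute_missing(fix_study(seed)$table)))
}

fix_clusters <- function(seed = 42) {
  memo(paste0("clusters_", seed),
       classify_sulfates(fix_normalized(seed), fix_profiles(seed), seed = 1))
}

# post-administration panel of the five planted markers, labeled by route
fix_panel <- function(seed = 42) {
  memo(paste0("panel_", seed), {
    st <- fix_study(seed)
    norm <- fix_normalized(seed)
    ids <- st$truth$feature_id[!is.na(st$truth$name)]
    is_post <- norm$samples$role == "sample" & norm$samples$time_h > 0
    list(
      data = as.data.frame(t(norm$areas[ids, is_post, drop = FALSE])),
      labels = factor(norm$samples$group[is_post], levels = c("oral", "IM"))
    )
  })
}

# tiny deterministic feature table: 3 features x 6 samples + 4 QCs
toy_table <- function() {
  features <- tibble::tibble(
    feature_id = c("F001", "F002", "F003"),
    mz = c(349.1115, 200.05, 450.2),
    rt = c(9.33, 5.0, 15.1)
  )
  samples <- tibble::tibble(
    sample_id = c("Q1", "a1", "a2", "a3", "Q2", "b1", "b2", "b3", "Q3", "Q4"),
    role = c("QC", rep("sample", 3), "QC", rep("sample", 3), "QC", "QC"),
    group = c("none", rep("oral", 3), "none", rep("IM", 3), "none", "none"),
    time_h = c(NA, 0, 0, 0, NA, 24, 24, 24, NA, NA)
  )
  areas <- matrix(c(
    100, 110, 120, 130, 100,  90, 105, 115, 100, 100,
    1000, NA, 900, 1100, 1000, 2000, 2100, NA, 1000, 1000,
    50, 60, 55, 65, 50, 70, 75, 80, 50, 50
  ), nrow = 3, byrow = TRUE)
  feature_table(features, samples, areas)
}

# brute-force within-cluster sum of squares over all 2-partitions
exhaustive_wcss2 <- function(m) {
  n <- nrow(m)
  stopifnot(n <= 12)
  wcss_part <- function(idx) {
    sum(vapply(list(m[idx, , drop = FALSE], m[!idx, , drop = FALSE]),
               function(x) sum(sweep(x, 2, colMeans(x))^2), numeric(1)))
  }
  best <- Inf
  for (mask in seq_len(2^(n - 1) - 1)) {
    idx <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (any(idx) && any(!idx)) best <- min(best, wcss_part(idx))
  }
  best
}

# O(n^2) pair-counting AUC oracle (ties count one half)
pair_count_auc <- function(values, pos) {
  vp <- values[pos]; vn <- values[!pos]
  tot <- 0
  for (a in vp) tot <- tot + sum(a > vn) + 0.5 * sum(a == vn)
  tot / (length(vp) * length(vn))
}

# O(n^2) Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(vapply(which(p >= p[i]), function(j) {
      n * p[j] / sum(p <= p[j])
    }, numeric(1))))
  }
  adj
}
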