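#' Aligned feature-by-sample peak-area table
#'
#' The central container of the workflow: aligned LC-MS features (rows)
#' against injected samples (columns), with per-feature m/z and retention
#' time and per-sample study metadata. Missing areas are `NA`.
#'
#' Sample columns are stored in injection order; `samples$injection_order`
#' is always `1:n` in column order, mirroring how an acquisition sequence
#' is laid out in an alignment export.
#'
#' @param features Tibble with columns `feature_id`, `mz`, `rt` (minutes).
#' @param samples Tibble with columns `sample_id`, `role` (`"sample"`,
#'   `"QC"` or `"control"`), `group` (`"oral"`, `"IM"` or `"none"`) and
#'   `time_h` (collection time in hours; `NA` for QCs/controls).
#' @param areas Numeric matrix (features x samples) of peak areas;
#'   `NA` marks a missing (undetected) value.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, samples, areas) {
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("feature_id", "mz", "rt") %in% names(features)),
    all(c("sample_id", "role", "group", "time_h") %in% names(samples))
  )
  areas <- as.matrix(areas)
  if (nrow(areas) != nrow(features) || ncol(areas) != nrow(samples)) {
    stop("area matrix dimensions do not match feature/sample metadata",
         call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature IDs", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  if (any(areas < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  bad_role <- setdiff(unique(samples$role), c("sample", "QC", "control"))
  if (length(bad_role) > 0) {
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  rownames(areas) <- features$feature_id
  colnames(areas) <- samples$sample_id
  samples$injection_order <- seq_len(nrow(samples))
  structure(
    list(features = features, samples = samples, areas = areas),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%d study, %d QC, %d control); %d missing cells\n",
    nrow(x$features), nrow(x$samples),
    sum(x$samples$role == "sample"), sum(x$samples$role == "QC"),
    sum(x$samples$role == "control"), sum(is.na(x$areas))
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$areas)

#' Long-format view of a feature table
#'
#' One row per (feature, sample) cell, joined with feature and sample
#' metadata — the shape dplyr/ggplot2 work expects.
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `mz`, `rt`, `sample_id`,
#'   `role`, `group`, `time_h`, `injection_order`, `area`.
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  long <- tibble::tibble(
    feature_id = rep(x$features$feature_id, times = ncol(x$areas)),
    sample_id = rep(x$samples$sample_id, each = nrow(x$areas)),
    area = as.vector(x$areas)
  )
  long <- dplyr::left_join(long, x$features, by = "feature_id")
  long <- dplyr::left_join(long, x$samples, by = "sample_id")
  dplyr::select(long, "feature_id", "mz", "rt", "sample_id", "role",
                "group", "time_h", "injection_order", "area")
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write a feature table to delimited text
#'
#' Emits the plain-text dialect used throughout the package: row 1 holds
#' `feature_id,mz,rt` then the sample IDs; rows 2-4 hold the per-sample
#' metadata (`role`, `group`, `time_h`); each following row is one
#' feature. Blank cells are missing areas. Sample columns are written in
#' injection order. Numbers are written with 17 significant digits so the
#' read/write cycle is lossless.
#'
#' @param x A `feature_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  header <- c(
    paste(c("feature_id", "mz", "rt", x$samples$sample_id), collapse = ","),
    paste(c("role", "", "", x$samples$role), collapse = ","),
    paste(c("group", "", "", x$samples$group), collapse = ","),
    paste(c("time_h", "", "", fmt_num(x$samples$time_h)), collapse = ",")
  )
  body <- vapply(seq_len(nrow(x$features)), function(i) {
    paste(c(x$features$feature_id[i], fmt_num(x$features$mz[i]),
            fmt_num(x$features$rt[i]), fmt_num(x$areas[i, ])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feature table from delimited text
#'
#' Inverse of [write_feature_table()]. Errors on duplicate feature or
#' sample IDs and on rows whose cell count does not match the header.
#'
#' @param path Path to a file in the package's feature-table dialect.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) {
    stop("feature table file must have at least 4 header rows", call. = FALSE)
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  width <- length(cells[[1]])
  if (any(lengths(cells) > width)) {
    stop("row width mismatch: expected ", width, " cells", call. = FALSE)
  }
  # strsplit drops trailing empties; pad to header width
  cells <- lapply(cells, function(x) c(x, rep("", width - length(x))))
  hdr <- cells[[1]]
  if (!identical(hdr[1:3], c("feature_id", "mz", "rt"))) {
    stop("malformed header row (expected feature_id,mz,rt,...)", call. = FALSE)
  }
  sample_id <- hdr[-(1:3)]
  meta <- function(i, label) {
    row <- cells[[i]]
    if (row[1] != label) {
      stop("metadata row ", i, " must start with '", label, "'", call. = FALSE)
    }
    row[-(1:3)]
  }
  samples <- tibble::tibble(
    sample_id = sample_id,
    role = meta(2, "role"),
    group = meta(3, "group"),
    time_h = as.numeric(ifelse(meta(4, "time_h") == "", NA, meta(4, "time_h")))
  )
  body <- cells[-(1:4)]
  features <- tibble::tibble(
    feature_id = vapply(body, `[`, character(1), 1L),
    mz = as.numeric(vapply(body, `[`, character(1), 2L)),
    rt = as.numeric(vapply(body, `[`, character(1), 3L))
  )
  areas <- matrix(NA_real_, nrow = length(body), ncol = length(sample_id))
  for (i in seq_along(body)) {
    v <- body[[i]][-(1:3)]
    areas[i, ] <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  }
  feature_table(features, samples, areas)
}
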