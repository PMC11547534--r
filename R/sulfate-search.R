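#' Build a theoretical steroid-sulfate reference list
#'
#' Computes the deprotonated-ion m/z for each (name, formula) pair via
#' the package's mass arithmetic. Entries must be sulfates: the formula
#' has to contain sulfur and at least three oxygens (the sulfate ester
#' group). Duplicate names are rejected; duplicate formulas are fine
#' (steroid isomers share compositions).
#'
#' @param entries Data frame with columns `name`, `formula`.
#' @return A tibble `name`, `formula`, `mz` (deprotonated), sorted as
#'   given.
#' @export
build_theoretical_list <- function(entries) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("name", "formula") %in% names(entries)))
  if (nrow(entries) == 0) {
    return(tibble::tibble(name = character(0), formula = character(0),
                          mz = numeric(0)))
  }
  if (anyDuplicated(entries$name)) {
    stop("duplicate compound names in reference list", call. = FALSE)
  }
  parsed <- lapply(entries$formula, parse_formula)
  for (i in seq_along(parsed)) {
    f <- parsed[[i]]
    if (!"S" %in% names(f) || f[["S"]] < 1L) {
      stop("'", entries$name[i], "' (", entries$formula[i],
           ") contains no sulfur: not a sulfate", call. = FALSE)
    }
    if (!"O" %in% names(f) || f[["O"]] < 3L) {
      stop("'", entries$name[i], "' (", entries$formula[i],
           ") has fewer than 3 oxygens: not a sulfate ester", call. = FALSE)
    }
  }
  tibble::tibble(
    name = entries$name,
    formula = vapply(parsed, formula_string, character(1)),
    mz = vapply(parsed, ion_mz, numeric(1), kind = "deprotonated")
  )
}

#' Default 26-entry steroid sulfate reference list
#'
#' The five compounds confirmed in the altrenogest administration work
#' (estrone sulfate, testosterone sulfate, 2-methoxyestradiol sulfate,
#' pregnenolone sulfate, cortisol sulfate) plus 21 further steroid
#' sulfates common in equine steroid-hormone metabolism. The extended
#' entries are representative stand-ins for a laboratory's in-house
#' screening list and should be replaced with a validated list for any
#' real casework.
#'
#' @return A [build_theoretical_list()] tibble of 26 entries.
#' @export
steroid_sulfate_list <- function() {
  build_theoretical_list(tibble::tibble(
    name = c(
      "estrone sulfate", "testosterone sulfate",
      "2-methoxyestradiol sulfate", "pregnenolone sulfate",
      "cortisol sulfate",
      "DHEA sulfate", "epitestosterone sulfate", "androsterone sulfate",
      "etiocholanolone sulfate", "epiandrosterone sulfate",
      "dihydrotestosterone sulfate", "17b-estradiol 3-sulfate",
      "17a-estradiol 3-sulfate", "estriol 3-sulfate",
      "2-methoxyestrone sulfate", "nandrolone sulfate",
      "boldenone sulfate", "epitrenbolone sulfate",
      "17a-hydroxyprogesterone sulfate", "allopregnanolone sulfate",
      "pregnanediol sulfate", "corticosterone 21-sulfate",
      "11-deoxycortisol sulfate", "cortisone 21-sulfate",
      "aldosterone 21-sulfate", "16a-hydroxy-DHEA sulfate"
    ),
    formula = c(
      "C18H22O5S", "C19H28O5S", "C19H26O6S", "C21H32O5S", "C21H30O8S",
      "C19H28O5S", "C19H28O5S", "C19H30O5S", "C19H30O5S", "C19H30O5S",
      "C19H30O5S", "C18H24O5S", "C18H24O5S", "C18H24O6S", "C19H24O6S",
      "C18H26O5S", "C19H26O5S", "C18H22O5S", "C21H30O5S", "C21H34O5S",
      "C21H36O5S", "C21H30O7S", "C21H30O7S", "C21H28O8S", "C21H28O8S",
      "C19H28O6S"
    )
  ))
}

#' Search sulfate-labeled features against a theoretical list
#'
#' Emits every (feature, compound) pair whose m/z agree within the ppm
#' tolerance (the boundary counts as a hit). A feature may hit several
#' compounds and a compound several features; ranking for manual review
#' is by `|ppm|`.
#'
#' @param features Tibble with columns `feature_id`, `mz` and optionally
#'   `rt` — normally the sulfate-labeled subset of a feature table.
#' @param reference A [build_theoretical_list()] tibble (default
#'   [steroid_sulfate_list()]).
#' @param tol_ppm Tolerance in ppm (default 5).
#' @return A tibble `feature_id`, `name`, `observed_mz`,
#'   `theoretical_mz`, `ppm`, `rt` (NA if absent), sorted by `|ppm|`.
#' @export
search_sulfates <- function(features, reference = steroid_sulfate_list(),
                            tol_ppm = 5) {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("feature_id", "mz") %in% names(features)))
  if (!is.numeric(tol_ppm) || tol_ppm < 0) {
    stop("`tol_ppm` must be non-negative", call. = FALSE)
  }
  if (nrow(features) == 0 || nrow(reference) == 0) {
    return(tibble::tibble(feature_id = character(0), name = character(0),
                          observed_mz = numeric(0), theoretical_mz = numeric(0),
                          ppm = numeric(0), rt = numeric(0)))
  }
  pairs <- tidyr::expand_grid(
    i = seq_len(nrow(features)), j = seq_len(nrow(reference))
  )
  hits <- tibble::tibble(
    feature_id = features$feature_id[pairs$i],
    name = reference$name[pairs$j],
    observed_mz = features$mz[pairs$i],
    theoretical_mz = reference$mz[pairs$j],
    rt = if ("rt" %in% names(features)) features$rt[pairs$i] else NA_real_
  )
  hits$ppm <- ppm_delta(hits$observed_mz, hits$theoretical_mz)
  hits <- dplyr::filter(hits, abs(.data$ppm) <= tol_ppm)
  hits <- dplyr::arrange(hits, abs(.data$ppm), .data$name, .data$feature_id)
  dplyr::select(hits, "feature_id", "name", "observed_mz",
                "theoretical_mz", "ppm", "rt")
}

#' Cross-dataset consistency filter
#'
#' A candidate compound is retained only when it was hit in at least
#' `min_datasets` of the per-horse (or per-batch) search runs —
#' confidence that the marker is reliably present across
#' administrations, not a one-off.
#'
#' @param hit_sets Named list of [search_sulfates()] hit tibbles, one per
#'   dataset.
#' @param min_datasets Minimum number of datasets a compound must appear
#'   in.
#' @return A tibble `name`, `n_datasets`, `retained`, with the full
#'   compound-by-dataset presence matrix in attribute `"presence"`.
#' @export
consistency_filter <- function(hit_sets, min_datasets) {
  if (length(hit_sets) < 1) stop("need at least one dataset", call. = FALSE)
  if (min_datasets > length(hit_sets)) {
    stop("`min_datasets` (", min_datasets, ") exceeds the number of datasets (",
         length(hit_sets), ")", call. = FALSE)
  }
  if (is.null(names(hit_sets))) {
    names(hit_sets) <- paste0("dataset_", seq_along(hit_sets))
  }
  compounds <- sort(unique(unlist(lapply(hit_sets, function(h) h$name))))
  presence <- vapply(hit_sets, function(h) compounds %in% h$name,
                     logical(length(compounds)))
  presence <- matrix(presence, nrow = length(compounds),
                     dimnames = list(compounds, names(hit_sets)))
  out <- tibble::tibble(
    name = compounds,
    n_datasets = unname(rowSums(presence)),
    retained = unname(rowSums(presence)) >= min_datasets
  )
  attr(out, "presence") <- presence
  out
}
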