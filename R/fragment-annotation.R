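#' The six sulfate-diagnostic MS/MS signals
#'
#' Steroid sulfates fragment predictably in negative mode: four low-mass
#' fragment ions (SO3-radical, HSO3-, SO4-radical, HSO4-) and two neutral
#' losses from the precursor (SO3 and H2SO4). Reference m/z values are
#' computed from the embedded element masses under the electron-inclusive
#' convention rather than stored as literals.
#'
#' @return A tibble with columns `label` (syntactic channel name), `kind`
#'   (`"fragment"` or `"neutral_loss"`), `formula` and `ref_mz` (fragment
#'   m/z, or loss mass in Da for neutral losses).
#' @examples
#' diagnostic_ions()
#' @export
diagnostic_ions <- function() {
  tibble::tibble(
    label = c("so3_ion", "hso3_ion", "so4_ion", "hso4_ion",
              "so3_loss", "h2so4_loss"),
    kind = c(rep("fragment", 4), rep("neutral_loss", 2)),
    formula = c("SO3", "HSO3", "SO4", "HSO4", "SO3", "H2SO4"),
    ref_mz = c(
      ion_mz("SO3", "anion"), ion_mz("HSO3", "anion"),
      ion_mz("SO4", "anion"), ion_mz("HSO4", "anion"),
      monoisotopic_mass("SO3"), monoisotopic_mass("H2SO4")
    )
  )
}

#' Match diagnostic signals in one product spectrum
#'
#' Fragment-ion entries match peaks with `|mz - ref| <= frag_tol`;
#' neutral-loss entries match peaks whose distance below the precursor is
#' within `frag_tol` of the loss mass (electron-mass asymmetry, under a
#' millidalton, is ignored). Per diagnostic, the most intense qualifying
#' peak is recorded; a single physical peak may satisfy several
#' diagnostics.
#'
#' @param spectrum A [product_spectrum()]; must be negative polarity.
#' @param ions Diagnostic set, default [diagnostic_ions()].
#' @param frag_tol Absolute match tolerance in Da (default 0.005 — the
#'   diagnostics sit at low m/z where a ppm window would be
#'   sub-millidalton).
#' @return A tibble with one row per diagnostic: `label`, `kind`,
#'   `ref_mz`, `peak_idx` (index into `spectrum$peaks`, `NA` if
#'   unmatched), `peak_mz`, `intensity` (0 if unmatched).
#' @export
match_diagnostics <- function(spectrum, ions = diagnostic_ions(),
                              frag_tol = 0.005) {
  stopifnot(inherits(spectrum, "product_spectrum"))
  if (!identical(spectrum$polarity, "negative")) {
    stop("sulfate diagnostics apply to negative-mode spectra only",
         call. = FALSE)
  }
  pk <- spectrum$peaks
  one <- function(label, kind, ref_mz) {
    delta <- if (kind == "fragment") {
      abs(pk$mz - ref_mz)
    } else {
      abs((spectrum$precursor_mz - pk$mz) - ref_mz)
    }
    hit <- which(delta <= frag_tol)
    if (length(hit) == 0) {
      tibble::tibble(label = label, kind = kind, ref_mz = ref_mz,
                     peak_idx = NA_integer_, peak_mz = NA_real_,
                     intensity = 0)
    } else {
      best <- hit[which.max(pk$intensity[hit])]
      tibble::tibble(label = label, kind = kind, ref_mz = ref_mz,
                     peak_idx = best, peak_mz = pk$mz[best],
                     intensity = pk$intensity[best])
    }
  }
  purrr::pmap_dfr(ions[c("label", "kind", "ref_mz")], one)
}

#' Sulfate profile of one spectrum: channel intensities, IR and MA
#'
#' Summarizes the diagnostic evidence for a spectrum as the workflow's
#' eight-parameter profile:
#' * the six matched channel intensities,
#' * IR (intensity ratio): summed intensity of all *distinct* peaks
#'   matched to any diagnostic, divided by the summed intensity of all
#'   peaks (each physical peak counted once even if it satisfies several
#'   diagnostics),
#' * MA (maximum abundance): the largest matched peak's intensity as a
#'   percentage of the base peak.
#'
#' @param spectrum A [product_spectrum()].
#' @param matches Output of [match_diagnostics()] on the same spectrum;
#'   computed if `NULL`.
#' @param ... Passed to [match_diagnostics()] when `matches` is `NULL`.
#' @return A one-row tibble: the six channel columns, `ir` in \[0, 1\]
#'   and `ma` in \[0, 100\].
#' @export
compute_profile <- function(spectrum, matches = NULL, ...) {
  stopifnot(inherits(spectrum, "product_spectrum"))
  if (is.null(matches)) matches <- match_diagnostics(spectrum, ...)
  total <- sum(spectrum$peaks$intensity)
  if (total <= 0) {
    stop("spectrum has zero total intensity", call. = FALSE)
  }
  idx <- unique(matches$peak_idx[!is.na(matches$peak_idx)])
  ir <- sum(spectrum$peaks$intensity[idx]) / total
  ma <- if (length(idx) == 0) 0 else {
    100 * max(spectrum$peaks$intensity[idx]) / max(spectrum$peaks$intensity)
  }
  out <- tibble::as_tibble(as.list(stats::setNames(matches$intensity,
                                                   matches$label)))
  out$ir <- ir
  out$ma <- ma
  out
}

#' Assign spectra to aligned features and profile them
#'
#' Each spectrum is assigned to the feature that minimizes the absolute
#' precursor-m/z deviation (ppm) among features within both the RT window
#' (default +/- 3 s) and the mass-accuracy window (default +/- 5 ppm);
#' ties break by smaller RT distance, then lower feature ID. Features
#' collecting several spectra keep the one with the largest base peak (a
#' proxy for precursor intensity). Unmatched spectra are reported in the
#' `unassigned` attribute.
#'
#' @param spectra List of [product_spectrum()] objects.
#' @param table A [feature_table()] whose features carry `mz` and `rt`.
#' @param rt_tol_s RT tolerance in seconds (default 3).
#' @param mz_tol_ppm Precursor mass tolerance in ppm (default 5).
#' @param frag_tol Fragment-match tolerance in Da (default 0.005).
#' @param ions Diagnostic set, default [diagnostic_ions()].
#' @return A tibble with one row per feature that received a spectrum:
#'   `feature_id`, the six channel columns, `ir`, `ma`. The number of
#'   unassigned spectra is attached as attribute `"unassigned"`.
#' @export
align_spectra_to_features <- function(spectra, table, rt_tol_s = 3,
                                      mz_tol_ppm = 5, frag_tol = 0.005,
                                      ions = diagnostic_ions()) {
  stopifnot(inherits(table, "feature_table"))
  ft <- table$features
  assign_one <- function(s) {
    dppm <- ppm_delta(s$precursor_mz, ft$mz)
    drt_s <- abs(s$rt_min - ft$rt) * 60
    ok <- which(abs(dppm) <= mz_tol_ppm & drt_s <= rt_tol_s)
    if (length(ok) == 0) return(NA_character_)
    ord <- order(abs(dppm)[ok], drt_s[ok], ft$feature_id[ok])
    ft$feature_id[ok[ord[1]]]
  }
  assigned <- vapply(spectra, assign_one, character(1))
  base_pk <- vapply(spectra, function(s) {
    if (nrow(s$peaks) == 0) 0 else max(s$peaks$intensity)
  }, numeric(1))
  keep <- tibble::tibble(
    i = seq_along(spectra), feature_id = assigned, base_pk = base_pk
  )
  keep <- dplyr::filter(keep, !is.na(.data$feature_id))
  keep <- dplyr::slice_max(
    dplyr::group_by(keep, .data$feature_id),
    order_by = .data$base_pk, n = 1, with_ties = FALSE
  )
  keep <- dplyr::ungroup(keep)
  profiles <- purrr::map_dfr(seq_len(nrow(keep)), function(r) {
    s <- spectra[[keep$i[r]]]
    p <- compute_profile(s, match_diagnostics(s, ions, frag_tol))
    dplyr::bind_cols(tibble::tibble(feature_id = keep$feature_id[r]), p)
  })
  if (nrow(profiles) == 0) {
    profiles <- tibble::tibble(
      feature_id = character(0),
      !!!stats::setNames(rep(list(numeric(0)), nrow(ions)), ions$label),
      ir = numeric(0), ma = numeric(0)
    )
  }
  profiles <- dplyr::arrange(profiles, .data$feature_id)
  attr(profiles, "unassigned") <- sum(is.na(assigned))
  profiles
}
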