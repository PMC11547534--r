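#' A single DDA product-ion spectrum
#'
#' @param precursor_mz Precursor m/z.
#' @param rt_min Retention time in minutes (converted from RTINSECONDS on
#'   MGF read).
#' @param peaks Tibble (or data frame) with columns `mz`, `intensity`;
#'   stored sorted by m/z.
#' @param title Free-text identifier (carried in the MGF TITLE line).
#' @param polarity `"negative"` for the sulfate screen.
#' @param charge Signed charge; `-1` for the deprotonated species.
#' @return An object of class `product_spectrum`.
#' @export
product_spectrum <- function(precursor_mz, rt_min, peaks, title = "",
                             polarity = "negative", charge = -1L) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$mz <= 0) || any(peaks$intensity < 0)) {
    stop("peaks need mz > 0 and intensity >= 0", call. = FALSE)
  }
  peaks <- dplyr::arrange(peaks, .data$mz)
  structure(
    list(precursor_mz = precursor_mz, rt_min = rt_min, peaks = peaks,
         title = title, polarity = polarity, charge = as.integer(charge)),
    class = "product_spectrum"
  )
}

#' @export
print.product_spectrum <- function(x, ...) {
  cat(sprintf("<product_spectrum> precursor %.4f @ %.2f min, %d peaks (%s)\n",
              x$precursor_mz, x$rt_min, nrow(x$peaks), x$title))
  invisible(x)
}

#' Write spectra to a Mascot Generic Format (MGF) file
#'
#' One `BEGIN IONS`/`END IONS` block per spectrum with `TITLE`,
#' `PEPMASS`, `RTINSECONDS` and `CHARGE=1-` headers. Peak m/z are written
#' to five decimals, so a read/write cycle preserves fragment m/z well
#' beyond the 4 d.p. the annotation uses.
#'
#' @param spectra List of [product_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- lapply(spectra, function(s) {
    stopifnot(inherits(s, "product_spectrum"))
    c(
      "BEGIN IONS",
      paste0("TITLE=", s$title),
      sprintf("PEPMASS=%.5f", s$precursor_mz),
      sprintf("RTINSECONDS=%.3f", s$rt_min * 60),
      if (s$charge < 0) paste0("CHARGE=", abs(s$charge), "-")
      else paste0("CHARGE=", s$charge, "+"),
      sprintf("%.5f %.6g", s$peaks$mz, s$peaks$intensity),
      "END IONS"
    )
  })
  writeLines(unlist(blocks %||% list(character(0))), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Read a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS` blocks into [product_spectrum()] objects.
#' `RTINSECONDS` is converted to minutes. Blocks missing `PEPMASS` are
#' skipped with a warning; structurally malformed files (nesting or
#' unterminated blocks) raise an error naming the offending line.
#'
#' @param path Path to an MGF file.
#' @return A list of `product_spectrum` objects (possibly empty).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  in_block <- FALSE
  hdr <- list()
  mzs <- NULL
  ints <- NULL
  begin_line <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" ) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", i, call. = FALSE)
      in_block <- TRUE
      hdr <- list(); mzs <- numeric(0); ints <- numeric(0); begin_line <- i
    } else if (ln == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i, call. = FALSE)
      in_block <- FALSE
      if (is.null(hdr$pepmass)) {
        warning("spectrum starting at line ", begin_line,
                " has no PEPMASS; skipped", call. = FALSE)
        next
      }
      charge <- hdr$charge %||% -1L
      out[[length(out) + 1L]] <- product_spectrum(
        precursor_mz = hdr$pepmass,
        rt_min = (hdr$rtinseconds %||% NA_real_) / 60,
        peaks = tibble::tibble(mz = mzs, intensity = ints),
        title = hdr$title %||% "",
        polarity = if (charge < 0) "negative" else "positive",
        charge = charge
      )
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (!in_block) next  # header junk outside blocks is tolerated
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") hdr$pepmass <- as.numeric(strsplit(val, "\\s+")[[1]][1])
      if (key == "RTINSECONDS") hdr$rtinseconds <- as.numeric(val)
      if (key == "TITLE") hdr$title <- val
      if (key == "CHARGE") {
        hdr$charge <- as.integer(sub("[+-]$", "", val)) *
          (if (grepl("-$", val)) -1L else 1L)
      }
    } else {
      if (!in_block) stop("peak data outside BEGIN/END IONS at line ", i,
                          call. = FALSE)
      fields <- strsplit(ln, "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(fields))
      if (length(v) < 2 || anyNA(v[1:2])) {
        stop("malformed peak line ", i, ": '", ln, "'", call. = FALSE)
      }
      mzs <- c(mzs, v[1]); ints <- c(ints, v[2])
    }
  }
  if (in_block) {
    stop("unterminated BEGIN IONS block starting at line ", begin_line,
         call. = FALSE)
  }
  out
}
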