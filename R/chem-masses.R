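#' Monoisotopic element masses
#'
#' Monoisotopic masses (Da) of the elements handled by the formula
#' arithmetic, plus the electron rest mass. Values follow the CODATA/NIST
#' recommended atomic masses (carbon-12 exactly 12 Da). The table is
#' embedded as a constant so that all m/z arithmetic is reproducible
#' offline.
#'
#' @format A named numeric vector of monoisotopic masses in Da.
#' @export
element_masses <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268
)

#' Electron rest mass in Da
#'
#' Used when converting neutral monoisotopic masses to singly charged
#' negative-ion m/z: an anion carries one extra electron.
#'
#' @export
electron_mass <- 0.00054857990907

#' Parse a molecular formula string
#'
#' Parses a Hill-style formula such as `"C18H22O5S"` into a named integer
#' vector of element counts. A missing count defaults to 1 (`"H"` is one
#' hydrogen). Repeated element symbols are summed.
#'
#' @param text A single formula string, e.g. `"C21H30O8S"`.
#' @return A named integer vector of element counts with class
#'   `"molecular_formula"`.
#' @examples
#' parse_formula("C18H22O5S")   # estrone sulfate
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty formula string", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: '", text, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(sym, names(element_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out[order(hill_rank(names(out)))], class = "molecular_formula")
}

# Hill ordering: C first, H second, remaining elements alphabetical.
hill_rank <- function(sym) {
  r <- match(sym, c("C", "H"))
  ifelse(is.na(r), 2L + rank(sym, ties.method = "first"), r)
}

#' Canonical Hill-order formula string
#'
#' @param f A `molecular_formula` (or a string, which is parsed first).
#' @return A single string; counts of 1 are omitted.
#' @export
formula_string <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

as_formula <- function(f) {
  if (inherits(f, "molecular_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) {
    if (any(f < 0) || any(f != round(f))) {
      stop("element counts must be non-negative integers", call. = FALSE)
    }
    return(structure(as.integer(f), names = names(f), class = "molecular_formula"))
  }
  stop("cannot interpret object as a molecular formula", call. = FALSE)
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", formula_string(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element monoisotopic masses weighted by counts. The empty
#' formula has mass 0.
#'
#' @param f A `molecular_formula`, formula string, or named count vector.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("SO3")    # 79.9568, the sulfite neutral-loss mass
#' monoisotopic_mass("H2SO4")  # 97.9674
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0) return(0)
  missing <- setdiff(names(f), names(element_masses))
  if (length(missing) > 0) {
    stop("no monoisotopic mass for element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(element_masses[names(f)] * unclass(f))
}

#' Negative-ion m/z of a formula
#'
#' Computes singly charged negative-ion m/z under the electron-inclusive
#' convention:
#' * `"deprotonated"` — \[M - H\]^-: neutral mass minus one hydrogen atom
#'   plus one electron.
#' * `"anion"` — the formula *is* the ion's elemental composition (e.g.
#'   `HSO4` for bisulfate, `SO3` for the sulfite radical anion): formula
#'   mass plus one electron.
#' * `"neutral_loss"` — charge 0; returns the plain monoisotopic mass so
#'   neutral-loss references can be built through the same interface.
#'
#' @param f Formula (string or `molecular_formula`).
#' @param kind One of `"deprotonated"`, `"anion"`, `"neutral_loss"`.
#' @return m/z (or mass in Da for `"neutral_loss"`).
#' @examples
#' ion_mz("HSO4", "anion")            # 96.9601
#' ion_mz("C18H22O5S", "deprotonated")  # 349.1115, estrone sulfate [M-H]-
#' @export
ion_mz <- function(f, kind = c("deprotonated", "anion", "neutral_loss")) {
  kind <- match.arg(kind)
  m <- monoisotopic_mass(f)
  switch(kind,
    deprotonated = {
      fl <- as_formula(f)
      if (!"H" %in% names(fl) || fl[["H"]] < 1L) {
        stop("deprotonation requires at least one hydrogen", call. = FALSE)
      }
      m - element_masses[["H"]] + electron_mass
    },
    anion = m + electron_mass,
    neutral_loss = m
  )
}

#' Signed mass deviation in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`, the standard accuracy
#' metric for high-resolution MS. Vectorized over both arguments.
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z; must be strictly positive.
#' @return Signed ppm deviation(s).
#' @export
ppm_delta <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("`theoretical` m/z must be positive and finite", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}
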