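# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
.MONOISOTOPIC <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.9720707300,
  P  = 30.9737615120,
  Br = 78.9183376000,
  Cl = 34.9688527100,
  Na = 22.9897692820,
  K  = 38.9637064900,
  F  = 18.9984031627,
  I  = 126.9044719000,
  Se = 79.9165218000
)

#' Mass of the proton charge carrier (Da)
#'
#' All m/z arithmetic in this package assumes positive-mode protonation with
#' this charge-carrier mass, which implicitly accounts for the electron.
#'
#' @export
PROTON_MASS <- 1.00727646677

#' Parse a molecular formula string
#'
#' Parses a Hill-like element-count string such as `"C61H88N9O15"` into a
#' named integer vector of element counts. Two-letter symbols (`Br`, `Cl`,
#' `Na`, ...) are recognized before one-letter symbols; an omitted count
#' means 1; repeated elements are summed.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts, class `"mol_formula"`.
#' @examples
#' parse_formula("C48H66BrN8O13")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- paste(tokens, collapse = "")
    stop("cannot parse formula '", text, "': unexpected characters near '",
         substr(text, nchar(covered) + 1L, nchar(text)), "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  unknown <- setdiff(sym, names(.MONOISOTOPIC))
  if (length(unknown)) {
    stop("unknown element symbol '", unknown[[1]], "' in formula '", text, "'")
  }
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[out > 0L]
  structure(out, class = "mol_formula")
}

.as_formula <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  f
}

#' Monoisotopic mass of a molecular formula
#'
#' @param f A formula string or a parsed `mol_formula`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  unknown <- setdiff(names(f), names(.MONOISOTOPIC))
  if (length(unknown)) stop("unknown element symbol '", unknown[[1]], "'")
  sum(.MONOISOTOPIC[names(f)] * as.numeric(f))
}

#' Convert neutral mass to m/z and back
#'
#' Positive-mode relation m/z = (M + z * proton) / z with the proton mass
#' [PROTON_MASS] as charge carrier. `mass_from_mz()` is the exact inverse.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param mz Observed m/z.
#' @param z Positive integer charge.
#' @return m/z (or neutral mass) in Da.
#' @export
mz_from_mass <- function(mass, z) {
  .check_charge(z)
  stopifnot(all(mass > 0))
  (mass + z * PROTON_MASS) / z
}

#' @rdname mz_from_mass
#' @export
mass_from_mz <- function(mz, z) {
  .check_charge(z)
  mz * z - z * PROTON_MASS
}

.check_charge <- function(z) {
  if (any(z < 1) || any(z != round(z))) {
    stop("charge z must be a positive integer, got ", paste(z, collapse = ", "))
  }
  invisible(TRUE)
}

#' Relative mass error in parts per million
#'
#' @param observed Observed m/z or mass.
#' @param theoretical Theoretical m/z or mass (> 0).
#' @return (observed - theoretical) / theoretical * 1e6.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical == 0)) stop("theoretical mass must be non-zero")
  (observed - theoretical) / theoretical * 1e6
}

#' Theoretical [M+H]+ m/z from a printed protonated-ion formula
#'
#' Ion formulas reported for protonated species (e.g. `"C61H88N9O15"` for an
#' [M+H]+ ion) contain the extra hydrogen. The theoretical m/z is computed as
#' the monoisotopic mass of the neutral molecule (one H fewer) plus the proton
#' charge-carrier mass, so that the electron mass is accounted for.
#'
#' @param ion_formula Character vector of protonated-species formulas.
#' @return Theoretical singly protonated m/z values in Da.
#' @examples
#' theoretical_mh("C61H88N9O15") # rivulariapeptolide 1185, ~1186.6394
#' @export
theoretical_mh <- function(ion_formula) {
  vapply(ion_formula, function(s) {
    f <- parse_formula(s)
    if (is.na(f["H"]) || f["H"] < 1L) stop("ion formula '", s, "' has no H to remove")
    f["H"] <- f["H"] - 1L
    monoisotopic_mass(unclass(f)[unclass(f) > 0]) + PROTON_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
format.mol_formula <- function(x, ...) {
  paste0(names(x), ifelse(x > 1L, x, ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula>", format(x), "\n")
  invisible(x)
}
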