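# Elemental-formula arithmetic on monoisotopic masses.
#
# Formulas are stored as named integer vectors of element counts
# (e.g. c(C = 16L, H = 32L, O = 3L)) carrying class "rg_formula".

#' Monoisotopic atomic masses (Da)
#'
#' Masses of the most abundant isotope for the elements that occur in resin
#' glycoside moieties.  Values in Da: C 12 (exact by definition),
#' H 1.00782503, O 15.9949146, N 14.0030740.
#'
#' @format Named numeric vector.
#' @export
ATOMIC_MASS <- c(
  C = 12.000000,
  H = 1.00782503,
  O = 15.9949146,
  N = 14.0030740
)

#' Physical constants used in adduct and neutral-loss arithmetic (Da)
#'
#' \code{proton} 1.007276 (the [M-H]- convention removes a proton and keeps
#' the electron), \code{electron} 0.000549, \code{water} 18.010565,
#' \code{co2} 43.989830, \code{formic_acid} 46.005480 and the formate anion
#' \code{formate} 44.998200.
#'
#' @format Named numeric vector.
#' @export
MASS_CONST <- c(
  proton      = 1.007276,
  electron    = 0.000549,
  water       = 18.010565,
  co2         = 43.989830,
  formic_acid = 46.005480,
  formate     = 44.998200
)

#' Parse a molecular formula in Hill notation
#'
#' Converts a string such as \code{"C16H32O3"} into a named integer count
#' vector.  Only element symbols with a known monoisotopic mass (C, H, O, N)
#' are accepted; an unknown symbol is an error naming the symbol.
#'
#' @param x Formula string, e.g. \code{"C62H104O27"}, or an object already
#'   produced by \code{parse_formula} (returned unchanged).
#' @return Named integer vector of element counts with class
#'   \code{"rg_formula"}.
#' @examples
#' parse_formula("C16H32O3")
#' @export
parse_formula <- function(x) {
  if (inherits(x, "rg_formula")) return(x)
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1L]]
  if (sum(nchar(parts)) != nchar(x)) {
    stop("cannot parse formula string: '", x, "'")
  }
  syms <- sub("[0-9]*$", "", parts)
  nums <- sub("^[A-Za-z]+", "", parts)
  counts <- ifelse(nzchar(nums), as.integer(nums), 1L)
  unknown <- setdiff(syms, names(ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  lev <- sort(unique(syms))
  f <- structure(as.integer(tapply(counts, factor(syms, levels = lev), sum)),
                 names = lev, class = "rg_formula")
  validate_formula(f)
  f
}

validate_formula <- function(f) {
  if (any(f < 0L)) stop("formula has negative element count")
  if (!any(f > 0L)) stop("formula must contain at least one atom")
  invisible(f)
}

#' @export
format.rg_formula <- function(x, ...) {
  # Hill notation: C, H, then alphabetic
  ord <- c(intersect(c("C", "H"), names(x)), sort(setdiff(names(x), c("C", "H"))))
  x <- x[ord]
  x <- x[x > 0L]
  paste0(names(x), ifelse(x == 1L, "", x), collapse = "")
}

#' @export
print.rg_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.4f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

formula_arith <- function(a, b, sign) {
  a <- parse_formula(a); b <- parse_formula(b)
  syms <- union(names(a), names(b))
  ca <- ifelse(syms %in% names(a), a[syms], 0L)
  cb <- ifelse(syms %in% names(b), b[syms], 0L)
  out <- as.integer(ca + sign * cb)
  names(out) <- syms
  if (any(out < 0L)) {
    stop("formula subtraction would yield negative count for ",
         paste(syms[out < 0L], collapse = ", "))
  }
  structure(out[out > 0L], class = "rg_formula")
}

#' Add or subtract elemental formulas
#'
#' @param a,b Formula strings or \code{rg_formula} objects.
#' @return An \code{rg_formula}.  Subtraction that would drive any element
#'   count negative is an error.
#' @export
formula_add <- function(a, b) formula_arith(a, b, +1L)

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) validate_formula(formula_arith(a, b, -1L))

#' Monoisotopic mass of a formula
#'
#' @param formula Formula string or \code{rg_formula}.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")       # 18.0106
#' monoisotopic_mass("C16H32O3")  # 272.2351
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(ATOMIC_MASS[names(f)] * as.numeric(f))
}

#' Deprotonated ([M-H]-) m/z of a neutral formula
#'
#' Removes one proton (1.007276 Da) and keeps the electron, the convention
#' that reproduces the jalapinolic-acid anion at m/z 271.2279.
#'
#' @param formula Formula string or \code{rg_formula}; must contain at least
#'   one hydrogen.
#' @return m/z in Da.
#' @examples
#' deprotonated_mz("C16H32O3")  # 271.2279, jalapinolic acid
#' @export
deprotonated_mz <- function(formula) {
  f <- parse_formula(formula)
  if (!("H" %in% names(f)) || f[["H"]] < 1L) {
    stop("cannot deprotonate a formula without hydrogen: ", format(f))
  }
  monoisotopic_mass(f) - MASS_CONST[["proton"]]
}

#' Pseudo-molecular ion m/z for a neutral mass under a negative-mode adduct
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct \code{"deprotonated"} ([M-H]-, mass - 1.007276) or
#'   \code{"formate"} ([M+HCOO]-, mass + 44.998200).
#' @return m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct = c("deprotonated", "formate")) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  adduct <- match.arg(adduct)
  switch(adduct,
    deprotonated = neutral_mass - MASS_CONST[["proton"]],
    formate      = neutral_mass + MASS_CONST[["formate"]]
  )
}
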