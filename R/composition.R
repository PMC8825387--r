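# RGComposition: the unit of prediction and simulation.
#
# Mass convention: every glycosidic or ester bond removes one water; one
# terminal water restores the free reducing/terminal end.  Hence
#   M = water + sum(sugar residues) + (hydroxy acid - water)
#       + sum(acyl acid - water) - (water if the macrolactone is closed).

#' Construct a resin-glycoside composition
#'
#' @param sugars Named integer vector of sugar-class counts, names among
#'   \code{pentose}, \code{deoxyhexose}, \code{hexose}; total must be >= 1
#'   (prediction additionally restricts to 2-7).
#' @param hydroxyacyl Name of exactly one hydroxyacyl moiety (e.g.
#'   \code{"C16-OH"} for jalapinolic acid).
#' @param acyls Character vector (multiset) of decorating acyl names; may be
#'   empty.
#' @param macrolactone \code{"closed"} if the hydroxyacyl carboxyl is
#'   esterified back onto the sugar core (one more water removed),
#'   \code{"open"} otherwise.
#' @param adduct Pseudo-molecular ion species, \code{"deprotonated"} or
#'   \code{"formate"}.
#' @return An object of class \code{rg_composition}.
#' @examples
#' tricolorin_a <- rg_composition(
#'   c(deoxyhexose = 3, hexose = 1), "C16-OH", c("C5", "C5"),
#'   macrolactone = "closed", adduct = "formate")
#' composition_mass(tricolorin_a)          # 1022.5662
#' precursor_mz(tricolorin_a)              # 1067.5644
#' @export
rg_composition <- function(sugars, hydroxyacyl, acyls = character(),
                           macrolactone = c("closed", "open"),
                           adduct = c("deprotonated", "formate")) {
  macrolactone <- match.arg(macrolactone)
  adduct <- match.arg(adduct)
  full <- c(pentose = 0L, deoxyhexose = 0L, hexose = 0L)
  if (length(sugars)) {
    bad <- setdiff(names(sugars), names(full))
    if (length(bad)) stop("unknown sugar class(es): ", paste(bad, collapse = ", "))
    full[names(sugars)] <- as.integer(sugars)
  }
  if (any(full < 0L)) stop("sugar counts must be non-negative")
  if (sum(full) < 1L) stop("composition needs at least one sugar")
  if (length(hydroxyacyl) != 1L || !nzchar(hydroxyacyl)) {
    stop("composition needs exactly one hydroxyacyl")
  }
  structure(
    list(sugars = full, hydroxyacyl = hydroxyacyl,
         acyls = sort(as.character(acyls)),
         macrolactone = macrolactone, adduct = adduct),
    class = "rg_composition"
  )
}

#' Neutral monoisotopic mass of a composition
#'
#' @param comp \code{rg_composition}.
#' @param db Moiety database supplying residue and acid masses.
#' @return Neutral mass M in Da.
#' @export
composition_mass <- function(comp, db = moiety_db()) {
  stopifnot(inherits(comp, "rg_composition"))
  su <- db_sugars(db)
  sugar_sum <- sum(su$residue_mass[match(names(comp$sugars), su$class)] * comp$sugars)
  hy <- moiety_row(db, comp$hydroxyacyl)
  if (hy$class != "hydroxyacyl") stop("'", comp$hydroxyacyl, "' is not a hydroxyacyl")
  acyl_sum <- if (length(comp$acyls)) sum(moiety_row(db, comp$acyls)$residue_mass) else 0
  m <- MASS_CONST[["water"]] + sugar_sum + hy$residue_mass + acyl_sum
  if (comp$macrolactone == "closed") m <- m - MASS_CONST[["water"]]
  unname(m)
}

#' Pseudo-molecular ion m/z of a composition under its adduct
#'
#' @inheritParams composition_mass
#' @return m/z in Da ([M-H]- or [M+HCOO]-).
#' @export
precursor_mz <- function(comp, db = moiety_db()) {
  adduct_mz(composition_mass(comp, db), comp$adduct)
}

#' Compact string form of a composition
#'
#' Format: \code{"p0 d3 h1 | C16-OH | C5+C5 | closed | formate"}; parse with
#' \code{\link{parse_composition}}.
#'
#' @param comp \code{rg_composition}.
#' @return Single string.
#' @export
format_composition <- function(comp) {
  paste(
    sprintf("p%d d%d h%d", comp$sugars[["pentose"]],
            comp$sugars[["deoxyhexose"]], comp$sugars[["hexose"]]),
    comp$hydroxyacyl,
    if (length(comp$acyls)) paste(comp$acyls, collapse = "+") else "-",
    comp$macrolactone, comp$adduct, sep = " | "
  )
}

#' @rdname format_composition
#' @param x String produced by \code{format_composition}.
#' @export
parse_composition <- function(x) {
  parts <- trimws(strsplit(x, "|", fixed = TRUE)[[1L]])
  if (length(parts) != 5L) stop("not a composition string: ", x)
  m <- regmatches(parts[1L], regexec("^p(\\d+) d(\\d+) h(\\d+)$", parts[1L]))[[1L]]
  if (length(m) != 4L) stop("bad sugar field in composition string: ", x)
  sugars <- c(pentose = as.integer(m[2L]), deoxyhexose = as.integer(m[3L]),
              hexose = as.integer(m[4L]))
  acyls <- if (parts[3L] == "-") character() else strsplit(parts[3L], "+", fixed = TRUE)[[1L]]
  rg_composition(sugars, parts[2L], acyls, macrolactone = parts[4L], adduct = parts[5L])
}

#' @export
print.rg_composition <- function(x, ...) {
  cat("<rg_composition> ", format_composition(x), "\n", sep = "")
  invisible(x)
}

# component identity: sugars + hydroxyacyl + acyl multiset (ring/adduct are
# mass bookkeeping, not structural components)
same_components <- function(a, b) {
  identical(unname(a$sugars), unname(b$sugars)) &&
    identical(a$hydroxyacyl, b$hydroxyacyl) &&
    identical(a$acyls, b$acyls)
}
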