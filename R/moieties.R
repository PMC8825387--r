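# Curated database of resin-glycoside building blocks.
#
# Sugar and acyl entries are stored in residue form (free molecule minus one
# water), matching how they contribute to a glycosidic or ester bond.
# The hydroxyacyl entries keep the free-acid formula because their signature
# fragment is the free hydroxy-acid anion.

#' Default resin-glycoside moiety database
#'
#' Builds the curated database of moieties observed in Convolvulaceae resin
#' glycosides: the three sugar classes (pentose 132.0423, deoxyhexose
#' 146.0579, hexose 162.0528 Da residues), ten hydroxyacyl chains
#' (mono- and dihydroxy C14-C18 fatty acids), and twenty-two short acyl
#' decorations spanning aliphatic, hydroxylated and aromatic acids between
#' 50 and 200 Da.  The \code{frequent} flag marks the acyls commonly seen in
#' more than 5\% of RG peaks; the empirical re-derivation of that set from a
#' dataset is \code{\link{derive_frequent_acyls}}.
#'
#' @param path Optional path to a YAML database written by
#'   \code{\link{write_moiety_db}}; when given, the file is loaded instead of
#'   the shipped defaults.
#' @return A data frame with columns \code{name}, \code{class} (one of
#'   pentose/deoxyhexose/hexose/hydroxyacyl/acyl), \code{formula} (Hill
#'   string; residue form for sugars and acyls, free acid for hydroxyacyls),
#'   \code{residue_mass}, \code{acid_mass} (free-acid mass for acyl-type
#'   entries, NA for sugars), \code{frequent}.
#' @examples
#' db <- moiety_db()
#' subset(db, class == "hydroxyacyl")
#' @export
moiety_db <- function(path = NULL) {
  if (!is.null(path)) return(read_moiety_db(path))
  sugars <- data.frame(
    name    = c("pentose", "deoxyhexose", "hexose"),
    class   = c("pentose", "deoxyhexose", "hexose"),
    formula = c("C5H8O4", "C6H10O4", "C6H10O5"),
    frequent = TRUE,
    stringsAsFactors = FALSE
  )
  # free-acid formulas; C14-C18 mono- and dihydroxy acids
  hy <- data.frame(
    name = c("C14-OH", "C15-OH", "C16-OH", "C17-OH", "C18-OH",
             "C14-OHOH", "C15-OHOH", "C16-OHOH", "C17-OHOH", "C18-OHOH"),
    class = "hydroxyacyl",
    formula = c("C14H28O3", "C15H30O3", "C16H32O3", "C17H34O3", "C18H36O3",
                "C14H28O4", "C15H30O4", "C16H32O4", "C17H34O4", "C18H36O4"),
    frequent = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  acyls <- data.frame(
    name = c("acetic", "propionic", "acrylic", "butyric", "crotonic",
             "C5", "tiglic", "acetoacetic", "HMBA", "hexanoic",
             "octanoic", "decanoic", "dodecanoic", "tetradecanoic",
             "hexadecanoic", "octadecanoic", "octadecenoic", "benzoic",
             "cinnamic", "coumaric", "caffeic", "ferulic"),
    class = "acyl",
    formula = c("C2H4O2", "C3H6O2", "C3H4O2", "C4H8O2", "C4H6O2",
                "C5H10O2", "C5H8O2", "C4H6O3", "C5H10O3", "C6H12O2",
                "C8H16O2", "C10H20O2", "C12H24O2", "C14H28O2",
                "C16H32O2", "C18H36O2", "C18H34O2", "C7H6O2",
                "C9H8O2", "C9H8O3", "C9H8O4", "C10H10O4"),
    frequent = FALSE,
    stringsAsFactors = FALSE
  )
  acyls$frequent[acyls$name %in% c("acetic", "butyric", "C5", "tiglic",
                                   "HMBA", "cinnamic")] <- TRUE
  db <- rbind(sugars, hy, acyls)
  # residue = molecule minus one water for sugars/acyls; hydroxyacyls keep the
  # free acid as the fragment-relevant species, residue is acid - water too
  acid_mass <- vapply(db$formula, monoisotopic_mass, numeric(1))
  db$residue_mass <- ifelse(db$class %in% c("pentose", "deoxyhexose", "hexose"),
                            acid_mass, acid_mass - MASS_CONST[["water"]])
  db$acid_mass <- ifelse(db$class %in% c("pentose", "deoxyhexose", "hexose"),
                         NA_real_, acid_mass)
  rownames(db) <- NULL
  validate_moiety_db(db)
}

validate_moiety_db <- function(db) {
  need <- c("name", "class", "formula", "frequent", "residue_mass", "acid_mass")
  stopifnot(all(need %in% names(db)))
  if (anyDuplicated(db$name)) {
    stop("moiety names must be unique; duplicated: ",
         paste(unique(db$name[duplicated(db$name)]), collapse = ", "))
  }
  sugar_classes <- unique(db$class[db$class %in% c("pentose", "deoxyhexose", "hexose")])
  if (length(sugar_classes) != 3L) stop("database must carry exactly 3 sugar classes")
  # round-trip: stored masses must agree with the formula to 1e-6 Da
  for (i in seq_len(nrow(db))) {
    m <- monoisotopic_mass(db$formula[i])
    ref <- if (db$class[i] %in% c("pentose", "deoxyhexose", "hexose")) {
      db$residue_mass[i]
    } else {
      db$acid_mass[i]
    }
    if (abs(m - ref) > 1e-6) {
      stop("mass/formula mismatch for moiety '", db$name[i], "'")
    }
  }
  class(db) <- c("rg_moiety_db", "data.frame")
  db
}

db_sugars <- function(db) db[db$class %in% c("pentose", "deoxyhexose", "hexose"), , drop = FALSE]
db_hydroxyacyls <- function(db) db[db$class == "hydroxyacyl", , drop = FALSE]
db_acyls <- function(db) db[db$class == "acyl", , drop = FALSE]

moiety_row <- function(db, name) {
  i <- match(name, db$name)
  if (anyNA(i)) stop("unknown moiety name(s): ", paste(name[is.na(i)], collapse = ", "))
  db[i, , drop = FALSE]
}

#' Write / read a moiety database as YAML
#'
#' The on-disk form stores name, class, Hill formula and the frequent flag;
#' masses are recomputed from the formulas on load so the file cannot drift
#' out of sync with the mass table.
#'
#' @param db Database from \code{\link{moiety_db}}.
#' @param path File path.
#' @return \code{read_moiety_db} returns a validated database data frame.
#' @export
write_moiety_db <- function(db, path) {
  entries <- lapply(seq_len(nrow(db)), function(i) {
    list(name = db$name[i], class = db$class[i], formula = db$formula[i],
         frequent = db$frequent[i])
  })
  yaml::write_yaml(list(moieties = entries), path)
  invisible(path)
}

#' @rdname write_moiety_db
#' @export
read_moiety_db <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$moieties)) stop("not a moiety database file: ", path)
  db <- do.call(rbind, lapply(raw$moieties, function(e) {
    data.frame(name = e$name, class = e$class, formula = e$formula,
               frequent = isTRUE(e$frequent), stringsAsFactors = FALSE)
  }))
  acid_mass <- vapply(db$formula, monoisotopic_mass, numeric(1))
  db$residue_mass <- ifelse(db$class %in% c("pentose", "deoxyhexose", "hexose"),
                            acid_mass, acid_mass - MASS_CONST[["water"]])
  db$acid_mass <- ifelse(db$class %in% c("pentose", "deoxyhexose", "hexose"),
                         NA_real_, acid_mass)
  validate_moiety_db(db)
}

#' Signature fragment-pair table
#'
#' The RG detection criterion: every hydroxyacyl [M-H]- fragment paired with
#' the same hydroxyacyl bound to one sugar residue of each class.  With the
#' default database (10 hydroxyacyls x 3 sugar classes) this yields exactly
#' 30 pairs, e.g. 271.2279-417.2858 for C16-OH + deoxyhexose.
#'
#' @param db Moiety database (default \code{\link{moiety_db}()}).
#' @return Data frame with columns \code{hydroxyacyl}, \code{sugar_class},
#'   \code{acyl_mz} ([M-H]- of the free hydroxy acid) and \code{combined_mz}
#'   (\code{acyl_mz} + sugar residue mass).
#' @examples
#' sp <- signature_pair_table()
#' nrow(sp)  # 30
#' @export
signature_pair_table <- function(db = moiety_db()) {
  hy <- db_hydroxyacyls(db)
  su <- db_sugars(db)
  out <- expand.grid(hydroxyacyl = hy$name, sugar_class = su$class,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$acyl_mz <- hy$acid_mass[match(out$hydroxyacyl, hy$name)] - MASS_CONST[["proton"]]
  out$combined_mz <- out$acyl_mz + su$residue_mass[match(out$sugar_class, su$class)]
  out[order(out$hydroxyacyl, out$sugar_class), , drop = FALSE]
}
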