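# Knowledge-based MS/MS fragment annotation.
#
# Step 1: match the top 20 fragments (by intensity) of each spectrum against
# a fragment database derived from the moiety database (hydroxyacyl anions,
# hydroxyacyl + 1 or 2 sugars, acyl anions, short sugar-chain ions).
# Step 2: compare all pairwise fragment differences (precursor included as a
# node) to a neutral-loss database (sugar residues, acyl residues and free
# acids, water, CO2, formic acid).
# Step 3 (predict module) uses the residual between the precursor and the
# highest annotated fragment.

#' Fragment database derived from the moiety database
#'
#' Theoretical negative-mode fragment m/z values: the hydroxyacyl free-acid
#' anions, each hydroxyacyl bound to one and to two sugar residues, acyl
#' free-acid anions, and sugar-chain ions of one to three residues (+ water,
#' deprotonated).
#'
#' @param db Moiety database.
#' @return Data frame with \code{name}, \code{type}, \code{mz}.
#' @export
fragment_db <- function(db = moiety_db()) {
  hy <- db_hydroxyacyls(db); su <- db_sugars(db); ac <- db_acyls(db)
  rows <- list()
  add <- function(name, type, mz) {
    rows[[length(rows) + 1L]] <<- data.frame(name = name, type = type, mz = mz,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(hy))) {
    base <- hy$acid_mass[i] - MASS_CONST[["proton"]]
    add(hy$name[i], "hydroxyacyl", base)
    for (j in seq_len(nrow(su))) {
      add(paste0(hy$name[i], "+", su$class[j]), "hydroxyacyl+sugar",
          base + su$residue_mass[j])
      for (k in j:nrow(su)) {
        add(paste0(hy$name[i], "+", su$class[j], "+", su$class[k]),
            "hydroxyacyl+2sugars",
            base + su$residue_mass[j] + su$residue_mass[k])
      }
    }
  }
  for (i in seq_len(nrow(ac))) {
    add(ac$name[i], "acyl", ac$acid_mass[i] - MASS_CONST[["proton"]])
  }
  # sugar-chain ions: 1-3 residues, restored terminal water, deprotonated
  chain_sets <- multisets(seq_len(nrow(su)), 1:3)
  for (s in chain_sets) {
    add(paste(su$class[s], collapse = "+"), "sugar_chain",
        sum(su$residue_mass[s]) + MASS_CONST[["water"]] - MASS_CONST[["proton"]])
  }
  do.call(rbind, rows)
}

# all multisets (as sorted index vectors) of sizes in `sizes` drawn from `x`
multisets <- function(x, sizes) {
  out <- list()
  for (n in sizes) {
    if (n == 0L) { out[[length(out) + 1L]] <- integer() ; next }
    grid <- utils::combn(length(x) + n - 1L, n)
    for (col in seq_len(ncol(grid))) {
      idx <- grid[, col] - seq_len(n) + 1L
      out[[length(out) + 1L]] <- x[idx]
    }
  }
  out
}

#' Neutral-loss database
#'
#' Sugar residues, acyl residues (acid minus water) and acyl free acids
#' (ester cleavage can release either form; acetic acid in particular is
#' recognised through its free-acid loss of 60.0211), plus water, CO2 and
#' formic acid.
#'
#' @param db Moiety database.
#' @return Data frame with \code{name}, \code{type}, \code{mass}.
#' @export
loss_db <- function(db = moiety_db()) {
  su <- db_sugars(db); ac <- db_acyls(db)
  rbind(
    data.frame(name = su$class, type = "sugar_residue", mass = su$residue_mass,
               stringsAsFactors = FALSE),
    data.frame(name = ac$name, type = "acyl_residue", mass = ac$residue_mass,
               stringsAsFactors = FALSE),
    data.frame(name = paste0(ac$name, "_acid"), type = "acyl_acid",
               mass = ac$acid_mass, stringsAsFactors = FALSE),
    data.frame(name = c("water", "co2", "formic_acid"), type = "small",
               mass = MASS_CONST[c("water", "co2", "formic_acid")],
               stringsAsFactors = FALSE)
  )
}

#' Most intense fragments of a spectrum
#'
#' @param record \code{rg_spectrum} with at least one fragment.
#' @param n Number of fragments to keep (default 20, the top-20 rule).
#' @return Fragment data frame (mz, intensity), at most \code{n} rows,
#'   ordered by m/z.  Intensity ties at the cutoff are broken toward the
#'   lower m/z, so the result is deterministic.
#' @export
top_fragments <- function(record, n = 20L) {
  fr <- record$fragments
  if (!nrow(fr)) stop("spectrum '", record$feature_id, "' has no fragments")
  ord <- order(-fr$intensity, fr$mz)
  keep <- sort(ord[seq_len(min(n, nrow(fr)))])
  fr[keep, , drop = FALSE]
}

#' Match fragments against the fragment database
#'
#' Every database entry within the tolerance of a fragment is reported;
#' multiple matches per fragment are allowed.
#'
#' @param fragments Data frame (mz, intensity).
#' @param fdb Fragment database from \code{\link{fragment_db}}.
#' @param tol Absolute tolerance in Da (default 0.01).
#' @return Data frame: fragment mz, intensity, matched name/type,
#'   theoretical mz and delta; fragments with no match appear once with
#'   \code{matched = NA}.
#' @export
match_fragments <- function(fragments, fdb = fragment_db(), tol = 0.01) {
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    mz <- fragments$mz[i]
    hit <- which(abs(fdb$mz - mz) <= tol)
    if (!length(hit)) {
      return(data.frame(mz = mz, intensity = fragments$intensity[i],
                        matched = NA_character_, type = NA_character_,
                        theoretical_mz = NA_real_, delta = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(mz = mz, intensity = fragments$intensity[i],
               matched = fdb$name[hit], type = fdb$type[hit],
               theoretical_mz = fdb$mz[hit], delta = mz - fdb$mz[hit],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Infer neutral losses from pairwise fragment differences
#'
#' All pairwise differences among the fragments plus the precursor (included
#' as a pseudo-fragment node) are compared to the loss database.  Each edge
#' runs from the higher to the lower m/z, so the edge set is antisymmetric.
#' Water (-18.0106), CO2 (-43.9898) and formic acid (-46.0055) losses are
#' flagged in the \code{special} column.
#'
#' @param fragments Data frame (mz, intensity).
#' @param precursor_mz Precursor m/z added as a node (use NA to omit).
#' @param ldb Loss database from \code{\link{loss_db}}.
#' @param tol Absolute tolerance in Da on the mass difference.
#' @return Data frame: higher_mz, lower_mz, loss_mass, loss_name, loss_type,
#'   special (one of "water", "co2", "formate", NA).
#' @export
infer_neutral_losses <- function(fragments, precursor_mz = NA_real_,
                                 ldb = loss_db(), tol = 0.01) {
  mz <- fragments$mz
  from_precursor <- logical(length(mz))
  if (!is.na(precursor_mz)) {
    mz <- c(mz, precursor_mz)
    from_precursor <- c(from_precursor, TRUE)
  }
  mz <- sort(unique(mz))
  out <- list()
  n <- length(mz)
  if (n < 2L) {
    return(data.frame(higher_mz = numeric(), lower_mz = numeric(),
                      loss_mass = numeric(), loss_name = character(),
                      loss_type = character(), special = character(),
                      stringsAsFactors = FALSE))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- mz[j] - mz[i]
      hit <- which(abs(ldb$mass - d) <= tol)
      for (h in hit) {
        special <- NA_character_
        if (ldb$name[h] == "water") special <- "water"
        if (ldb$name[h] == "co2") special <- "co2"
        if (ldb$name[h] == "formic_acid") special <- "formate"
        out[[length(out) + 1L]] <- data.frame(
          higher_mz = mz[j], lower_mz = mz[i], loss_mass = d,
          loss_name = ldb$name[h], loss_type = ldb$type[h], special = special,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(higher_mz = numeric(), lower_mz = numeric(),
                      loss_mass = numeric(), loss_name = character(),
                      loss_type = character(), special = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Annotate one spectrum
#'
#' Runs the top-n selection, fragment matching and neutral-loss inference
#' and computes the residual mass (precursor minus highest annotated
#' fragment) used downstream by component prediction.
#'
#' @param record \code{rg_spectrum}.
#' @param db Moiety database.
#' @param tol Match tolerance (Da).
#' @param n_top Number of top fragments considered (default 20).
#' @return List of class \code{rg_annotation}: \code{feature_id},
#'   \code{assignments}, \code{losses}, \code{considered} (fragment m/z
#'   vector), \code{annotated_fraction}, \code{max_annotated_mz},
#'   \code{residual}.
#' @export
annotate_spectrum <- function(record, db = moiety_db(), tol = 0.01, n_top = 20L) {
  fr <- top_fragments(record, n_top)
  assignments <- match_fragments(fr, fragment_db(db), tol)
  losses <- infer_neutral_losses(fr, record$precursor_mz, loss_db(db), tol)
  in_edge <- fr$mz %in% c(losses$higher_mz, losses$lower_mz)
  matched <- fr$mz %in% assignments$mz[!is.na(assignments$matched)]
  annotated <- matched | in_edge
  max_ann <- if (any(matched)) max(fr$mz[matched]) else NA_real_
  structure(list(
    feature_id = record$feature_id,
    precursor_mz = record$precursor_mz,
    assignments = assignments,
    losses = losses,
    considered = fr$mz,
    annotated = annotated,
    annotated_fraction = mean(annotated),
    max_annotated_mz = max_ann,
    residual = if (is.na(max_ann)) NA_real_ else record$precursor_mz - max_ann
  ), class = "rg_annotation")
}

#' Annotate a list of spectra
#'
#' @param records List of \code{rg_spectrum}.
#' @inheritParams annotate_spectrum
#' @return Named list of \code{rg_annotation}, keyed by feature id.
#' @export
annotate_spectra <- function(records, db = moiety_db(), tol = 0.01, n_top = 20L) {
  out <- lapply(records, annotate_spectrum, db = db, tol = tol, n_top = n_top)
  names(out) <- vapply(records, function(r) r$feature_id, character(1))
  out
}

#' Overall annotation coverage
#'
#' Fraction of considered fragments (the top-n of each spectrum) that carry
#' at least one database assignment or participate in at least one inferred
#' neutral-loss edge.
#'
#' @param annotations List of \code{rg_annotation}.
#' @param per_spectrum If TRUE, also return the per-spectrum fractions.
#' @return Pooled fraction in [0, 1] (with attribute \code{per_spectrum}
#'   when requested).
#' @export
annotation_coverage <- function(annotations, per_spectrum = FALSE) {
  stopifnot(length(annotations) >= 1L)
  ann <- unlist(lapply(annotations, `[[`, "annotated"))
  pooled <- mean(ann)
  if (per_spectrum) {
    attr(pooled, "per_spectrum") <-
      vapply(annotations, `[[`, numeric(1), "annotated_fraction")
  }
  pooled
}

#' Component-occurrence scans across detected RGs
#'
#' Reproduces the structure-scan summaries: how many detected RG peaks carry
#' each hydroxyacyl fragment, each hydroxyacyl+sugar pair class, and what
#' percentage of RG peaks (among those with at least one acyl inference)
#' carry each acyl chain.  Acetic acid is inferred from its neutral loss
#' only; every other acyl requires its fragment ion.
#'
#' @param detection \code{rg_detection}.
#' @param records List of \code{rg_spectrum} covering the detected features.
#' @param db Moiety database.
#' @param tol Match tolerance (Da).
#' @return List with data frames \code{hydroxyacyl} (name, n),
#'   \code{sugar_pair} (class, n) and \code{acyl} (name, n, pct).
#' @export
scan_components <- function(detection, records, db = moiety_db(), tol = 0.01) {
  ids <- vapply(records, function(r) r$feature_id, character(1))
  det_ids <- detection$detected$feature_id
  recs <- records[ids %in% det_ids]
  hy <- db_hydroxyacyls(db); su <- db_sugars(db); ac <- db_acyls(db)
  pairs <- signature_pair_table(db)

  hy_count <- setNames(integer(nrow(hy)), hy$name)
  sugar_count <- setNames(integer(nrow(su)), su$class)
  acyl_hits <- setNames(integer(nrow(ac)), ac$name)
  n_with_acyl <- 0L

  for (r in recs) {
    fr <- top_fragments(r, n = 20L)
    has_mz <- function(target) any(abs(fr$mz - target) <= tol)
    for (i in seq_len(nrow(hy))) {
      if (has_mz(hy$acid_mass[i] - MASS_CONST[["proton"]])) {
        hy_count[[hy$name[i]]] <- hy_count[[hy$name[i]]] + 1L
      }
    }
    for (j in seq_len(nrow(su))) {
      p <- pairs[pairs$sugar_class == su$class[j], , drop = FALSE]
      hit <- any(vapply(seq_len(nrow(p)), function(k) {
        has_mz(p$acyl_mz[k]) && has_mz(p$combined_mz[k])
      }, logical(1)))
      if (hit) sugar_count[[su$class[j]]] <- sugar_count[[su$class[j]]] + 1L
    }
    losses <- infer_neutral_losses(fr, r$precursor_mz, loss_db(db), tol)
    this_acyls <- character()
    for (i in seq_len(nrow(ac))) {
      nm <- ac$name[i]
      found <- if (nm == "acetic") {
        any(losses$loss_name %in% c("acetic", "acetic_acid"))
      } else {
        has_mz(ac$acid_mass[i] - MASS_CONST[["proton"]])
      }
      if (found) this_acyls <- c(this_acyls, nm)
    }
    if (length(this_acyls)) {
      n_with_acyl <- n_with_acyl + 1L
      acyl_hits[this_acyls] <- acyl_hits[this_acyls] + 1L
    }
  }
  list(
    hydroxyacyl = data.frame(name = names(hy_count), n = as.integer(hy_count),
                             stringsAsFactors = FALSE),
    sugar_pair = data.frame(class = names(sugar_count),
                            n = as.integer(sugar_count), stringsAsFactors = FALSE),
    acyl = data.frame(name = names(acyl_hits), n = as.integer(acyl_hits),
                      pct = if (n_with_acyl) 100 * as.integer(acyl_hits) / n_with_acyl
                            else rep(0, length(acyl_hits)),
                      stringsAsFactors = FALSE),
    n_rg = length(recs), n_with_acyl = n_with_acyl
  )
}
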