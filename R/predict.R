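# Combinatorial prediction of RG structural components.
#
# Candidate space: oligosaccharide cores of 2-7 sugars over the three
# classes, exactly one hydroxyacyl, 0..max_acyls decorating acyls from the
# configured pool, open or closed macrolactone, deprotonated or formate
# adduct.  A candidate is retained when its theoretical pseudo-molecular ion
# m/z falls within the precursor tolerance.  Candidates are then re-ranked
# by observed-fragment evidence.

#' Prediction configuration
#'
#' @param max_acyls Maximum number of decorating acyls per composition:
#'   3 in default mode, 5 in extended mode.
#' @param acyl_pool Character vector of acyl names to draw from.  The default
#'   is the database's frequent set; \code{mode = "extended"} adds decanoic
#'   acid and raises \code{max_acyls} to 5.
#' @param precursor_tolerance Absolute tolerance (Da) between candidate and
#'   observed precursor m/z (default 0.01).
#' @param sugar_range Total sugar count bounds (default 2:7, up to
#'   hepta-saccharide cores).
#' @param adducts Adducts considered (default both).
#' @param macrolactone Ring states considered (default both, i.e. water loss
#'   allowed).
#' @param candidate_cap Hard cap on candidates per peak; exceeding it is an
#'   error advising a narrower tolerance rather than silent truncation.
#' @param mode Convenience switch: \code{"default"} or \code{"extended"};
#'   explicit arguments override it.
#' @param db Moiety database the pools refer to.
#' @return List of class \code{rg_predict_config}.
#' @export
prediction_config <- function(mode = c("default", "extended"),
                              max_acyls = NULL, acyl_pool = NULL,
                              precursor_tolerance = 0.01,
                              sugar_range = 2:7,
                              adducts = c("deprotonated", "formate"),
                              macrolactone = c("closed", "open"),
                              candidate_cap = 10000L,
                              db = moiety_db()) {
  mode <- match.arg(mode)
  frequent <- db_acyls(db)$name[db_acyls(db)$frequent]
  if (is.null(acyl_pool)) {
    acyl_pool <- if (mode == "extended") union(frequent, "decanoic") else frequent
  }
  if (is.null(max_acyls)) max_acyls <- if (mode == "extended") 5L else 3L
  stopifnot(length(acyl_pool) >= 1L, max_acyls >= 0L, precursor_tolerance > 0,
            all(sugar_range >= 1L))
  structure(list(mode = mode, max_acyls = as.integer(max_acyls),
                 acyl_pool = acyl_pool,
                 precursor_tolerance = precursor_tolerance,
                 sugar_range = as.integer(sugar_range),
                 adducts = adducts, macrolactone = macrolactone,
                 candidate_cap = as.integer(candidate_cap)),
            class = "rg_predict_config")
}

#' Empirically derive the frequent acyl set
#'
#' Re-derives the "frequent" pool from data: acyls whose fragment (or, for
#' acetic acid, neutral-loss) occurrence across detected RG peaks strictly
#' exceeds the threshold fraction.
#'
#' @param detection \code{rg_detection} with at least one detected peak.
#' @param records Spectra covering the detected features.
#' @param db Moiety database.
#' @param threshold Occurrence fraction that must be strictly exceeded
#'   (default 0.05, the >5\% rule).
#' @param tol Fragment match tolerance (Da).
#' @return Character vector of acyl names.
#' @export
derive_frequent_acyls <- function(detection, records, db = moiety_db(),
                                  threshold = 0.05, tol = 0.01) {
  n <- nrow(detection$detected)
  if (n == 0L) stop("no detected RG peaks; cannot derive frequent acyls")
  scan <- scan_components(detection, records, db, tol)
  scan$acyl$name[scan$acyl$n / n > threshold]
}

# vector of acyl-multiset residue-mass sums + the index sets, sizes 0..k
acyl_multiset_table <- function(db, pool, k) {
  ac <- db_acyls(db)
  pool_idx <- match(pool, ac$name)
  if (anyNA(pool_idx)) stop("unknown acyl(s) in pool: ",
                            paste(pool[is.na(pool_idx)], collapse = ", "))
  sets <- multisets(pool_idx, 0:k)
  masses <- vapply(sets, function(s) sum(ac$residue_mass[s]), numeric(1))
  names_list <- lapply(sets, function(s) sort(ac$name[s]))
  list(sets = names_list, mass = masses)
}

# sugar multisets of given total sizes over the 3 classes
sugar_count_table <- function(db, sizes) {
  su <- db_sugars(db)
  grids <- list()
  for (n in sizes) {
    g <- expand.grid(pentose = 0:n, deoxyhexose = 0:n, hexose = 0:n)
    g <- g[rowSums(g) == n, , drop = FALSE]
    grids[[length(grids) + 1L]] <- g
  }
  counts <- do.call(rbind, grids)
  mass <- as.matrix(counts) %*% su$residue_mass[match(colnames(counts), su$class)]
  list(counts = as.matrix(counts), mass = as.numeric(mass))
}

#' Enumerate candidate compositions for a precursor m/z
#'
#' Exhaustively enumerates the composition space defined by the
#' configuration and keeps every candidate whose theoretical m/z is within
#' the precursor tolerance.  Completeness of the enumeration is checked in
#' the test suite against a brute-force generate-and-test oracle on reduced
#' pools.
#'
#' @param precursor_mz Observed pseudo-molecular ion m/z (> 0).
#' @param db Moiety database.
#' @param cfg \code{\link{prediction_config}}.
#' @return Data frame of class \code{rg_candidates}: sugar counts, hydroxyacyl,
#'   acyls (\code{+}-joined string), macrolactone, adduct, theoretical_mz,
#'   delta, n_components; ordered by |delta| then composition string.
#' @export
enumerate_candidates <- function(precursor_mz, db = moiety_db(),
                                 cfg = prediction_config()) {
  stopifnot(precursor_mz > 0)
  su_tab <- sugar_count_table(db, cfg$sugar_range)
  ac_tab <- acyl_multiset_table(db, cfg$acyl_pool, cfg$max_acyls)
  hy <- db_hydroxyacyls(db)
  rows <- list()
  for (hi in seq_len(nrow(hy))) {
    for (ring in cfg$macrolactone) {
      for (adduct in cfg$adducts) {
        base <- MASS_CONST[["water"]] + hy$residue_mass[hi] -
          (if (ring == "closed") MASS_CONST[["water"]] else 0) +
          (if (adduct == "formate") MASS_CONST[["formate"]] else -MASS_CONST[["proton"]])
        # theoretical mz = base + sugar_mass + acyl_mass
        target <- precursor_mz - base
        # outer sum over sugar x acyl masses
        d <- abs(outer(su_tab$mass, ac_tab$mass, `+`) - target)
        hit <- which(d <= cfg$precursor_tolerance, arr.ind = TRUE)
        if (!nrow(hit)) next
        for (r in seq_len(nrow(hit))) {
          si <- hit[r, 1L]; ai <- hit[r, 2L]
          sugars <- su_tab$counts[si, ]
          acyls <- ac_tab$sets[[ai]]
          theo <- base + su_tab$mass[si] + ac_tab$mass[ai]
          rows[[length(rows) + 1L]] <- data.frame(
            pentose = sugars[["pentose"]], deoxyhexose = sugars[["deoxyhexose"]],
            hexose = sugars[["hexose"]], hydroxyacyl = hy$name[hi],
            acyls = paste(acyls, collapse = "+"),
            macrolactone = ring, adduct = adduct,
            theoretical_mz = theo, delta = theo - precursor_mz,
            n_components = sum(sugars) + 1L + length(acyls),
            stringsAsFactors = FALSE)
          if (length(rows) > cfg$candidate_cap) {
            stop("candidate cap (", cfg$candidate_cap,
                 ") exceeded; narrow the precursor tolerance")
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    pentose = integer(), deoxyhexose = integer(), hexose = integer(),
    hydroxyacyl = character(), acyls = character(), macrolactone = character(),
    adduct = character(), theoretical_mz = numeric(), delta = numeric(),
    n_components = integer(), stringsAsFactors = FALSE)
  key <- candidate_key(out)
  out <- out[order(abs(out$delta), out$n_components, key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rg_candidates", "data.frame")
  out
}

candidate_key <- function(cand) {
  paste(cand$pentose, cand$deoxyhexose, cand$hexose, cand$hydroxyacyl,
        cand$acyls, cand$macrolactone, cand$adduct)
}

candidate_to_composition <- function(cand_row) {
  acyls <- if (nzchar(cand_row$acyls)) strsplit(cand_row$acyls, "+", fixed = TRUE)[[1L]]
           else character()
  rg_composition(
    c(pentose = cand_row$pentose, deoxyhexose = cand_row$deoxyhexose,
      hexose = cand_row$hexose),
    cand_row$hydroxyacyl, acyls,
    macrolactone = cand_row$macrolactone, adduct = cand_row$adduct)
}

#' Re-rank candidates with observed-fragment evidence
#'
#' Each candidate earns one point per component class supported by an
#' observed fragment or loss edge: its hydroxyacyl fragment, its
#' hydroxyacyl+sugar pair for each sugar class it uses, and each distinct
#' acyl (fragment ion, or the acetic free-acid loss).  A formate-adduct
#' candidate with no observed formic-acid loss from the precursor is
#' penalised by one point.  Ties are broken by smaller |delta|, then fewer
#' components, then the lexicographic composition string, so the ranking is
#' fully deterministic.
#'
#' @param candidates \code{rg_candidates}.
#' @param annotation \code{rg_annotation} for the same peak (NULL leaves the
#'   mass-closeness order untouched with scores of 0).
#' @param db Moiety database.
#' @param tol Fragment match tolerance (Da).
#' @return \code{rg_candidates} with a \code{score} column, re-ranked.
#' @export
score_candidates <- function(candidates, annotation = NULL, db = moiety_db(),
                             tol = 0.01) {
  if (!nrow(candidates)) {
    candidates$score <- numeric()
    return(candidates)
  }
  if (is.null(annotation)) {
    candidates$score <- 0
    return(candidates)
  }
  frag_mz <- annotation$considered
  losses <- annotation$losses
  has_mz <- function(target) any(abs(frag_mz - target) <= tol)
  hy <- db_hydroxyacyls(db); su <- db_sugars(db); ac <- db_acyls(db)
  formate_loss_seen <- any(!is.na(losses$special) & losses$special == "formate" &
                             abs(losses$higher_mz - annotation$precursor_mz) <= tol)
  score <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    s <- 0
    hy_mass <- hy$acid_mass[match(cand$hydroxyacyl, hy$name)]
    hy_mz <- hy_mass - MASS_CONST[["proton"]]
    if (has_mz(hy_mz)) s <- s + 1
    for (class in c("pentose", "deoxyhexose", "hexose")) {
      if (cand[[class]] > 0) {
        res <- su$residue_mass[su$class == class]
        if (has_mz(hy_mz + res)) s <- s + 1
      }
    }
    acyls <- if (nzchar(cand$acyls)) unique(strsplit(cand$acyls, "+", fixed = TRUE)[[1L]])
             else character()
    for (a in acyls) {
      seen <- if (a == "acetic") {
        any(losses$loss_name %in% c("acetic", "acetic_acid"))
      } else {
        has_mz(ac$acid_mass[match(a, ac$name)] - MASS_CONST[["proton"]])
      }
      if (seen) s <- s + 1
    }
    if (cand$adduct == "formate" && !formate_loss_seen) s <- s - 1
    score[i] <- s
  }
  candidates$score <- score
  key <- candidate_key(candidates)
  candidates <- candidates[order(-score, abs(candidates$delta),
                                 candidates$n_components, key), , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

#' Predict components for detected peaks
#'
#' Enumerates and evidence-ranks candidate compositions for each detected
#' feature.
#'
#' @param detection \code{rg_detection}.
#' @param annotations Named list of \code{rg_annotation} (from
#'   \code{\link{annotate_spectra}}); optional.
#' @param db Moiety database.
#' @param cfg \code{\link{prediction_config}}.
#' @return Named list of \code{rg_candidates}, keyed by feature id.
#' @export
predict_components <- function(detection, annotations = NULL, db = moiety_db(),
                               cfg = prediction_config()) {
  out <- list()
  for (i in seq_len(nrow(detection$detected))) {
    fid <- detection$detected$feature_id[i]
    cand <- enumerate_candidates(detection$detected$precursor_mz[i], db, cfg)
    ann <- if (!is.null(annotations)) annotations[[fid]] else NULL
    out[[fid]] <- score_candidates(cand, ann, db, cfg$precursor_tolerance)
  }
  out
}

#' Recall of known compositions against candidate sets
#'
#' A known RG counts as correctly predicted when its component identity
#' (sugar-class counts, hydroxyacyl, acyl multiset) appears anywhere in the
#' candidate set for its peak.
#'
#' @param known Data frame with columns \code{name}, \code{feature_id} and
#'   \code{composition} (string form, \code{\link{format_composition}}).
#' @param candidate_sets Named list of \code{rg_candidates} keyed by feature
#'   id (e.g. from \code{\link{predict_components}}).
#' @return List with \code{recall} (fraction) and \code{verdicts} data frame
#'   (name, feature_id, correct).
#' @export
evaluate_recall <- function(known, candidate_sets) {
  if (!nrow(known)) stop("empty known-RG list")
  correct <- logical(nrow(known))
  for (i in seq_len(nrow(known))) {
    truth <- parse_composition(known$composition[i])
    cands <- candidate_sets[[known$feature_id[i]]]
    if (is.null(cands) || !nrow(cands)) next
    for (j in seq_len(nrow(cands))) {
      if (same_components(candidate_to_composition(cands[j, ]), truth)) {
        correct[i] <- TRUE
        break
      }
    }
  }
  list(recall = mean(correct),
       verdicts = data.frame(name = known$name, feature_id = known$feature_id,
                             correct = correct, stringsAsFactors = FALSE))
}
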