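# Co-occurrence statistics: pairwise Pearson correlation of nominal-mass
# fragment intensities across a species' RG peaks, and leaf-vs-root
# peak-area correlation.

#' Fragment intensity matrix at nominal mass
#'
#' Rows are detected RG features, columns are nominal (integer Da) fragment
#' masses; fragments rounding into the same bin are summed, so each row sum
#' equals the spectrum's total intensity.
#'
#' @param detection \code{rg_detection}.
#' @param records Spectra covering the detected features.
#' @param transform \code{"raw"} (default) or \code{"log10"} (log10(1 + x)).
#' @return Numeric matrix with feature ids as row names and nominal masses
#'   as column names (ascending).
#' @export
build_fragment_matrix <- function(detection, records, transform = c("raw", "log10")) {
  transform <- match.arg(transform)
  ids <- vapply(records, function(r) r$feature_id, character(1))
  det_ids <- detection$detected$feature_id
  recs <- records[match(det_ids, ids)]
  if (anyNA(match(det_ids, ids))) stop("spectra missing for some detected features")
  bins_list <- lapply(recs, function(r) {
    if (!nrow(r$fragments)) return(integer())
    round(r$fragments$mz)
  })
  all_bins <- sort(unique(unlist(bins_list)))
  m <- matrix(0, nrow = length(recs), ncol = length(all_bins),
              dimnames = list(det_ids, as.character(all_bins)))
  for (i in seq_along(recs)) {
    fr <- recs[[i]]$fragments
    if (!nrow(fr)) next
    agg <- tapply(fr$intensity, round(fr$mz), sum)
    m[i, names(agg)] <- agg
  }
  if (transform == "log10") m <- log10(1 + m)
  m
}

#' Pairwise fragment correlations with water-loss flags
#'
#' Pearson correlation for every pair of nominal-mass columns with at least
#' \code{min_obs} jointly nonzero observations; zero-variance columns yield
#' NA (undefined, not 0).  Pairs whose nominal masses differ by exactly 18
#' are flagged as candidate water-loss partners.
#'
#' @param matrix Output of \code{\link{build_fragment_matrix}}.
#' @param min_obs Minimum number of rows where both columns are nonzero
#'   (default 3).
#' @return Data frame: mass_a, mass_b (a < b), pcc, n_joint, delta18.
#' @export
fragment_correlations <- function(matrix, min_obs = 3L) {
  stopifnot(nrow(matrix) >= 2L)
  masses <- as.integer(colnames(matrix))
  nc <- ncol(matrix)
  rows <- list()
  cm <- suppressWarnings(stats::cor(matrix))
  nonzero <- matrix > 0
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      n_joint <- sum(nonzero[, i] & nonzero[, j])
      if (n_joint < min_obs) next
      pcc <- cm[i, j]
      if (stats::sd(matrix[, i]) == 0 || stats::sd(matrix[, j]) == 0) pcc <- NA_real_
      lo <- min(masses[i], masses[j]); hi <- max(masses[i], masses[j])
      rows[[length(rows) + 1L]] <- data.frame(
        mass_a = lo, mass_b = hi, pcc = pcc, n_joint = n_joint,
        delta18 = (hi - lo) == 18L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mass_a = integer(), mass_b = integer(), pcc = numeric(),
                      n_joint = integer(), delta18 = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Leaf-vs-root peak-area correlation over detected RGs
#'
#' Pearson correlation of relative peak areas (each organ's areas normalised
#' to its total over the detected RGs) between leaf and root.  Raw areas can
#' be used instead.
#'
#' @param detection \code{rg_detection} (uses its leaf/root areas).
#' @param relative Normalise each organ to its total area first (default
#'   TRUE).
#' @return List with \code{pcc} (NA when fewer than 3 usable features, with
#'   \code{note}) and \code{n} (features used).
#' @export
organ_correlation <- function(detection, relative = TRUE) {
  d <- detection$detected
  if (nrow(d) < 3L) {
    return(list(pcc = NA_real_, n = nrow(d), note = "insufficient data (<3 RGs)"))
  }
  leaf <- d$leaf_area; root <- d$root_area
  if (relative) {
    if (sum(leaf) == 0 || sum(root) == 0) {
      return(list(pcc = NA_real_, n = nrow(d), note = "an organ has zero total area"))
    }
    leaf <- leaf / sum(leaf); root <- root / sum(root)
  }
  if (stats::sd(leaf) == 0 || stats::sd(root) == 0) {
    return(list(pcc = NA_real_, n = nrow(d), note = "zero variance in an organ"))
  }
  list(pcc = stats::cor(leaf, root), n = nrow(d), note = "")
}
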