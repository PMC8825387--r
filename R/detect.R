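# RG peak detection: separate likely true resin-glycoside features from
# noise with four filters, then assign organ localisation.
#
#   (i)  blank/area: leaf or root area > 1000 and > 10x the blank area
#   (iv) linked peaks: of two linked features keep one (default the higher
#        mass); adduct-labelled features are always retained
#   (ii) signature pairs: at least one hydroxyacyl / hydroxyacyl+sugar
#        fragment pair present, with
#   (iii) both pair members > 10% of the base-peak intensity
#
# followed by the organ rule (>1000 in one organ and 0 in the other ->
# single organ; >1000 in both -> both; otherwise ambiguous).

#' Detection configuration
#'
#' @param blank_ratio_min Minimum organ/blank area ratio (default 10).
#' @param area_min Minimum peak area in leaf or root (default 1000).
#' @param relative_intensity_min Minimum fragment intensity relative to the
#'   base peak for signature-pair members (default 0.10).
#' @param fragment_match_tolerance Absolute m/z tolerance in Da for matching
#'   signature fragments (default 0.01, Orbitrap-appropriate; it also absorbs
#'   the small differences between theoretical and instrument-observed values
#'   such as 417.2858 vs 417.2854).
#' @param tolerance_mode \code{"da"} (absolute) or \code{"ppm"}; in ppm mode
#'   \code{fragment_match_tolerance} is read as ppm of the fragment m/z.
#' @param keep_linked Which member of a linked pair survives filter (iv):
#'   \code{"higher"} (default, matching the upstream alignment convention),
#'   \code{"lower"}, or
#'   \code{"both"}.
#' @return List of class \code{rg_detect_config}.
#' @export
detection_config <- function(blank_ratio_min = 10, area_min = 1000,
                             relative_intensity_min = 0.10,
                             fragment_match_tolerance = 0.01,
                             tolerance_mode = c("da", "ppm"),
                             keep_linked = c("higher", "lower", "both")) {
  stopifnot(blank_ratio_min > 0, area_min > 0,
            relative_intensity_min > 0, fragment_match_tolerance > 0)
  structure(list(blank_ratio_min = blank_ratio_min, area_min = area_min,
                 relative_intensity_min = relative_intensity_min,
                 fragment_match_tolerance = fragment_match_tolerance,
                 tolerance_mode = match.arg(tolerance_mode),
                 keep_linked = match.arg(keep_linked)),
            class = "rg_detect_config")
}

mz_tol <- function(mz, cfg) {
  if (cfg$tolerance_mode == "ppm") mz * cfg$fragment_match_tolerance * 1e-6
  else cfg$fragment_match_tolerance
}

#' Filter (i): blank-subtraction and minimum-area test
#'
#' Passes iff max(leaf, root) area exceeds \code{area_min} AND that same area
#' exceeds \code{blank_ratio_min} times the blank area (a blank area of 0
#' passes the ratio clause).
#'
#' @param record \code{rg_spectrum}.
#' @param table \code{rg_alignment}.
#' @param cfg \code{\link{detection_config}}.
#' @return List with \code{pass} (logical) and \code{reason} (string, empty
#'   when passing).
#' @export
filter_blank_area <- function(record, table, cfg = detection_config()) {
  a <- organ_areas(table, record$feature_id)
  best <- max(a[["leaf"]], a[["root"]])
  if (best <= cfg$area_min) {
    return(list(pass = FALSE,
                reason = sprintf("area %.0f <= %.0f", best, cfg$area_min)))
  }
  if (a[["blank"]] > 0 && best <= cfg$blank_ratio_min * a[["blank"]]) {
    return(list(pass = FALSE,
                reason = sprintf("area/blank ratio %.1f <= %.0f",
                                 best / a[["blank"]], cfg$blank_ratio_min)))
  }
  list(pass = TRUE, reason = "")
}

#' Filters (ii)+(iii): signature fragment-pair matching
#'
#' A pair matches when both members are found among the spectrum's fragments
#' within the match tolerance and both matched fragments exceed the relative
#' intensity floor (fraction of the base-peak intensity).
#'
#' @param record \code{rg_spectrum}.
#' @param pairs Signature-pair table from \code{\link{signature_pair_table}}.
#' @param cfg \code{\link{detection_config}}.
#' @return Subset of \code{pairs} that matched (zero rows means reject).
#' @export
filter_signature_pairs <- function(record, pairs, cfg = detection_config()) {
  fr <- record$fragments
  if (!nrow(fr)) return(pairs[0, , drop = FALSE])
  base <- max(fr$intensity)
  ok_member <- function(target) {
    hit <- abs(fr$mz - target) <= mz_tol(target, cfg)
    any(hit & fr$intensity > cfg$relative_intensity_min * base)
  }
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    ok_member(pairs$acyl_mz[i]) && ok_member(pairs$combined_mz[i])
  }, logical(1))
  pairs[hit, , drop = FALSE]
}

#' Filter (iv): resolve linked peaks
#'
#' MS-DIAL links some features to co-eluting features of higher mass; of each
#' linked pair only one is processed further.  With \code{keep_linked =
#' "higher"} (default) the lower-mass member carrying the link is dropped —
#' the behaviour that loses a peak linked to a higher mass.  Adduct-labelled
#' records are always retained.  A link pointing at a feature id absent from
#' the input warns and keeps both.
#'
#' @param records List of \code{rg_spectrum}.
#' @param cfg \code{\link{detection_config}}.
#' @return List with \code{kept} (surviving records) and \code{dropped}
#'   (feature ids removed by this filter).
#' @export
resolve_linked_peaks <- function(records, cfg = detection_config()) {
  ids <- vapply(records, function(r) r$feature_id, character(1))
  drop <- character()
  if (cfg$keep_linked != "both") {
    for (r in records) {
      if (is.na(r$linked_to)) next
      if (!is.na(r$adduct_label)) next
      j <- match(r$linked_to, ids)
      if (is.na(j)) {
        warning("feature '", r$feature_id, "' links to unknown feature '",
                r$linked_to, "'; both kept")
        next
      }
      target <- records[[j]]
      if (cfg$keep_linked == "higher") {
        drop <- c(drop, if (target$precursor_mz >= r$precursor_mz) r$feature_id
                        else target$feature_id)
      } else {
        drop <- c(drop, if (target$precursor_mz >= r$precursor_mz) target$feature_id
                        else r$feature_id)
      }
    }
  }
  drop <- unique(drop)
  list(kept = records[!ids %in% drop], dropped = drop)
}

#' Organ-localisation call from unnormalised areas
#'
#' @param leaf_area,root_area Peak areas (>= 0).
#' @return One of \code{"leaf_only"}, \code{"root_only"}, \code{"both"},
#'   \code{"ambiguous"}.
#' @export
assign_organ <- function(leaf_area, root_area) {
  stopifnot(leaf_area >= 0, root_area >= 0)
  if (leaf_area > 1000 && root_area > 1000) return("both")
  if (leaf_area > 1000 && root_area == 0) return("leaf_only")
  if (root_area > 1000 && leaf_area == 0) return("root_only")
  "ambiguous"
}

#' Detect resin-glycoside peaks
#'
#' Applies the filters in order (i) blank/area, (iv) linked peaks,
#' (ii)+(iii) signature pairs, then assigns organs, and reports attrition.
#' The result is independent of record input order.
#'
#' @param records List of \code{rg_spectrum} (one per aligned feature).
#' @param table \code{rg_alignment} of peak areas.
#' @param db Moiety database; signature pairs are derived from it.
#' @param cfg \code{\link{detection_config}}.
#' @return List of class \code{rg_detection}: \code{detected} data frame
#'   (feature_id, precursor_mz, rt, n_pairs, matched_pairs, organ_call,
#'   leaf_area, root_area, blank_area), \code{attrition} named counts of
#'   rejections per filter, \code{pair_hits} list of matched-pair tables
#'   keyed by feature id.
#' @export
detect_rg <- function(records, table, db = moiety_db(), cfg = detection_config()) {
  pairs <- signature_pair_table(db)
  ids <- vapply(records, function(r) r$feature_id, character(1))
  records <- records[order(ids)]
  attrition <- c(blank_area = 0L, linked = 0L, signature_pair = 0L)

  keep1 <- list()
  for (r in records) {
    f <- filter_blank_area(r, table, cfg)
    if (f$pass) keep1[[length(keep1) + 1L]] <- r
    else attrition[["blank_area"]] <- attrition[["blank_area"]] + 1L
  }
  lr <- resolve_linked_peaks(keep1, cfg)
  attrition[["linked"]] <- length(lr$dropped)

  rows <- list(); pair_hits <- list()
  for (r in lr$kept) {
    hits <- filter_signature_pairs(r, pairs, cfg)
    if (!nrow(hits)) {
      attrition[["signature_pair"]] <- attrition[["signature_pair"]] + 1L
      next
    }
    a <- organ_areas(table, r$feature_id)
    pair_hits[[r$feature_id]] <- hits
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = r$feature_id, precursor_mz = r$precursor_mz, rt = r$rt,
      n_pairs = nrow(hits),
      matched_pairs = paste(paste0(hits$hydroxyacyl, ":", hits$sugar_class),
                            collapse = ";"),
      organ_call = assign_organ(a[["leaf"]], a[["root"]]),
      leaf_area = a[["leaf"]], root_area = a[["root"]], blank_area = a[["blank"]],
      stringsAsFactors = FALSE
    )
  }
  detected <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(), precursor_mz = numeric(), rt = numeric(),
               n_pairs = integer(), matched_pairs = character(),
               organ_call = character(), leaf_area = numeric(),
               root_area = numeric(), blank_area = numeric(),
               stringsAsFactors = FALSE)
  structure(list(detected = detected, attrition = attrition,
                 pair_hits = pair_hits, n_input = length(records)),
            class = "rg_detection")
}

#' @export
print.rg_detection <- function(x, ...) {
  cat(sprintf("<rg_detection> %d/%d features kept\n", nrow(x$detected), x$n_input))
  cat("attrition:", paste(names(x$attrition), x$attrition, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
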