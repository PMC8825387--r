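# Shared fixture builders and the brute-force prediction oracle.

# minimal spectrum record built from bare vectors
make_spectrum <- function(id, precursor, mz, intensity = NULL,
                          rt = 10, linked_to = NA_character_,
                          adduct_label = NA_character_) {
  if (is.null(intensity)) intensity <- rep(1e5, length(mz))
  rgspect:::new_spectrum(id, precursor, rt,
                         data.frame(mz = mz, intensity = intensity),
                         linked_to = linked_to, adduct_label = adduct_label)
}

# one-row alignment table wrapper for hand-built area sets
make_alignment <- function(ids, leaf, root, blank) {
  structure(list(
    areas = data.frame(feature_id = ids, Leaf = leaf, Root = root,
                       Blank = blank, stringsAsFactors = FALSE),
    roles = c(Leaf = "leaf", Root = "root", Blank = "blank"),
    n_missing = 0L), class = "rg_alignment")
}

# fabricate a detection object for functions that only need the id/area table
make_detection <- function(ids, leaf = NULL, root = NULL) {
  n <- length(ids)
  structure(list(
    detected = data.frame(
      feature_id = ids, precursor_mz = rep(1000, n), rt = rep(10, n),
      n_pairs = rep(1L, n), matched_pairs = rep("", n),
      organ_call = rep("both", n),
      leaf_area = if (is.null(leaf)) rep(5000, n) else leaf,
      root_area = if (is.null(root)) rep(5000, n) else root,
      blank_area = rep(0, n), stringsAsFactors = FALSE),
    attrition = c(blank_area = 0L, linked = 0L, signature_pair = 0L),
    pair_hits = list(), n_input = n), class = "rg_detection")
}

# reduced moiety database: 3 sugar classes, 2 hydroxyacyls, 3 acyls
reduced_db <- function() {
  db <- moiety_db()
  keep <- db$class %in% c("pentose", "deoxyhexose", "hexose") |
    db$name %in% c("C16-OH", "C15-OH", "C5", "HMBA", "tiglic")
  rgspect:::validate_moiety_db(as.data.frame(db[keep, , drop = FALSE]))
}

# brute-force generate-and-test oracle for candidate enumeration: nested
# loops over every composition in the (reduced) space, testing each against
# the precursor tolerance via the composition-mass path
oracle_candidates <- function(precursor_mz, db, sugar_range, hydroxyacyls,
                              acyl_pool, max_acyls, tol) {
  out <- character()
  smax <- max(sugar_range)
  acyl_grid <- expand.grid(rep(list(0:max_acyls), length(acyl_pool)))
  acyl_grid <- acyl_grid[rowSums(acyl_grid) <= max_acyls, , drop = FALSE]
  for (p in 0:smax) for (d in 0:smax) for (h in 0:smax) {
    if (!((p + d + h) %in% sugar_range)) next
    for (hy in hydroxyacyls) {
      for (g in seq_len(nrow(acyl_grid))) {
        acyls <- rep(acyl_pool, times = as.integer(acyl_grid[g, ]))
        for (ring in c("closed", "open")) {
          for (adduct in c("deprotonated", "formate")) {
            comp <- rg_composition(c(pentose = p, deoxyhexose = d, hexose = h),
                                   hy, acyls, macrolactone = ring,
                                   adduct = adduct)
            if (abs(precursor_mz(comp, db) - precursor_mz) <= tol) {
              out <- c(out, format_composition(comp))
            }
          }
        }
      }
    }
  }
  sort(out)
}

# composition strings of a candidate table, for set comparison with the oracle
candidate_strings <- function(cand) {
  if (!nrow(cand)) return(character())
  sort(vapply(seq_len(nrow(cand)), function(i) {
    format_composition(rgspect:::candidate_to_composition(cand[i, ]))
  }, character(1)))
}
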