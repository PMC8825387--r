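# Synthetic-spectrum generator: in-silico RG spectra and matching
# MGF + alignment-table fixtures with planted compositions, decoys and
# blank signal, so every pipeline stage is testable without instrument data.

#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed makes the simulated dataset
#'   reproducible run to run.
#' @param n_rg Number of planted RG features.
#' @param sugar_weights Named sampling weights for sugar classes (default
#'   favours deoxyhexose, the ancestral hydroxyacyl-bearing sugar).
#' @param hydroxyacyl_weights Named weights over hydroxyacyl names (default
#'   dominated by C16-OH/jalapinolic acid, with C15-OH, C17-OH and C16-OHOH
#'   as the common alternatives).
#' @param acyl_weights Named weights over the frequent acyl pool.
#' @param sugar_count_range,acyl_count_range Ranges for core size (default
#'   2:7) and decorating acyl count (default 0:3, within the default
#'   prediction limits).
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da (clean preset 0.001,
#'   well under a third of the 0.01 match tolerance).
#' @param n_decoy_fragments Unexplainable noise fragments added per RG
#'   spectrum (0 in the clean preset).
#' @param decoys Named integer vector of decoy feature counts:
#'   \code{pairless} (valid area, no signature pair),
#'   \code{blank_dominated} (fails the blank ratio),
#'   \code{low_area} (RG spectrum under the area floor),
#'   \code{low_intensity_pair} (signature pair member at 4\% of base peak),
#'   \code{linked_higher} (true RG linked to a co-eluting higher mass).
#' @param organ_weights Sampling weights for organ localisation (defaults
#'   lean to roots, where RGs accumulate).
#' @param scan_range Precursor m/z window (default 500-2000); compositions
#'   are resampled until the precursor falls inside it.
#' @param area_range log10 bounds for organ peak areas (default 2e3-1e6).
#' @return List of class \code{rg_sim_config}.
#' @export
simulation_config <- function(seed = 1L, n_rg = 20L,
                              sugar_weights = c(pentose = 0.15, deoxyhexose = 0.6,
                                                hexose = 0.25),
                              hydroxyacyl_weights = c("C16-OH" = 0.6, "C15-OH" = 0.12,
                                                      "C17-OH" = 0.12, "C16-OHOH" = 0.1,
                                                      "C14-OH" = 0.03, "C18-OH" = 0.03),
                              acyl_weights = c(C5 = 0.35, HMBA = 0.2, tiglic = 0.15,
                                               butyric = 0.12, acetic = 0.1,
                                               cinnamic = 0.08),
                              sugar_count_range = 2:7,
                              acyl_count_range = 0:3,
                              mz_jitter_sd = 0.001,
                              n_decoy_fragments = 0L,
                              decoys = c(pairless = 5L, blank_dominated = 2L,
                                         low_area = 2L, low_intensity_pair = 1L,
                                         linked_higher = 1L),
                              organ_weights = c(root_only = 0.45, leaf_only = 0.1,
                                                both = 0.45),
                              scan_range = c(500, 2000),
                              area_range = c(2e3, 1e6)) {
  stopifnot(n_rg >= 0, mz_jitter_sd >= 0, scan_range[1] < scan_range[2])
  structure(as.list(environment()), class = "rg_sim_config")
}

#' Theoretical fragment ladder of a composition
#'
#' Emits the deprotonated fragments a resin glycoside of this composition
#' would produce: the hydroxyacyl free-acid anion; the glycosidic ladder of
#' the hydroxyacyl bound to 1..k sugars (for open-chain structures the
#' ladder retains the ring water, +18.0106); a water-loss satellite for each
#' ladder ion; a fragment ion for each decorating acyl except acetic (which
#' is instead expressed as a 60.0211 free-acid neutral loss from the
#' precursor); and precursor-side losses (formic acid and CO2 for formate
#' adducts, water always).
#'
#' @param comp \code{rg_composition}.
#' @param db Moiety database.
#' @return Data frame: mz, role (hydroxyacyl / ladder / satellite / acyl /
#'   precursor_loss).
#' @export
fragment_composition <- function(comp, db = moiety_db()) {
  hy <- moiety_row(db, comp$hydroxyacyl)
  su <- db_sugars(db)
  acyl_mz <- hy$acid_mass - MASS_CONST[["proton"]]
  # expand sugars in fixed anchor order: deoxyhexose, hexose, pentose
  order_classes <- c("deoxyhexose", "hexose", "pentose")
  seq_sugars <- unlist(lapply(order_classes, function(cl)
    rep(cl, comp$sugars[[cl]])))
  residues <- su$residue_mass[match(seq_sugars, su$class)]
  shift <- if (comp$macrolactone == "open") MASS_CONST[["water"]] else 0
  rows <- list(data.frame(mz = acyl_mz, role = "hydroxyacyl",
                          stringsAsFactors = FALSE))
  if (length(residues)) {
    ladder <- acyl_mz + cumsum(residues) + shift
    rows[[length(rows) + 1L]] <- data.frame(mz = ladder, role = "ladder",
                                            stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(mz = ladder - MASS_CONST[["water"]],
                                            role = "satellite",
                                            stringsAsFactors = FALSE)
  }
  pmz <- precursor_mz(comp, db)
  for (a in comp$acyls) {
    if (a == "acetic") {
      rows[[length(rows) + 1L]] <- data.frame(
        mz = pmz - monoisotopic_mass("C2H4O2"), role = "precursor_loss",
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        mz = moiety_row(db, a)$acid_mass - MASS_CONST[["proton"]], role = "acyl",
        stringsAsFactors = FALSE)
    }
  }
  ploss <- pmz - MASS_CONST[["water"]]
  if (comp$adduct == "formate") {
    ploss <- c(ploss, pmz - MASS_CONST[["formic_acid"]], pmz - MASS_CONST[["co2"]])
  }
  rows[[length(rows) + 1L]] <- data.frame(mz = ploss, role = "precursor_loss",
                                          stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(round(out$mz, 6)), , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_weighted <- function(x, weights, n = 1L) {
  x[sample.int(length(x), n, replace = TRUE, prob = weights)]
}

sample_composition <- function(cfg, db) {
  for (try in 1:200) {
    n_sugar <- sample(cfg$sugar_count_range, 1L)
    classes <- sample_weighted(names(cfg$sugar_weights), cfg$sugar_weights, n_sugar)
    sugars <- table(factor(classes, levels = c("pentose", "deoxyhexose", "hexose")))
    hy <- sample_weighted(names(cfg$hydroxyacyl_weights), cfg$hydroxyacyl_weights)
    n_acyl <- sample(cfg$acyl_count_range, 1L)
    acyls <- if (n_acyl > 0) sample_weighted(names(cfg$acyl_weights),
                                             cfg$acyl_weights, n_acyl) else character()
    ring <- sample(c("closed", "open"), 1L, prob = c(0.7, 0.3))
    adduct <- sample(c("deprotonated", "formate"), 1L, prob = c(0.5, 0.5))
    comp <- rg_composition(c(pentose = sugars[["pentose"]],
                             deoxyhexose = sugars[["deoxyhexose"]],
                             hexose = sugars[["hexose"]]),
                           hy, acyls, macrolactone = ring, adduct = adduct)
    pm <- precursor_mz(comp, db)
    if (pm >= cfg$scan_range[1] && pm <= cfg$scan_range[2]) return(comp)
  }
  stop("could not sample a composition inside the scan range")
}

# intensity model: base peak 1e6 on the hydroxyacyl anion, other explainable
# ions log-uniform 10-100% of base so the signature pair always clears the
# 10% relative-intensity floor in clean presets
spectrum_from_composition <- function(comp, feature_id, cfg, db,
                                      pair_member_rel = NULL) {
  theo <- fragment_composition(comp, db)
  base <- 1e6
  rel <- exp(runif(nrow(theo), log(0.101), log(1)))
  rel[theo$role == "hydroxyacyl"] <- 1
  if (!is.null(pair_member_rel)) {
    # force the combined pair members (ladder level 1 and its satellite)
    # to a given relative intensity, e.g. 0.04 for the filtered-out case
    first_ladder <- which(theo$role %in% c("ladder", "satellite"))
    rel[first_ladder] <- pair_member_rel
  }
  mz <- theo$mz + rnorm(nrow(theo), 0, cfg$mz_jitter_sd)
  fr <- data.frame(mz = mz, intensity = base * rel)
  pmz <- precursor_mz(comp, db) + rnorm(1, 0, cfg$mz_jitter_sd)
  if (cfg$n_decoy_fragments > 0L) {
    dmz <- decoy_mz(cfg$n_decoy_fragments, 150, 900, db,
                    existing = c(fr$mz, pmz))
    fr <- rbind(fr, data.frame(mz = dmz,
                               intensity = base * runif(cfg$n_decoy_fragments,
                                                        0.01, 0.09)))
  }
  new_spectrum(feature_id, pmz, rt = runif(1, 1, 30), fragments = fr)
}

# sample m/z values that neither match any database fragment mass nor form
# any database neutral loss among themselves (rejection sampling; margin is
# twice the usual 0.01 Da tolerance)
decoy_mz <- function(n, lo, hi, db, existing = numeric(), margin = 0.02) {
  fdb_mz <- fragment_db(db)$mz
  losses <- loss_db(db)$mass
  out <- existing
  guard <- 0L
  while (length(out) < length(existing) + n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("decoy m/z sampling failed to converge")
    cand <- runif(1, lo, hi)
    if (any(abs(fdb_mz - cand) <= margin)) next
    if (length(out)) {
      d <- abs(out - cand)
      if (any(abs(outer(d, losses, `-`)) <= margin)) next
    }
    out <- c(out, cand)
  }
  out[(length(existing) + 1L):length(out)]
}

decoy_spectrum <- function(feature_id, cfg, db) {
  n <- 12L
  pm <- runif(1, cfg$scan_range[1], cfg$scan_range[2])
  mz <- decoy_mz(n, 150, min(1400, pm), db, existing = pm)
  new_spectrum(feature_id, pm, rt = runif(1, 1, 30),
               fragments = data.frame(mz = sort(mz),
                                      intensity = 1e6 * runif(n, 0.2, 1)))
}

sample_areas <- function(organ, cfg, blank_frac = 0) {
  lo <- log10(cfg$area_range[1]); hi <- log10(cfg$area_range[2])
  draw <- function() 10^runif(1, lo, hi)
  leaf <- 0; root <- 0
  if (organ %in% c("leaf_only", "both")) leaf <- draw()
  if (organ %in% c("root_only", "both")) root <- draw()
  blank <- blank_frac * max(leaf, root)
  c(leaf = leaf, root = root, blank = blank)
}

#' Simulate an RG LC-MS/MS dataset
#'
#' Generates planted RG features (known compositions, organ assignments),
#' decoy features that violate specific detection filters on purpose, and a
#' matching peak-area alignment table, plus a truth table recording every
#' planted fact for recall scoring.  Deterministic under the configured
#' seed.
#'
#' @param cfg \code{\link{simulation_config}}.
#' @param db Moiety database.
#' @return List of class \code{rg_simulation}: \code{records} (list of
#'   \code{rg_spectrum}), \code{table} (\code{rg_alignment}), \code{truth}
#'   (data frame: feature_id, kind, composition, organ, expect_detected).
#' @export
simulate_dataset <- function(cfg = simulation_config(), db = moiety_db()) {
  set.seed(cfg$seed)
  records <- list(); truth <- list(); areas <- list()
  push <- function(rec, kind, comp, organ, expect, a) {
    records[[length(records) + 1L]] <<- rec
    truth[[length(truth) + 1L]] <<- data.frame(
      feature_id = rec$feature_id, kind = kind,
      composition = if (is.null(comp)) NA_character_ else format_composition(comp),
      organ = organ, expect_detected = expect, stringsAsFactors = FALSE)
    areas[[length(areas) + 1L]] <<- data.frame(
      feature_id = rec$feature_id, Leaf = a[["leaf"]], Root = a[["root"]],
      Blank = a[["blank"]], stringsAsFactors = FALSE)
  }

  for (i in seq_len(cfg$n_rg)) {
    comp <- sample_composition(cfg, db)
    organ <- sample_weighted(names(cfg$organ_weights), cfg$organ_weights)
    fid <- sprintf("RG_%03d", i)
    push(spectrum_from_composition(comp, fid, cfg, db), "rg", comp, organ,
         TRUE, sample_areas(organ, cfg))
  }
  d <- cfg$decoys
  nd <- function(nm) if (nm %in% names(d)) d[[nm]] else 0L
  for (i in seq_len(nd("pairless"))) {
    fid <- sprintf("DECOY_PAIRLESS_%02d", i)
    push(decoy_spectrum(fid, cfg, db), "pairless", NULL, "both", FALSE,
         sample_areas("both", cfg))
  }
  for (i in seq_len(nd("blank_dominated"))) {
    comp <- sample_composition(cfg, db)
    fid <- sprintf("DECOY_BLANK_%02d", i)
    push(spectrum_from_composition(comp, fid, cfg, db), "blank_dominated",
         comp, "both", FALSE, sample_areas("both", cfg, blank_frac = 0.5))
  }
  for (i in seq_len(nd("low_area"))) {
    comp <- sample_composition(cfg, db)
    fid <- sprintf("DECOY_LOWAREA_%02d", i)
    a <- c(leaf = runif(1, 10, 900), root = 0, blank = 0)
    push(spectrum_from_composition(comp, fid, cfg, db), "low_area",
         comp, "ambiguous", FALSE, a)
  }
  for (i in seq_len(nd("low_intensity_pair"))) {
    comp <- sample_composition(cfg, db)
    fid <- sprintf("DECOY_LOWINT_%02d", i)
    push(spectrum_from_composition(comp, fid, cfg, db, pair_member_rel = 0.04),
         "low_intensity_pair", comp, "both", FALSE, sample_areas("both", cfg))
  }
  for (i in seq_len(nd("linked_higher"))) {
    comp <- sample_composition(cfg, db)
    fid <- sprintf("DECOY_LINKED_%02d", i)
    hid <- sprintf("DECOY_LINKHI_%02d", i)
    rec <- spectrum_from_composition(comp, fid, cfg, db)
    # companion: higher-mass pairless feature with solid areas, so the link
    # resolves (the lower true-RG peak is lost, as for Dichondrin D)
    hi_rec <- decoy_spectrum(hid, cfg, db)
    hi_rec$precursor_mz <- rec$precursor_mz + runif(1, 40, 120)
    rec$linked_to <- hid
    push(rec, "linked_higher", comp, "both", FALSE, sample_areas("both", cfg))
    push(hi_rec, "linked_companion", NULL, "both", FALSE,
         sample_areas("both", cfg))
  }
  truth <- do.call(rbind, truth)
  areas <- do.call(rbind, areas)
  table <- structure(list(areas = areas,
                          roles = c(Leaf = "leaf", Root = "root", Blank = "blank"),
                          n_missing = 0L),
                     class = "rg_alignment")
  structure(list(records = records, table = table, truth = truth, config = cfg),
            class = "rg_simulation")
}

#' Write a simulated dataset to disk
#'
#' Writes the MGF, the alignment TSV, the truth TSV and a sample-roles YAML
#' into a directory.
#'
#' @param sim \code{rg_simulation}.
#' @param out_dir Directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mgf = file.path(out_dir, "spectra.mgf"),
    areas = file.path(out_dir, "areas.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    roles = file.path(out_dir, "roles.yaml")
  )
  write_mgf(sim$records, paths$mgf)
  write_alignment(sim$table, paths$areas)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(as.list(sim$table$roles), paths$roles)
  invisible(paths)
}

#' The hard-case benchmark: 13 known RGs
#'
#' Builds 13 synthetic known-RG spectra mirroring the structure of the
#' benchmark set: 11 compositions within the default prediction limits
#' (2-7 sugars, at most three frequent acyls), one open-chain RG carrying
#' five acyl chains (assembling exactly to C62H104O27, the Dichondrin D
#' formula) and one containing decanoic acid (a Merremin-like structure).
#' Default-mode prediction can recover 11 of the 13; extended mode (five
#' acyls, decanoic in the pool) recovers all 13.
#'
#' @param cfg \code{\link{simulation_config}} controlling jitter (spectra
#'   are generated with its seed).
#' @param db Moiety database.
#' @return List: \code{records}, \code{known} (data frame name, feature_id,
#'   composition, precursor_mz).
#' @export
known_rg_benchmark <- function(cfg = simulation_config(seed = 42L), db = moiety_db()) {
  set.seed(cfg$seed)
  comps <- list(
    tricolorin_A   = rg_composition(c(deoxyhexose = 3, hexose = 1), "C16-OH",
                                    c("C5", "C5"), "closed", "formate"),
    tricolorin_D   = rg_composition(c(deoxyhexose = 3, hexose = 1), "C16-OH",
                                    c("C5", "C5"), "closed", "formate"),
    tetra_tiglic   = rg_composition(c(deoxyhexose = 2, hexose = 2), "C16-OH",
                                    c("tiglic"), "closed", "deprotonated"),
    penta_hmba     = rg_composition(c(pentose = 1, deoxyhexose = 3, hexose = 1),
                                    "C16-OH", c("HMBA", "C5"), "closed", "formate"),
    tri_plain      = rg_composition(c(deoxyhexose = 2, hexose = 1), "C15-OH",
                                    character(), "closed", "deprotonated"),
    hexa_cinnamic  = rg_composition(c(deoxyhexose = 4, hexose = 2), "C16-OH",
                                    c("cinnamic", "C5"), "closed", "formate"),
    di_open        = rg_composition(c(deoxyhexose = 2), "C16-OH",
                                    c("butyric"), "open", "deprotonated"),
    tetra_dihydroxy = rg_composition(c(deoxyhexose = 3, pentose = 1), "C16-OHOH",
                                     c("C5"), "closed", "deprotonated"),
    hepta_core     = rg_composition(c(pentose = 2, deoxyhexose = 3, hexose = 2),
                                    "C17-OH", c("tiglic", "acetic"), "closed",
                                    "formate"),
    tetra_acetic   = rg_composition(c(deoxyhexose = 3, hexose = 1), "C16-OH",
                                    c("acetic", "C5", "C5"), "closed",
                                    "deprotonated"),
    tri_c18        = rg_composition(c(deoxyhexose = 2, hexose = 1), "C18-OH",
                                    c("HMBA"), "closed", "formate"),
    # hard case 1: five acyl chains; assembles to C62H104O27 (open chain)
    dichondrin_D   = rg_composition(c(deoxyhexose = 2, hexose = 2), "C16-OH",
                                    c("C5", "C5", "HMBA", "tiglic", "acetic"),
                                    "open", "deprotonated"),
    # hard case 2: contains decanoic acid
    merremin_like  = rg_composition(c(deoxyhexose = 3, hexose = 1), "C16-OH",
                                    c("decanoic", "C5"), "closed", "formate")
  )
  records <- list(); rows <- list()
  for (i in seq_along(comps)) {
    nm <- names(comps)[i]
    fid <- sprintf("KNOWN_%02d_%s", i, nm)
    records[[i]] <- spectrum_from_composition(comps[[i]], fid, cfg, db)
    rows[[i]] <- data.frame(name = nm, feature_id = fid,
                            composition = format_composition(comps[[i]]),
                            precursor_mz = precursor_mz(comps[[i]], db),
                            stringsAsFactors = FALSE)
  }
  list(records = records, known = do.call(rbind, rows))
}
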