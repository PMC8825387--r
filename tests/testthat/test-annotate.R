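# Fragment matching, neutral-loss inference, coverage, component scans.

test_that("top_fragments keeps the n most intense with a deterministic tie rule", {
  r25 <- make_spectrum("a", 900, seq(100, 340, 10), intensity = c(1:24, 24))
  top <- top_fragments(r25, 20)
  expect_equal(nrow(top), 20L)
  # intensity 24 is shared by m/z 330 and 340; the cutoff keeps the lower m/z
  expect_true(330 %in% top$mz)
  r8 <- make_spectrum("b", 900, seq(100, 170, 10))
  expect_equal(nrow(top_fragments(r8, 20)), 8L)
  tie <- make_spectrum("c", 900, c(200, 100), intensity = c(5, 5))
  expect_equal(top_fragments(tie, 1)$mz, 100)
})

test_that("fragment matching reports all database entries within tolerance", {
  fdb <- fragment_db()
  m <- match_fragments(data.frame(mz = c(271.2279, 101.0608, 500.0),
                                  intensity = c(1, 1, 1)), fdb, tol = 0.01)
  expect_true(any(m$matched == "C16-OH" & m$mz == 271.2279, na.rm = TRUE))
  expect_true(any(m$matched == "C5" & abs(m$mz - 101.0608) < 1e-6, na.rm = TRUE))
  expect_true(is.na(m$matched[m$mz == 500.0]))
  # every reported match is within tolerance
  ok <- !is.na(m$delta)
  expect_true(all(abs(m$delta[ok]) <= 0.01))
})

test_that("neutral losses are inferred from pairwise differences", {
  ldb <- loss_db()
  # deoxyhexose residue between the signature pair
  e1 <- infer_neutral_losses(data.frame(mz = c(417.2858, 271.2279),
                                        intensity = c(1, 1)), NA, ldb, 0.01)
  expect_true(any(e1$loss_name == "deoxyhexose"))
  # water between consecutive ladder/satellite ions
  e2 <- infer_neutral_losses(data.frame(mz = c(579.3386, 561.3281),
                                        intensity = c(1, 1)), NA, ldb, 0.01)
  expect_true(any(e2$special == "water", na.rm = TRUE))
  # formic acid between the formate adduct and the deprotonated ion
  e3 <- infer_neutral_losses(data.frame(mz = c(1021.5589, 900.0),
                                        intensity = c(1, 1)),
                             precursor_mz = 1067.5644, ldb, 0.01)
  expect_true(any(e3$special == "formate", na.rm = TRUE))
  # antisymmetry: edges always run higher -> lower
  all_edges <- rbind(e1, e2, e3)
  expect_true(all(all_edges$higher_mz > all_edges$lower_mz))
  expect_true(all(all_edges$loss_mass > 0))
})

test_that("annotation coverage is 1 on clean RG spectra and 0 on decoys", {
  db <- moiety_db()
  cfg <- simulation_config(seed = 21, n_rg = 6,
                           decoys = c(pairless = 0L, blank_dominated = 0L,
                                      low_area = 0L, low_intensity_pair = 0L,
                                      linked_higher = 0L))
  sim <- simulate_dataset(cfg)
  ann <- annotate_spectra(sim$records)
  expect_equal(annotation_coverage(ann), 1.0)
  # decoy-only spectrum: nothing matches, nothing forms a known loss
  set.seed(4)
  dmz <- rgspect:::decoy_mz(8, 150, 900, db, existing = 1500.9)
  dec <- make_spectrum("dec", 1500.9, sort(dmz))
  expect_equal(annotation_coverage(annotate_spectra(list(dec))), 0.0)
})

test_that("coverage on a half-planted spectrum is one half", {
  db <- moiety_db()
  planted <- c(271.2279, 417.2858, 433.2807, 101.0608)
  set.seed(8)
  decoys <- rgspect:::decoy_mz(4, 150, 900, db, existing = c(planted, 1500.9))
  rec <- make_spectrum("half", 1500.9, c(planted, decoys))
  expect_equal(annotation_coverage(annotate_spectra(list(rec))), 0.5)
})

test_that("coverage is monotone in tolerance", {
  sim <- simulate_dataset(simulation_config(seed = 31, n_rg = 4,
                                            mz_jitter_sd = 0.004,
                                            decoys = c(pairless = 2L)))
  covs <- vapply(c(0.001, 0.005, 0.02), function(tol) {
    annotation_coverage(annotate_spectra(sim$records, tol = tol))
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("component scans count fragments and the acetic neutral loss", {
  db <- moiety_db()
  # 10 RG-like records: all carry the C16-OH/deoxyhexose pair and a tiglic
  # fragment; 3 also carry the C5 fragment; 2 show acetic acid only as a
  # -60.0211 neutral loss from the precursor
  tiglic_mz <- 99.0452
  recs <- lapply(1:10, function(i) {
    mz <- c(271.2279, 417.2858, tiglic_mz)
    if (i <= 3) mz <- c(mz, 101.0608)
    pm <- 1000.5
    if (i <= 2) mz <- c(mz, pm - 60.02113)
    make_spectrum(sprintf("s%02d", i), pm, mz)
  })
  det <- make_detection(sprintf("s%02d", 1:10))
  scan <- scan_components(det, recs, db)
  expect_equal(scan$hydroxyacyl$n[scan$hydroxyacyl$name == "C16-OH"], 10L)
  expect_equal(scan$sugar_pair$n[scan$sugar_pair$class == "deoxyhexose"], 10L)
  expect_equal(scan$n_with_acyl, 10L)
  expect_equal(scan$acyl$pct[scan$acyl$name == "C5"], 30)
  expect_equal(scan$acyl$n[scan$acyl$name == "acetic"], 2L)
})
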