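# Elemental-mass arithmetic and the moiety database.

test_that("monoisotopic masses match independently hand-summed values", {
  # frozen by summing atomic masses by hand:
  # C16H32O3 = 16*12 + 32*1.00782503 + 3*15.9949146 = 272.23514
  expect_equal(monoisotopic_mass("C16H32O3"), 272.23514, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  # C62H104O27 = 744 + 104.81380 + 431.86269 = 1280.67650
  expect_equal(monoisotopic_mass("C62H104O27"), 1280.67650, tolerance = 1e-4)
  expect_error(monoisotopic_mass("C2HxO"), "unknown element")
})

test_that("formula parsing and arithmetic behave as count vectors", {
  f <- parse_formula("C6H12O6")
  expect_s3_class(f, "rg_formula")
  expect_identical(unclass(f)[c("C", "H", "O")], c(C = 6L, H = 12L, O = 6L))
  expect_equal(format(formula_add("C2H4O2", "C2H4O2")), "C4H8O4")
  expect_equal(format(formula_subtract("C6H12O6", "H2O")), "C6H10O5")
  expect_error(formula_subtract("H2O", "C2H4O2"), "negative")
  expect_error(parse_formula("notaformula!"), "cannot parse|unknown")
})

test_that("deprotonation reproduces the hydroxyacyl anion m/z values", {
  cases <- list(
    list("C16H32O3", 271.2279),  # jalapinolic acid, C16-OH
    list("C15H30O3", 257.2122),  # C15-OH
    list("C16H32O4", 287.2228),  # C16-OHOH
    list("C5H10O2", 101.0608)    # five-carbon acyl acids
  )
  for (cs in cases) {
    expect_equal(deprotonated_mz(cs[[1]]), cs[[2]], tolerance = 5e-5)
  }
  expect_error(deprotonated_mz("C2O4"), "hydrogen")
})

test_that("adduct arithmetic applies the proton/formate offsets", {
  expect_equal(adduct_mz(1022.5662, "formate"), 1067.5644, tolerance = 2e-4)
  expect_equal(adduct_mz(1280.6765, "deprotonated"), 1279.6692, tolerance = 2e-4)
  expect_equal(adduct_mz(100, "deprotonated"), 98.992724, tolerance = 1e-6)
  expect_error(adduct_mz(100, "sodiated"))
})

test_that("the default database is internally consistent", {
  db <- moiety_db()
  expect_equal(nrow(rgspect:::db_sugars(db)), 3L)
  expect_equal(nrow(rgspect:::db_hydroxyacyls(db)), 10L)
  expect_equal(nrow(rgspect:::db_acyls(db)), 22L)
  # formula/mass round trip to 1e-6 Da
  for (i in seq_len(nrow(db))) {
    m <- monoisotopic_mass(db$formula[i])
    ref <- if (is.na(db$acid_mass[i])) db$residue_mass[i] else db$acid_mass[i]
    expect_lt(abs(m - ref), 1e-6)
  }
  # sugar residues carry the canonical masses
  su <- rgspect:::db_sugars(db)
  expect_equal(sort(su$residue_mass), c(132.0423, 146.0579, 162.0528),
               tolerance = 1e-4)
})

test_that("database YAML round-trips and validation catches corruption", {
  db <- moiety_db()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_moiety_db(db, path)
  db2 <- read_moiety_db(path)
  expect_equal(db2$name, db$name)
  expect_equal(db2$residue_mass, db$residue_mass, tolerance = 1e-9)
  bad <- as.data.frame(db)
  bad$name[2] <- bad$name[1]
  expect_error(rgspect:::validate_moiety_db(bad), "unique")
})

test_that("signature-pair table is the hydroxyacyl x sugar product", {
  sp <- signature_pair_table()
  expect_equal(nrow(sp), 30L)
  expect_equal(length(unique(sp$hydroxyacyl)), 10L)
  expect_equal(length(unique(sp$sugar_class)), 3L)
  c16_deoxy <- sp[sp$hydroxyacyl == "C16-OH" & sp$sugar_class == "deoxyhexose", ]
  expect_equal(c16_deoxy$acyl_mz, 271.2279, tolerance = 5e-5)
  expect_equal(c16_deoxy$combined_mz, 417.2858, tolerance = 5e-5)
  c16_pent <- sp[sp$hydroxyacyl == "C16-OH" & sp$sugar_class == "pentose", ]
  expect_equal(c16_pent$combined_mz, 403.2702, tolerance = 2e-4)
  # pair consistency: the gap is always one sugar residue mass
  gaps <- sp$combined_mz - sp$acyl_mz
  residues <- c(132.042259, 146.057909, 162.052824)
  expect_true(all(vapply(gaps, function(g) any(abs(g - residues) < 1e-6),
                         logical(1))))
})

test_that("composition masses reproduce assembled structures", {
  db <- moiety_db()
  tricolorin_a <- rg_composition(c(deoxyhexose = 3, hexose = 1), "C16-OH",
                                 c("C5", "C5"), "closed", "formate")
  expect_equal(composition_mass(tricolorin_a, db), 1022.5662, tolerance = 2e-4)
  expect_equal(precursor_mz(tricolorin_a, db), 1067.5644, tolerance = 2e-4)
  # five-acyl open structure assembling to C62H104O27
  dichondrin_d <- rg_composition(c(deoxyhexose = 2, hexose = 2), "C16-OH",
                                 c("C5", "C5", "HMBA", "tiglic", "acetic"),
                                 "open", "deprotonated")
  expect_equal(composition_mass(dichondrin_d, db),
               monoisotopic_mass("C62H104O27"), tolerance = 1e-6)
  # single hexose + open C16-OH, no acyls: brute-force formula C22H42O8
  expect_equal(composition_mass(rg_composition(c(hexose = 1), "C16-OH",
                                               macrolactone = "open"), db),
               monoisotopic_mass("C22H42O8"), tolerance = 1e-6)
  expect_error(rg_composition(c(), "C16-OH"), "at least one sugar")
})

test_that("composition-mass properties hold across the composition space", {
  db <- moiety_db()
  set.seed(11)
  for (rep in 1:20) {
    sugars <- c(pentose = sample(0:2, 1), deoxyhexose = sample(1:3, 1),
                hexose = sample(0:2, 1))
    hy <- sample(rgspect:::db_hydroxyacyls(db)$name, 1)
    acyls <- sample(rgspect:::db_acyls(db)$name, sample(0:3, 1))
    base <- rg_composition(sugars, hy, acyls, macrolactone = "open")
    m0 <- composition_mass(base, db)
    # additivity: one more sugar residue adds exactly its residue mass
    for (cl in c("pentose", "deoxyhexose", "hexose")) {
      plus <- sugars; plus[cl] <- plus[cl] + 1L
      m1 <- composition_mass(rg_composition(plus, hy, acyls,
                                            macrolactone = "open"), db)
      res <- rgspect:::db_sugars(db)$residue_mass[
        rgspect:::db_sugars(db)$class == cl]
      expect_equal(m1 - m0, res, tolerance = 1e-9)
    }
    # ring closure removes exactly one water
    closed <- rg_composition(sugars, hy, acyls, macrolactone = "closed")
    expect_equal(m0 - composition_mass(closed, db), 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("composition strings round-trip", {
  comp <- rg_composition(c(pentose = 1, deoxyhexose = 2), "C17-OH",
                         c("tiglic", "acetic"), "open", "formate")
  back <- parse_composition(format_composition(comp))
  expect_equal(back$sugars, comp$sugars)
  expect_equal(back$acyls, comp$acyls)
  expect_equal(back$macrolactone, comp$macrolactone)
  expect_equal(back$adduct, comp$adduct)
})
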