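# Detection filters (i)-(iv) and organ assignment.

pairs <- signature_pair_table()

test_that("blank/area filter applies both the area floor and the ratio", {
  tab <- make_alignment(c("a", "b", "c", "d"),
                        leaf = c(5000, 600, 20000, 2000),
                        root = c(0, 0, 0, 0),
                        blank = c(100, 50, 5000, 0))
  cfg <- detection_config()
  rec <- function(id) make_spectrum(id, 1000, 500)
  expect_true(filter_blank_area(rec("a"), tab, cfg)$pass)   # ratio 50, area ok
  fb <- filter_blank_area(rec("b"), tab, cfg)
  expect_false(fb$pass)                                     # area 600 <= 1000
  expect_match(fb$reason, "area")
  fc <- filter_blank_area(rec("c"), tab, cfg)
  expect_false(fc$pass)                                     # ratio 4 <= 10
  expect_match(fc$reason, "ratio")
  expect_true(filter_blank_area(rec("d"), tab, cfg)$pass)   # blank 0 passes ratio
})

test_that("signature pairs require both members above 10% of base peak", {
  cfg <- detection_config()
  # C16-OH + deoxyhexose at full strength
  r1 <- make_spectrum("r1", 1067.56, c(271.2279, 417.2858), c(1e6, 4e5))
  hits <- filter_signature_pairs(r1, pairs, cfg)
  expect_true(nrow(hits) >= 1L)
  expect_true(any(hits$hydroxyacyl == "C16-OH" & hits$sugar_class == "deoxyhexose"))
  # pair member at 4% of base: the filtered-out scenario
  r2 <- make_spectrum("r2", 1079.49, c(257.2122, 419.2650, 500.0),
                      c(0.04e6, 0.6e6, 1e6))
  expect_equal(nrow(filter_signature_pairs(r2, pairs, cfg)), 0L)
  # lone hydroxyacyl fragment is not a pair
  r3 <- make_spectrum("r3", 900, 271.2279, 5e5)
  expect_equal(nrow(filter_signature_pairs(r3, pairs, cfg)), 0L)
})

test_that("linked peaks resolve per configuration", {
  lo <- make_spectrum("lo", 1279.6695, 271.2279, linked_to = "hi")
  hi <- make_spectrum("hi", 1364.642, 500.1)
  free <- make_spectrum("free", 800, 300.2)
  out <- resolve_linked_peaks(list(lo, hi, free), detection_config())
  expect_identical(out$dropped, "lo")   # peak linked to a higher mass is lost
  out2 <- resolve_linked_peaks(list(lo, hi, free),
                               detection_config(keep_linked = "both"))
  expect_length(out2$dropped, 0L)
  out3 <- resolve_linked_peaks(list(lo, hi, free),
                               detection_config(keep_linked = "lower"))
  expect_identical(out3$dropped, "hi")
  # dangling link warns and keeps both
  dangling <- make_spectrum("d", 700, 100.5, linked_to = "ghost")
  expect_warning(out4 <- resolve_linked_peaks(list(dangling), detection_config()),
                 "ghost")
  expect_length(out4$dropped, 0L)
  # adduct-labelled records are always retained
  add <- make_spectrum("add", 900, 100.5, linked_to = "hi",
                       adduct_label = "[M+FA-H]-")
  out5 <- resolve_linked_peaks(list(add, hi), detection_config())
  expect_length(out5$dropped, 0L)
})

test_that("organ assignment follows the area scenarios", {
  expect_identical(assign_organ(0, 5000), "root_only")
  expect_identical(assign_organ(5000, 0), "leaf_only")
  expect_identical(assign_organ(1500, 1200), "both")
  expect_identical(assign_organ(800, 300), "ambiguous")
  expect_identical(assign_organ(1500, 500), "ambiguous")
  expect_error(assign_organ(-1, 0))
})

test_that("detection separates planted RGs from decoys exactly", {
  sim <- simulate_dataset(simulation_config(
    seed = 3, n_rg = 5,
    decoys = c(pairless = 5L, blank_dominated = 0L, low_area = 1L,
               low_intensity_pair = 0L, linked_higher = 0L)))
  det <- detect_rg(sim$records, sim$table)
  expect_setequal(det$detected$feature_id,
                  sim$truth$feature_id[sim$truth$expect_detected])
  expect_equal(det$attrition[["blank_area"]], 1L)       # the low-area decoy
  expect_equal(det$attrition[["signature_pair"]], 5L)   # the pairless decoys
})

test_that("detection is independent of record order and monotone in thresholds", {
  sim <- simulate_dataset(simulation_config(seed = 5, n_rg = 8))
  det1 <- detect_rg(sim$records, sim$table)
  set.seed(99)
  shuffled <- sim$records[sample(length(sim$records))]
  det2 <- suppressWarnings(detect_rg(shuffled, sim$table))
  expect_identical(det1$detected, det2$detected)
  # raising any threshold never increases the detected count
  n0 <- nrow(det1$detected)
  for (cfg in list(detection_config(area_min = 1e5),
                   detection_config(blank_ratio_min = 1e4),
                   detection_config(relative_intensity_min = 0.5),
                   detection_config(fragment_match_tolerance = 1e-5))) {
    expect_lte(nrow(detect_rg(sim$records, sim$table, cfg = cfg)$detected), n0)
  }
})

test_that("an all-blank dataset yields zero detections with full attrition", {
  sim <- simulate_dataset(simulation_config(
    seed = 9, n_rg = 0,
    decoys = c(pairless = 0L, blank_dominated = 4L, low_area = 0L,
               low_intensity_pair = 0L, linked_higher = 0L)))
  det <- detect_rg(sim$records, sim$table)
  expect_equal(nrow(det$detected), 0L)
  expect_equal(det$attrition[["blank_area"]], 4L)
})
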