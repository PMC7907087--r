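ref24 <- function(vol = 2) well_geometry(15.6, 3.3, vol, plate_format = "24")

test_that("cylinder geometry derivation matches hand arithmetic", {
  g <- ref24()
  expect_equal(g$headspace_volume_ml, 1.3)
  expect_equal(g$bottom_area_cm2, pi * 0.78^2)        # ~1.911 cm^2
  expect_equal(g$bottom_area_cm2, 1.911, tolerance = 1e-3)
  expect_equal(g$wetted_wall_area_cm2, pi * 1.56 * (2 / (pi * 0.78^2)))
  expect_equal(g$wetted_wall_area_cm2, 5.13, tolerance = 1e-3)
  # halving the medium halves the wetted wall exactly (linear fill height)
  g1 <- ref24(1)
  expect_equal(g1$wetted_wall_area_cm2, g$wetted_wall_area_cm2 / 2)
  # medium approaching the total drives headspace to zero
  tiny <- well_geometry(15.6, 3.3, 3.3 - 1e-9)
  expect_equal(tiny$headspace_volume_ml, 1e-9, tolerance = 1e-3)
  expect_error(well_geometry(15.6, 3.3, 3.3), "no headspace")
  expect_error(well_geometry(15.6, 3.3, 4), "no headspace")
})

test_that("geometry scale factors reproduce the worked volume change", {
  sc_id <- geometry_scales(ref24(), ref24())
  expect_equal(sc_id$s_hydrophobic, 1)
  expect_equal(sc_id$s_volatile, 1)
  expect_equal(sc_id$s_biota, 1)
  # 24-well, 2 mL -> 1 mL: wall-only plastic halves with the volume,
  # headspace grows 1.3 -> 2.3 mL (1.76-fold)
  sc <- geometry_scales(ref24(2), ref24(1))
  expect_equal(sc$s_hydrophobic, 1)
  expect_equal(sc$plastic_area_factor, 0.5)
  expect_equal(sc$headspace_factor, 2.3 / 1.3)
  expect_equal(sc$headspace_factor, 1.76, tolerance = 6e-3)
  expect_equal(sc$s_volatile, (2.3 / 1) / (1.3 / 2))   # ~3.54
  # wall+bottom convention gives ~0.64, not 0.5
  scb <- geometry_scales(ref24(2), ref24(1), "wall_plus_bottom")
  expect_equal(scb$plastic_area_factor, 0.64, tolerance = 1e-2)
})

test_that("biota scaling follows the payload per medium volume", {
  cells <- list(kind = "cell_monolayer", count = 3e5, diameter_um = 15)
  a <- well_geometry(15.6, 3.3, 2, biota = cells)
  b <- well_geometry(15.6, 3.3, 1, biota = cells)
  sc <- geometry_scales(a, b)
  expect_equal(sc$s_biota, 2)   # same cells, half the medium
})

test_that("extrapolation is the identity on the reference geometry", {
  fx <- intext_chemicals()
  p <- starting_params("adhesive_foil")
  r <- predict_ratio(fx, p, warn_missing = FALSE)
  expect_identical(extrapolate_ratio(fx, p, ref24(), ref24()), r)
})

test_that("volume reduction hits volatile chemicals, spares non-volatile", {
  p <- starting_params()
  naph <- chemicals("naphthalene", 3.3, -3.36)
  difen <- chemicals("difenoconazole", 4.3, -11.05)
  r_ref <- predict_ratio(naph, p)
  r_new <- extrapolate_ratio(naph, p, ref24(2), ref24(1))
  # hand arithmetic: O = 10^1.94, O_h = 10^-0.7, s_v = 2.3/0.65
  o <- 10^1.94
  oh <- 10^-0.7
  expect_equal(r_new, 1 / (1 + oh + (o - oh) * (2.3 / 0.65)))
  expect_equal(r_new, 0.0032, tolerance = 2e-2)
  expect_lt(r_new, r_ref)
  # fully non-volatile chemical with s_hydrophobic = 1: unchanged
  expect_equal(extrapolate_ratio(difen, p, ref24(2), ref24(1)),
               predict_ratio(difen, p), tolerance = 1e-12)
})

test_that("extrapolated ratios stay in (0,1) and fall with every scale", {
  p <- truth_params()
  chems <- generate_chemicals(40, seed = 61)
  vols <- c(2.8, 2.4, 2, 1.5, 1, 0.6)
  rr <- sapply(vols, function(v)
    extrapolate_ratio(chems, p, ref24(2), ref24(v)))
  expect_true(all(rr > 0 & rr < 1))
  # shrinking medium monotonically increases both scales -> ratios fall
  ord <- order(vols, decreasing = TRUE)
  for (i in seq_len(nrow(rr)))
    expect_true(all(diff(rr[i, ord]) < 1e-12))
})

test_that("non-volatile chemicals respond only to the plastic scale", {
  p <- truth_params()
  difen <- chemicals("difenoconazole", 4.3, -11.05)
  # two targets with identical wetted-area/volume but different headspace
  a <- well_geometry(15.6, 3.3, 1)
  b <- well_geometry(15.6, 9.9, 1)
  expect_equal(geometry_scales(ref24(), a)$s_hydrophobic,
               geometry_scales(ref24(), b)$s_hydrophobic)
  expect_false(isTRUE(all.equal(geometry_scales(ref24(), a)$s_volatile,
                                geometry_scales(ref24(), b)$s_volatile)))
  expect_equal(extrapolate_ratio(difen, p, ref24(), a),
               extrapolate_ratio(difen, p, ref24(), b), tolerance = 1e-12)
})

test_that("the odds transfer rule inverts exactly", {
  # applying the rule with scales s and then 1/s returns the start ratio
  p <- truth_params()
  chems <- generate_chemicals(25, seed = 67)
  r <- predict_ratio(chems, p, warn_missing = FALSE)
  odds_h <- 10^((p$p1 - chems$log_kow) * p$p4)
  odds_v <- (1 - r) / r - odds_h
  s_h <- 1.7
  s_v <- 3.2
  r_new <- 1 / (1 + odds_h * s_h + odds_v * s_v)
  oh_new <- odds_h * s_h
  ov_new <- odds_v * s_v
  r_back <- 1 / (1 + oh_new / s_h + ov_new / s_v)
  expect_equal(r_back, r, tolerance = 1e-12)
})

test_that("shipped default geometries are self-consistent", {
  for (fmt in c(6, 24, 48)) {
    g <- default_geometry(fmt)
    expect_s3_class(g, "well_geometry")
    expect_gt(g$headspace_volume_ml, 0)
    expect_equal(g$headspace_volume_ml,
                 g$total_well_volume_ml - g$medium_volume_ml)
  }
  expect_error(default_geometry(96), "no default")
})
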