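test_that("layer boundaries tile the normalized depth axis", {
  b <- layer_boundaries()
  expect_equal(unname(unclass(b)[length(b)]), 1)
  expect_error(layer_boundaries(c(L1 = 0.3, `L2/3` = 0.2, L6 = 1)))
  expect_error(layer_boundaries(c(L1 = 0.3, L6 = 0.9)), "must be 1")
  lay <- layer_of(c(0.005, 0.15, 0.30, 0.5, 0.99), b)
  expect_equal(as.character(lay), c("L1", "L2/3", "L4", "L5", "L6"))
})

test_that("synthetic profiles honor their construction", {
  for (line in names(expression_lines())) {
    p <- synthetic_profile(line)
    expect_equal(max(p$value), 1)
    expect_true(all(p$value >= 0))
    expect_true(all(diff(p$depth_mm) > 0))
  }
  # deterministic: no randomness involved
  expect_identical(synthetic_profile("Cux2-Ai93"),
                   synthetic_profile("Cux2-Ai93"))
  # layer-4 line peaks within layer 4
  p4 <- synthetic_profile("Rorb-Ai93")
  zmax <- p4$depth_mm[which.max(p4$value)]
  expect_gt(zmax, 0.30)
  expect_lt(zmax, 0.42)
  # zero baseline: support confined to the somatic layer (plus smoothing)
  solo <- synthetic_profile(somatic_layers = "L5", neuropil_baseline = 0,
                            smoothing_scale = 0.02)
  expect_lt(max(solo$value[solo$depth_mm < 0.3]), 0.02)
  expect_lt(max(solo$value[solo$depth_mm > 0.8]), 0.02)
  expect_error(synthetic_profile(somatic_layers = character(0),
                                 neuropil_baseline = 0), "zero")
  expect_error(synthetic_profile(somatic_layers = "L9"), "subset")
})

test_that("section-image profiles rescale depth and intensity correctly", {
  img <- matrix(1, nrow = 120, ncol = 60)
  p <- profile_from_section_image(img, surface_row = 10, wm_row = 110,
                                  pixel_pitch_mm = 0.01)
  expect_true(all(abs(p$value - 1) < 1e-12))
  expect_equal(min(p$depth_mm), 0)
  expect_equal(max(p$depth_mm), 1)   # white-matter row maps to 1 mm exactly
  # single bright row at the midpoint appears at depth 0.5
  img2 <- matrix(0.01, 120, 60)
  img2[60, ] <- 5
  p2 <- profile_from_section_image(img2, 10, 110, 0.01)
  expect_equal(p2$depth_mm[which.max(p2$value)], 0.5)
  # invariant to global intensity scaling
  p3 <- profile_from_section_image(img2 * 37.5, 10, 110, 0.01)
  expect_equal(p2$value, p3$value)
  # strip narrower than the image: uses the central columns only
  img4 <- matrix(0.01, 120, 200)
  img4[, 90:110] <- 1   # bright central band
  img4[, 1:10] <- 100   # bright edge outside the 0.75 mm strip
  p4 <- profile_from_section_image(img4, 10, 110, 0.01)
  expect_true(all(p4$value > 0.5))
  expect_error(profile_from_section_image(img, 50, 20, 0.01))
  expect_error(profile_from_section_image(matrix(0, 10, 10), 1, 9, 0.01),
               "no signal")
})

test_that("profiles resample onto the simulation grid by interpolation", {
  p <- synthetic_profile("Ntsr1-Ai148", pitch = 0.05)
  r <- resample_profile(p, pitch = 0.01)
  expect_equal(nrow(r), 100)
  expect_equal(max(r$value), 1, tolerance = 1e-9)
  expect_equal(approx(p$depth_mm, p$value, xout = 0.505)$y,
               r$value[r$depth_mm == 0.505], tolerance = 1e-9)
})
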