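test_that("Beer-Lambert transmission reproduces the closed form", {
  expect_equal(beer_lambert_transmission(path_length = 0), 1)
  # 200 um of blood transmits about 6%
  t200 <- beer_lambert_transmission(path_length = 0.02)
  expect_equal(t200, 10^(-27895 * 2.2e-3 * 0.02))
  expect_equal(t200, 0.0592, tolerance = 1e-3)
  # 500 um transmits well under 1%
  expect_lt(beer_lambert_transmission(path_length = 0.05), 0.01)
  m <- blood_optical_model(path_length = 0.01)
  expect_equal(beer_lambert_transmission(m), 10^(-27895 * 2.2e-3 * 0.01))
  expect_error(blood_optical_model(oxygenation_fraction = 1.4))
  expect_error(blood_optical_model(hemoglobin_concentration = -1))
})

test_that("vessel shadowing attenuates the column under the vessel", {
  set.seed(51)
  iuv <- cached_run("iuv_250", {
    illumination_under_vessel(scene_preset("vessel-250um"), tl2x(), 1e5)
  })
  expect_true(all(c("illum_ratio", "intensity_vessel",
                    "intensity_no_vessel") %in% names(iuv)))
  # shadow: strong average attenuation in the first millimeter, yet nonzero
  band <- iuv[iuv$depth_mm > 0.3 & iuv$depth_mm < 1, ]
  expect_lt(mean(band$illum_ratio, na.rm = TRUE), 0.7)
  expect_gt(sum(band$intensity_vessel), 0)
  # ratio recovers with depth as scattered light fills in underneath
  shallow <- mean(iuv$illum_ratio[iuv$depth_mm > 0.3 & iuv$depth_mm < 0.6],
                  na.rm = TRUE)
  deep <- mean(iuv$illum_ratio[iuv$depth_mm > 1.5 & iuv$depth_mm < 2],
               na.rm = TRUE)
  expect_gt(deep, shallow)
  expect_error(illumination_under_vessel(win_scene(), tl2x(), 100),
               "exactly one vessel")
})

test_that("a smaller vessel casts a weaker shadow", {
  iuv250 <- cached_run("iuv_250", {
    set.seed(51)
    illumination_under_vessel(scene_preset("vessel-250um"), tl2x(), 1e5)
  })
  set.seed(52)
  iuv100 <- illumination_under_vessel(scene_preset("vessel-100um"), tl2x(),
                                      1e5)
  band <- function(x) mean(x$illum_ratio[x$depth_mm > 0.3 & x$depth_mm < 1],
                           na.rm = TRUE)
  expect_gt(band(iuv100), band(iuv250))
})

test_that("collection under a vessel recovers laterally off the center line", {
  # same source depth, vessel centered overhead vs shifted 1 mm sideways
  centered <- layered_scene(vessels = list(vessel(0.25)))
  shifted <- layered_scene(vessels = list(vessel(0.25, offset = 1)))
  set.seed(53)
  r_c <- run_collection_from_point(centered, 0.5, tl2x(), 1e5)
  set.seed(53)
  r_s <- run_collection_from_point(shifted, 0.5, tl2x(), 1e5)
  set.seed(53)
  r_n <- run_collection_from_point(win_scene(), 0.5, tl2x(), 1e5)
  expect_lt(r_c$fraction, r_s$fraction)
  expect_lte(r_s$fraction, r_n$fraction * 1.05)
})
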