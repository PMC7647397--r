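test_that("the illumination sampler respects the objective geometry", {
  set.seed(31)
  em <- emit_illumination_photons(tl2x(), 2e4)
  # every direction within the 5.74 degree acceptance cone
  expect_true(all(em$direction[, 3] >= cos(asin(0.1)) - 1e-12))
  expect_true(all(rowSums(em$direction^2) - 1 < 1e-9))
  r2 <- rowSums(em$position^2)
  expect_true(all(r2 <= (11 / 2)^2))
  # uniform over the disc: r^2 is uniform; chi-square over deciles
  h <- table(cut(r2 / max(5.5^2), seq(0, 1, 0.1)))
  expect_gt(stats::chisq.test(h)$p.value, 1e-4)
  # wider cone for NA 0.5
  em5 <- emit_illumination_photons(objective(numerical_aperture = 0.5,
                                             field_of_view_diameter = 11),
                                   1e3)
  expect_true(all(em5$direction[, 3] >= cos(asin(0.5)) - 1e-12))
  expect_gt(max(acos(em5$direction[, 3])), 25 * pi / 180)
})

test_that("depth profiles follow the two normalization conventions", {
  f <- cached_run("illum_win_5e4", {
    set.seed(32)
    run_illumination(win_scene(), tl2x(), 5e4)
  })
  ps <- depth_profile(f, "surface")
  expect_equal(ps$intensity[1], 1)
  pt <- depth_profile(f, "total")
  expect_equal(sum(pt$intensity) * f$pitch, 1)
  expect_true(all(pt$intensity >= 0))
  # beyond the peak the profile declines monotonically (after smoothing)
  sm <- stats::filter(ps$intensity, rep(1 / 9, 9))
  i0 <- which.max(sm)
  late <- sm[seq(i0, 350, by = 25)]
  expect_true(all(diff(late) < 0))
})

test_that("without scattering the profile is pure Beer-Lambert decay", {
  sc <- layered_scene(skull_thickness = 0,
                      grey_matter = list("480" = optical_properties(0.37, 0, 0)))
  set.seed(33)
  f <- run_illumination(sc, tl2x(), 3e4)
  p <- depth_profile(f, "surface")
  idx <- c(50, 100, 200, 300)
  expect_equal(p$intensity[idx],
               exp(-0.37 * (p$depth_mm[idx] - p$depth_mm[1])),
               tolerance = 0.03)
})

test_that("overlying skull randomizes directions and weights light superficial", {
  f_win <- cached_run("illum_win_5e4", {
    set.seed(32)
    run_illumination(win_scene(), tl2x(), 5e4)
  })
  f_sk <- cached_run("illum_skull300_5e4", {
    set.seed(34)
    run_illumination(scene_preset("skull-300um"), tl2x(), 5e4)
  })
  # with skull the profile declines from the surface: maximum in the top bins
  sm <- stats::filter(depth_profile(f_sk, "total")$intensity, rep(1 / 5, 5))
  expect_lte(which.max(sm), 4)
  expect_gt(sm[5], sm[50])
  expect_gt(sm[50], sm[150])
  # fraction of fluence in the top 100 um grows with skull thickness
  top_frac <- function(f) sum(f$fluence[1:10]) / sum(f$fluence)
  set.seed(35)
  f_sk100 <- run_illumination(scene_preset("skull-100um"), tl2x(), 3e4)
  set.seed(36)
  f_sk1000 <- run_illumination(scene_preset("skull-1000um"), tl2x(), 3e4)
  expect_lt(top_frac(f_win), top_frac(f_sk100))
  expect_lt(top_frac(f_sk100), top_frac(f_sk))
  expect_lt(top_frac(f_sk), top_frac(f_sk1000))
})

test_that("the mean propagation angle relaxes with depth and under skull", {
  f <- cached_run("illum_win_5e4", {
    set.seed(32)
    run_illumination(win_scene(), tl2x(), 5e4)
  })
  mc <- mean_cos_profile(f)$mean_cos
  expect_gt(mc[1], 0.4)               # downward-dominated at the surface
  # relaxes over roughly one transport length toward the diffusive
  # asymptote (flux over fluence, about 0.3 in absorbing grey matter)
  expect_gt(mc[1], mc[50])
  expect_gt(mc[50], mc[200])
  expect_lt(mean(mc[250:320]), 0.36)
  f_sk <- cached_run("illum_skull300_5e4", {
    set.seed(34)
    run_illumination(scene_preset("skull-300um"), tl2x(), 5e4)
  })
  # 300 um of bone randomizes propagation before the light reaches tissue:
  # the surface bin starts near the diffusive asymptote instead of the
  # collimated value
  mc_sk <- mean_cos_profile(f_sk)$mean_cos
  expect_lt(mc_sk[1], 0.36)
  expect_lt(mc_sk[1], mc[1] - 0.15)
})
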