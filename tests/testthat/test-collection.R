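test_that("the acceptance gate combines cone angle and field of view", {
  obj <- tl2x()
  up <- c(0, 0, -1)
  expect_true(is_collected(up, c(0, 0), obj))
  # 6.0 degrees is outside the 5.74 degree cone
  d6 <- c(sin(6 * pi / 180), 0, -cos(6 * pi / 180))
  expect_false(is_collected(d6, c(0, 0), obj))
  d5 <- c(sin(5 * pi / 180), 0, -cos(5 * pi / 180))
  expect_true(is_collected(d5, c(0, 0), obj))
  # vignetting: within the cone but outside the field of view
  expect_false(is_collected(up, c(5.6, 0), obj))
  expect_error(is_collected(c(0, 0, 1), c(0, 0), obj), "out of the tissue")
  # front-window gate removes steep off-axis rays when enabled
  off <- c(sin(5 * pi / 180), 0, -cos(5 * pi / 180))
  expect_true(is_collected(off, c(4, 0), obj))
  expect_false(is_collected(off, c(4, 0), obj, front_window_gate = TRUE))
})

test_that("a non-interacting medium collects the analytic cone fraction", {
  set.seed(41)
  r <- run_collection_from_point(vacuum_scene(), 0, tl2x(), 2e5)
  p0 <- (1 - cos(asin(0.1))) / 2
  expect_equal(r$fraction, p0, tolerance = 3 / sqrt(2e5 * p0))
  # no scattering: all collected photons exit at the source axis
  expect_lt(max(r$exit_radius), 1e-6)
  d <- surface_spread_quantiles(r)
  expect_lt(max(d), 1e-6)
})

test_that("spread quantiles agree with a brute-force oracle", {
  set.seed(42)
  x <- runif(400, -2, 2)
  y <- runif(400, -2, 2)
  w <- sample(c(0.25, 0.5, 1), 400, replace = TRUE)
  fake <- structure(list(source_depth = 0.5, n_emitted = 1e4,
                         collected_weight = sum(w),
                         fraction = sum(w) / 1e4,
                         exit_positions = cbind(x = x, y = y),
                         exit_weights = w,
                         exit_radius = sqrt(x^2 + y^2),
                         pitch = 0.01),
                    class = "collection_result")
  for (p in c(0.3, 0.5, 0.95)) {
    q_axis <- surface_spread_quantiles(fake, p)
    oracle <- expand_quantile_oracle(c(abs(x), abs(y)), rep(w, 2), p)
    expect_equal(unname(q_axis) / 2, oracle, tolerance = 0.02)
    q_rad <- surface_spread_quantiles(fake, p, projection = "radial")
    oracle_r <- expand_quantile_oracle(sqrt(x^2 + y^2), w, p)
    expect_equal(unname(q_rad) / 2, oracle_r, tolerance = 0.02)
  }
  # binned estimator stays within one bin of the exact quantile
  qb <- surface_spread_quantiles(fake, 0.5, binned = TRUE)
  expect_lt(abs(qb - surface_spread_quantiles(fake, 0.5)), 0.02)
  expect_error(surface_spread_quantiles(fake, 0.5, min_collected = 1000),
               "collected")
})

test_that("surface spread grows with source depth", {
  res <- cached_run("coll_depths_1e5", {
    lapply(c(0.1, 0.4, 1.0), function(d) {
      set.seed(round(1000 * d))
      run_collection_from_point(win_scene(), d, tl2x(), 1e5)
    })
  })
  sp <- t(vapply(res, surface_spread_quantiles, numeric(2)))
  expect_true(all(diff(sp[, 1]) > 0))
  expect_true(all(diff(sp[, 2]) > 0))
  expect_true(all(vapply(res, `[[`, 0, "fraction") > 0))
  expect_true(all(vapply(res, `[[`, 0, "fraction") < 1))
})

test_that("collection declines from mid-depths to deep cortex", {
  res <- cached_run("coll_depths_1e5", {
    lapply(c(0.1, 0.4, 1.0), function(d) {
      set.seed(round(1000 * d))
      run_collection_from_point(win_scene(), d, tl2x(), 1e5)
    })
  })
  set.seed(1500)
  deep <- run_collection_from_point(win_scene(), 1.5, tl2x(), 1e5)
  expect_gt(res[[2]]$fraction, deep$fraction)
})

test_that("shrinking the field of view vignettes deep sources", {
  set.seed(44)
  wide <- run_collection_from_point(win_scene(), 0.8, tl2x(), 1e5)
  set.seed(44)
  narrow <- run_collection_from_point(
    win_scene(), 0.8,
    objective(numerical_aperture = 0.1, field_of_view_diameter = 4.4), 1e5)
  expect_lt(narrow$fraction, wide$fraction)
  expect_lt(surface_spread_quantiles(narrow)[["d95"]],
            surface_spread_quantiles(wide)[["d95"]])
})

test_that("the radial kernel integrates to the collection efficiency", {
  set.seed(45)
  kern <- collection_kernel(win_scene(), tl2x(), depths = c(0.2, 0.6),
                            n_photons_per_depth = 3e4, r_max = 8)
  set.seed(45)
  eff <- collection_efficiency_vs_depth(win_scene(), tl2x(),
                                        depths = c(0.2, 0.6),
                                        n_photons_per_depth = 3e4)
  expect_equal(rowSums(kern$K), eff$pct_collected / 100, tolerance = 1e-10)
  # the shallow kernel is more concentrated than the deep one
  med_r <- apply(kern$K, 1, function(k)
    kern$r[which(cumsum(k) >= 0.5 * sum(k))[1]])
  expect_lt(med_r[1], med_r[2])
})
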