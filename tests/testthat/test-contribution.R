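flat <- function(z) rep(1, length(z))

test_that("flat inputs attribute fluorescence by layer thickness", {
  w <- fluorescence_by_depth(flat, flat, flat)
  b <- layer_boundaries()
  thickness <- unname(diff(c(0, unclass(b))))
  expect_equal(unname(w$layer_percent), 100 * thickness, tolerance = 1e-9)
  expect_equal(sum(w$layer_percent), 100)
})

test_that("expression confined to one layer gets full attribution", {
  only_l4 <- function(z) as.numeric(z >= 0.30 & z < 0.42)
  w <- fluorescence_by_depth(flat, only_l4, flat)
  expect_equal(unname(w$layer_percent[["L4"]]), 100)
})

test_that("percentages are invariant to input scaling and sum to 100", {
  expr <- synthetic_profile("Cux2-Ai93")
  decay <- function(z) exp(-z)
  w1 <- fluorescence_by_depth(decay, expr, flat)
  w2 <- fluorescence_by_depth(function(z) 17 * decay(z), expr,
                              function(z) 0.003 * flat(z))
  expect_equal(w1$layer_percent, w2$layer_percent, tolerance = 1e-12)
  expect_equal(sum(w1$layer_percent), 100)
})

test_that("laminar presets order layer contributions as expected", {
  decay <- function(z) exp(-z / 2)
  w_cux <- fluorescence_by_depth(decay, synthetic_profile("Cux2-Ai93"), decay)
  w_nts <- fluorescence_by_depth(decay, synthetic_profile("Ntsr1-Ai148"),
                                 decay)
  # superficial line: layer 2/3 dominates, and more layer-1 signal than the
  # deep-layer line
  expect_equal(names(which.max(w_cux$layer_percent)), "L2/3")
  expect_gt(w_cux$layer_percent[["L1"]], w_nts$layer_percent[["L1"]])
  expect_gt(w_nts$layer_percent[["L6"]], w_cux$layer_percent[["L6"]])
})

test_that("dF/F scenarios rescale layers and renormalize", {
  w <- fluorescence_by_depth(flat, synthetic_profile("Slc17a7-Ai93"), flat)
  base <- apply_dff_scenario(w, dff_scenario())
  expect_equal(base, w$layer_percent, tolerance = 1e-12)
  # raising neuropil dF/F favors layer 1 (largest neuropil fraction)
  up <- apply_dff_scenario(w, dff_scenario(neuropil_soma_dff_ratio = 10))
  expect_gt(up[["L1"]], base[["L1"]])
  expect_equal(sum(up), 100)
  # a 10x layer-1 multiplier raises the layer-1 share severalfold
  l1x <- apply_dff_scenario(w, dff_scenario(layer1_multiplier = 10))
  expect_gt(l1x[["L1"]], 3 * base[["L1"]])
  expect_equal(sum(l1x), 100)
})

test_that("greedy contour volumes match the exhaustive voxel oracle", {
  set.seed(61)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    values <- round(runif(k, 0, 5), 2)      # ties likely
    counts <- sample(1:80, k, replace = TRUE)
    fr <- c(0.25, 0.5, 0.75, 0.9, 0.95)
    got <- contour_volumes(values, counts, fr, voxel_volume = 1)
    # oracle: expand to individual voxels, sort descending, accumulate
    vox <- rep(values, counts)
    vox <- sort(vox[vox > 0], decreasing = TRUE)
    cm <- cumsum(vox)
    oracle <- vapply(fr, function(f)
      which(cm >= f * sum(vox) - 1e-9)[1], numeric(1))
    expect_equal(unname(got), oracle)
    expect_true(all(diff(got) >= 0))
  }
})

test_that("source volumes grow with expression depth", {
  # analytic kernel emulating depth-dependent lateral spread
  depths <- seq(0.05, 1, by = 0.05)
  r <- seq(0.005, 3, by = 0.01)
  K <- outer(depths, r, function(z, rr) {
    s <- 0.05 + 0.8 * z
    exp(-rr / s) / s
  })
  K <- K / rowSums(K) * 0.004          # constant efficiency per depth
  kern <- structure(list(depths = depths, r = r, K = K, pitch = 0.01,
                         n_photons_per_depth = NA),
                    class = "collection_kernel")
  decay <- function(z) exp(-z)
  m_sup <- source_volume_map(decay, synthetic_profile("Cux2-Ai93"), kern)
  m_deep <- source_volume_map(decay, synthetic_profile("Ntsr1-Ai148"), kern)
  expect_true(all(diff(m_sup$contour_volumes) >= 0))
  expect_gt(m_deep$contour_volumes[["V95"]], m_sup$contour_volumes[["V95"]])
  # expression concentrated at one depth with a near-delta kernel collapses
  # every contour onto a handful of voxels
  K0 <- matrix(0, length(depths), length(r)); K0[, 1] <- 0.004
  kern0 <- structure(list(depths = depths, r = r, K = K0, pitch = 0.01,
                          n_photons_per_depth = NA),
                     class = "collection_kernel")
  spike <- function(z) as.numeric(abs(z - 0.5) < 0.006)
  m0 <- source_volume_map(flat, spike, kern0, pitch = 0.01)
  expect_lt(m0$contour_volumes[["V95"]] / 0.01^3, 10)
})
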