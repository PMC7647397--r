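test_that("pure-absorption packets terminate at exponential depths", {
  # mu_s = 0: every packet deposits at its first interaction, whose depth
  # is exponential with the absorption length
  sc <- layered_scene(skull_thickness = 0,
                      grey_matter = list("480" = optical_properties(2, 0, 0)))
  set.seed(21)
  n <- 2e4
  p <- propagate_packets(sc, matrix(rep(c(0, 0, 0), each = n), n, 3),
                         matrix(rep(c(0, 0, 1), each = n), n, 3))
  term <- p$terminals
  absorbed <- term[term$status == "absorbed", ]
  expect_gt(nrow(absorbed), 0.99 * n)        # exp(-8) leaks out the bottom
  expect_lt(abs(mean(absorbed$z) - 0.5), 4 * 0.5 / sqrt(n))
  # survival fraction to 1 mm
  expect_lt(abs(mean(absorbed$z > 1) - exp(-2)), 4 * sqrt(exp(-2) / n))
})

test_that("weight accounting closes and packets never gain weight", {
  set.seed(22)
  f <- run_illumination(win_scene(), tl2x(), 2e4)
  a <- f$accounting
  resid <- a[["launched"]] - a[["deposited"]] - a[["exited_top"]] -
    a[["exited_lateral"]] - a[["exited_bottom"]] - a[["roulette_net"]] -
    a[["cap_killed"]]
  expect_lt(abs(resid) / a[["launched"]], 1e-3)
  set.seed(23)
  p <- propagate_packets(win_scene(), c(0, 0, 0.2), c(0, 0, 1))
  expect_lte(p$terminals$w, 1)
})

test_that("identical seeds reproduce recorder outputs bit for bit", {
  set.seed(99)
  f1 <- run_illumination(win_scene(), tl2x(), 5e3)
  set.seed(99)
  f2 <- run_illumination(win_scene(), tl2x(), 5e3)
  expect_identical(f1$fluence, f2$fluence)
  expect_identical(f1$fluence_rz, f2$fluence_rz)
  expect_identical(f1$accounting, f2$accounting)
  set.seed(77)
  r1 <- run_collection_from_point(win_scene(), 0.3, tl2x(), 5e3)
  set.seed(77)
  r2 <- run_collection_from_point(win_scene(), 0.3, tl2x(), 5e3)
  expect_identical(r1$exit_positions, r2$exit_positions)
})

test_that("the step cap kills pathological packets with a warning", {
  sc <- layered_scene(skull_thickness = 0,
                      grey_matter = list("480" = optical_properties(0, 50, 0)))
  set.seed(24)
  expect_warning(
    p <- propagate_packets(sc, c(0, 0, 2), c(0, 0, 1), max_steps = 20),
    "step cap")
  expect_gt(p$n_step_cap, 0)
})

test_that("packets entering a vessel are absorbed outright", {
  vs <- scene_preset("vessel-250um")
  set.seed(25)
  p <- propagate_packets(vs, c(0, 0, 0.9), c(0, 0, -1), wavelength = "480")
  expect_equal(as.character(p$terminals$status), "absorbed")
  # deposited weight equals the full launched weight
  expect_equal(p$accounting[["deposited"]], 1)
})
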