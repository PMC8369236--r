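test_that("peak finding refines to sub-voxel accuracy and breaks ties by depth", {
  g <- phantom_grid(extent = c(2, 2, 4), voxel = c(0.1, 0.1, 0.1))
  v <- array(0, dim = g$n)
  v[10, 10, 20] <- 1
  d <- braggshift:::.new_dose_grid(v, g, list(entry_point = c(0, 0)))
  pk <- find_bragg_peak(d)
  expect_equal(unname(pk$position),
               c(-1 + 9.5 * 0.1, -1 + 9.5 * 0.1, 19.5 * 0.1))

  # off-center Gaussian: refined position within 0.1 voxel of the truth
  truth <- c(0.03, -0.02, 5.04)
  gg <- make_gaussian_grid(sigma = c(0.4, 0.5, 0.4), center = truth)
  pk <- find_bragg_peak(gg)
  expect_lt(max(abs(pk$position - truth)), 0.012)

  # tie broken toward the smaller depth
  v2 <- array(0, dim = g$n)
  v2[10, 10, 30] <- 1; v2[10, 10, 5] <- 1
  d2 <- braggshift:::.new_dose_grid(v2, g, list(entry_point = c(0, 0)))
  expect_equal(find_bragg_peak(d2)$index[3], 5L)
  expect_error(find_bragg_peak(braggshift:::.new_dose_grid(
    array(0, dim = g$n), g, list())), "zero")
})

test_that("pencil-mode field-free peak sits at the range", {
  d <- simulate_dose_grid(beam_spec(100), field_spec(0),
                          phantom_grid(extent = c(6, 6, 10),
                                       voxel = c(0.1, 0.1, 0.1)),
                          mode = "pencil", histories = 1e4)
  pk <- find_bragg_peak(d)
  # straggling pulls the peak slightly upstream of the CSDA range
  expect_equal(unname(pk$position["z"]), range_from_energy(100),
               tolerance = 0.1 / 7.7)
  dd <- depth_dose_curve(d, "surface")
  expect_lt(abs(dd$z_cm[which.max(dd$dose)] - pk$position["z"]), 0.1)
  expect_gt(max(dd$dose), 2) # peak-to-entrance ratio of a Bragg curve
})

test_that("shift measurement recovers the worked-example displacements", {
  g <- phantom_grid(extent = c(12, 6, 17), voxel = c(0.05, 0.05, 0.1))
  for (e in c(141, 148)) {
    db <- simulate_dose_grid(beam_spec(e), field_spec(3), g,
                             mode = "pencil", histories = 1e4)
    d0 <- simulate_dose_grid(beam_spec(e), field_spec(0), g,
                             mode = "pencil", histories = 1e4)
    ms <- measure_shifts(db, d0)
    if (e == 141) expect_equal(ms$wd, 2.0, tolerance = 0.05)
    if (e == 148) expect_equal(ms$ddd, 0.24, tolerance = 0.05)
    expect_gt(ms$angle_def, 7); expect_lt(ms$angle_def, 10)
    # identical grids give null shifts
    null <- measure_shifts(d0, d0)
    expect_equal(null$wd, 0); expect_equal(null$ddd, 0)
    expect_equal(null$angle_def, 0)
  }
})

test_that("incompatible grid pairs are rejected", {
  g <- phantom_grid(extent = c(6, 6, 10), voxel = c(0.1, 0.1, 0.1))
  d1 <- simulate_dose_grid(beam_spec(100), field_spec(3), g,
                           mode = "pencil", histories = 10)
  d2 <- simulate_dose_grid(beam_spec(110), field_spec(0), g,
                           mode = "pencil", histories = 10)
  expect_error(measure_shifts(d1, d2), "incompatible")
  d3 <- simulate_dose_grid(beam_spec(100), field_spec(1), g,
                           mode = "pencil", histories = 10)
  expect_error(measure_shifts(d1, d3), "incompatible")
})

test_that("depth-dose normalization behaves on uniform and zero grids", {
  g <- phantom_grid(extent = c(2, 2, 3), voxel = c(0.5, 0.5, 0.5))
  u <- braggshift:::.new_dose_grid(array(1, dim = g$n), g, list())
  dd <- depth_dose_curve(u, "surface")
  expect_equal(dd$dose, rep(1, g$n[3]))
  expect_error(depth_dose_curve(
    braggshift:::.new_dose_grid(array(0, dim = g$n), g, list()), "surface"),
    "zero entrance")
})

test_that("peak slab is normalized, centered and boundary-checked", {
  gg <- make_gaussian_grid(sigma = c(0.5, 0.5, 0.4), center = c(0, 0, 5))
  slab <- planar_at_peak(gg)
  expect_equal(max(slab$values), 1)
  im <- which(slab$values == 1, arr.ind = TRUE)
  expect_lt(abs(slab$u[im[1]]), 0.06)
  expect_lt(abs(slab$v[im[2]]), 0.06)
  # slab maximum is the grid maximum
  expect_equal(max(slab$values) * find_bragg_peak(gg)$value, max(gg$values))
  edge <- make_gaussian_grid(sigma = c(0.5, 0.5, 0.4), center = c(0, 0, 9.98))
  expect_warning(planar_at_peak(edge), "boundary")
})
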