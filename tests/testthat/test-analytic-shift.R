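test_that("shifts vanish without field and scale as B and B^2", {
  e <- c(70, 141, 270)
  expect_equal(lateral_shift(e, 0), rep(0, 3))
  expect_equal(depth_retraction(e, 0), rep(0, 3))
  # WD linear in B, dDD quadratic in B (exact)
  expect_equal(lateral_shift(e, 3), 2 * lateral_shift(e, 1.5),
               tolerance = 1e-14)
  expect_equal(depth_retraction(e, 3), 4 * depth_retraction(e, 1.5),
               tolerance = 1e-14)
  expect_error(lateral_shift(-1, 3), "non-negative")
  expect_error(depth_retraction(141, -1), "non-negative")
})

test_that("closed-form WD agrees with the curvature double-integral oracle", {
  # independent midpoint quadrature of WD = int int kappa dz' dz
  expect_equal(lateral_shift(170, 3), 3.5135, tolerance = 1e-4)
  expect_equal(lateral_shift(170, 3, relativistic = TRUE), 3.3941,
               tolerance = 1e-4)
  for (e in c(70, 90, 110, 130, 150, 170, 200, 270)) {
    for (b in c(0.5, 1.5, 3)) {
      expect_equal(lateral_shift(e, b), wd_quadrature_oracle(e, b),
                   tolerance = 5e-3)
    }
  }
})

test_that("closed-form dDD agrees with the theta^2 path-length oracle", {
  for (e in c(70, 90, 110, 130, 150, 170, 200, 270)) {
    for (b in c(0.5, 1.5, 3)) {
      expect_equal(depth_retraction(e, b), ddd_quadrature_oracle(e, b),
                   tolerance = 5e-3)
    }
  }
})

test_that("dDD reproduces the published benchmark cells to printed rounding", {
  mm <- function(e, b) 10 * depth_retraction(e, b)
  expect_equal(mm(100, 3.0), 0.5, tolerance = 0.15 / 0.5)
  expect_equal(mm(120, 3.0), 1.0, tolerance = 0.15 / 1.0)
  expect_equal(mm(130, 3.0), 1.4, tolerance = 0.15 / 1.4)
  expect_equal(mm(150, 2.5), 1.8, tolerance = 0.15 / 1.8)
  expect_equal(mm(170, 3.0), 4.4, tolerance = 0.15 / 4.4)
})

test_that("energy selection inverts the forward model to machine precision", {
  # published worked example: WD = 2.0 cm or dDD = 0.25 cm at 3 T
  expect_equal(round(energy_for_lateral_shift(2.0, 3)), 141)
  expect_equal(round(energy_for_depth_retraction(0.25, 3)), 148)
  expect_equal(round(energy_for_depth_retraction(0.44, 3)), 169)
  expect_identical(energy_for_lateral_shift(0, 3), 0)
  expect_identical(energy_for_depth_retraction(0, 3), 0)

  set.seed(4)
  e <- runif(100, 70, 270)
  b <- runif(100, 0.5, 3)
  expect_equal(energy_for_lateral_shift(lateral_shift(e, b), b), e,
               tolerance = 1e-9)
  expect_equal(energy_for_depth_retraction(depth_retraction(e, b), b), e,
               tolerance = 1e-9)
  expect_error(energy_for_lateral_shift(2, 0), "zero field")
  expect_error(energy_for_depth_retraction(0.25, 0), "zero field")
})

test_that("relativistic correction is below one and decreasing in energy", {
  e <- seq(70, 270, by = 10)
  corr <- lateral_shift(e, 3, relativistic = TRUE) / lateral_shift(e, 3)
  expect_true(all(corr < 1))
  expect_true(all(diff(corr) < 0))
})

test_that("deflection angle follows the retracted-range geometry", {
  expect_equal(deflection_angle(0, 0.2, 141), 0)
  expect_equal(deflection_angle(2.0, 0.20, 141),
               atan2(2.0, 2.43e-3 * 141^1.75 - 0.20) * 180 / pi)
  expect_equal(deflection_angle(2.0, 0.20, 141), 8.2, tolerance = 0.01)
  expect_gt(deflection_angle(4.0, 0.20, 141),
            deflection_angle(2.0, 0.20, 141))
  expect_error(deflection_angle(2, 30, 141), "range")
})

test_that("prediction table covers the energy/field grid consistently", {
  energies <- c(70, 80, 90, 100, 110, 120, 130, 140, 150, 160, 170, 200, 270)
  fields <- c(0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0)
  tab <- prediction_table(energies, fields)
  expect_equal(nrow(tab), 91)
  expect_true(all(tab$wd_cm[tab$field_t == 0] == 0))
  expect_true(all(tab$ddd_cm[tab$field_t == 0] == 0))
  # energy-major ordering
  expect_equal(tab$energy_mev, rep(energies, each = length(fields)))
  row <- tab[tab$energy_mev == 170 & tab$field_t == 3, ]
  expect_identical(row$wd_cm, lateral_shift(170, 3))
  expect_identical(row$ddd_cm, depth_retraction(170, 3))
  expect_error(prediction_table(numeric(), fields), "non-empty")
})
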