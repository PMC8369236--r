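test_that("1D Gaussian fit recovers exact parameters and flags skew", {
  x <- seq(-3, 3, by = 0.05)
  y <- 2.5 * exp(-(x - 0.2)^2 / (2 * 0.5^2))
  f <- fit_gaussian_1d(x, y)
  expect_equal(f$sigma, 0.5, tolerance = 1e-6)
  expect_equal(f$mean, 0.2, tolerance = 1e-6)
  expect_equal(f$amplitude, 2.5, tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-6)
  expect_equal(f$halfwidth_asymmetry, 0, tolerance = 1e-6)

  # right-skewed profile: positive half-width asymmetry
  ys <- 2 * stats::dnorm(x) * stats::pnorm(4 * x)
  fs <- fit_gaussian_1d(x, ys)
  expect_gt(fs$halfwidth_asymmetry, 0)
  expect_error(fit_gaussian_1d(x[1:3], y[1:3]), "5 samples")
  expect_error(fit_gaussian_1d(x, 0 * y), "mass")
})

test_that("sigma ratio is unity for isotropic slabs and tracks the axis ratio", {
  iso <- make_gaussian_slab(0.6, 0.6)
  expect_equal(sigma_ratio(iso)$ratio, 1, tolerance = 0.01)
  ani <- make_gaussian_slab(0.75, 0.5)
  expect_equal(sigma_ratio(ani)$ratio, 1.5, tolerance = 0.02)
})

test_that("isodose contours match Gaussian level-set geometry and nest", {
  slab <- make_gaussian_slab(0.5, 0.5)
  cont <- isodose_contour(slab, 0.5)
  r <- sqrt(rowSums(cont^2))
  expect_equal(mean(r), 0.5 * sqrt(2 * log(2)), tolerance = 0.05 / 0.58)
  expect_lt(max(r) - min(r), 0.05)

  # strict nesting of 0.8 / 0.5 / 0.2 contours
  radii <- vapply(c(0.8, 0.5, 0.2), function(lv) {
    mean(sqrt(rowSums(isodose_contour(slab, lv)^2)))
  }, numeric(1))
  expect_true(all(diff(radii) > 0))

  # elliptical level sets keep the sigma ratio
  ell <- isodose_contour(make_gaussian_slab(0.8, 0.4), 0.5)
  expect_equal(diff(range(ell[, 1])) / diff(range(ell[, 2])), 2,
               tolerance = 0.02)
  expect_error(isodose_contour(slab, 1.2), "level")
  # a contour cut by the slab edge is rejected
  wide <- make_gaussian_slab(4, 1, extent = 6)
  expect_error(isodose_contour(wide, 0.5), "open")
})

test_that("IC/EC circle fit gives exact radii for circles and ellipses", {
  circ <- make_ellipse_contour(3, 3)
  fc <- fit_ic_ec(circ)
  expect_equal(fc$r_ic, 3, tolerance = 1e-3)
  expect_equal(fc$radius_diff, 0, tolerance = 1e-3)

  ell <- fit_ic_ec(make_ellipse_contour(4, 2))
  expect_equal(ell$r_ic, 2, tolerance = 1e-3)
  expect_equal(ell$r_ec, 4, tolerance = 1e-3)
  expect_equal(unname(ell$center), c(0, 0), tolerance = 1e-2)

  # rotation and translation invariance
  rot <- fit_ic_ec(make_ellipse_contour(4, 2, angle_deg = 30,
                                        center = c(1.3, -0.7)))
  expect_equal(rot$r_ic, ell$r_ic, tolerance = 1e-3)
  expect_equal(rot$r_ec, ell$r_ec, tolerance = 1e-3)
  expect_error(fit_ic_ec(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("skewness-by-level pairs matched slabs and sorts by radius", {
  slab <- make_gaussian_slab(0.7, 0.5)
  sk <- skewness_by_level(slab, slab, levels = c(0.8, 0.5, 0.2))
  expect_equal(sk$radius_diff_field_cm, sk$radius_diff_nofield_cm)
  expect_true(all(diff(sk$standard_radius_cm) > 0))
  expect_equal(sk$level, c(0.8, 0.5, 0.2))
})

test_that("FWHM scan matches closed forms and finds rotated principal axes", {
  iso <- make_gaussian_grid(sigma = c(0.5, 0.5, 0.5), center = c(0, 0, 5))
  sc <- fwhm_scan(iso, angle_step = 5)
  expect_equal(sc$fwhm_max, 2 * sqrt(2 * log(2)) * 0.5, tolerance = 0.01)
  expect_equal(sc$fwhm_min, sc$fwhm_max, tolerance = 0.01)
  expect_identical(sc$fwhm_vertical, sc$profile$fwhm_cm[1])

  ani <- make_gaussian_grid(sigma = c(0.3, 0.6, 0.4), center = c(0, 0, 5),
                            angle_deg = 25)
  sc2 <- fwhm_scan(ani, angle_step = 1)
  expect_equal(sc2$angle_max, 25, tolerance = 1)
  expect_equal(sc2$angle_min, 115, tolerance = 1)
  expect_equal(sc2$fwhm_max, 2 * sqrt(2 * log(2)) * 0.6, tolerance = 0.01)
  expect_lte(sc2$fwhm_min, sc2$fwhm_vertical)
  expect_gte(sc2$fwhm_max, sc2$fwhm_vertical)
  expect_error(fwhm_scan(iso, angle_step = 30), "angle_step")
})
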