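small_grid <- function() phantom_grid(extent = c(8, 6, 10),
                                      voxel = c(0.1, 0.1, 0.1))

test_that("Highland angle decreases with energy and vanishes with the step", {
  expect_lt(scattering_sigma_increment(200, 0.05),
            scattering_sigma_increment(70, 0.05))
  expect_lt(scattering_sigma_increment(150, 1e-6),
            scattering_sigma_increment(150, 0.05))
  expect_gt(scattering_sigma_increment(150, 0.05), 0)
  expect_error(scattering_sigma_increment(0.05, 0.05), "cutoff")
  # accumulated lateral spread at the peak is a few mm at 150 MeV
  m <- stopping_model()
  step <- 0.05
  r0 <- range_from_energy(150, m)
  s <- seq(step / 2, r0 - 0.2, by = step)
  th2 <- scattering_sigma_increment(energy_from_range(r0 - s, m), step, m)^2
  sig <- sqrt(sum(th2 * (r0 - s)^2))
  expect_gt(sig, 0.2)
  expect_lt(sig, 1.0)
})

test_that("mc mode conserves energy, hits the range and keeps the spot width", {
  d <- simulate_dose_grid(beam_spec(100), field_spec(0), small_grid(),
                          mode = "mc", histories = 2e4, seed = 3)
  expect_lte(sum(d$values), 2e4 * 100)
  expect_gt(sum(d$values), 0.95 * 2e4 * 100)
  dd <- depth_dose_curve(d, "max")
  expect_equal(dd$z_cm[which.max(dd$dose)], range_from_energy(100),
               tolerance = 0.15 / 7.7)
  # entrance-slab lateral profile keeps the 5 mm spot sigma within 3%
  f <- fit_gaussian_1d(grid_centers_of(d, 1), rowSums(d$values[, , 2]))
  expect_equal(f$sigma, 0.5, tolerance = 0.03)
})

test_that("mc mode is reproducible from its seed and requires one", {
  a <- simulate_dose_grid(beam_spec(100), field_spec(1.5), small_grid(),
                          mode = "mc", histories = 3e3, seed = 99)
  b <- simulate_dose_grid(beam_spec(100), field_spec(1.5), small_grid(),
                          mode = "mc", histories = 3e3, seed = 99)
  expect_identical(a$values, b$values)
  c <- simulate_dose_grid(beam_spec(100), field_spec(1.5), small_grid(),
                          mode = "mc", histories = 3e3, seed = 100)
  expect_false(identical(a$values, c$values))
  expect_error(simulate_dose_grid(beam_spec(100), field_spec(0),
                                  small_grid(), mode = "mc",
                                  histories = 10), "seed")
})

test_that("pencil and mc modes agree at the Bragg peak", {
  g <- small_grid()
  dm <- simulate_dose_grid(beam_spec(100), field_spec(3), g, mode = "mc",
                           histories = 3e5, seed = 21)
  dp <- simulate_dose_grid(beam_spec(100), field_spec(3), g,
                           mode = "pencil", histories = 3e5)
  pm <- find_bragg_peak(dm)$position
  pp <- find_bragg_peak(dp)$position
  expect_lt(abs(pm["z"] - pp["z"]), 0.1) # one voxel
  expect_lt(abs(pm["x"] - pp["x"]), 0.1)
  sm <- sigma_ratio(planar_at_peak(dm))
  sp <- sigma_ratio(planar_at_peak(dp))
  expect_equal(sm$fit_u$sigma, sp$fit_u$sigma, tolerance = 0.05)
  expect_equal(sm$fit_v$sigma, sp$fit_v$sigma, tolerance = 0.05)
})

test_that("uncertainty estimator follows the sampling laws", {
  g <- phantom_grid(extent = c(2, 2, 2), voxel = c(0.5, 0.5, 0.5))
  mk <- function(lambda) {
    v <- array(stats::rpois(prod(g$n), lambda), dim = g$n)
    braggshift:::.new_dose_grid(v, g, list(mode = "synthetic",
                                           entry_point = c(0, 0)))
  }
  # identical batches: zero error
  one <- mk(100)
  est <- estimate_uncertainty(list(one, one, one))
  expect_equal(max(est$mean$uncertainty), 0)
  expect_error(estimate_uncertainty(list(one)), "two batches")

  set.seed(8)
  med_rel <- function(nb, lambda) {
    est <- estimate_uncertainty(lapply(seq_len(nb), function(i) mk(lambda)))
    stats::median(est$mean$uncertainty, na.rm = TRUE)
  }
  # error drops as 1/sqrt(batches): 16 vs 4 batches gives a factor ~2
  r <- med_rel(4, 400) / med_rel(16, 400)
  expect_equal(r, 2, tolerance = 0.25)
  # doubling the count (histories) per batch gives a factor ~sqrt(2)
  r2 <- med_rel(8, 200) / med_rel(8, 400)
  expect_equal(r2, sqrt(2), tolerance = 0.2)
})
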