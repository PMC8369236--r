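#' Bragg-Kleeman stopping model for protons in water
#'
#' Bundles the constants of the range-energy power law `R = alpha * E^p`
#' (Bragg-Kleeman rule) together with the proton rest energy, charge number
#' and the transport cutoff energy. Every range, stopping-power, momentum and
#' curvature primitive in the package, as well as the closed-form shift model
#' and the transport simulator, takes one of these objects.
#'
#' Defaults are the water values commonly used in proton dosimetry:
#' `alpha = 2.43e-3` cm MeV^-p and `p = 1.75`, proton rest energy
#' `mc^2 = 938.272` MeV, charge `q = 1`, transport cutoff 0.1 MeV.
#'
#' @param alpha Range coefficient, cm MeV^-p. Must be positive.
#' @param p Range exponent, dimensionless, in (1, 2).
#' @param rest_energy Proton rest energy `mc^2`, MeV.
#' @param charge_number Charge in elementary charges (1 for protons).
#' @param cutoff_energy Transport stop energy, MeV (residual energy below this
#'   is deposited locally by the simulator).
#' @return An object of class `stopping_model`.
#' @examples
#' m <- stopping_model()
#' range_from_energy(150, m)
#' @export
stopping_model <- function(alpha = 2.43e-3, p = 1.75, rest_energy = 938.272,
                           charge_number = 1, cutoff_energy = 0.1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(rest_energy), length(rest_energy) == 1L,
            is.numeric(charge_number), length(charge_number) == 1L,
            is.numeric(cutoff_energy), length(cutoff_energy) == 1L)
  if (alpha <= 0) stop("'alpha' must be positive")
  if (p <= 1 || p >= 2) stop("'p' must lie in (1, 2)")
  if (rest_energy <= 0) stop("'rest_energy' must be positive")
  if (charge_number != 1) stop("only protons (charge_number = 1) are supported")
  if (cutoff_energy < 0) stop("'cutoff_energy' must be non-negative")
  structure(
    list(alpha = alpha, p = p, rest_energy = rest_energy,
         charge_number = charge_number, cutoff_energy = cutoff_energy),
    class = "stopping_model"
  )
}

#' @export
print.stopping_model <- function(x, ...) {
  cat("Bragg-Kleeman stopping model (water)\n")
  cat(sprintf("  alpha = %g cm MeV^-p, p = %g\n", x$alpha, x$p))
  cat(sprintf("  rest energy mc^2 = %g MeV, charge q = %d\n",
              x$rest_energy, as.integer(x$charge_number)))
  cat(sprintf("  transport cutoff = %g MeV\n", x$cutoff_energy))
  invisible(x)
}

#' Physical constants used for unit conversion
#'
#' The magnetic-rigidity constant converts momentum to curvature
#' (`pc[GeV] = 0.29979 * B[T] * r[m]`), and `fwhm_factor` is the Gaussian
#' sigma-to-FWHM factor `2 sqrt(2 ln 2)`.
#'
#' @return A list with elements `rigidity_constant` (GeV per Tesla metre) and
#'   `fwhm_factor` (dimensionless).
#' @export
physics_constants <- function() {
  list(rigidity_constant = 0.29979, fwhm_factor = 2 * sqrt(2 * log(2)))
}

.assert_model <- function(model) {
  if (!inherits(model, "stopping_model"))
    stop("'model' must be a stopping_model object")
  model
}

#' Range in water from kinetic energy
#'
#' Evaluates the Bragg-Kleeman rule `R = alpha * E^p`.
#'
#' @param energy Kinetic energy, MeV (vectorized, non-negative).
#' @param model A [stopping_model()].
#' @return Continuous-slowing-down range in water, cm.
#' @examples
#' range_from_energy(100) # about 7.7 cm
#' @export
range_from_energy <- function(energy, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(energy)) || any(energy < 0))
    stop("'energy' must be finite and non-negative")
  model$alpha * energy^model$p
}

#' Kinetic energy from range in water
#'
#' Exact inverse of [range_from_energy()]: `E = (R / alpha)^(1/p)`.
#'
#' @param range Range in water, cm (vectorized, non-negative).
#' @inheritParams range_from_energy
#' @return Kinetic energy, MeV.
#' @export
energy_from_range <- function(range, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(range)) || any(range < 0))
    stop("'range' must be finite and non-negative")
  (range / model$alpha)^(1 / model$p)
}

#' Stopping power consistent with the range law
#'
#' The linear stopping power implied by differentiating the Bragg-Kleeman
#' rule: `S(E) = E^(1-p) / (alpha * p)`, so that the integral of `1/S` from 0
#' to `E` reproduces `alpha * E^p` exactly.
#'
#' @param energy Kinetic energy, MeV (vectorized, positive).
#' @inheritParams range_from_energy
#' @return Stopping power, MeV/cm.
#' @export
stopping_power <- function(energy, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("'energy' must be finite and positive")
  energy^(1 - model$p) / (model$alpha * model$p)
}

#' Proton momentum (as pc, MeV)
#'
#' Relativistic momentum `pc = sqrt(E^2 + 2 mc^2 E)` or its non-relativistic
#' limit `pc = sqrt(2 mc^2 E)`.
#'
#' @param energy Kinetic energy, MeV (vectorized, non-negative).
#' @param relativistic Use the relativistic form (default) or the
#'   non-relativistic limit.
#' @inheritParams range_from_energy
#' @return Momentum times c, MeV.
#' @export
momentum <- function(energy, relativistic = TRUE, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(energy)) || any(energy < 0))
    stop("'energy' must be finite and non-negative")
  if (relativistic) sqrt(energy^2 + 2 * model$rest_energy * energy)
  else sqrt(2 * model$rest_energy * energy)
}

#' Track curvature in a uniform magnetic field
#'
#' Curvature `kappa = qB / (p c)` of the proton trajectory projected onto the
#' plane perpendicular to the field, expressed in 1/cm for `B` in Tesla and
#' momentum in MeV. The radius of curvature is `1/kappa`.
#'
#' @param energy Kinetic energy, MeV (vectorized, positive when `field > 0`).
#' @param field Magnetic field strength, Tesla (non-negative).
#' @inheritParams momentum
#' @return Curvature, 1/cm (0 where `field == 0`).
#' @export
curvature <- function(energy, field, relativistic = TRUE,
                      model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(field)) || any(field < 0))
    stop("'field' must be finite and non-negative")
  if (any(energy <= 0 & field > 0))
    stop("curvature is unbounded at zero energy in a non-zero field")
  k <- physics_constants()$rigidity_constant * 10 * model$charge_number *
    field / momentum(pmax(energy, .Machine$double.xmin), relativistic, model)
  k[rep_len(field == 0, length(k))] <- 0
  k
}

# Straggling sigma of the range distribution (cm) for a CSDA range R (cm).
# Standard water parameterization used by the transport simulator.
sigma_range_straggling <- function(range) 0.012 * range^0.935
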