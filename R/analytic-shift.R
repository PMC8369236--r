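# Closed-form model of Bragg-peak displacement in a uniform magnetic field.
#
# A proton entering water along +z, perpendicular to a uniform field, follows
# a curving CSDA track. To leading (small-angle) order the lateral peak shift
# WD and the depth retraction dDD have closed forms in the Bragg-Kleeman
# parameters. For general exponent p,
#   WD  = g1(p) * (C q B / sqrt(2 mc^2)) * alpha^2 * E^(2p - 1/2)
#   dDD = (C q B)^2 / (2 mc^2) * alpha^3 * E^(3p - 1) * 2 p^2 / ((4p-1)(3p-1))
# with C the rigidity conversion (curvature in 1/cm per Tesla per MeV of
# momentum) and g1(p) = [1/(1 - 1/(2p))] * [1 - 1/(2 - 1/(2p))], which equals
# 7/12 at p = 1.75 so the classical 7/12 * qB/sqrt(2m) * alpha^2 * E^3 form is
# recovered. Both formulas are exact evaluations of the small-angle curvature
# integrals WD = int int kappa dz' dz and dDD = (1/2) int theta(z)^2 dz over
# the non-relativistic CSDA depth-energy profile.

# g1(p): lateral-shift shape factor; 7/12 at p = 1.75
.g1 <- function(p) {
  a <- 1 / (2 * p)
  (1 / (1 - a)) * (1 - 1 / (2 - a))
}

# curvature prefactor C*q/sqrt(2 mc^2): kappa(E) = .cb(model) * B / sqrt(E)
.cb <- function(model) {
  physics_constants()$rigidity_constant * 10 * model$charge_number /
    sqrt(2 * model$rest_energy)
}

# dDD prefactor K(B) such that dDD = K * E^(3p-1)
.ddd_prefactor <- function(field, model) {
  p <- model$p
  (physics_constants()$rigidity_constant * 10 * model$charge_number * field)^2 /
    (2 * model$rest_energy) * model$alpha^3 *
    2 * p^2 / ((4 * p - 1) * (3 * p - 1))
}

#' Lateral Bragg-peak shift WD
#'
#' Closed-form lateral displacement (cm) of the Bragg-peak position,
#' perpendicular to both the beam and the field, for a proton of kinetic
#' energy `energy` (MeV) in a uniform field of strength `field` (Tesla).
#' With `relativistic = TRUE` the non-relativistic result is multiplied by
#' the first-order momentum correction `1 - (3/8) E / (2 mc^2)`.
#'
#' @param energy Kinetic energy, MeV (vectorized, non-negative).
#' @param field Magnetic field strength, Tesla (vectorized, non-negative).
#' @param relativistic Apply the first-order relativistic correction factor.
#' @param model A [stopping_model()].
#' @return WD in cm; zero where `field == 0`; strictly increasing in both
#'   arguments.
#' @examples
#' lateral_shift(141, 3) # about 2.0 cm
#' @export
lateral_shift <- function(energy, field, relativistic = FALSE,
                          model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(energy)) || any(energy < 0))
    stop("'energy' must be finite and non-negative")
  if (any(!is.finite(field)) || any(field < 0))
    stop("'field' must be finite and non-negative")
  wd <- .g1(model$p) * .cb(model) * field * model$alpha^2 *
    energy^(2 * model$p - 0.5)
  if (relativistic)
    wd <- wd * (1 - (3 / 8) * energy / (2 * model$rest_energy))
  wd
}

#' Penetration-depth retraction dDD
#'
#' Closed-form shortening (cm) of the Bragg-peak penetration depth along the
#' incident direction caused by path curvature. Scales exactly as the square
#' of the field strength.
#'
#' @inheritParams lateral_shift
#' @return dDD in cm; zero where `field == 0`.
#' @examples
#' depth_retraction(170, 3) * 10 # about 4.5 mm
#' @export
depth_retraction <- function(energy, field, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(energy)) || any(energy < 0))
    stop("'energy' must be finite and non-negative")
  if (any(!is.finite(field)) || any(field < 0))
    stop("'field' must be finite and non-negative")
  .ddd_prefactor(field, model) * energy^(3 * model$p - 1)
}

#' Incident energy for a required lateral shift
#'
#' Exact algebraic inverse of the non-relativistic [lateral_shift()]:
#' given the lateral Bragg-peak shift needed to clear an organ at risk and
#' the scanner field strength, returns the proton energy that produces it.
#'
#' @param wd Required lateral shift, cm (vectorized, non-negative).
#' @param field Magnetic field strength, Tesla (positive when `wd > 0`).
#' @param model A [stopping_model()].
#' @return Incident kinetic energy, MeV (continuous; round for a nominal
#'   machine energy).
#' @examples
#' round(energy_for_lateral_shift(2.0, 3)) # 141 MeV
#' @export
energy_for_lateral_shift <- function(wd, field, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(wd)) || any(wd < 0))
    stop("'wd' must be finite and non-negative")
  if (any(field <= 0 & wd > 0))
    stop("no energy can produce a non-zero lateral shift at zero field")
  scale <- .g1(model$p) * .cb(model) * field * model$alpha^2
  ifelse(wd == 0, 0, (wd / scale)^(1 / (2 * model$p - 0.5)))
}

#' Incident energy for a required depth retraction
#'
#' Exact algebraic inverse of [depth_retraction()].
#'
#' @param ddd Required depth retraction, cm (vectorized, non-negative).
#' @inheritParams energy_for_lateral_shift
#' @return Incident kinetic energy, MeV (continuous).
#' @examples
#' round(energy_for_depth_retraction(0.25, 3)) # 148 MeV
#' @export
energy_for_depth_retraction <- function(ddd, field, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(ddd)) || any(ddd < 0))
    stop("'ddd' must be finite and non-negative")
  if (any(field <= 0 & ddd > 0))
    stop("no energy can produce a non-zero depth retraction at zero field")
  ifelse(ddd == 0, 0,
         (ddd / .ddd_prefactor(field, model))^(1 / (3 * model$p - 1)))
}

#' Deflection angle of the Bragg-peak position
#'
#' Angle (degrees) between the incident beam axis and the line from the entry
#' point to the shifted Bragg-peak position, computed as
#' `atan(WD / (R - dDD))` with `R` the field-free range: the retracted depth
#' is the adjacent side of the triangle.
#'
#' @param wd Lateral shift, cm (non-negative).
#' @param ddd Depth retraction, cm (non-negative, less than the range).
#' @param energy Incident kinetic energy, MeV (positive).
#' @param model A [stopping_model()].
#' @return Deflection angle, degrees; 0 where `wd == 0`.
#' @export
deflection_angle <- function(wd, ddd, energy, model = stopping_model()) {
  .assert_model(model)
  if (any(!is.finite(wd)) || any(wd < 0) || any(!is.finite(ddd)) ||
      any(ddd < 0))
    stop("'wd' and 'ddd' must be finite and non-negative")
  if (any(energy <= 0)) stop("'energy' must be positive")
  r <- range_from_energy(energy, model)
  if (any(ddd >= r)) stop("'ddd' must be smaller than the range")
  atan2(wd, r - ddd) * 180 / pi
}

#' Table of shift predictions over an energy/field grid
#'
#' Evaluates [lateral_shift()], [depth_retraction()] and [deflection_angle()]
#' on the Cartesian product of the supplied energies and field strengths,
#' energy-major (all fields for the first energy, then the second, ...).
#'
#' @param energies Kinetic energies, MeV (non-empty).
#' @param fields Field strengths, Tesla (non-empty).
#' @inheritParams lateral_shift
#' @return A data frame with columns `energy_mev`, `field_t`, `wd_cm`,
#'   `ddd_cm`, `angle_deg`, `relativistic`.
#' @examples
#' head(prediction_table(c(100, 170), c(0, 1.5, 3)))
#' @export
prediction_table <- function(energies, fields, relativistic = FALSE,
                             model = stopping_model()) {
  if (length(energies) == 0L || length(fields) == 0L)
    stop("'energies' and 'fields' must be non-empty")
  grid <- expand.grid(field_t = fields, energy_mev = energies,
                      KEEP.OUT.ATTRS = FALSE)[, c("energy_mev", "field_t")]
  wd <- lateral_shift(grid$energy_mev, grid$field_t, relativistic, model)
  dd <- depth_retraction(grid$energy_mev, grid$field_t, model)
  ang <- deflection_angle(wd, dd, grid$energy_mev, model)
  data.frame(energy_mev = grid$energy_mev, field_t = grid$field_t,
             wd_cm = wd, ddd_cm = dd, angle_deg = ang,
             relativistic = relativistic, row.names = NULL)
}
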