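# Geometry specifications and the deterministic central-track integrator.
#
# Conventions: the beam travels along +z, the magnetic field points along +y,
# so the Lorentz force bends the track in the x-z plane. For a positive
# charge moving along +z in a +y field the force points toward -x; analyses
# report magnitudes, the sign is kept in the provenance.

#' Pencil-beam specification
#'
#' @param energy Kinetic energy, MeV, in (0, 300].
#' @param spot_sigma Initial lateral Gaussian sigma of the spot, cm
#'   (default 0.5 cm, i.e. the 5 mm entrance spot).
#' @param entry_point Entry coordinates `c(x, y)` on the phantom face, cm.
#' @param direction Beam direction (only `c(0, 0, 1)` is supported).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(energy, spot_sigma = 0.5, entry_point = c(0, 0),
                      direction = c(0, 0, 1)) {
  stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy))
  if (energy <= 0 || energy > 300)
    stop("'energy' must lie in (0, 300] MeV")
  if (!is.numeric(spot_sigma) || spot_sigma <= 0)
    stop("'spot_sigma' must be positive")
  stopifnot(length(entry_point) == 2L, is.numeric(entry_point),
            length(direction) == 3L)
  if (max(abs(direction - c(0, 0, 1))) > 1e-12)
    stop("unsupported geometry: the beam must travel along +z")
  structure(list(energy = energy, spot_sigma = spot_sigma,
                 entry_point = as.numeric(entry_point),
                 direction = c(0, 0, 1)),
            class = "beam_spec")
}

#' Uniform magnetic-field specification
#'
#' @param magnitude Field strength, Tesla, in `[0, 3]`.
#' @param direction Field direction (only `c(0, 1, 0)` is supported, which is
#'   perpendicular to the beam).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(magnitude, direction = c(0, 1, 0)) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L,
            is.finite(magnitude))
  if (magnitude < 0 || magnitude > 3)
    stop("'magnitude' must lie in [0, 3] Tesla")
  stopifnot(length(direction) == 3L)
  if (max(abs(direction - c(0, 1, 0))) > 1e-12)
    stop("unsupported geometry: the field must point along +y")
  structure(list(magnitude = magnitude, direction = c(0, 1, 0),
                 uniform = TRUE),
            class = "field_spec")
}

#' Voxelized water-phantom grid
#'
#' Defines the scoring grid: a rectangular water phantom entered by the beam
#' at `z = 0`. The lateral axes are centred on the beam axis
#' (`x, y` in `[-extent/2, extent/2]`), depth runs over `z` in `[0, extent]`.
#'
#' @param extent Phantom size `c(x, y, z)`, cm (default 20 x 20 x 35 cm).
#' @param voxel Voxel size `c(x, y, z)`, cm (default 0.5 x 0.5 x 1 mm).
#' @return An object of class `phantom_grid` with the voxel counts, spacings
#'   and the grid origin (lower corner).
#' @export
phantom_grid <- function(extent = c(20, 20, 35), voxel = c(0.05, 0.05, 0.1)) {
  stopifnot(length(extent) == 3L, length(voxel) == 3L,
            all(extent > 0), all(voxel > 0), all(voxel <= extent))
  n <- as.integer(round(extent / voxel))
  structure(list(n = n, voxel = as.numeric(voxel),
                 origin = c(-extent[1] / 2, -extent[2] / 2, 0),
                 extent = n * voxel),
            class = "phantom_grid")
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("phantom_grid: %d x %d x %d voxels of %g x %g x %g cm\n",
              x$n[1], x$n[2], x$n[3], x$voxel[1], x$voxel[2], x$voxel[3]))
  invisible(x)
}

# Voxel-centre coordinates along axis k (1 = x, 2 = y, 3 = z)
grid_centers <- function(grid, k) {
  grid$origin[k] + (seq_len(grid$n[k]) - 0.5) * grid$voxel[k]
}

#' Integrate the curved central trajectory
#'
#' Deterministic CSDA track of a proton slowing in water inside a uniform
#' field: at each step the residual energy follows the Bragg-Kleeman schedule
#' `E(s) = ((R0 - s)/alpha)^(1/p)` and the direction is rotated through the
#' exact circular arc `kappa(E) * step` in the bending (x-z) plane. The track
#' terminates at the cutoff energy.
#'
#' By default curvature uses the non-relativistic momentum, making the
#' integrator the exact-geometry counterpart of the closed-form shift model;
#' set `relativistic = TRUE` for the relativistic rigidity.
#'
#' @param beam A [beam_spec()].
#' @param field A [field_spec()].
#' @param step Arc-length step, cm (default 0.01).
#' @param relativistic Momentum form used for the curvature.
#' @param model A [stopping_model()].
#' @return An object of class `track_polyline`: a list with `samples` (data
#'   frame of arc length `s`, bending-plane coordinates `x`, `z` and residual
#'   `energy`, all cm/MeV), endpoint summaries `wd` (|lateral offset|, cm),
#'   `depth` (cm), `exit_angle_deg`, and the inputs.
#' @examples
#' tr <- integrate_central_track(beam_spec(141), field_spec(3))
#' tr$wd # about 2 cm
#' @export
integrate_central_track <- function(beam, field, step = 0.01,
                                    relativistic = FALSE,
                                    model = stopping_model()) {
  stopifnot(inherits(beam, "beam_spec"), inherits(field, "field_spec"))
  .assert_model(model)
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive")
  if (abs(sum(beam$direction * field$direction)) > 1e-9)
    stop("unsupported geometry: beam and field must be perpendicular")

  r0 <- range_from_energy(beam$energy, model)
  r_stop <- range_from_energy(model$cutoff_energy, model)
  n <- max(1L, floor((r0 - r_stop) / step))
  s_mid <- (seq_len(n) - 0.5) * step
  e_mid <- energy_from_range(r0 - s_mid, model)
  kap <- curvature(e_mid, field$magnitude, relativistic, model)
  # bending sign: q v x B with v = +z, B = +y gives force along -x
  dphi <- -kap * step
  phi <- c(0, cumsum(dphi))
  # exact arc per step; straight step where curvature vanishes
  dz <- ifelse(dphi != 0,
               (sin(phi[-1]) - sin(phi[-(n + 1)])) * step / dphi,
               cos(phi[-(n + 1)]) * step)
  dx <- ifelse(dphi != 0,
               -(cos(phi[-1]) - cos(phi[-(n + 1)])) * step / dphi,
               sin(phi[-(n + 1)]) * step)
  x <- beam$entry_point[1] + c(0, cumsum(dx))
  z <- c(0, cumsum(dz))
  samples <- data.frame(
    s = c(0, seq_len(n) * step),
    x = x, z = z,
    energy = c(beam$energy, energy_from_range(r0 - seq_len(n) * step, model))
  )
  structure(
    list(samples = samples,
         wd = abs(x[n + 1] - beam$entry_point[1]),
         depth = z[n + 1],
         exit_angle_deg = abs(phi[n + 1]) * 180 / pi,
         bend_sign = -1,
         step = step, relativistic = relativistic,
         beam = beam, field = field, model = model),
    class = "track_polyline"
  )
}

#' @export
print.track_polyline <- function(x, ...) {
  cat(sprintf(
    "central track: E0 = %g MeV, B = %g T -> depth %.3f cm, |WD| %.3f cm, exit angle %.2f deg\n",
    x$beam$energy, x$field$magnitude, x$depth, x$wd, x$exit_angle_deg))
  invisible(x)
}
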