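# Bragg-peak localization and shift measurement on 3D dose grids.

# 3-point parabolic vertex offset in voxel units, clamped to half a voxel
.parabolic_offset <- function(lo, mid, hi) {
  den <- lo - 2 * mid + hi
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (lo - hi) / den
  max(-0.5, min(0.5, off))
}

#' Locate the Bragg peak in a dose grid
#'
#' Finds the global dose maximum and refines its position to sub-voxel
#' precision with a 3-point parabolic fit along each axis. Ties between
#' equal-valued maxima are broken toward the smallest depth, then the
#' smallest |x|.
#'
#' @param grid A `dose_grid`.
#' @return A list with `position` (named vector `x`, `y`, `z` in cm),
#'   `value` (peak dose) and `index` (the argmax voxel indices).
#' @export
find_bragg_peak <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  v <- grid$values
  mx <- max(v)
  if (mx <= 0) stop("no peak: the dose grid is identically zero")
  cand <- which(v == mx, arr.ind = TRUE)
  xc <- grid_centers(grid$grid, 1)
  ord <- order(cand[, 3], abs(xc[cand[, 1]]), cand[, 2])
  idx <- cand[ord[1], ]
  pos <- numeric(3)
  for (k in 1:3) {
    i <- idx[k]
    off <- 0
    if (i > 1 && i < dim(v)[k]) {
      sel <- lapply(1:3, function(kk) if (kk == k) (i - 1):(i + 1) else idx[kk])
      tri <- v[sel[[1]], sel[[2]], sel[[3]]]
      off <- .parabolic_offset(tri[1], tri[2], tri[3])
    }
    pos[k] <- grid$grid$origin[k] + (i - 0.5 + off) * grid$grid$voxel[k]
  }
  list(position = c(x = pos[1], y = pos[2], z = pos[3]), value = mx,
       index = as.integer(idx))
}

#' Measure Bragg-peak shifts against a field-free reference
#'
#' Extracts the lateral shift `WD` (in-plane distance of the in-field peak
#' from the field-free beam axis), the depth retraction `dDD` (field-free
#' peak depth minus in-field peak depth) and the deflection angle
#' `atan(WD / depth)` from a matched pair of dose grids.
#'
#' @param grid_b In-field `dose_grid`.
#' @param grid_0 Field-free reference `dose_grid` (same beam energy and
#'   geometry, field 0).
#' @return A list of class `shift_measurement` with `wd` (cm), `ddd` (cm),
#'   `angle_def` (degrees) and `reference_peak_depth` (cm).
#' @export
measure_shifts <- function(grid_b, grid_0) {
  stopifnot(inherits(grid_b, "dose_grid"), inherits(grid_0, "dose_grid"))
  pb <- grid_b$provenance; p0 <- grid_0$provenance
  if (!isTRUE(all.equal(pb$energy, p0$energy)) ||
      !identical(dim(grid_b$values), dim(grid_0$values)) ||
      p0$field != 0)
    stop("incompatible grids: need matching energy/geometry and a field-free reference")
  peak_b <- find_bragg_peak(grid_b)
  peak_0 <- find_bragg_peak(grid_0)
  axis_x <- pb$entry_point[1]
  wd <- abs(peak_b$position["x"] - axis_x)
  ddd <- peak_0$position["z"] - peak_b$position["z"]
  structure(list(
    wd = unname(wd), ddd = unname(ddd),
    angle_def = unname(atan2(wd, peak_b$position["z"]) * 180 / pi),
    reference_peak_depth = unname(peak_0$position["z"])),
    class = "shift_measurement")
}

#' @export
print.shift_measurement <- function(x, ...) {
  cat(sprintf("WD = %.3f cm, dDD = %.3f cm, deflection angle = %.2f deg (reference depth %.3f cm)\n",
              x$wd, x$ddd, x$angle_def, x$reference_peak_depth))
  invisible(x)
}

#' Laterally-integrated depth-dose curve
#'
#' Sums the dose over each z-slab and normalizes either to the entrance
#' (surface) slab or to the curve maximum.
#'
#' @param grid A `dose_grid`.
#' @param normalization `"surface"` (divide by the entrance-slab value) or
#'   `"max"`.
#' @return A data frame with columns `z_cm` and `dose`.
#' @export
depth_dose_curve <- function(grid, normalization = c("surface", "max")) {
  stopifnot(inherits(grid, "dose_grid"))
  normalization <- match.arg(normalization)
  prof <- apply(grid$values, 3, sum)
  denom <- if (normalization == "surface") prof[1] else max(prof)
  if (denom <= 0) stop("cannot normalize: zero entrance dose")
  data.frame(z_cm = grid_centers(grid$grid, 3), dose = prof / denom)
}

#' Planar dose distribution at the Bragg-peak depth
#'
#' Extracts the z-slab containing the refined Bragg peak, relabels the axes
#' to `u` (the bending axis, x) and `v` (the field axis, y), and normalizes
#' to the slab maximum. Warns if the peak slab touches the grid boundary.
#'
#' @param grid A `dose_grid`.
#' @return An object of class `planar_slab`: `values` (matrix indexed
#'   `[u, v]`, maximum 1), coordinate vectors `u`, `v` (cm), `pixel` (cm),
#'   `peak_uv` (refined in-plane peak position) and `z_cm` (slab depth).
#' @export
planar_at_peak <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  pk <- find_bragg_peak(grid)
  iz <- pk$index[3]
  if (iz == 1L || iz == dim(grid$values)[3])
    warning("Bragg peak lies on the grid boundary")
  slab <- grid$values[, , iz]
  structure(list(values = slab / max(slab),
                 u = grid_centers(grid$grid, 1),
                 v = grid_centers(grid$grid, 2),
                 pixel = grid$grid$voxel[1:2],
                 peak_uv = c(u = unname(pk$position["x"]),
                             v = unname(pk$position["y"])),
                 z_cm = unname(pk$position["z"])),
            class = "planar_slab")
}

# Trilinear interpolation of a dose grid at arbitrary points (n x 3 matrix
# of x, y, z in cm). Points outside the grid return 0.
interp_trilinear <- function(grid, pts) {
  v <- grid$values
  g <- grid$grid
  out <- numeric(nrow(pts))
  fx <- (pts[, 1] - g$origin[1]) / g$voxel[1] - 0.5
  fy <- (pts[, 2] - g$origin[2]) / g$voxel[2] - 0.5
  fz <- (pts[, 3] - g$origin[3]) / g$voxel[3] - 0.5
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  ok <- i0 >= 0 & i0 <= g$n[1] - 2 & j0 >= 0 & j0 <= g$n[2] - 2 &
    k0 >= 0 & k0 <= g$n[3] - 2
  if (!any(ok)) return(out)
  i0 <- i0[ok] + 1L; j0 <- j0[ok] + 1L; k0 <- k0[ok] + 1L
  tx <- tx[ok]; ty <- ty[ok]; tz <- tz[ok]
  nxy <- g$n[1] * g$n[2]
  base <- i0 + (j0 - 1L) * g$n[1] + (k0 - 1L) * nxy
  val <- (1 - tz) * ((1 - ty) * ((1 - tx) * v[base] + tx * v[base + 1L]) +
                     ty * ((1 - tx) * v[base + g$n[1]] +
                           tx * v[base + g$n[1] + 1L])) +
    tz * ((1 - ty) * ((1 - tx) * v[base + nxy] + tx * v[base + nxy + 1L]) +
          ty * ((1 - tx) * v[base + nxy + g$n[1]] +
                tx * v[base + nxy + g$n[1] + 1L]))
  out[ok] <- val
  out
}
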