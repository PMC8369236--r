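# Dose-grid simulation: deterministic pencil-beam mode and sampled Monte
# Carlo mode. Both share the CSDA energy schedule, the curvature of the
# central track, Highland multiple scattering and Gaussian range straggling;
# MC samples them per history, pencil mode applies them as analytic widths.

#' Highland multiple-scattering angle per step
#'
#' RMS projected scattering angle (radians) accumulated over a water slab of
#' thickness `step`: `theta0 = 14.1/(p v) * sqrt(step/X0) *
#' (1 + log10(step/X0)/9)` with `X0 = 36.08` cm.
#'
#' @param energy Kinetic energy, MeV (vectorized, above the model cutoff).
#' @param step Slab thickness, cm (positive).
#' @param model A [stopping_model()].
#' @return RMS projected angle, radians.
#' @export
scattering_sigma_increment <- function(energy, step,
                                       model = stopping_model()) {
  .assert_model(model)
  if (any(energy <= model$cutoff_energy))
    stop("'energy' must exceed the model cutoff")
  if (!is.numeric(step) || any(step <= 0)) stop("'step' must be positive")
  x0 <- 36.08
  pc <- momentum(energy, relativistic = TRUE, model = model)
  pv <- pc^2 / (energy + model$rest_energy)
  t <- step / x0
  pmax(0, 14.1 / pv * sqrt(t) * (1 + log10(t) / 9))
}

.new_dose_grid <- function(values, grid, provenance, uncertainty = NULL) {
  structure(list(values = values, grid = grid, provenance = provenance,
                 uncertainty = uncertainty),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("dose_grid: %d x %d x %d voxels, %s mode\n",
              x$grid$n[1], x$grid$n[2], x$grid$n[3], pv$mode))
  cat(sprintf("  beam %g MeV (spot sigma %g cm), field %g T, histories %g\n",
              pv$energy, pv$spot_sigma, pv$field, pv$histories))
  cat(sprintf("  total deposited energy %.4g MeV%s\n", sum(x$values),
              if (isTRUE(pv$truncated)) " (track partially outside grid)" else ""))
  invisible(x)
}

#' Simulate a 3D dose grid for one pencil-beam spot
#'
#' Scores deposited energy (MeV) on a voxel grid for a Gaussian proton spot
#' entering a water phantom perpendicular to a uniform magnetic field.
#'
#' `mode = "mc"`: each history samples its entry position from the 2D
#' Gaussian spot and a Gaussian range perturbation (straggling), then is
#' transported in condensed-history steps with magnetic bending and Highland
#' multiple-scattering kicks, depositing `stopping_power * step` per step and
#' the sub-cutoff residual locally. `mode = "pencil"` is deterministic: the
#' central track of [integrate_central_track()] carries a longitudinal
#' straggling convolution and an analytic lateral Gaussian (entrance spot
#' combined in quadrature with the accumulated scattering width).
#'
#' Results are reproducible bit-for-bit from the provenance (beam, field,
#' grid, mode, histories, seed, step).
#'
#' @param beam A [beam_spec()].
#' @param field A [field_spec()].
#' @param grid A [phantom_grid()].
#' @param mode `"pencil"` (deterministic) or `"mc"` (sampled).
#' @param histories Number of protons (the pencil mode scales its
#'   deterministic result to this many).
#' @param seed RNG seed, mandatory for `mode = "mc"`.
#' @param step Transport step, cm (default 0.01 pencil, 0.05 mc).
#' @param relativistic Momentum form for the curvature (default
#'   non-relativistic, matching the closed-form model).
#' @param model A [stopping_model()].
#' @return A `dose_grid` object: `values` (3D array of deposited MeV,
#'   dimensions x, y, z), `grid`, `provenance` and (unset here) `uncertainty`.
#' @examples
#' g <- phantom_grid(extent = c(6, 6, 9), voxel = c(0.1, 0.1, 0.1))
#' d <- simulate_dose_grid(beam_spec(100), field_spec(0), g,
#'                         mode = "pencil", histories = 1000)
#' @export
simulate_dose_grid <- function(beam, field, grid = phantom_grid(),
                               mode = c("pencil", "mc"), histories = 2e5,
                               seed = NULL, step = NULL,
                               relativistic = FALSE,
                               model = stopping_model()) {
  mode <- match.arg(mode)
  stopifnot(inherits(beam, "beam_spec"), inherits(field, "field_spec"),
            inherits(grid, "phantom_grid"))
  .assert_model(model)
  if (histories < 1) stop("'histories' must be at least 1")
  if (is.null(step)) step <- if (mode == "mc") 0.05 else 0.01
  r0 <- range_from_energy(beam$energy, model)
  strag <- sigma_range_straggling(r0)

  if (mode == "mc") {
    if (is.null(seed)) stop("'seed' is mandatory for mc mode")
    set.seed(as.integer(seed))
    res <- cpp_transport_mc(
      as.integer(histories), beam$energy, beam$spot_sigma,
      beam$entry_point[1], beam$entry_point[2],
      field$magnitude, -1,
      model$alpha, model$p, model$rest_energy, model$cutoff_energy,
      physics_constants()$rigidity_constant * 10, relativistic,
      step, strag, grid$n, grid$voxel, grid$origin)
    values <- array(res$dose, dim = grid$n)
    truncated <- res$truncated
  } else {
    pk <- .simulate_pencil(beam, field, grid, model, step, relativistic, strag)
    values <- pk$values * histories
    truncated <- pk$truncated
  }
  if (truncated)
    warning("part of the track lies outside the scoring grid")
  prov <- list(energy = beam$energy, spot_sigma = beam$spot_sigma,
               entry_point = beam$entry_point, field = field$magnitude,
               field_direction = field$direction, mode = mode,
               histories = histories, seed = seed, step = step,
               relativistic = relativistic, bend_sign = -1,
               truncated = truncated,
               model = unclass(model))
  .new_dose_grid(values, grid, prov)
}

# Deterministic pencil-beam scoring (per single history; caller scales).
.simulate_pencil <- function(beam, field, grid, model, step, relativistic,
                             strag) {
  tr <- integrate_central_track(beam, field, step, relativistic, model)
  sm <- tr$samples
  n <- nrow(sm) - 1L
  r0 <- range_from_energy(beam$energy, model)
  s_mid <- (seq_len(n) - 0.5) * step
  e_mid <- energy_from_range(r0 - s_mid, model)
  de <- stopping_power(e_mid, model) * step
  de[n] <- de[n] + sm$energy[n + 1L] # sub-cutoff residual deposited locally

  # midpoint positions and local track angle in the bending plane
  xm <- (sm$x[-1L] + sm$x[-(n + 1L)]) / 2
  zm <- (sm$z[-1L] + sm$z[-(n + 1L)]) / 2
  phim <- atan2(diff(sm$x), diff(sm$z))

  # accumulated multiple-scattering lateral sigma at each midpoint:
  # independent kicks theta0(s_i) displace by theta0 * (s - s_i)
  th2 <- scattering_sigma_increment(e_mid, step, model)^2
  a <- cumsum(th2); b <- cumsum(th2 * s_mid); cc <- cumsum(th2 * s_mid^2)
  sig_mcs2 <- pmax(0, s_mid^2 * a - 2 * s_mid * b + cc)

  # extend beyond the track end along the exit direction so the straggling
  # convolution can push dose past the nominal range
  n_ext <- ceiling(4 * strag / step)
  phi_end <- phim[n]
  s_ext <- s_mid[n] + seq_len(n_ext) * step
  xm <- c(xm, xm[n] + sin(phi_end) * seq_len(n_ext) * step)
  zm <- c(zm, zm[n] + cos(phi_end) * seq_len(n_ext) * step)
  phim <- c(phim, rep(phi_end, n_ext))
  sig_mcs2 <- c(sig_mcs2, rep(sig_mcs2[n], n_ext))
  de <- c(de, rep(0, n_ext))

  # longitudinal range-straggling convolution along arc length
  half <- ceiling(4 * strag / step)
  kern <- stats::dnorm(seq(-half, half) * step, sd = strag) * step
  kern <- kern / sum(kern)
  de_conv <- stats::convolve(c(rep(0, half), de, rep(0, half)), rev(kern),
                             type = "filter")

  sig_lat <- sqrt(beam$spot_sigma^2 + sig_mcs2)
  sig_x <- sig_lat / pmax(cos(phim), 0.5) # slab projection of the
  sig_y <- sig_lat                        # transverse width

  xc <- grid$origin[1] + seq(0, grid$n[1]) * grid$voxel[1] # voxel edges
  yc <- grid$origin[2] + seq(0, grid$n[2]) * grid$voxel[2]
  values <- array(0, dim = grid$n)
  truncated <- FALSE
  y0 <- beam$entry_point[2]
  for (j in seq_along(de_conv)) {
    if (de_conv[j] <= 0) next
    iz <- floor((zm[j] - grid$origin[3]) / grid$voxel[3]) + 1
    if (iz < 1 || iz > grid$n[3]) { truncated <- TRUE; next }
    ix <- which(xc[-1] > xm[j] - 4 * sig_x[j] &
                xc[-length(xc)] < xm[j] + 4 * sig_x[j])
    iy <- which(yc[-1] > y0 - 4 * sig_y[j] &
                yc[-length(yc)] < y0 + 4 * sig_y[j])
    if (length(ix) == 0L || length(iy) == 0L) { truncated <- TRUE; next }
    wx <- diff(stats::pnorm(xc[c(ix, ix[length(ix)] + 1L)], xm[j], sig_x[j]))
    wy <- diff(stats::pnorm(yc[c(iy, iy[length(iy)] + 1L)], y0, sig_y[j]))
    values[ix, iy, iz] <- values[ix, iy, iz] + de_conv[j] * outer(wx, wy)
  }
  list(values = values, truncated = truncated)
}

#' Per-voxel statistical uncertainty from independent batches
#'
#' Combines two or more statistically independent dose grids (same beam,
#' field, grid and histories, different seeds) into their mean and the
#' per-voxel relative standard error of that mean, with a summary of the
#' error in the peak region (voxels above half the maximum) and in the
#' distal low-dose region (voxels beyond the peak depth between 1% and 10%
#' of the maximum).
#'
#' @param batches A list of at least two `dose_grid` objects with matching
#'   geometry and beam parameters.
#' @return A list with `mean` (a `dose_grid` whose `uncertainty` element is
#'   the relative standard error array) and `summary` (median relative error
#'   in the peak and distal regions, number of batches).
#' @export
estimate_uncertainty <- function(batches) {
  if (!is.list(batches) || length(batches) < 2L)
    stop("at least two batches are required to estimate uncertainty")
  if (!all(vapply(batches, inherits, logical(1), "dose_grid")))
    stop("'batches' must be a list of dose_grid objects")
  dims <- lapply(batches, function(b) dim(b$values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("batches must share the same grid")
  nb <- length(batches)
  stack <- vapply(batches, function(b) as.vector(b$values),
                  numeric(length(batches[[1]]$values)))
  m <- rowMeans(stack)
  sd_v <- sqrt(pmax(0, rowMeans(stack^2) - m^2) * nb / (nb - 1))
  rel <- ifelse(m > 0, sd_v / sqrt(nb) / m, NA_real_)
  dims1 <- dim(batches[[1]]$values)
  mean_grid <- .new_dose_grid(array(m, dims1), batches[[1]]$grid,
                              batches[[1]]$provenance,
                              uncertainty = array(rel, dims1))
  mx <- max(m)
  pk <- find_bragg_peak(mean_grid)
  zc <- grid_centers(batches[[1]]$grid, 3)
  zvox <- array(rep(zc, each = dims1[1] * dims1[2]), dims1)
  peak_sel <- m >= 0.5 * mx
  distal_sel <- as.vector(zvox) > pk$position["z"] & m >= 0.01 * mx &
    m < 0.1 * mx
  list(mean = mean_grid,
       summary = list(
         batches = nb,
         peak_rel_error = stats::median(rel[peak_sel], na.rm = TRUE),
         distal_rel_error = if (any(distal_sel))
           stats::median(rel[distal_sel], na.rm = TRUE) else NA_real_))
}
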