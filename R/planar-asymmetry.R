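# Planar asymmetry metrics: 1D Gaussian fits and sigma ratios, isodose
# contours with inscribed/circumscribed circle fitting, and the rotating
# FWHM scan through the Bragg peak.

#' Fit a 1D Gaussian to a dose profile
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 sigma^2))` to a sampled
#' profile, with moment-based starting values. Also reports the RMS residual
#' (as a fraction of the fitted amplitude) and the half-width asymmetry
#' `(right - left) / (right + left)` of the half-maximum crossings of the raw
#' profile around its (parabolically refined) mode.
#'
#' @param position Sample positions, cm (at least 5).
#' @param value Dose values (non-negative, positive total mass).
#' @return A list of class `gaussian_fit_1d` with `amplitude`, `mean`,
#'   `sigma`, `rms_residual`, `halfwidth_asymmetry`.
#' @export
fit_gaussian_1d <- function(position, value) {
  stopifnot(length(position) == length(value))
  if (length(position) < 5L) stop("at least 5 samples are required")
  if (all(value <= 0)) stop("profile has no positive mass")
  w <- pmax(value, 0)
  mu0 <- sum(position * w) / sum(w)
  s0 <- sqrt(max(sum((position - mu0)^2 * w) / sum(w), 1e-12))
  a0 <- max(value)
  df <- data.frame(x = position, y = value)
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
               start = list(a = a0, mu = mu0, s = s0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to direct least squares for profiles nls refuses (e.g. an
    # exact Gaussian with zero residual)
    obj <- function(par) {
      sum((value - par[1] * exp(-(position - par[2])^2 / (2 * par[3]^2)))^2)
    }
    op <- stats::optim(c(a0, mu0, s0), obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    cf <- op$par
  } else {
    cf <- stats::coef(fit)
  }
  a <- cf[[1]]; mu <- cf[[2]]; s <- abs(cf[[3]])
  if (!is.finite(s) || s <= 0)
    stop("Gaussian fit failed: non-positive width (profile may be degenerate)")
  resid <- value - a * exp(-(position - mu)^2 / (2 * s^2))
  # half-width asymmetry from the raw profile
  im <- which.max(value)
  xm <- position[im]
  if (im > 1 && im < length(value)) {
    d <- mean(diff(position))
    xm <- xm + d * .parabolic_offset(value[im - 1], value[im], value[im + 1])
  }
  half <- max(value) / 2
  cross <- function(side) {
    idx <- if (side < 0) seq(im, 2) else seq(im, length(value) - 1)
    for (i in idx) {
      j <- i + side
      if ((value[i] - half) * (value[j] - half) <= 0 && value[i] != value[j]) {
        t <- (half - value[i]) / (value[j] - value[i])
        return(position[i] + t * (position[j] - position[i]))
      }
    }
    NA_real_
  }
  xl <- cross(-1L); xr <- cross(1L)
  asym <- if (is.na(xl) || is.na(xr)) NA_real_ else
    ((xr - xm) - (xm - xl)) / ((xr - xm) + (xm - xl))
  structure(list(amplitude = a, mean = mu, sigma = s,
                 rms_residual = sqrt(mean(resid^2)) / a,
                 halfwidth_asymmetry = asym),
            class = "gaussian_fit_1d")
}

#' Sigma ratio of the planar distribution
#'
#' Fits 1D Gaussians to the central-axis profiles of a Bragg-peak slab along
#' the bending axis `u` and the field axis `v`, and returns the width ratio
#' `sigma_u / sigma_v`. Lorentz deflection distorts the distribution along
#' `u` only, so the ratio is 1 without field and grows with deflection.
#'
#' @param slab A `planar_slab` from [planar_at_peak()].
#' @return A list with `ratio` (`sigma_u / sigma_v`), the two fits (`fit_u`,
#'   `fit_v`) and the `convention` string.
#' @export
sigma_ratio <- function(slab) {
  stopifnot(inherits(slab, "planar_slab"))
  jv <- which.min(abs(slab$v - slab$peak_uv["v"]))
  iu <- which.min(abs(slab$u - slab$peak_uv["u"]))
  fit_u <- fit_gaussian_1d(slab$u, slab$values[, jv])
  fit_v <- fit_gaussian_1d(slab$v, slab$values[iu, ])
  list(ratio = fit_u$sigma / fit_v$sigma, fit_u = fit_u, fit_v = fit_v,
       convention = "bending-axis sigma over field-axis sigma")
}

# ray-casting point-in-polygon test (polygon as n x 2 matrix, closed or open)
.point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[j, 1] + (pt[2] - poly[j, 2]) / (poly[i, 2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Extract a closed isodose contour from a planar slab
#'
#' Sub-pixel contour (marching-squares with linear interpolation, via
#' [grDevices::contourLines()]) of the given dose level, selecting the closed
#' contour that encloses the in-plane peak.
#'
#' @param slab A `planar_slab`.
#' @param level Dose level as a fraction of the slab maximum, in (0, 1).
#' @return A closed polyline: an `n x 2` matrix of `(u, v)` coordinates (cm)
#'   whose last row repeats the first.
#' @export
isodose_contour <- function(slab, level) {
  stopifnot(inherits(slab, "planar_slab"))
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)")
  cl <- grDevices::contourLines(slab$u, slab$v, slab$values,
                                levels = level * max(slab$values))
  if (length(cl) == 0L) stop("no contour found at this level")
  pk <- slab$peak_uv
  for (cc in cl) {
    poly <- cbind(cc$x, cc$y)
    closed <- sqrt(sum((poly[1, ] - poly[nrow(poly), ])^2)) <
      2 * max(slab$pixel)
    if (closed && .point_in_polygon(pk, poly)) {
      if (any(poly[1, ] != poly[nrow(poly), ]))
        poly <- rbind(poly, poly[1, ])
      return(poly)
    }
  }
  stop("the contour enclosing the peak is open at the slab boundary")
}

#' Fit inscribed and circumscribed circles to a closed contour
#'
#' Chooses a single shared center minimizing the annulus area
#' `pi * (r_ec^2 - r_ic^2)`, where `r_ic`/`r_ec` are the minimum/maximum
#' distances from the center to the contour, via a coarse grid over the
#' bounding box followed by Nelder-Mead refinement. The radius difference
#' `r_ec - r_ic` is the skewness metric: 0 for a circle, growing with
#' ellipticity.
#'
#' @param contour An `n x 2` matrix of closed-contour coordinates (cm).
#' @return A list of class `isodose_fit` with `center`, `r_ic`, `r_ec`,
#'   `radius_diff` (all cm).
#' @export
fit_ic_ec <- function(contour) {
  contour <- as.matrix(contour)
  stopifnot(ncol(contour) == 2, nrow(contour) >= 4)
  pts <- contour[!duplicated(contour), , drop = FALSE]
  if (abs(stats::sd(pts[, 1])) < 1e-12 || abs(stats::sd(pts[, 2])) < 1e-12 ||
      abs(stats::cor(pts[, 1], pts[, 2])) > 1 - 1e-12)
    stop("degenerate (collinear) contour")
  obj <- function(ctr) {
    d2 <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2
    max(d2) - min(d2)
  }
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  gx <- seq(rx[1], rx[2], length.out = 25)
  gy <- seq(ry[1], ry[2], length.out = 25)
  grid <- as.matrix(expand.grid(gx, gy))
  vals <- apply(grid, 1, obj)
  start <- grid[which.min(vals), ]
  op <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 2000))
  ctr <- op$par
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  structure(list(center = c(u = ctr[1], v = ctr[2]),
                 r_ic = min(d), r_ec = max(d),
                 radius_diff = max(d) - min(d)),
            class = "isodose_fit")
}

#' Isodose skewness across dose levels, with and without field
#'
#' For each dose level, fits IC/EC circles to the isodose contour of the
#' in-field slab and of the matched field-free slab, and reports the radius
#' differences together with the standard radius (the mean fitted radius of
#' the field-free circle). Rows are sorted by standard radius (lower dose
#' level, larger circle).
#'
#' @param slab_b In-field `planar_slab`.
#' @param slab_0 Field-free `planar_slab` at the same energy.
#' @param levels Dose levels, fractions of the planar maximum.
#' @return A data frame with columns `level`, `standard_radius_cm`,
#'   `radius_diff_field_cm`, `radius_diff_nofield_cm`.
#' @export
skewness_by_level <- function(slab_b, slab_0, levels = c(0.8, 0.5, 0.2)) {
  stopifnot(inherits(slab_b, "planar_slab"), inherits(slab_0, "planar_slab"))
  rows <- lapply(levels, function(lv) {
    fb <- fit_ic_ec(isodose_contour(slab_b, lv))
    f0 <- fit_ic_ec(isodose_contour(slab_0, lv))
    data.frame(level = lv,
               standard_radius_cm = (f0$r_ic + f0$r_ec) / 2,
               radius_diff_field_cm = fb$radius_diff,
               radius_diff_nofield_cm = f0$radius_diff)
  })
  out <- do.call(rbind, rows)
  out[order(out$standard_radius_cm), , drop = FALSE]
}

#' Rotating FWHM scan through the Bragg peak
#'
#' Samples the dose along lines through the refined Bragg-peak position,
#' rotated in steps from the beam axis within the chosen plane (the bending
#' plane `u`-`z` by default, or the field plane `v`-`z`), and measures the
#' full width at half maximum of each line profile via linearly interpolated
#' half-maximum crossings. Reports the extrema and their angles, plus the
#' beam-axis ("vertical") FWHM.
#'
#' @param grid A `dose_grid`.
#' @param plane `"bending"` (u-z) or `"field"` (v-z).
#' @param angle_step Angular step in degrees, in (0, 10].
#' @return A list of class `fwhm_scan`: `profile` (data frame `angle_deg`,
#'   `fwhm_cm`), `fwhm_max`, `angle_max`, `fwhm_min`, `angle_min`,
#'   `fwhm_vertical`.
#' @export
fwhm_scan <- function(grid, plane = c("bending", "field"), angle_step = 1) {
  stopifnot(inherits(grid, "dose_grid"))
  plane <- match.arg(plane)
  if (!is.numeric(angle_step) || angle_step <= 0 || angle_step > 10)
    stop("'angle_step' must lie in (0, 10] degrees")
  pk <- find_bragg_peak(grid)
  p0 <- pk$position
  tstep <- min(grid$grid$voxel) / 2
  tmax <- sqrt(sum((grid$grid$extent)^2))
  tgrid <- seq(-tmax, tmax, by = tstep)
  angles <- seq(0, 180 - angle_step, by = angle_step)
  fwhm <- vapply(angles, function(th) {
    a <- th * pi / 180
    dvec <- if (plane == "bending") c(sin(a), 0, cos(a)) else
      c(0, sin(a), cos(a))
    pts <- cbind(p0[1] + tgrid * dvec[1], p0[2] + tgrid * dvec[2],
                 p0[3] + tgrid * dvec[3])
    prof <- interp_trilinear(grid, pts)
    half <- max(prof) / 2
    i0 <- which.max(prof)
    above <- prof >= half
    lo <- i0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i0; while (hi < length(prof) && above[hi + 1]) hi <- hi + 1
    if (lo == 1 || hi == length(prof))
      stop(sprintf("profile at %g deg leaves the grid above half maximum", th))
    tl <- tgrid[lo] - tstep * (half - prof[lo]) / (prof[lo - 1] - prof[lo])
    tr <- tgrid[hi] + tstep * (half - prof[hi]) / (prof[hi + 1] - prof[hi])
    tr - tl
  }, numeric(1))
  imax <- which.max(fwhm); imin <- which.min(fwhm)
  structure(list(profile = data.frame(angle_deg = angles, fwhm_cm = fwhm),
                 fwhm_max = fwhm[imax], angle_max = angles[imax],
                 fwhm_min = fwhm[imin], angle_min = angles[imin],
                 fwhm_vertical = fwhm[1]),
            class = "fwhm_scan")
}

#' @export
print.fwhm_scan <- function(x, ...) {
  cat(sprintf("FWHM scan: max %.4f cm at %g deg, min %.4f cm at %g deg, vertical %.4f cm\n",
              x$fwhm_max, x$angle_max, x$fwhm_min, x$angle_min,
              x$fwhm_vertical))
  invisible(x)
}
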