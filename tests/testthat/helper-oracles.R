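# Independent numerical oracles and synthetic-grid builders shared by the
# tests. The oracles integrate the curvature of the CSDA depth-energy
# profile directly (midpoint quadrature) and never call the closed forms
# they are used to check.

# lateral shift as the double integral of curvature over depth:
# WD = int_0^R int_0^z kappa(E(z')) dz' dz  (non-relativistic momentum)
wd_quadrature_oracle <- function(energy, field, model = stopping_model(),
                                 n = 20000) {
  r0 <- range_from_energy(energy, model)
  dz <- r0 / n
  z_mid <- (seq_len(n) - 0.5) * dz
  kap <- curvature(energy_from_range(r0 - z_mid, model), field,
                   relativistic = FALSE, model = model)
  theta <- cumsum(kap) * dz
  sum(theta) * dz
}

# depth retraction as the small-angle path-length excess:
# dDD = (1/2) int_0^R theta(z)^2 dz
ddd_quadrature_oracle <- function(energy, field, model = stopping_model(),
                                  n = 20000) {
  r0 <- range_from_energy(energy, model)
  dz <- r0 / n
  z_mid <- (seq_len(n) - 0.5) * dz
  kap <- curvature(energy_from_range(r0 - z_mid, model), field,
                   relativistic = FALSE, model = model)
  theta <- cumsum(kap) * dz
  0.5 * sum(theta^2) * dz
}

grid_centers_of <- function(dose, k) braggshift:::grid_centers(dose$grid, k)

# dose_grid filled with an anisotropic 3D Gaussian whose principal axes in
# the x-z plane are rotated by angle_deg away from the beam (z) axis;
# sigma = c(transverse short axis, long axis, y axis) in cm
make_gaussian_grid <- function(sigma = c(0.5, 0.5, 0.5), center = c(0, 0, 5),
                               angle_deg = 0,
                               extent = c(6, 6, 10),
                               voxel = c(0.1, 0.1, 0.1)) {
  g <- phantom_grid(extent = extent, voxel = voxel)
  xc <- braggshift:::grid_centers(g, 1) - center[1]
  yc <- braggshift:::grid_centers(g, 2) - center[2]
  zc <- braggshift:::grid_centers(g, 3) - center[3]
  a <- angle_deg * pi / 180
  # long axis direction (sin a, cos a) in (x, z)
  vals <- array(0, dim = g$n)
  for (k in seq_along(zc)) {
    lon <- outer(xc * sin(a), rep(1, length(yc))) + zc[k] * cos(a)
    sho <- outer(xc * cos(a), rep(1, length(yc))) - zc[k] * sin(a)
    yy <- outer(rep(1, length(xc)), yc)
    vals[, , k] <- exp(-0.5 * ((lon / sigma[2])^2 + (sho / sigma[1])^2 +
                                 (yy / sigma[3])^2))
  }
  braggshift:::.new_dose_grid(vals, g, list(
    energy = NA_real_, spot_sigma = NA_real_, entry_point = c(0, 0),
    field = 0, mode = "synthetic", histories = NA_real_, seed = NULL,
    step = NA_real_, relativistic = FALSE, bend_sign = -1,
    truncated = FALSE))
}

# planar_slab carrying an elliptical 2D Gaussian (sigma_u, sigma_v)
make_gaussian_slab <- function(sigma_u = 0.5, sigma_v = 0.5,
                               extent = 6, pixel = 0.05) {
  n <- round(extent / pixel)
  u <- (seq_len(n) - 0.5) * pixel - extent / 2
  vals <- exp(-0.5 * outer((u / sigma_u)^2, (u / sigma_v)^2, "+"))
  structure(list(values = vals / max(vals), u = u, v = u,
                 pixel = c(pixel, pixel), peak_uv = c(u = 0, v = 0),
                 z_cm = 0),
            class = "planar_slab")
}

# analytic closed polyline of an ellipse, optionally rotated/translated
make_ellipse_contour <- function(a = 4, b = 2, angle_deg = 0,
                                 center = c(0, 0), n = 720) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  p <- cbind(a * cos(t), b * sin(t))
  rot <- angle_deg * pi / 180
  rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  sweep(p %*% t(rm), 2, center, "+")
}
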