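#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Condensed-history Monte Carlo transport of protons in water inside a
// uniform magnetic field along +y. Beam along +z. Per history: entry
// position sampled from the 2D Gaussian spot; the CSDA range is perturbed
// by a Gaussian range-straggling draw (implemented as a stretch factor on
// the arc length so each history still deposits its full energy); per step
// the direction is rotated about the field axis by kappa * ds and receives
// two transverse Highland multiple-scattering kicks; stopping_power * ds is
// deposited into the containing voxel. Uses R's RNG (seed via set.seed()).
//
// The energy schedule depends only on the step index (residual range on the
// unstretched arc), so stopping power, curvature and the Highland angle are
// precomputed per step outside the history loop.

// [[Rcpp::export]]
List cpp_transport_mc(int histories, double energy, double spot_sigma,
                      double entry_x, double entry_y,
                      double field, double bend_sign,
                      double alpha, double p, double mc2, double cutoff,
                      double kappa_const, bool relativistic,
                      double step, double strag_sigma,
                      IntegerVector n, NumericVector voxel,
                      NumericVector origin) {
  const int nx = n[0], ny = n[1], nz = n[2];
  NumericVector dose(static_cast<R_xlen_t>(nx) * ny * nz);
  double *d = REAL(dose);
  const double R0 = alpha * std::pow(energy, p);
  const double Rstop = alpha * std::pow(cutoff, p);
  const double inv_p = 1.0 / p;
  const int nsteps = static_cast<int>(std::floor((R0 - Rstop) / step));
  const double X0 = 36.08; // radiation length of water, cm

  // per-step schedule at unit stretch
  std::vector<double> de(nsteps), dphi0(nsteps), th0(nsteps);
  for (int i = 0; i < nsteps; ++i) {
    double s_mid = (i + 0.5) * step;
    double E = std::pow((R0 - s_mid) / alpha, inv_p);
    de[i] = std::pow(E, 1.0 - p) / (alpha * p) * step;
    double pc_curv = relativistic ? std::sqrt(E * E + 2.0 * mc2 * E)
                                  : std::sqrt(2.0 * mc2 * E);
    dphi0[i] = bend_sign * kappa_const * field / pc_curv * step;
    double pc = std::sqrt(E * E + 2.0 * mc2 * E);
    double pbeta = pc * pc / (E + mc2);
    double t = step / X0;
    double f = 1.0 + std::log10(t) / 9.0;
    if (f < 0.0) f = 0.0;
    th0[i] = 14.1 / pbeta * std::sqrt(t) * f;
  }
  // sub-cutoff residual of the schedule, deposited at the stopping point
  de[nsteps - 1] += std::pow((R0 - nsteps * step) / alpha, inv_p);

  bool truncated = false;
  RNGScope scope;

  for (int h = 0; h < histories; ++h) {
    double x = entry_x + R::rnorm(0.0, spot_sigma);
    double y = entry_y + R::rnorm(0.0, spot_sigma);
    double z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    // range straggling as an arc-length stretch: energy schedule unchanged
    double stretch = 1.0 + R::rnorm(0.0, strag_sigma) / R0;
    if (stretch < 0.1) stretch = 0.1;
    const double ds = step * stretch;
    const double sqst = std::sqrt(stretch);

    for (int i = 0; i < nsteps; ++i) {
      if (field > 0.0) {
        // rotation about +y by dphi (|dphi| << 1: 3rd-order series)
        double dphi = dphi0[i] * stretch;
        double s = dphi * (1.0 - dphi * dphi / 6.0);
        double c = 1.0 - 0.5 * dphi * dphi;
        double nux = c * ux + s * uz;
        double nuz = -s * ux + c * uz;
        ux = nux; uz = nuz;
      }
      double t0 = th0[i] * sqst;
      if (t0 > 0.0) {
        // transverse basis: e1 = u x yhat (normalized), e2 = u x e1
        double e1x = -uz, e1z = ux;
        double e1n = std::sqrt(e1x * e1x + e1z * e1z);
        if (e1n < 1e-12) { e1x = 1.0; e1z = 0.0; e1n = 1.0; }
        e1x /= e1n; e1z /= e1n;
        double e2x = uy * e1z;
        double e2y = uz * e1x - ux * e1z;
        double e2z = -uy * e1x;
        double t1 = R::norm_rand() * t0, t2 = R::norm_rand() * t0;
        ux += t1 * e1x + t2 * e2x;
        uy += t2 * e2y;
        uz += t1 * e1z + t2 * e2z;
        double un = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= un; uy /= un; uz /= un;
      }
      x += ux * ds; y += uy * ds; z += uz * ds;
      int ix = static_cast<int>(std::floor((x - origin[0]) / voxel[0]));
      int iy = static_cast<int>(std::floor((y - origin[1]) / voxel[1]));
      int iz = static_cast<int>(std::floor((z - origin[2]) / voxel[2]));
      if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
        d[ix + static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz)] += de[i];
      } else {
        truncated = true;
      }
    }
  }
  return List::create(_["dose"] = dose, _["truncated"] = truncated);
}
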