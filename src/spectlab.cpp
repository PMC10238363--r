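// Compiled core: rotation-based attenuated projector / adjoint with
// distance-dependent Gaussian collimator response, and a Monte Carlo
// photon-transport projector (Compton scatter, photopeak energy windows,
// forced-detection and analog binary-cone scoring modes).
//
// Geometry convention (shared with the R side): volumes are (nx, ny, nz)
// arrays, x fastest. For projection angle A (radians) the ray direction in
// world coordinates is (-sin A, cos A, 0); the volume is resampled onto a
// frame rotated by -A so rays run along +j. Detector bins are (u, v) =
// (nx, nz) at the voxel pitch. Rotated-frame coordinates of a world voxel
// offset (dx, dy): di = cos A * dx + sin A * dy, dj = -sin A * dx + cos A * dy.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FWHM_TO_SIGMA = 1.0 / 2.3548200450309493;

// ---------- rotation resampling (gather) and its exact transpose ----------

static void rotate_gather(const double* vol, double* out,
                          int nx, int ny, int nz, double A) {
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double ca = std::cos(A), sa = std::sin(A);
  for (int z = 0; z < nz; ++z) {
    const double* src = vol + (size_t)z * nx * ny;
    double* dst = out + (size_t)z * nx * ny;
    for (int j = 0; j < ny; ++j) {
      const double dj = j - cy;
      for (int i = 0; i < nx; ++i) {
        const double di = i - cx;
        const double x = cx + ca * di - sa * dj;
        const double y = cy + sa * di + ca * dj;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        const double fx = x - x0, fy = y - y0;
        double v = 0.0;
        for (int oy = 0; oy <= 1; ++oy) {
          const int yy = y0 + oy;
          if (yy < 0 || yy >= ny) continue;
          const double wy = oy ? fy : 1.0 - fy;
          for (int ox = 0; ox <= 1; ++ox) {
            const int xx = x0 + ox;
            if (xx < 0 || xx >= nx) continue;
            const double wx = ox ? fx : 1.0 - fx;
            v += wx * wy * src[xx + (size_t)yy * nx];
          }
        }
        dst[i + (size_t)j * nx] = v;
      }
    }
  }
}

// Splat resampling with the same bilinear weights (the exact transpose of
// rotate_gather at angle -A). Used to rotate the activity into the ray
// frame because splatting conserves total mass for interior voxels, which
// keeps projection totals angle-independent.
static void rotate_scatter(const double* rot, double* out,
                           int nx, int ny, int nz, double A) {
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double ca = std::cos(A), sa = std::sin(A);
  for (int z = 0; z < nz; ++z) {
    const double* src = rot + (size_t)z * nx * ny;
    double* dst = out + (size_t)z * nx * ny;
    for (int j = 0; j < ny; ++j) {
      const double dj = j - cy;
      for (int i = 0; i < nx; ++i) {
        const double v = src[i + (size_t)j * nx];
        if (v == 0.0) continue;
        const double di = i - cx;
        const double x = cx + ca * di - sa * dj;
        const double y = cy + sa * di + ca * dj;
        const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
        const double fx = x - x0, fy = y - y0;
        for (int oy = 0; oy <= 1; ++oy) {
          const int yy = y0 + oy;
          if (yy < 0 || yy >= ny) continue;
          const double wy = oy ? fy : 1.0 - fy;
          for (int ox = 0; ox <= 1; ++ox) {
            const int xx = x0 + ox;
            if (xx < 0 || xx >= nx) continue;
            const double wx = ox ? fx : 1.0 - fx;
            dst[xx + (size_t)yy * nx] += wx * wy * v;
          }
        }
      }
    }
  }
}

// ---------- separable zero-padded Gaussian blur on a (nu, nv) slab ----------

static void gauss_kernel(double sigma, std::vector<double>& k) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  k.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
}

// zero-padded separable convolution (self-adjoint for symmetric kernels)
static void blur_slab(double* slab, int nu, int nv, double sigma,
                      std::vector<double>& buf) {
  if (sigma < 0.25) return;
  std::vector<double> k;
  gauss_kernel(sigma, k);
  const int r = ((int)k.size() - 1) / 2;
  buf.assign((size_t)nu * nv, 0.0);
  // along u
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      double acc = 0.0;
      for (int o = -r; o <= r; ++o) {
        const int uu = u + o;
        if (uu < 0 || uu >= nu) continue;
        acc += k[o + r] * slab[uu + (size_t)v * nu];
      }
      buf[u + (size_t)v * nu] = acc;
    }
  // along v
  for (int v = 0; v < nv; ++v)
    for (int u = 0; u < nu; ++u) {
      double acc = 0.0;
      for (int o = -r; o <= r; ++o) {
        const int vv = v + o;
        if (vv < 0 || vv >= nv) continue;
        acc += k[o + r] * buf[u + (size_t)vv * nu];
      }
      slab[u + (size_t)v * nu] = acc;
    }
}

// attenuation survival grid: T(i,j,z) = exp(-dl*(0.5*mu(i,j,z) + sum_{j'>j} mu))
static void atten_to_detector(const double* mur, double* T,
                              int nx, int ny, int nz, double dl) {
  for (int z = 0; z < nz; ++z) {
    for (int i = 0; i < nx; ++i) {
      double cum = 0.0;
      for (int j = ny - 1; j >= 0; --j) {
        const size_t id = i + (size_t)j * nx + (size_t)z * nx * ny;
        T[id] = std::exp(-dl * (0.5 * mur[id] + cum));
        cum += mur[id];
      }
    }
  }
}

// log-survival grid (negated optical path), for interpolation in MC scoring
static void logatten_to_detector(const double* mur, double* L,
                                 int nx, int ny, int nz, double dl) {
  for (int z = 0; z < nz; ++z) {
    for (int i = 0; i < nx; ++i) {
      double cum = 0.0;
      for (int j = ny - 1; j >= 0; --j) {
        const size_t id = i + (size_t)j * nx + (size_t)z * nx * ny;
        L[id] = dl * (0.5 * mur[id] + cum);
        cum += mur[id];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector act, NumericVector mu,
                                  IntegerVector dims, double voxsize,
                                  NumericVector angles_rad,
                                  NumericVector orbit_mm, double scale,
                                  bool cdr, double fwhm0, double slope) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  const double cy = (ny - 1) / 2.0;
  NumericVector sino((size_t)nx * nz * na);
  std::vector<double> actr((size_t)nx * ny * nz), mur((size_t)nx * ny * nz),
      T((size_t)nx * ny * nz), slab((size_t)nx * nz), buf;
  for (int a = 0; a < na; ++a) {
    // activity: mass-conserving splat into the ray frame; attenuation:
    // field interpolation (gather) in the same frame
    std::fill(actr.begin(), actr.end(), 0.0);
    rotate_scatter(REAL(act), actr.data(), nx, ny, nz, -angles_rad[a]);
    rotate_gather(REAL(mu), mur.data(), nx, ny, nz, angles_rad[a]);
    atten_to_detector(mur.data(), T.data(), nx, ny, nz, voxsize);
    double* out = REAL(sino) + (size_t)a * nx * nz;
    for (int j = 0; j < ny; ++j) {
      for (int z = 0; z < nz; ++z)
        for (int i = 0; i < nx; ++i) {
          const size_t id = i + (size_t)j * nx + (size_t)z * nx * ny;
          slab[i + (size_t)z * nx] = actr[id] * voxsize * T[id];
        }
      if (cdr) {
        double d = orbit_mm[a] - (j - cy) * voxsize;
        if (d < 0) d = 0;
        const double sig = (fwhm0 + slope * d) * FWHM_TO_SIGMA / voxsize;
        blur_slab(slab.data(), nx, nz, sig, buf);
      }
      for (size_t q = 0; q < (size_t)nx * nz; ++q) out[q] += slab[q];
    }
    for (size_t q = 0; q < (size_t)nx * nz; ++q) out[q] *= scale;
  }
  sino.attr("dim") = IntegerVector::create(nx, nz, na);
  return sino;
}

// exact transpose of cpp_forward_project
// [[Rcpp::export]]
NumericVector cpp_back_project(NumericVector sino, NumericVector mu,
                               IntegerVector dims, double voxsize,
                               NumericVector angles_rad,
                               NumericVector orbit_mm, double scale,
                               bool cdr, double fwhm0, double slope) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  const double cy = (ny - 1) / 2.0;
  NumericVector vol((size_t)nx * ny * nz);
  std::vector<double> mur((size_t)nx * ny * nz), T((size_t)nx * ny * nz),
      volr((size_t)nx * ny * nz), volw((size_t)nx * ny * nz),
      slab((size_t)nx * nz), buf;
  for (int a = 0; a < na; ++a) {
    rotate_gather(REAL(mu), mur.data(), nx, ny, nz, angles_rad[a]);
    atten_to_detector(mur.data(), T.data(), nx, ny, nz, voxsize);
    const double* in = REAL(sino) + (size_t)a * nx * nz;
    std::fill(volr.begin(), volr.end(), 0.0);
    for (int j = 0; j < ny; ++j) {
      for (size_t q = 0; q < (size_t)nx * nz; ++q) slab[q] = in[q] * scale;
      if (cdr) {
        double d = orbit_mm[a] - (j - cy) * voxsize;
        if (d < 0) d = 0;
        const double sig = (fwhm0 + slope * d) * FWHM_TO_SIGMA / voxsize;
        blur_slab(slab.data(), nx, nz, sig, buf);
      }
      for (int z = 0; z < nz; ++z)
        for (int i = 0; i < nx; ++i) {
          const size_t id = i + (size_t)j * nx + (size_t)z * nx * ny;
          volr[id] = slab[i + (size_t)z * nx] * voxsize * T[id];
        }
    }
    // transpose of the mass-conserving splat used in the forward pass
    rotate_gather(volr.data(), volw.data(), nx, ny, nz, -angles_rad[a]);
    for (size_t q = 0; q < (size_t)nx * ny * nz; ++q) REAL(vol)[q] += volw[q];
  }
  vol.attr("dim") = dims;
  return vol;
}

// separable 3-D Gaussian convolution with boundary renormalization
// (kernel sums to 1; truncated taps at the edges are renormalized so a
// constant volume is preserved exactly)
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims,
                          double sigma_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = (int)std::ceil(4.0 * sigma_vox);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double ks = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    ks += k[i + r];
  }
  for (double& v : k) v /= ks;
  NumericVector out(clone(vol));
  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  double* p = REAL(out);
  auto pass = [&](int n, size_t stride, size_t base) {
    for (int i = 0; i < n; ++i) line[i] = p[base + stride * i];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0, wsum = 0.0;
      const int lo = std::max(-r, -i), hi = std::min(r, n - 1 - i);
      for (int o = lo; o <= hi; ++o) {
        acc += k[o + r] * line[i + o];
        wsum += k[o + r];
      }
      p[base + stride * i] = acc / wsum;
    }
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      pass(nx, 1, (size_t)y * nx + (size_t)z * nx * ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      pass(ny, nx, (size_t)x + (size_t)z * nx * ny);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      pass(nz, (size_t)nx * ny, (size_t)x + (size_t)y * nx);
  out.attr("dim") = dims;
  return out;
}

// ---------- Klein-Nishina Compton kinematics ----------

// unnormalized differential cross-section in cos(theta), alpha = E/511
static double kn_f(double cost, double alpha) {
  const double r = 1.0 / (1.0 + alpha * (1.0 - cost)); // E'/E
  const double sin2 = 1.0 - cost * cost;
  return r * r * (r + 1.0 / r - sin2);
}

// integral of kn_f over cos(theta) in [-1, 1] (trapezoid, 128 panels)
static double kn_int(double alpha) {
  const int n = 128;
  double s = 0.5 * (kn_f(-1.0, alpha) + kn_f(1.0, alpha));
  for (int i = 1; i < n; ++i) s += kn_f(-1.0 + 2.0 * i / n, alpha);
  return s * 2.0 / n;
}

// rejection sampling of cos(theta) from the Klein-Nishina distribution
static double kn_sample(double alpha) {
  const double fmax = kn_f(1.0, alpha);
  for (int it = 0; it < 10000; ++it) {
    const double c = -1.0 + 2.0 * unif_rand();
    if (unif_rand() * fmax <= kn_f(c, alpha)) return c;
  }
  return 1.0; // unreachable in practice
}

static double compton_energy(double E, double cost) {
  return E / (1.0 + (E / 511.0) * (1.0 - cost));
}

// voxelwise mu at energy E, log-linear in energy between the photopeak maps
static inline double mu_at(double m171, double m245, double tE) {
  if (m171 <= 0.0 || m245 <= 0.0) return 0.0;
  return std::exp((1.0 - tE) * std::log(m171) + tE * std::log(m245));
}

static inline double energy_t(double E) {
  double Ec = E < 100.0 ? 100.0 : E; // clamped extrapolation below 100 keV
  return (std::log(Ec) - std::log(171.0)) /
         (std::log(245.0) - std::log(171.0));
}

// probability a photon of true energy E is recorded in any window,
// under a Gaussian energy resolution of fractional FWHM eres (0 = sharp)
static double window_prob(double E, const double* wlo, const double* whi,
                          int nw, double eres) {
  if (eres <= 0.0) {
    for (int w = 0; w < nw; ++w)
      if (E >= wlo[w] && E <= whi[w]) return 1.0;
    return 0.0;
  }
  const double sig = eres * E * FWHM_TO_SIGMA;
  double p = 0.0;
  for (int w = 0; w < nw; ++w)
    p += R::pnorm(whi[w], E, sig, 1, 0) - R::pnorm(wlo[w], E, sig, 1, 0);
  return p;
}

// lookup table of window_prob over energy, to keep pnorm out of the
// per-vertex scoring loops
struct WindowLut {
  double e0, de;
  std::vector<double> p;
  void build(const double* wlo, const double* whi, int nw, double eres) {
    e0 = 40.0; de = 0.25;
    const int n = 1 + (int)((320.0 - e0) / de);
    p.resize(n);
    for (int i = 0; i < n; ++i)
      p[i] = window_prob(e0 + i * de, wlo, whi, nw, eres);
  }
  double operator()(double E) const {
    const double x = (E - e0) / de;
    if (x <= 0) return p.front();
    const int i = (int)x;
    if (i >= (int)p.size() - 1) return p.back();
    const double f = x - i;
    return (1 - f) * p[i] + f * p[i + 1];
  }
};

// trilinear interpolation on a (nx, ny, nz) grid at voxel-centre coords
static double trilin(const double* g, int nx, int ny, int nz,
                     double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  const int x0 = std::min((int)std::floor(x), nx - 2);
  const int y0 = std::min((int)std::floor(y), ny - 2);
  const int z0 = std::min((int)std::floor(z), nz - 2);
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  double v = 0.0;
  for (int oz = 0; oz <= 1; ++oz)
    for (int oy = 0; oy <= 1; ++oy)
      for (int ox = 0; ox <= 1; ++ox) {
        const double w = (ox ? fx : 1 - fx) * (oy ? fy : 1 - fy) *
                         (oz ? fz : 1 - fz);
        v += w * g[(x0 + ox) + (size_t)(y0 + oy) * nx +
                   (size_t)(z0 + oz) * nx * ny];
      }
  return v;
}

// Monte Carlo projector.
// mode 0: forced detection -- every emission and every Compton vertex
//   deposits its expected contribution at every requested angle, using
//   precomputed log-attenuation-to-detector grids at the photopeak
//   energies (log-interpolated in energy for scattered photons); the
//   collimator response is applied as a sampled Gaussian (u, v) offset.
// mode 1: analog -- photons are tracked to escape and tallied only if the
//   escape direction lies within the binary acceptance cone of an angle;
//   the tally carries the 4*pi/Omega_cone deconditioning weight. This is
//   the reference estimator used for unbiasedness checks.
// [[Rcpp::export]]
NumericVector cpp_mc_forward(NumericVector act,
                             NumericVector mu171, NumericVector mu245,
                             IntegerVector dims, double voxsize,
                             NumericVector angles_rad, NumericVector orbit_mm,
                             double scale, double n_photons,
                             NumericMatrix windows, double abund171,
                             double abund245, bool scatter,
                             double compton_fraction, int mode,
                             double accept_half_angle_rad, bool cdr,
                             double fwhm0, double slope, double eres,
                             int max_orders) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  const size_t nvox = (size_t)nx * ny * nz;
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  NumericVector sino((size_t)nx * nz * na);
  double* tal = REAL(sino);

  const int nw = windows.nrow();
  std::vector<double> wlo(nw), whi(nw);
  for (int w = 0; w < nw; ++w) { wlo[w] = windows(w, 0); whi[w] = windows(w, 1); }
  WindowLut wlut;
  wlut.build(wlo.data(), whi.data(), nw, eres);
  // Klein-Nishina normalization (mean of kn_f over cos) tabulated in energy
  const double kE0 = 40.0, kdE = 2.0;
  std::vector<double> knorm_tab(1 + (int)((320.0 - kE0) / kdE));
  for (size_t i = 0; i < knorm_tab.size(); ++i)
    knorm_tab[i] = kn_int((kE0 + i * kdE) / 511.0) / 2.0;
  auto knorm_of = [&](double E) {
    double xq = (E - kE0) / kdE;
    if (xq <= 0) return knorm_tab.front();
    int i = (int)xq;
    if (i >= (int)knorm_tab.size() - 1) return knorm_tab.back();
    double f = xq - i;
    return (1 - f) * knorm_tab[i] + f * knorm_tab[i + 1];
  };
  const double pw171 = window_prob(171.0, wlo.data(), whi.data(), nw, eres);
  const double pw245 = window_prob(245.0, wlo.data(), whi.data(), nw, eres);
  // exact at the photopeaks, table-interpolated elsewhere
  auto pw_of = [&](double E) {
    if (E == 171.0) return pw171;
    if (E == 245.0) return pw245;
    return wlut(E);
  };

  // cumulative emission distribution over voxels
  const double* A = REAL(act);
  std::vector<double> cdf(nvox);
  double tot = 0.0;
  for (size_t v = 0; v < nvox; ++v) { tot += A[v]; cdf[v] = tot; }
  if (tot <= 0.0) { sino.attr("dim") = IntegerVector::create(nx, nz, na); return sino; }

  const double asum = abund171 + abund245;
  const double p171 = abund171 / asum;
  const double W = tot * voxsize * scale * asum / n_photons;

  // forced mode: per-angle log-attenuation grids at both photopeaks
  std::vector<double> L171, L245, mur;
  std::vector<double> ca(na), sa(na);
  for (int a = 0; a < na; ++a) { ca[a] = std::cos(angles_rad[a]); sa[a] = std::sin(angles_rad[a]); }
  if (mode == 0) {
    L171.resize(nvox * na); L245.resize(nvox * na); mur.resize(nvox);
    for (int a = 0; a < na; ++a) {
      rotate_gather(REAL(mu171), mur.data(), nx, ny, nz, angles_rad[a]);
      logatten_to_detector(mur.data(), L171.data() + nvox * a, nx, ny, nz, voxsize);
      rotate_gather(REAL(mu245), mur.data(), nx, ny, nz, angles_rad[a]);
      logatten_to_detector(mur.data(), L245.data() + nvox * a, nx, ny, nz, voxsize);
    }
  }

  // Woodcock majorant: mu is voxelwise nonincreasing in energy above the
  // 100 keV clamp, so the 100 keV map bounds all transported energies
  const double t100 = energy_t(100.0);
  double mumax = 0.0;
  for (size_t v = 0; v < nvox; ++v) {
    const double m = mu_at(REAL(mu171)[v], REAL(mu245)[v], t100);
    if (m > mumax) mumax = m;
  }
  if (mumax <= 0.0) mumax = 1e-9;

  const double cos_acc = std::cos(accept_half_angle_rad);
  const double omega_frac = 0.5 * (1.0 - cos_acc); // Omega / 4pi
  const long n = (long)n_photons;

  // deposit the forced-detection contribution of an isotropic emission
  auto forced_score = [&](double px, double py, double pz, double E,
                          double w) {
    const double tE = energy_t(E);
    const double pw = pw_of(E);
    if (pw <= 0.0) return;
    for (int a = 0; a < na; ++a) {
      const double di = ca[a] * (px - cx) + sa[a] * (py - cy);
      const double dj = -sa[a] * (px - cx) + ca[a] * (py - cy);
      const double uf = cx + di, jf = cy + dj;
      const double l171 = trilin(L171.data() + nvox * a, nx, ny, nz, uf, jf, pz);
      const double l245 = trilin(L245.data() + nvox * a, nx, ny, nz, uf, jf, pz);
      const double L = (1.0 - tE) * l171 + tE * l245;
      double ub = uf, vb = pz;
      if (cdr) {
        double d = orbit_mm[a] - dj * voxsize;
        if (d < 0) d = 0;
        const double sig = (fwhm0 + slope * d) * FWHM_TO_SIGMA / voxsize;
        ub += sig * norm_rand();
        vb += sig * norm_rand();
      }
      const int iu = (int)std::lround(ub), iv = (int)std::lround(vb);
      if (iu < 0 || iu >= nx || iv < 0 || iv >= nz) continue;
      tal[iu + (size_t)iv * nx + (size_t)a * nx * nz] +=
          w * std::exp(-L) * pw;
    }
  };

  for (long ph = 0; ph < n; ++ph) {
    // emission voxel by inverse CDF, uniform position within the voxel
    const double r = unif_rand() * tot;
    size_t lo = 0, hi = nvox - 1;
    while (lo < hi) { const size_t mid = (lo + hi) / 2; if (cdf[mid] < r) lo = mid + 1; else hi = mid; }
    const size_t v0 = lo;
    const int ix = (int)(v0 % nx), iy = (int)((v0 / nx) % ny), iz = (int)(v0 / ((size_t)nx * ny));
    double px = ix + unif_rand() - 0.5;
    double py = iy + unif_rand() - 0.5;
    double pz = iz + unif_rand() - 0.5;
    double E = (unif_rand() < p171) ? 171.0 : 245.0;
    double w = W;

    // isotropic initial direction
    double cz = 2.0 * unif_rand() - 1.0;
    double phi = 2.0 * M_PI * unif_rand();
    double st = std::sqrt(1.0 - cz * cz);
    double dx = st * std::cos(phi), dy = st * std::sin(phi), dz = cz;
    // last emission/scatter vertex: analog tallies bin by this position,
    // matching the ray the analytic model assigns the photon to
    double lvx = px, lvy = py, lvz = pz;

    if (mode == 0) forced_score(px, py, pz, E, w);
    if (mode == 0 && !scatter) continue;

    int orders = 0;
    while (true) {
      // Woodcock free path (mm -> voxel units)
      const double s = -std::log(unif_rand()) / mumax / voxsize;
      const double ox_ = px, oy_ = py, oz_ = pz;
      px += dx * s; py += dy * s; pz += dz * s;
      if (px < -0.5 || px >= nx - 0.5 || py < -0.5 || py >= ny - 0.5 ||
          pz < -0.5 || pz >= nz - 0.5) {
        // escaped: clip the position back to the grid boundary so the
        // analog tally bins at the exit point, not the overshoot point
        double tmin = s;
        if (dx > 0) tmin = std::min(tmin, (nx - 0.5 - 1e-9 - ox_) / dx);
        else if (dx < 0) tmin = std::min(tmin, (-0.5 - ox_) / dx);
        if (dy > 0) tmin = std::min(tmin, (ny - 0.5 - 1e-9 - oy_) / dy);
        else if (dy < 0) tmin = std::min(tmin, (-0.5 - oy_) / dy);
        if (dz > 0) tmin = std::min(tmin, (nz - 0.5 - 1e-9 - oz_) / dz);
        else if (dz < 0) tmin = std::min(tmin, (-0.5 - oz_) / dz);
        if (tmin < 0) tmin = 0;
        px = ox_ + dx * tmin; py = oy_ + dy * tmin; pz = oz_ + dz * tmin;
        if (mode == 1) {
          const double pw = pw_of(E);
          if (pw > 0.0) {
            for (int a = 0; a < na; ++a) {
              const double cdet = -sa[a] * dx + ca[a] * dy;
              if (cdet < cos_acc) continue;
              const double di = ca[a] * (lvx - cx) + sa[a] * (lvy - cy);
              const int iu = (int)std::lround(cx + di);
              const int iv = (int)std::lround(lvz);
              if (iu < 0 || iu >= nx || iv < 0 || iv >= nz) continue;
              tal[iu + (size_t)iv * nx + (size_t)a * nx * nz] +=
                  w * pw / omega_frac;
            }
          }
        }
        break;
      }
      const int vx = (int)std::lround(px), vy = (int)std::lround(py),
                vz = (int)std::lround(pz);
      const size_t vid = vx + (size_t)vy * nx + (size_t)vz * nx * ny;
      const double tE = energy_t(E);
      const double muh = mu_at(REAL(mu171)[vid], REAL(mu245)[vid], tE);
      if (unif_rand() * mumax > muh) continue; // virtual interaction
      lvx = px; lvy = py; lvz = pz;            // real interaction vertex
      if (!scatter) {
        if (mode == 1) break; // analog, scatter off: interaction = absorption
        break;
      }
      // real interaction: Compton scatter with survival biasing (forced
      // mode) or analog absorption (analog mode)
      if (mode == 1) {
        if (unif_rand() > compton_fraction) break; // absorbed
      } else {
        w *= compton_fraction;
      }
      if (++orders > max_orders) break;
      const double alpha = E / 511.0;
      const double knn = knorm_of(E); // mean of kn_f over cos; 4pi*pdf = f/knn
      // scattered forced scoring: the scattered energy depends on the
      // deflection angle toward each detector, so it is computed per angle
      if (mode == 0) {
        for (int a = 0; a < na; ++a) {
          const double cdet = -sa[a] * dx + ca[a] * dy;
          const double dfac = kn_f(cdet, alpha) / knn;
          if (dfac <= 0.0) continue;
          const double Edet = compton_energy(E, cdet);
          const double pw = wlut(Edet);
          if (pw <= 0.0) continue;
          const double tEd = energy_t(Edet);
          const double di = ca[a] * (px - cx) + sa[a] * (py - cy);
          const double dj = -sa[a] * (px - cx) + ca[a] * (py - cy);
          const double uf = cx + di, jf = cy + dj;
          const double l171 = trilin(L171.data() + nvox * a, nx, ny, nz, uf, jf, pz);
          const double l245 = trilin(L245.data() + nvox * a, nx, ny, nz, uf, jf, pz);
          const double L = (1.0 - tEd) * l171 + tEd * l245;
          double ub = uf, vb = pz;
          if (cdr) {
            double d = orbit_mm[a] - dj * voxsize;
            if (d < 0) d = 0;
            const double sig = (fwhm0 + slope * d) * FWHM_TO_SIGMA / voxsize;
            ub += sig * norm_rand();
            vb += sig * norm_rand();
          }
          const int iu = (int)std::lround(ub), iv = (int)std::lround(vb);
          if (iu < 0 || iu >= nx || iv < 0 || iv >= nz) continue;
          tal[iu + (size_t)iv * nx + (size_t)a * nx * nz] +=
              w * dfac * std::exp(-L) * pw;
        }
      }
      // sample the actual scattered direction and energy
      const double cost = kn_sample(alpha);
      const double Enew = compton_energy(E, cost);
      const double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
      const double aphi = 2.0 * M_PI * unif_rand();
      // rotate (dx,dy,dz) by (cost, aphi)
      double ux, uy, uz;
      if (std::fabs(dz) < 0.99) { ux = -dy; uy = dx; uz = 0.0; }
      else { ux = 1.0; uy = 0.0; uz = 0.0; }
      double un = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= un; uy /= un; uz /= un;
      const double wx = dy * uz - dz * uy, wy = dz * ux - dx * uz,
                   wz = dx * uy - dy * ux;
      const double ndx = cost * dx + sint * (std::cos(aphi) * ux + std::sin(aphi) * wx);
      const double ndy = cost * dy + sint * (std::cos(aphi) * uy + std::sin(aphi) * wy);
      const double ndz = cost * dz + sint * (std::cos(aphi) * uz + std::sin(aphi) * wz);
      dx = ndx; dy = ndy; dz = ndz;
      E = Enew;
      if (E < 50.0) break; // below any window reach; terminate history
      // Russian roulette on low weights (forced mode keeps unbiasedness)
      if (mode == 0 && w < 1e-4 * W) {
        if (unif_rand() < 0.5) w *= 2.0; else break;
      }
    }
  }
  sino.attr("dim") = IntegerVector::create(nx, nz, na);
  return sino;
}
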