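#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Confined random walk in a cylindrical channel: pre-drawn Gaussian
// increments are applied sequentially; transverse (x, y) excursions beyond
// the channel radius are folded back by reflecting the radial coordinate at
// the wall (specular no-flux boundary); z is unbounded.
// [[Rcpp::export]]
NumericMatrix cpp_reflect_walk(double x0, double y0, double z0,
                               NumericVector dx, NumericVector dy,
                               NumericVector dz, double radius) {
  int n = dx.size();
  NumericMatrix out(n, 3);
  double x = x0, y = y0, z = z0;
  for (int i = 0; i < n; ++i) {
    x += dx[i];
    y += dy[i];
    z += dz[i];
    double r = std::sqrt(x * x + y * y);
    // fold the radial coordinate at r = radius (repeat for pathological steps)
    int guard = 0;
    while (r > radius && guard < 64) {
      double rr = 2.0 * radius - r;
      if (rr < 0) rr = -rr;
      if (r > 0) {
        x *= rr / r;
        y *= rr / r;
      }
      r = std::sqrt(x * x + y * y);
      ++guard;
    }
    out(i, 0) = x;
    out(i, 1) = y;
    out(i, 2) = z;
  }
  return out;
}

static inline double airy_lookup(const std::vector<double> &tab,
                                 double r_px, double dr, double rmax) {
  if (r_px >= rmax) return 0.0;
  double u = r_px / dr;
  int i = (int)u;
  double f = u - i;
  if (i + 1 >= (int)tab.size()) return tab.back();
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// Render a chunk of camera frames. Each exposure substep deposits an Airy
// point-spread function (peak-normalized) at its (x, z) pixel position,
// scaled by `weight` counts. Noise model: Poisson shot noise on the signal,
// Gaussian read noise, a constant offset at the camera noise floor, integer
// quantization and clipping at saturation. Uses R's RNG (seed-reproducible).
//
// frame_of: 1-based frame index per substep (into 1..nframes of this chunk)
// x_px, z_px: substep positions in local pixel coordinates (0-based)
// weight: counts contributed by this substep at the PSF peak
// [[Rcpp::export]]
IntegerVector cpp_render_frames(IntegerVector frame_of,
                                NumericVector x_px, NumericVector z_px,
                                NumericVector weight,
                                int nx, int nz, int nframes,
                                double v_per_px, double stamp_radius,
                                double noise_floor, double read_noise,
                                double saturation, bool noise) {
  IntegerVector out(nx * (R_xlen_t)nz * nframes);
  std::vector<double> signal((size_t)nx * nz, 0.0);
  // radial lookup table for the Airy intensity (2 J1(v)/v)^2
  double dr = 0.01;
  int ntab = (int)std::ceil(stamp_radius / dr) + 2;
  std::vector<double> tab(ntab);
  for (int i = 0; i < ntab; ++i) {
    double v = v_per_px * (i * dr);
    if (v < 1e-8) {
      tab[i] = 1.0;
    } else {
      double a = 2.0 * R::bessel_j(v, 1.0) / v;
      tab[i] = a * a;
    }
  }
  int hw = (int)std::ceil(stamp_radius);
  int ns = frame_of.size();
  int pos = 0;
  for (int f = 0; f < nframes; ++f) {
    std::fill(signal.begin(), signal.end(), 0.0);
    while (pos < ns && frame_of[pos] == f + 1) {
      double xc = x_px[pos], zc = z_px[pos], w = weight[pos];
      int i0 = std::max(0, (int)std::floor(xc) - hw);
      int i1 = std::min(nx - 1, (int)std::ceil(xc) + hw);
      int j0 = std::max(0, (int)std::floor(zc) - hw);
      int j1 = std::min(nz - 1, (int)std::ceil(zc) + hw);
      for (int j = j0; j <= j1; ++j) {
        double dzp = j - zc;
        for (int i = i0; i <= i1; ++i) {
          double dxp = i - xc;
          double r = std::sqrt(dxp * dxp + dzp * dzp);
          if (r < stamp_radius)
            signal[(size_t)j * nx + i] += w * airy_lookup(tab, r, dr, stamp_radius);
        }
      }
      ++pos;
    }
    R_xlen_t base = (R_xlen_t)f * nx * nz;
    for (size_t p = 0; p < (size_t)nx * nz; ++p) {
      double val;
      if (noise) {
        double s = signal[p] > 0 ? R::rpois(signal[p]) : 0.0;
        val = noise_floor + s + R::rnorm(0.0, read_noise);
      } else {
        val = noise_floor + signal[p];
      }
      val = std::floor(val + 0.5);
      if (val < 0) val = 0;
      if (val > saturation) val = saturation;
      out[base + p] = (int)val;
    }
  }
  return out;
}

// Locate the brightest diffraction-limited spots in each frame of a chunk.
// Background = per-frame median; candidates = pixels above
// background + thresh_sigma * MAD (or an absolute threshold), refined by an
// iterated centroid over a circular mask. Saturated spots are flagged.
// Returns one row per detection: frame (1-based), x_px, z_px, mass,
// background, saturated(0/1).
// [[Rcpp::export]]
NumericMatrix cpp_locate_frames(IntegerVector frames, int nx, int nz,
                                int nframes, double mask_radius,
                                double abs_threshold, double thresh_sigma,
                                int max_spots, int iters, double saturation) {
  std::vector<double> rows;
  std::vector<double> buf((size_t)nx * nz);
  std::vector<double> work((size_t)nx * nz);
  int mr = (int)std::ceil(mask_radius);
  for (int f = 0; f < nframes; ++f) {
    R_xlen_t base = (R_xlen_t)f * nx * nz;
    for (size_t p = 0; p < (size_t)nx * nz; ++p) buf[p] = frames[base + p];
    // median background and MAD noise scale
    work = buf;
    size_t mid = work.size() / 2;
    std::nth_element(work.begin(), work.begin() + mid, work.end());
    double bg = work[mid];
    for (size_t p = 0; p < work.size(); ++p) work[p] = std::fabs(buf[p] - bg);
    std::nth_element(work.begin(), work.begin() + mid, work.end());
    double mad = 1.4826 * work[mid];
    double thr = R_finite(abs_threshold) ? abs_threshold
                                         : bg + thresh_sigma * std::max(mad, 1.0);
    for (int s = 0; s < max_spots; ++s) {
      // global maximum of the residual image
      double best = -1.0;
      int bi = 0, bj = 0;
      for (int j = 0; j < nz; ++j)
        for (int i = 0; i < nx; ++i) {
          double v = buf[(size_t)j * nx + i];
          if (v > best) { best = v; bi = i; bj = j; }
        }
      if (best < thr) break;
      // iterated centroid of (value - bg)+ inside the circular mask
      double xc = bi, zc = bj;
      bool sat = false;
      double mass = 0.0;
      for (int it = 0; it < iters; ++it) {
        double sw = 0.0, sx = 0.0, sz = 0.0;
        int i0 = std::max(0, (int)std::floor(xc) - mr);
        int i1 = std::min(nx - 1, (int)std::ceil(xc) + mr);
        int j0 = std::max(0, (int)std::floor(zc) - mr);
        int j1 = std::min(nz - 1, (int)std::ceil(zc) + mr);
        sat = false;
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            double dxp = i - xc, dzp = j - zc;
            if (dxp * dxp + dzp * dzp > mask_radius * mask_radius) continue;
            double raw = buf[(size_t)j * nx + i];
            if (raw >= saturation) sat = true;
            double w = raw - bg;
            if (w <= 0) continue;
            sw += w;
            sx += w * i;
            sz += w * j;
          }
        if (sw <= 0) break;
        xc = sx / sw;
        zc = sz / sw;
        mass = sw;
      }
      rows.push_back(f + 1);
      rows.push_back(xc);
      rows.push_back(zc);
      rows.push_back(mass);
      rows.push_back(bg);
      rows.push_back(sat ? 1.0 : 0.0);
      // suppress this spot before searching for the next
      int i0 = std::max(0, (int)std::floor(xc) - 2 * mr);
      int i1 = std::min(nx - 1, (int)std::ceil(xc) + 2 * mr);
      int j0 = std::max(0, (int)std::floor(zc) - 2 * mr);
      int j1 = std::min(nz - 1, (int)std::ceil(zc) + 2 * mr);
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          buf[(size_t)j * nx + i] = bg;
    }
  }
  int nrow = rows.size() / 6;
  NumericMatrix out(nrow, 6);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < 6; ++c) out(r, c) = rows[(size_t)r * 6 + c];
  return out;
}
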