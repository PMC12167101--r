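#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline int refl(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// Canny edge detector: Gaussian smoothing (sigma 1, 5x5), Sobel gradients,
// non-maximum suppression along the quantized gradient direction, and
// double-threshold hysteresis (8-connected). Thresholds apply to the L2
// Sobel magnitude of a 0-255 image.
// [[Rcpp::export]]
IntegerMatrix canny_cpp(NumericMatrix img, double low, double high) {
  const int nr = img.nrow(), nc = img.ncol();

  // 5x5 Gaussian, sigma = 1 (separable)
  static const double g[5] = {0.054488684549642945, 0.24420134200323332,
                              0.4026199468942474, 0.24420134200323332,
                              0.054488684549642945};
  NumericMatrix tmp(nr, nc), sm(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int k = -2; k <= 2; ++k) s += g[k + 2] * img(refl(i + k, nr), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0;
      for (int k = -2; k <= 2; ++k) s += g[k + 2] * tmp(i, refl(j + k, nc));
      sm(i, j) = s;
    }

  // Sobel; x = column direction, y = row direction (increasing downward)
  NumericMatrix gx(nr, nc), gy(nr, nc), mag(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int im = refl(i - 1, nr), ip = refl(i + 1, nr);
      const int jm = refl(j - 1, nc), jp = refl(j + 1, nc);
      const double sx = (sm(im, jp) + 2 * sm(i, jp) + sm(ip, jp)) -
                        (sm(im, jm) + 2 * sm(i, jm) + sm(ip, jm));
      const double sy = (sm(ip, jm) + 2 * sm(ip, j) + sm(ip, jp)) -
                        (sm(im, jm) + 2 * sm(im, j) + sm(im, jp));
      gx(i, j) = sx;
      gy(i, j) = sy;
      mag(i, j) = std::sqrt(sx * sx + sy * sy);
    }
  }

  // non-maximum suppression, gradient direction quantized to 4 sectors
  IntegerMatrix nms(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double m = mag(i, j);
      if (m < low) continue;
      double ang = std::atan2(gy(i, j), gx(i, j)) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      int di1, dj1;
      if (ang < 22.5 || ang >= 157.5) { di1 = 0; dj1 = 1; }        // horizontal gradient
      else if (ang < 67.5)            { di1 = 1; dj1 = 1; }        // diagonal
      else if (ang < 112.5)           { di1 = 1; dj1 = 0; }        // vertical gradient
      else                            { di1 = 1; dj1 = -1; }       // anti-diagonal
      const double m1 = mag(refl(i + di1, nr), refl(j + dj1, nc));
      const double m2 = mag(refl(i - di1, nr), refl(j - dj1, nc));
      if (m >= m1 && m >= m2) nms(i, j) = (m >= high) ? 2 : 1;     // 2 strong, 1 weak
    }
  }

  // hysteresis: keep weak pixels 8-connected to a strong pixel
  IntegerMatrix edges(nr, nc);
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (nms(i, j) == 2 && !edges(i, j)) {
        edges(i, j) = 1;
        stack.push_back(std::make_pair(i, j));
        while (!stack.empty()) {
          const int ci = stack.back().first, cj = stack.back().second;
          stack.pop_back();
          for (int a = -1; a <= 1; ++a)
            for (int b = -1; b <= 1; ++b) {
              const int ni = ci + a, nj = cj + b;
              if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
              if (nms(ni, nj) >= 1 && !edges(ni, nj)) {
                edges(ni, nj) = 1;
                stack.push_back(std::make_pair(ni, nj));
              }
            }
        }
      }
  return edges;
}

// principal (total-least-squares) direction of a pixel subset
static void pca_dir(const std::vector<double>& ex,
                    const std::vector<double>& ey,
                    const std::vector<int>& pts, double& vx, double& vy) {
  double mx = 0, my = 0;
  for (size_t q = 0; q < pts.size(); ++q) { mx += ex[pts[q]]; my += ey[pts[q]]; }
  mx /= pts.size(); my /= pts.size();
  double sxx = 0, syy = 0, sxy = 0;
  for (size_t q = 0; q < pts.size(); ++q) {
    const double ux = ex[pts[q]] - mx, uy = ey[pts[q]] - my;
    sxx += ux * ux; syy += uy * uy; sxy += ux * uy;
  }
  const double half = 0.5 * std::atan2(2.0 * sxy, sxx - syy);
  vx = std::cos(half);
  vy = std::sin(half);
}

// Deterministic Hough line-segment extraction. Edge pixels vote in a
// (rho, theta) accumulator (theta in [0, 180) deg, normal parameterization
// rho = x cos t + y sin t with x = column, y = row, both 0-based). Every
// cell reaching vote_threshold is expanded back into its voting pixels,
// which are sorted along the line direction and split into runs wherever
// consecutive projections gap by more than max_gap; runs at least
// min_line_length long (Euclidean endpoint distance) become segments.
// Columns of the returned matrix:
//   rho, theta_deg (normal angle), votes, x1, y1, x2, y2, length, angle_deg
// where angle_deg is the segment direction measured from the image
// horizontal, sign increasing counter-clockwise on screen (y axis down),
// folded to (-90, 90].
// [[Rcpp::export]]
NumericMatrix hough_segments_cpp(IntegerMatrix edges, double rho_res,
                                 double theta_res, int vote_threshold,
                                 double min_len, double max_gap) {
  const int nr = edges.nrow(), nc = edges.ncol();
  std::vector<double> ex, ey;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (edges(i, j)) { ex.push_back((double)j); ey.push_back((double)i); }
  const int npts = (int)ex.size();

  const int ntheta = std::max(1, (int)std::floor(180.0 / theta_res + 0.5));
  const double diag = std::sqrt((double)nr * nr + (double)nc * nc);
  const int nrho = 2 * (int)std::ceil(diag / rho_res) + 1;
  const int rho0 = (nrho - 1) / 2;  // index of rho = 0

  std::vector<double> ct(ntheta), st(ntheta);
  for (int t = 0; t < ntheta; ++t) {
    const double th = t * theta_res * M_PI / 180.0;
    ct[t] = std::cos(th);
    st[t] = std::sin(th);
  }

  std::vector<int> acc((size_t)ntheta * nrho, 0);
  std::vector<char> alive(npts, 1);
  for (int p = 0; p < npts; ++p)
    for (int t = 0; t < ntheta; ++t) {
      const double rho = ex[p] * ct[t] + ey[p] * st[t];
      const int ri = rho0 + (int)std::floor(rho / rho_res + 0.5);
      acc[(size_t)t * nrho + ri]++;
    }

  // progressive extraction: repeatedly take the strongest cell (ties to
  // the lowest theta, then lowest rho), pull out the edge pixels in a
  // one-pixel corridor around its line, emit the long-enough runs, and
  // retract the removed pixels' votes so one physical edge cannot
  // resurface as quantized staircase sub-segments.
  std::vector<double> rows;  // flat, 9 values per segment
  std::vector<int> idx;
  std::vector<double> proj;
  for (;;) {
    int best = -1, bt = -1, bri = -1;
    for (int t = 0; t < ntheta; ++t)
      for (int ri = 0; ri < nrho; ++ri) {
        const int v = acc[(size_t)t * nrho + ri];
        if (v > best) { best = v; bt = t; bri = ri; }
      }
    if (best < vote_threshold) break;
    const int votes = best;
    const double rho_c = (bri - rho0) * rho_res;
    const double corridor = rho_res;  // half-width for pixel gathering

    idx.clear();
    proj.clear();
    for (int p = 0; p < npts; ++p) {
      if (!alive[p]) continue;
      const double rho = ex[p] * ct[bt] + ey[p] * st[bt];
      if (std::fabs(rho - rho_c) <= corridor) {
        idx.push_back(p);
        proj.push_back(-ex[p] * st[bt] + ey[p] * ct[bt]);
      }
    }
    const int m = (int)idx.size();
    if (m == 0) break;  // should not happen; guards against stalling

    std::vector<int> ord(m);
    for (int k = 0; k < m; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return proj[a] < proj[b]; });
    int run_start = 0;
    for (int k = 1; k <= m; ++k) {
      const bool split =
          (k == m) || (proj[ord[k]] - proj[ord[k - 1]] > max_gap);
      if (!split) continue;
      const int p1 = idx[ord[run_start]], p2 = idx[ord[k - 1]];
      const double dx = ex[p2] - ex[p1], dy = ey[p2] - ey[p1];
      const double len = std::sqrt(dx * dx + dy * dy);
      if (len >= min_len) {
        // total-least-squares direction of the run's pixels: robust to
        // the corridor clipping the staircase chain asymmetrically,
        // which would bias an endpoint-based angle toward the cell angle
        std::vector<int> run;
        for (int q = run_start; q < k; ++q) run.push_back(idx[ord[q]]);
        double vx, vy;
        pca_dir(ex, ey, run, vx, vy);
        if (vx * dx + vy * dy < 0) { vx = -vx; vy = -vy; }

        // one refinement pass: re-gather alive pixels in a corridor
        // aligned with the fitted direction (the cell's quantized angle
        // can clip the chain at up to half a resolution step of tilt),
        // restricted to the run's own extent, then refit
        double mx = 0, my = 0;
        for (size_t q = 0; q < run.size(); ++q) {
          mx += ex[run[q]]; my += ey[run[q]];
        }
        mx /= run.size(); my /= run.size();
        double tmin = R_PosInf, tmax = R_NegInf;
        for (size_t q = 0; q < run.size(); ++q) {
          const double tq = (ex[run[q]] - mx) * vx + (ey[run[q]] - my) * vy;
          if (tq < tmin) tmin = tq;
          if (tq > tmax) tmax = tq;
        }
        std::vector<int> ref;
        for (int p = 0; p < npts; ++p) {
          if (!alive[p]) continue;
          const double tx = ex[p] - mx, ty = ey[p] - my;
          const double tq = tx * vx + ty * vy;
          const double pq = -tx * vy + ty * vx;
          if (tq >= tmin - 1.5 && tq <= tmax + 1.5 &&
              std::fabs(pq) <= 1.5 * rho_res)
            ref.push_back(p);
        }
        if (ref.size() >= run.size()) {
          double rvx, rvy;
          pca_dir(ex, ey, ref, rvx, rvy);
          if (rvx * vx + rvy * vy < 0) { rvx = -rvx; rvy = -rvy; }
          vx = rvx; vy = rvy;
          run = ref;
        }

        // endpoints and length from the extreme pixels along the axis
        int pa = run[0], pb = run[0];
        double ta = R_PosInf, tb2 = R_NegInf;
        for (size_t q = 0; q < run.size(); ++q) {
          const double tq = (ex[run[q]] - mx) * vx + (ey[run[q]] - my) * vy;
          if (tq < ta) { ta = tq; pa = run[q]; }
          if (tq > tb2) { tb2 = tq; pb = run[q]; }
        }
        const double rdx = ex[pb] - ex[pa], rdy = ey[pb] - ey[pa];
        const double rlen = std::sqrt(rdx * rdx + rdy * rdy);
        double ang = std::atan2(-vy, vx) * 180.0 / M_PI;  // y axis down
        if (ang <= -90.0) ang += 180.0;
        if (ang > 90.0) ang -= 180.0;
        rows.push_back(rho_c);
        rows.push_back(bt * theta_res);
        rows.push_back((double)votes);
        rows.push_back(ex[pa]); rows.push_back(ey[pa]);
        rows.push_back(ex[pb]); rows.push_back(ey[pb]);
        rows.push_back(rlen);
        rows.push_back(ang);
        // retract the refined pixel set as well
        for (size_t q = 0; q < run.size(); ++q) {
          const int p = run[q];
          if (!alive[p]) continue;
          alive[p] = 0;
          for (int t = 0; t < ntheta; ++t) {
            const double rho = ex[p] * ct[t] + ey[p] * st[t];
            const int ri2 = rho0 + (int)std::floor(rho / rho_res + 0.5);
            acc[(size_t)t * nrho + ri2]--;
          }
        }
      }
      run_start = k;
    }

    // retract all gathered pixels (long and short runs alike)
    for (int k = 0; k < m; ++k) {
      const int p = idx[k];
      if (!alive[p]) continue;
      alive[p] = 0;
      for (int t = 0; t < ntheta; ++t) {
        const double rho = ex[p] * ct[t] + ey[p] * st[t];
        const int ri = rho0 + (int)std::floor(rho / rho_res + 0.5);
        acc[(size_t)t * nrho + ri]--;
      }
    }
  }

  const int nseg = (int)rows.size() / 9;
  NumericMatrix out(nseg, 9);
  for (int s = 0; s < nseg; ++s)
    for (int c = 0; c < 9; ++c) out(s, c) = rows[(size_t)s * 9 + c];
  colnames(out) = CharacterVector::create("rho", "theta", "votes", "x1", "y1",
                                          "x2", "y2", "length", "angle");
  return out;
}
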