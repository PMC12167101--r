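#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exhaustive stride-1 sliding-window mean-squared-error template search.
// Templates are visited in list order; within a template, window positions
// are scanned in row-major order (top-left row by row). The global best is
// updated only on a strict MSE improvement, so ties resolve to the first
// placement encountered in (template, position) order. A coarse pre-pass
// (prepass_stride) plus partial-sum early abort prunes provably worse
// windows without ever changing the result: a window is abandoned only when
// its accumulated squared error already strictly exceeds the best complete
// MSE seen (scaled by this template's pixel count). Squared errors are
// accumulated column-major within the window.
// Returns 1-based template index and 1-based (x, y) of the window's
// top-left corner, or index 0 when no template fits anywhere.
// [[Rcpp::export]]
List match_template_cpp(NumericMatrix image, List templates,
                        int prepass_stride) {
  const int H = image.nrow(), W = image.ncol();
  double best_mse = R_PosInf;   // strict-improvement incumbent
  double bound = R_PosInf;      // tightest known achievable MSE
  int best_t = -1, best_x = -1, best_y = -1;

  const double* im = REAL(image);

  for (int t = 0; t < templates.size(); ++t) {
    NumericMatrix tpl = templates[t];
    const int h = tpl.nrow(), w = tpl.ncol();
    if (h > H || w > W) continue;
    const double npix = (double)h * (double)w;
    const double* tp = REAL(tpl);

    // The abort cap is inflated by a hair: the bound round-trips through
    // an MSE division and a multiplication by npix, which can round just
    // below the SSE it came from and would otherwise prune the optimum
    // itself. Windows completing under the inflated cap still pass
    // through the strict comparison, so the result is unchanged.
    const double cap_slack = 1.0 + 1e-12;

    // pre-pass: tighten the abort bound with a sparse grid of windows
    // (itself abort-pruned; only the bound value is kept, never a position)
    if (prepass_stride > 1) {
      for (int y0 = 0; y0 <= H - h; y0 += prepass_stride) {
        for (int x0 = 0; x0 <= W - w; x0 += prepass_stride) {
          const double cap = bound * npix * cap_slack + 1e-9;
          double sse = 0.0;
          for (int j = 0; j < w; ++j) {
            const double* ic = im + (size_t)(x0 + j) * H + y0;
            const double* tc = tp + (size_t)j * h;
            for (int i = 0; i < h; ++i) {
              const double d = ic[i] - tc[i];
              sse += d * d;
            }
            if (sse > cap) { sse = R_PosInf; break; }
          }
          if (sse / npix < bound) bound = sse / npix;
        }
      }
    }

    double sse_cap = std::min(bound, best_mse) * npix * cap_slack + 1e-9;
    for (int y0 = 0; y0 <= H - h; ++y0) {
      for (int x0 = 0; x0 <= W - w; ++x0) {
        double sse = 0.0;
        bool aborted = false;
        for (int j = 0; j < w && !aborted; ++j) {
          const double* ic = im + (size_t)(x0 + j) * H + y0;
          const double* tc = tp + (size_t)j * h;
          int i = 0;
          while (i < h) {
            const int stop = std::min(h, i + 16);
            for (; i < stop; ++i) {
              const double d = ic[i] - tc[i];
              sse += d * d;
            }
            if (sse > sse_cap) { aborted = true; break; }
          }
        }
        if (aborted) continue;
        const double mse = sse / npix;
        if (mse < best_mse) {
          best_mse = mse;
          best_t = t;
          best_x = x0;
          best_y = y0;
          if (mse < bound) bound = mse;
          sse_cap = std::min(bound, best_mse) * npix * cap_slack + 1e-9;
        }
      }
    }
  }

  return List::create(_["template"] = best_t + 1, _["x"] = best_x + 1,
                      _["y"] = best_y + 1, _["mse"] = best_mse);
}

// Plain mean squared error between two equal-sized windows, accumulated
// column-major like R's sum().
// [[Rcpp::export]]
double mse_cpp(NumericMatrix a, NumericMatrix b) {
  double sse = 0.0;
  const int n = a.nrow() * a.ncol();
  for (int k = 0; k < n; ++k) {
    const double d = a[k] - b[k];
    sse += d * d;
  }
  return sse / (double)n;
}
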