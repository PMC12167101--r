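#include <Rcpp.h>
using namespace Rcpp;

// reflect-101 style boundary: mirror without repeating the border pixel twice
// would need n >= 2; plain mirror (repeat border) is used so n >= 1 works.
static inline int reflect_idx(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// Edge-preserving bilateral filter on a 2-D intensity matrix (0-255 scale).
// Weights combine a spatial Gaussian (sigma_space, pixels) with an intensity
// Gaussian (sigma_color, intensity units); borders use reflect padding.
// [[Rcpp::export]]
NumericMatrix bilateral_cpp(NumericMatrix img, int d,
                            double sigma_color, double sigma_space) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = d / 2;
  NumericMatrix out(nr, nc);

  // precompute spatial kernel
  NumericMatrix sk(d, d);
  const double ss2 = 2.0 * sigma_space * sigma_space;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      sk(a + r, b + r) = std::exp(-(double)(a * a + b * b) / ss2);

  // intensity kernel as a lookup table on |dI| in 0.25-intensity steps
  // (quantization error is negligible against sigma_color >= 1)
  const double sc2 = 2.0 * sigma_color * sigma_color;
  const double lut_step = 0.25;
  const int lut_n = (int)(512.0 / lut_step) + 2;
  std::vector<double> lut(lut_n);
  for (int k = 0; k < lut_n; ++k) {
    const double dI = k * lut_step;
    lut[k] = std::exp(-(dI * dI) / sc2);
  }

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double c = img(i, j);
      double wsum = 0.0, vsum = 0.0;
      for (int b = -r; b <= r; ++b) {
        const int jj = reflect_idx(j + b, nc);
        const double* col = &img(0, jj);
        const double* skc = &sk(0, b + r);
        for (int a = -r; a <= r; ++a) {
          const int ii = reflect_idx(i + a, nr);
          const double v = col[ii];
          const int k = (int)(std::abs(v - c) / lut_step + 0.5);
          const double w = skc[a + r] * lut[k];
          wsum += w;
          vsum += w * v;
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}
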