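#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

//' Separable Gaussian blur with reflected boundaries
//'
//' @param img numeric matrix
//' @param sigma Gaussian sigma in pixels
//' @return blurred matrix of the same size
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix gauss_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;

  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };

  NumericMatrix tmp(H, W), out(H, W);
  // rows (blur along y)
  for (int c = 0; c < W; ++c)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * img(reflect(i + d, H), c);
      tmp(i, c) = acc;
    }
  // cols (blur along x)
  for (int c = 0; c < W; ++c)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, reflect(c + d, W));
      out(i, c) = acc;
    }
  return out;
}
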