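// Small image primitives on the package's hot paths: affine warping for
// augmentation, summed-area tables for window filters, and bag extraction.

#include <Rcpp.h>
using namespace Rcpp;

// Affine warp of an image (bilinear) and its mask (nearest), in one pass.
// The forward map is y = A x + off on (row, col) coordinates (1-based);
// the warp inverts it per output pixel. Out-of-frame samples are zero.
// [[Rcpp::export]]
List warp_affine_cpp(NumericVector img, NumericMatrix mask, NumericMatrix A,
                     NumericVector off) {
  IntegerVector dims = img.attr("dim");
  const int h = dims[0], w = dims[1], nc = dims[2];
  const double det = A(0, 0) * A(1, 1) - A(0, 1) * A(1, 0);
  const double i00 = A(1, 1) / det, i01 = -A(0, 1) / det;
  const double i10 = -A(1, 0) / det, i11 = A(0, 0) / det;
  const double o0 = off[0], o1 = off[1];

  NumericVector out(img.size());
  out.attr("dim") = dims;
  NumericMatrix mout(h, w);
  const double* src = img.begin();
  const double* msk = mask.begin();
  double* dst = out.begin();
  double* mo = mout.begin();
  const int plane = h * w;

  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      const double yr = (i + 1) - o0, yc = (j + 1) - o1;
      const double xr = i00 * yr + i01 * yc - 1.0;  // back to 0-based
      const double xc = i10 * yr + i11 * yc - 1.0;
      const int r0 = static_cast<int>(std::floor(xr));
      const int c0 = static_cast<int>(std::floor(xc));
      // nearest-neighbour for the mask
      const int rn = static_cast<int>(std::lround(xr));
      const int cn = static_cast<int>(std::lround(xc));
      if (rn >= 0 && rn < h && cn >= 0 && cn < w) {
        mo[i + h * j] = msk[rn + h * cn];
      }
      if (r0 < -1 || r0 >= h || c0 < -1 || c0 >= w) continue;
      const double fr = xr - r0, fc = xc - c0;
      const int r1 = r0 + 1, c1 = c0 + 1;
      const bool ok00 = r0 >= 0 && c0 >= 0;
      const bool ok01 = r0 >= 0 && c1 < w;
      const bool ok10 = r1 < h && c0 >= 0;
      const bool ok11 = r1 < h && c1 < w;
      const double w00 = (1 - fr) * (1 - fc), w01 = (1 - fr) * fc;
      const double w10 = fr * (1 - fc), w11 = fr * fc;
      for (int ch = 0; ch < nc; ++ch) {
        const double* p = src + ch * plane;
        double v = 0.0;
        if (ok00) v += w00 * p[r0 + h * c0];
        if (ok01) v += w01 * p[r0 + h * c1];
        if (ok10) v += w10 * p[r1 + h * c0];
        if (ok11) v += w11 * p[r1 + h * c1];
        dst[i + h * j + ch * plane] = v;
      }
    }
  }
  return List::create(Named("image") = out, Named("mask") = mout);
}

// Summed-area table with a zero top row/left column, so the sum over rows
// r..r+d-1, cols c..c+d-1 (1-based) is S[r+d,c+d]-S[r,c+d]-S[r+d,c]+S[r,c].
// [[Rcpp::export]]
NumericMatrix sat_cpp(NumericMatrix m) {
  const int h = m.nrow(), w = m.ncol();
  NumericMatrix S(h + 1, w + 1);
  const double* mp = m.begin();
  double* sp = S.begin();
  const int sh = h + 1;
  for (int j = 0; j < w; ++j) {
    const double* mc = mp + static_cast<size_t>(j) * h;
    const double* prev = sp + static_cast<size_t>(j) * sh;
    double* cur = sp + static_cast<size_t>(j + 1) * sh;
    double colsum = 0.0;
    for (int i = 0; i < h; ++i) {
      colsum += mc[i];
      cur[i + 1] = prev[i + 1] + colsum;
    }
  }
  return S;
}

// Copy the d x d windows at the given 1-based origins into a d x d x C x K
// array.
// [[Rcpp::export]]
NumericVector extract_windows_cpp(NumericVector img, IntegerVector row0,
                                  IntegerVector col0, int d) {
  IntegerVector dims = img.attr("dim");
  const int h = dims[0], nc = dims[2];
  const int K = row0.size();
  const int plane = h * dims[1];
  NumericVector out(static_cast<R_xlen_t>(d) * d * nc * K);
  out.attr("dim") = IntegerVector::create(d, d, nc, K);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int k = 0; k < K; ++k) {
    const int r0 = row0[k] - 1, c0 = col0[k] - 1;
    for (int ch = 0; ch < nc; ++ch) {
      const double* p = src + ch * plane;
      double* q = dst + (static_cast<R_xlen_t>(k) * nc + ch) * d * d;
      for (int j = 0; j < d; ++j) {
        std::copy(p + r0 + h * (c0 + j), p + r0 + d + h * (c0 + j),
                  q + j * d);
      }
    }
  }
  return out;
}

// Photometric jitter in one pass: contrast about mid-gray, brightness
// offset, saturation scaling about the per-pixel luminance, hue rotation
// about the gray axis (3x3 matrix R), clipping to [0,1], and re-zeroing
// outside the mask.
// [[Rcpp::export]]
NumericVector photometric_cpp(NumericVector img, NumericMatrix mask,
                              double brightness, double contrast,
                              double saturation, NumericMatrix R) {
  IntegerVector dims = img.attr("dim");
  const int h = dims[0], w = dims[1];
  const int plane = h * w;
  NumericVector out(img.size());
  out.attr("dim") = dims;
  const double* s = img.begin();
  const double* mk = mask.begin();
  double* o = out.begin();
  const double cg = 1.0 + contrast, sg = 1.0 + saturation;
  const double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  const double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  const double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  for (int p = 0; p < plane; ++p) {
    if (mk[p] == 0) continue;
    double r = (s[p] - 0.5) * cg + 0.5 + brightness;
    double g = (s[p + plane] - 0.5) * cg + 0.5 + brightness;
    double b = (s[p + 2 * plane] - 0.5) * cg + 0.5 + brightness;
    const double lum = (r + g + b) / 3.0;
    r = lum + sg * (r - lum);
    g = lum + sg * (g - lum);
    b = lum + sg * (b - lum);
    const double r2 = r00 * r + r01 * g + r02 * b;
    const double g2 = r10 * r + r11 * g + r12 * b;
    const double b2 = r20 * r + r21 * g + r22 * b;
    o[p] = std::min(std::max(r2, 0.0), 1.0);
    o[p + plane] = std::min(std::max(g2, 0.0), 1.0);
    o[p + 2 * plane] = std::min(std::max(b2, 0.0), 1.0);
  }
  return out;
}

// Unpack an 8-bit raw array back to doubles in [0, 1] (value / 255).
// [[Rcpp::export]]
NumericVector unpack_raw_cpp(RawVector r) {
  NumericVector out(r.size());
  const Rbyte* s = r.begin();
  double* o = out.begin();
  const R_xlen_t n = r.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = s[i] / 255.0;
  out.attr("dim") = r.attr("dim");
  return out;
}
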