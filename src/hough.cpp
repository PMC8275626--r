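// Gradient-direction circle Hough voting.
//
// Each edge pixel votes, for every candidate radius, for the two centre
// candidates lying at distance r along +/- its gradient direction (the
// retina disk is bright inside, so the sign of the gradient at its rim is
// not assumed).  Votes are accumulated on a 2-px binned grid per radius and
// the best (score, radius, centre) peak over all radii is returned; final
// sub-pixel refinement is done by a least-squares circle fit on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List hough_vote_cpp(NumericVector er, NumericVector ec, NumericVector gr,
                    NumericVector gc, NumericVector radii, int nrow,
                    int ncol) {
  const int ne = er.size(), nr = radii.size();
  const int bin = 2;
  const int br = nrow / bin + 1, bc = ncol / bin + 1;

  double best_votes = -1.0;
  double best_r = NA_REAL, best_cr = NA_REAL, best_cc = NA_REAL;

  std::vector<int> acc(static_cast<size_t>(br) * bc);
  for (int ri = 0; ri < nr; ++ri) {
    std::fill(acc.begin(), acc.end(), 0);
    const double r = radii[ri];
    for (int e = 0; e < ne; ++e) {
      for (int s = -1; s <= 1; s += 2) {
        const double cr = er[e] + s * r * gr[e];
        const double cc = ec[e] + s * r * gc[e];
        const int bi = static_cast<int>(cr / bin + 0.5);
        const int bj = static_cast<int>(cc / bin + 0.5);
        if (bi < 0 || bi >= br || bj < 0 || bj >= bc) continue;
        ++acc[static_cast<size_t>(bj) * br + bi];
      }
    }
    // per-radius peak of the 3x3 bin neighbourhood (only around bins that
    // received direct votes), normalised by in-frame circumference
    int peak_v = 0, peak_bi = -1, peak_bj = -1;
    for (int bj = 1; bj + 1 < bc; ++bj) {
      for (int bi = 1; bi + 1 < br; ++bi) {
        if (acc[static_cast<size_t>(bj) * br + bi] == 0) continue;
        int v = 0;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di)
            v += acc[static_cast<size_t>(bj + dj) * br + bi + di];
        if (v > peak_v) {
          peak_v = v;
          peak_bi = bi;
          peak_bj = bj;
        }
      }
    }
    if (peak_v == 0) continue;
    const double cr = peak_bi * bin, cc = peak_bj * bin;
    int inb = 0;
    for (int a = 0; a < 72; ++a) {
      const double th = a * (2.0 * M_PI / 72.0);
      const double pr = cr + r * std::sin(th), pc = cc + r * std::cos(th);
      if (pr >= 0 && pr < nrow && pc >= 0 && pc < ncol) ++inb;
    }
    if (inb == 0) continue;
    const double arc = 2.0 * M_PI * r * (inb / 72.0);
    const double score = peak_v / arc;
    if (score > best_votes) {
      best_votes = score;
      best_r = r;
      best_cr = cr;
      best_cc = cc;
    }
  }
  return List::create(Named("score") = best_votes, Named("radius") = best_r,
                      Named("center_row") = best_cr,
                      Named("center_col") = best_cc);
}

// Add per-window attention weights onto an accumulator image and count the
// number of windows covering each pixel.  Origins are 1-based.
// [[Rcpp::export]]
List accumulate_windows_cpp(NumericMatrix acc, IntegerMatrix cov,
                            IntegerVector row0, IntegerVector col0,
                            NumericVector alpha, int d) {
  const int n = row0.size();
  for (int k = 0; k < n; ++k) {
    const int r0 = row0[k] - 1, c0 = col0[k] - 1;
    const double a = alpha[k];
    for (int j = c0; j < c0 + d; ++j)
      for (int i = r0; i < r0 + d; ++i) {
        acc(i, j) += a;
        cov(i, j) += 1;
      }
  }
  return List::create(Named("acc") = acc, Named("cov") = cov);
}
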