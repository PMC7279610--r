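// Moving-window GLCM engine.
//
// For each valid center pixel, gathers the ordered gray-level pairs of the
// four unit-distance directions (0, 45, 90, 135 degrees; each pair counted
// in both orders, i.e. symmetric accumulation) within the window, skipping
// pairs that touch an invalid pixel, and computes the eight Haralick
// statistics directly from the sparse pair counts. A dense Ng*Ng scratch
// array with a touched-cell list keeps the per-window cost proportional to
// the number of pairs, not Ng^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int OFF_R[4] = {0, -1, -1, -1};
static const int OFF_C[4] = {1, 1, 0, -1};

// [[Rcpp::export]]
NumericVector glcm_window_stack(IntegerMatrix levels, LogicalMatrix valid,
                                int window, int ng, int min_pairs) {
  const int nr = levels.nrow(), nc = levels.ncol();
  const int half = window / 2;
  const int nstat = 8;

  NumericVector out(Dimension(nr, nc, nstat));
  std::fill(out.begin(), out.end(), NA_REAL);

  std::vector<double> cnt((size_t)ng * ng, 0.0);   // ordered-pair counts
  std::vector<double> marg(ng, 0.0);               // row marginal
  std::vector<int> touched;                        // codes with cnt > 0
  std::vector<int> mlev;                           // levels with marg > 0
  touched.reserve(4 * window * window);
  mlev.reserve(2 * window);

  const R_xlen_t plane = (R_xlen_t)nr * nc;

  for (int cc = 0; cc < nc; ++cc) {
    for (int cr = 0; cr < nr; ++cr) {
      if (!valid(cr, cc)) continue;

      const int r0 = std::max(0, cr - half), r1 = std::min(nr - 1, cr + half);
      const int c0 = std::max(0, cc - half), c1 = std::min(nc - 1, cc + half);

      int n_pairs = 0;
      for (int j = c0; j <= c1; ++j) {
        for (int i = r0; i <= r1; ++i) {
          if (!valid(i, j)) continue;
          const int a = levels(i, j);
          if (a == NA_INTEGER) continue;
          for (int o = 0; o < 4; ++o) {
            const int i2 = i + OFF_R[o], j2 = j + OFF_C[o];
            if (i2 < r0 || i2 > r1 || j2 < c0 || j2 > c1) continue;
            if (!valid(i2, j2)) continue;
            const int b = levels(i2, j2);
            if (b == NA_INTEGER) continue;
            const int code1 = a * ng + b, code2 = b * ng + a;
            if (cnt[code1] == 0.0) touched.push_back(code1);
            if (code2 == code1) {
              cnt[code1] += 2.0;  // diagonal: pair and its reverse coincide
            } else {
              cnt[code1] += 1.0;
              if (cnt[code2] == 0.0) touched.push_back(code2);
              cnt[code2] += 1.0;
            }
            ++n_pairs;
          }
        }
      }

      if (n_pairs >= min_pairs && n_pairs > 0) {
        const double tot = 2.0 * n_pairs;  // ordered-pair total
        double entropy = 0.0, second = 0.0, contrast = 0.0, dissim = 0.0,
               homog = 0.0;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int code = touched[t];
          const double p = cnt[code] / tot;
          const int a = code / ng, b = code % ng;
          const double d = (double)(a - b);
          entropy -= p * std::log(p);
          second += p * p;
          contrast += d * d * p;
          dissim += std::fabs(d) * p;
          homog += p / (1.0 + d * d);
          if (marg[a] == 0.0) mlev.push_back(a);
          marg[a] += p;
        }
        double mu = 0.0;
        for (size_t t = 0; t < mlev.size(); ++t)
          mu += mlev[t] * marg[mlev[t]];
        double sigma2 = 0.0;
        for (size_t t = 0; t < mlev.size(); ++t)
          sigma2 += (mlev[t] - mu) * (mlev[t] - mu) * marg[mlev[t]];
        double corr_num = 0.0;
        for (size_t t = 0; t < touched.size(); ++t) {
          const int code = touched[t];
          const double p = cnt[code] / tot;
          corr_num += ((code / ng) - mu) * ((code % ng) - mu) * p;
        }
        const double corr = sigma2 > 0.0 ? corr_num / sigma2 : NA_REAL;

        const R_xlen_t base = (R_xlen_t)cc * nr + cr;
        out[base + 0 * plane] = entropy;
        out[base + 1 * plane] = second;
        out[base + 2 * plane] = contrast;
        out[base + 3 * plane] = corr;
        out[base + 4 * plane] = sigma2;
        out[base + 5 * plane] = homog;
        out[base + 6 * plane] = mu;
        out[base + 7 * plane] = dissim;
      }

      for (size_t t = 0; t < touched.size(); ++t) cnt[touched[t]] = 0.0;
      touched.clear();
      for (size_t t = 0; t < mlev.size(); ++t) marg[mlev[t]] = 0.0;
      mlev.clear();
    }
  }
  return out;
}
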