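#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Distance-truncated Gaussian Bernoulli edge sampling.
// Returns a 2-column integer matrix of (pre, post) indices (1-based) into
// the supplied position vectors.  Uses R's RNG so results follow set.seed.
// Candidate pairs are found with a uniform grid of bucket size `cutoff`,
// so the cost is proportional to the number of pairs within the cutoff.
// [[Rcpp::export]]
IntegerMatrix sample_gaussian_edges_cpp(NumericVector pre_x, NumericVector pre_y,
                                        NumericVector post_x, NumericVector post_y,
                                        double peak, double sigma, double cutoff,
                                        bool same_population) {
  const int n_pre = pre_x.size(), n_post = post_x.size();
  const double c2 = cutoff * cutoff, inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double xmin = R_PosInf, ymin = R_PosInf;
  for (int i = 0; i < n_pre; ++i) {
    xmin = std::min(xmin, pre_x[i]);
    ymin = std::min(ymin, pre_y[i]);
  }
  double xmax = R_NegInf, ymax = R_NegInf;
  for (int i = 0; i < n_pre; ++i) {
    xmax = std::max(xmax, pre_x[i]);
    ymax = std::max(ymax, pre_y[i]);
  }
  const int nbx = std::max(1, (int)((xmax - xmin) / cutoff) + 1);
  const int nby = std::max(1, (int)((ymax - ymin) / cutoff) + 1);
  std::vector< std::vector<int> > bucket((size_t)nbx * nby);
  for (int i = 0; i < n_pre; ++i) {
    int bx = std::min(nbx - 1, std::max(0, (int)((pre_x[i] - xmin) / cutoff)));
    int by = std::min(nby - 1, std::max(0, (int)((pre_y[i] - ymin) / cutoff)));
    bucket[(size_t)by * nbx + bx].push_back(i);
  }
  std::vector<int> epre, epost;
  epre.reserve(n_post * 8);
  epost.reserve(n_post * 8);
  RNGScope scope;
  for (int j = 0; j < n_post; ++j) {
    int bx = (int)((post_x[j] - xmin) / cutoff);
    int by = (int)((post_y[j] - ymin) / cutoff);
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = by + dy;
      if (yy < 0 || yy >= nby) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = bx + dx;
        if (xx < 0 || xx >= nbx) continue;
        const std::vector<int>& cell = bucket[(size_t)yy * nbx + xx];
        for (size_t k = 0; k < cell.size(); ++k) {
          int i = cell[k];
          if (same_population && i == j) continue;
          double ddx = pre_x[i] - post_x[j], ddy = pre_y[i] - post_y[j];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 > c2) continue;
          if (unif_rand() < peak * std::exp(-d2 * inv2s2)) {
            epre.push_back(i + 1);
            epost.push_back(j + 1);
          }
        }
      }
    }
  }
  IntegerMatrix out(epre.size(), 2);
  for (size_t k = 0; k < epre.size(); ++k) {
    out(k, 0) = epre[k];
    out(k, 1) = epost[k];
  }
  colnames(out) = CharacterVector::create("pre", "post");
  return out;
}
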