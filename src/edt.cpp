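#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Euclidean distance transform of a label image with nearest-site
// tracking (Felzenszwalb-Huttenlocher lower-envelope transform).  For every
// pixel returns the squared distance (in pixels) to the nearest labelled
// (non-zero) pixel and the label of that pixel.  Used for Voronoi-constrained
// expansion of nucleus labels into whole-cell territories.
//
// [[Rcpp::export]]
List edt_nearest_label(IntegerMatrix lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  const double INF = 1e30;

  NumericMatrix d2(nr, nc);   // squared distance after column pass
  IntegerMatrix srow(nr, nc); // row of nearest labelled pixel in same column

  // pass 1: per column, 1-D distance to nearest labelled pixel
  for (int c = 0; c < nc; ++c) {
    int sr = -1;
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) > 0) sr = r;
      if (sr >= 0) {
        double d = (double)(r - sr);
        d2(r, c) = d * d;
      } else {
        d2(r, c) = INF;
      }
      srow(r, c) = sr;
    }
    sr = -1;
    for (int r = nr - 1; r >= 0; --r) {
      if (lab(r, c) > 0) sr = r;
      if (sr >= 0) {
        double d = (double)(sr - r);
        if (d * d < d2(r, c)) {
          d2(r, c) = d * d;
          srow(r, c) = sr;
        }
      }
    }
  }

  NumericMatrix dist2(nr, nc);
  IntegerMatrix nearest(nr, nc); // label of nearest site, 0 if none

  // pass 2: per row, lower envelope of parabolas over columns
  std::vector<int> v(nc);      // columns of parabolas in envelope
  std::vector<double> z(nc + 1); // envelope breakpoints
  for (int r = 0; r < nr; ++r) {
    int k = -1;
    for (int q = 0; q < nc; ++q) {
      double fq = d2(r, q);
      if (fq >= INF) continue;
      if (k < 0) {
        k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
        continue;
      }
      double s;
      while (true) {
        int p = v[k];
        s = ((fq + (double)q * q) - (d2(r, p) + (double)p * p)) /
            (2.0 * (q - p));
        if (s <= z[k]) { --k; if (k < 0) break; } else break;
      }
      ++k;
      v[k] = q;
      z[k] = (k == 0) ? -INF : s;
      z[k + 1] = INF;
    }
    if (k < 0) { // no labelled pixel anywhere
      for (int c = 0; c < nc; ++c) { dist2(r, c) = INF; nearest(r, c) = 0; }
      continue;
    }
    int j = 0;
    for (int c = 0; c < nc; ++c) {
      while (z[j + 1] < (double)c) ++j;
      int p = v[j];
      double dc = (double)(c - p);
      dist2(r, c) = dc * dc + d2(r, p);
      nearest(r, c) = lab(srow(r, p), p);
    }
  }

  return List::create(_["dist2"] = dist2, _["label"] = nearest);
}
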