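#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Connected-component labelling of a binary mask.
// Components are numbered 1..K in raster-scan order (column-major storage,
// but raster order means row-major visual order: row 1 left-to-right, ...).
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (nr == 0 || nc == 0) return lab;
  const int ndir = (connectivity == 4) ? 4 : 8;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next_id = 0;
  std::vector<int> stack;
  // raster order: rows outer, cols inner
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_id;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next_id;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int rr = cr + dr[d], cch = cc + dc[d];
          if (rr < 0 || rr >= nr || cch < 0 || cch >= nc) continue;
          if (mask(rr, cch) && lab(rr, cch) == 0) {
            lab(rr, cch) = next_id;
            stack.push_back(rr + cch * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
// f: input squared distances; d: output; n: length. Integer-valued doubles
// stay exact (all quantities < 2^53), so cross-object ties compare exactly.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance transform to the pixels where seed != 0.
static void edt_sq(const std::vector<char>& seed, int nr, int nc,
                   std::vector<double>& out) {
  const double INF = 1e30; // larger than any attainable squared distance
  out.assign((size_t)nr * nc, INF);
  for (size_t i = 0; i < seed.size(); ++i) if (seed[i]) out[i] = 0.0;
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);
  // transform along columns (within each column, over rows)
  for (int c = 0; c < nc; ++c) {
    double* col = &out[(size_t)c * nr];
    for (int r = 0; r < nr; ++r) f[r] = col[r];
    dt1d(f.data(), d.data(), nr, v, z);
    for (int r = 0; r < nr; ++r) col[r] = d[r];
  }
  // then along rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out[(size_t)c * nr + r];
    dt1d(f.data(), d.data(), nc, v, z);
    for (int c = 0; c < nc; ++c) out[(size_t)c * nr + r] = d[c];
  }
}

// Discrete Voronoi tessellation of a label map: every pixel is assigned the
// id of the object whose nearest pixel (Euclidean, pixel centres) is closest;
// ties go to the lowest object id. Pixels farther than max_distance keep 0.
// Returns list(assign = integer matrix, distance = double matrix).
// [[Rcpp::export]]
List cpp_voronoi(const IntegerMatrix& labels, const IntegerVector& ids,
                 double max_distance) {
  const int nr = labels.nrow(), nc = labels.ncol();
  const size_t n = (size_t)nr * nc;
  IntegerMatrix assign(nr, nc);
  NumericMatrix dist(nr, nc);
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<int> who(n, 0);
  std::vector<char> seed(n);
  std::vector<double> dsq;
  // ids ascending => strict '<' keeps the lowest id on exact ties
  IntegerVector ids_sorted = clone(ids).sort();
  for (int k = 0; k < ids_sorted.size(); ++k) {
    const int id = ids_sorted[k];
    bool any = false;
    for (size_t i = 0; i < n; ++i) {
      seed[i] = (labels[i] == id);
      any = any || seed[i];
    }
    if (!any) continue;
    edt_sq(seed, nr, nc, dsq);
    for (size_t i = 0; i < n; ++i) {
      if (dsq[i] < best[i]) { best[i] = dsq[i]; who[i] = id; }
    }
  }
  const bool limited = R_finite(max_distance);
  const double md_sq = limited ? max_distance * max_distance : 0.0;
  for (size_t i = 0; i < n; ++i) {
    double d = std::sqrt(best[i]);
    if (limited && best[i] > md_sq) { assign[i] = 0; dist[i] = d; }
    else { assign[i] = who[i]; dist[i] = d; }
  }
  return List::create(_["assign"] = assign, _["distance"] = dist);
}
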