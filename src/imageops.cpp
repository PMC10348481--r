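#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Two-pass connected-component labelling with union-find.
// `mask` is a logical matrix; `connectivity` is 4 or 8.
// Returns an integer matrix with 0 for background and labels 1..n
// assigned in raster-scan order of first encounter (deterministic).

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously visited neighbours under a column-major scan:
      // (i-1,j) in this column; (i-1,j-1),(i,j-1),(i+1,j-1) in the previous
      int ni4[4] = { i - 1, i - 1, i,     i + 1 };
      int nj4[4] = { j,     j - 1, j - 1, j - 1 };
      bool use[4] = { true, connectivity == 8, true, connectivity == 8 };
      int best = 0, seen[4], ns = 0;
      for (int k = 0; k < 4; ++k) {
        if (!use[k]) continue;
        int a = ni4[k], b = nj4[k];
        if (a < 0 || a >= nr || b < 0 || b >= nc) continue;
        int l = lab(a, b);
        if (l > 0) { seen[ns++] = l; if (best == 0 || l < best) best = l; }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
        for (int k = 0; k < ns; ++k) uf_union(parent, best, seen[k]);
      }
    }
  }

  // flatten and renumber in order of first appearance
  std::vector<int> newlab(next, 0);
  int out = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (newlab[r] == 0) newlab[r] = ++out;
      lab(i, j) = newlab[r];
    }
  lab.attr("n") = out;
  return lab;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012):
// squared distance from every pixel to the nearest `false` pixel of `mask`.
// Returned distances are in pixel units (not squared).

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
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

// [[Rcpp::export(name = ".edt")]]
NumericMatrix edt(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d2(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) d2(i, j) = d[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d2(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) d2(i, j) = d[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) d2(i, j) = std::sqrt(d2(i, j));
  return d2;
}
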