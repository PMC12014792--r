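#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving
static inline int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labeling of a binary matrix.
// connectivity: 4 (edge neighbors) or 8 (edge + diagonal).
// Labels are renumbered 1..N in raster order (row-major) of each
// component's first pixel; background stays 0.
// [[Rcpp::export]]
IntegerMatrix cc_label(const IntegerMatrix& bin, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;

  // first pass: raster scan (row-major), look at already-visited neighbors
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (bin(r, c) == 0) continue;
      int best = -1;
      int nbr[4][2] = { {r, c - 1}, {r - 1, c - 1}, {r - 1, c}, {r - 1, c + 1} };
      int from = (connectivity == 8) ? 0 : 0;
      for (int k = from; k < 4; ++k) {
        if (connectivity == 4 && (k == 1 || k == 3)) continue;
        int rr = nbr[k][0], cc = nbr[k][1];
        if (rr < 0 || cc < 0 || cc >= nc) continue;
        if (bin(rr, cc) == 0) continue;
        int l = lab(rr, cc) - 1;
        if (best < 0) best = l;
        else uf_union(parent, best, l);
      }
      if (best < 0) {
        parent.push_back(next);
        lab(r, c) = ++next;
      } else {
        lab(r, c) = uf_find(parent, best) + 1;
      }
    }
  }

  // second pass: resolve equivalences, renumber in raster order of first pixel
  std::vector<int> newlab(next, 0);
  int nfinal = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (lab(r, c) == 0) continue;
      int root = uf_find(parent, lab(r, c) - 1);
      if (newlab[root] == 0) newlab[root] = ++nfinal;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}

// Per-label pixel count and centroid (0-based row/col means).
// [[Rcpp::export]]
List cc_stats(const IntegerMatrix& lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  int n = 0;
  for (int i = 0; i < nr * nc; ++i) n = std::max(n, lab[i]);
  IntegerVector size(n);
  NumericVector rsum(n), csum(n);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0) {
        ++size[l - 1];
        rsum[l - 1] += r;
        csum[l - 1] += c;
      }
    }
  for (int k = 0; k < n; ++k) {
    rsum[k] /= size[k];
    csum[k] /= size[k];
  }
  return List::create(_["size_px"] = size,
                      _["centroid_row"] = rsum,
                      _["centroid_col"] = csum);
}
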