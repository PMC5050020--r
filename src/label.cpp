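#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling of a logical matrix.
// Labels are assigned in raster (column-major) order of first contact and
// renumbered 1..k so results are deterministic for a given mask.

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

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background, self-parent

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int up   = (i > 0)          ? lab(i - 1, j) : 0;
      int left = (j > 0)          ? lab(i, j - 1) : 0;
      int ul = 0, ll = 0;
      if (connectivity == 8 && j > 0) {
        if (i > 0)      ul = lab(i - 1, j - 1);
        if (i < nr - 1) ll = lab(i + 1, j - 1);
      }
      int neigh[4] = {up, left, ul, ll};
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (neigh[k] > 0 && (lmin == 0 || neigh[k] < lmin)) lmin = neigh[k];
      if (lmin == 0) {
        int lnew = (int) parent.size();
        parent.push_back(lnew);
        lab(i, j) = lnew;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k)
          if (neigh[k] > 0 && neigh[k] != lmin)
            uf_union(parent, neigh[k], lmin);
      }
    }
  }

  // Resolve equivalences and renumber compactly in first-appearance order.
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++next;
      lab(i, j) = remap[root];
    }
  lab.attr("n_objects") = next;
  return lab;
}
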