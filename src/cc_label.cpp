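#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// union-find with path compression
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Two-pass connected-component labelling.
//'
//' Labels foreground pixels of a logical matrix under 4- or 8-connectivity.
//' Labels are contiguous integers from 1, assigned in raster order of the
//' first pixel of each component.
//'
//' @param mask logical matrix
//' @param connectivity 4 or 8
//' @return integer matrix of labels (0 = background)
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 unused
  int next = 1;

  // neighbours already visited in raster order (column-major as stored):
  // we scan column by column, row by row within column.
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      int nb[4][2] = {{i - 1, j}, {i, j - 1}, {i - 1, j - 1}, {i + 1, j - 1}};
      int nnb = (connectivity == 4) ? 2 : 4;
      std::vector<int> seen;
      for (int k = 0; k < nnb; ++k) {
        int ii = nb[k][0], jj = nb[k][1];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          seen.push_back(l);
          if (best == 0 || l < best) best = l;
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
        for (size_t k = 0; k < seen.size(); ++k) uf_union(parent, best, seen[k]);
      }
    }
  }

  // resolve equivalences and compact to 1..n in raster order of first pixel
  std::vector<int> remap(parent.size(), 0);
  int nlab = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (remap[r] == 0) remap[r] = ++nlab;
      lab(i, j) = remap[r];
    }
  }
  return lab;
}

//' Pairs of labelled objects that touch or lie within a pixel gap.
//'
//' Two objects are reported iff some pixel of A and some pixel of B are
//' within `reach` steps of each other, where distance is Chebyshev under
//' 8-connectivity and Manhattan under 4-connectivity. `reach = 1` is strict
//' touching (overlap or adjacency); `reach = gap + 1` allows `gap`
//' background pixels between the objects.
//'
//' @param labA,labB integer label matrices of equal shape
//' @param reach positive integer pixel reach
//' @param connectivity 4 or 8
//' @return two-column integer matrix of (label in A, label in B) pairs
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix touching_pairs(IntegerMatrix labA, IntegerMatrix labB,
                             int reach, int connectivity) {
  if (labA.nrow() != labB.nrow() || labA.ncol() != labB.ncol())
    stop("label images must share one shape");
  if (reach < 0) stop("reach must be >= 0");
  const int nr = labA.nrow(), nc = labA.ncol();
  std::set<std::pair<int, int> > pairs;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int a = labA(i, j);
      if (a == 0) continue;
      for (int dj = -reach; dj <= reach; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -reach; di <= reach; ++di) {
          if (connectivity == 4 &&
              (std::abs(di) + std::abs(dj)) > reach) continue;
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          int b = labB(ii, jj);
          if (b > 0) pairs.insert(std::make_pair(a, b));
        }
      }
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  int k = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = pairs.begin();
       it != pairs.end(); ++it, ++k) {
    out(k, 0) = it->first;
    out(k, 1) = it->second;
  }
  return out;
}
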