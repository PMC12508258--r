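#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Topographic persistences of all summits of an image (8-connectivity):
// descending-intensity region growing; each region merge records the dying
// (lower) summit's persistence = summit - saddle level. The surviving
// global summit gets the image relief. Plateaus yield one summit.
// [[Rcpp::export(name = ".maxima_persistences_cpp")]]
NumericVector maxima_persistences_cpp(NumericMatrix image) {
  const int h = image.nrow(), w = image.ncol(), n = h * w;
  const double *v = REAL(image);
  double vmin = *std::min_element(v, v + n);
  double vmax = *std::max_element(v, v + n);
  if (vmax == vmin) return NumericVector(0);

  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] > v[b]; });

  std::vector<int> parent(n, -1);
  std::vector<double> peak(n, 0.0);
  std::vector<double> pers;
  pers.reserve(1024);

  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};

  for (int k = 0; k < n; ++k) {
    int p = ord[k];
    int r = p % h, c = p / h;
    parent[p] = p;
    peak[p] = v[p];
    for (int d = 0; d < 8; ++d) {
      int nr = r + dr[d], nc = c + dc[d];
      if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
      int q = nc * h + nr;
      if (parent[q] < 0) continue;
      int ra = uf_find(parent, p);
      int rb = uf_find(parent, q);
      if (ra == rb) continue;
      if (peak[ra] < peak[rb]) std::swap(ra, rb);
      pers.push_back(peak[rb] - v[p]);
      parent[rb] = ra;
    }
  }
  pers.push_back(vmax - vmin);
  return wrap(pers);
}
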