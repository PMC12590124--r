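#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a logical matrix under 4- or 8-neighbor
// adjacency. Returns an integer matrix with 0 for background and 1..K for
// cluster membership.
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, bool diagonal) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(64);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = diagonal ? dr8 : dr4;
  const int* dc = diagonal ? dc8 : dc4;
  const int nd = diagonal ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int d = 0; d < nd; ++d) {
          int ni = ci + dr[d], nj = cj + dc[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Maximum absolute cluster mass (sum of the statistic over a connected
// suprathreshold region, positive and negative regions separately) of a
// statistic matrix. Used in the permutation loop where only the maximum is
// needed.
// [[Rcpp::export]]
double max_cluster_mass(const NumericMatrix& stat, double threshold,
                        bool diagonal) {
  const int nr = stat.nrow(), nc = stat.ncol();
  std::vector<char> visited(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  stack.reserve(64);
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1}, dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = diagonal ? dr8 : dr4;
  const int* dc = diagonal ? dc8 : dc4;
  const int nd = diagonal ? 8 : 4;
  double best = 0.0;
  for (int sgn = 0; sgn < 2; ++sgn) {
    std::fill(visited.begin(), visited.end(), 0);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double v0 = sgn ? -stat(i, j) : stat(i, j);
        size_t off = static_cast<size_t>(i) + static_cast<size_t>(j) * nr;
        if (ISNAN(v0) || v0 <= threshold || visited[off]) continue;
        double mass = 0.0;
        stack.clear();
        stack.push_back(i + j * nr);
        visited[off] = 1;
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int ci = idx % nr, cj = idx / nr;
          mass += sgn ? -stat(ci, cj) : stat(ci, cj);
          for (int d = 0; d < nd; ++d) {
            int ni = ci + dr[d], nj = cj + dc[d];
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            double v = sgn ? -stat(ni, nj) : stat(ni, nj);
            size_t noff = static_cast<size_t>(ni) + static_cast<size_t>(nj) * nr;
            if (!ISNAN(v) && v > threshold && !visited[noff]) {
              visited[noff] = 1;
              stack.push_back(ni + nj * nr);
            }
          }
        }
        if (mass > best) best = mass;
      }
    }
  }
  return best;
}
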