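#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling of a logical mask, labels assigned in
// row-major scan order (rows vary fastest within a column in R storage, so
// "row-major" here means the order of R's matrix indexing by [row, col]
// scanned column-by-column is NOT used; we scan rows first to honour the
// row-major contract).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Count local maxima whose prominence (peak height minus the level of the
// highest saddle joining them to a higher peak) strictly exceeds `prominence`.
// Pixels are processed from high to low intensity; ties broken by row-major
// scan order so plateaus contribute a single maximum. The globally highest
// component's prominence is its peak minus the image minimum.
struct DSU {
  std::vector<int> parent;
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
};

// [[Rcpp::export]]
int cpp_count_prominent_maxima(const NumericMatrix& img, double prominence) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  if (n == 0) return 0;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  // value descending; ties: row-major order (row varies slowest)
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    double va = img[a], vb = img[b];
    if (va != vb) return va > vb;
    int ra = a % nr, ca = a / nr, rb = b % nr, cb = b / nr;
    if (ra != rb) return ra < rb;
    return ca < cb;
  });
  DSU dsu; dsu.parent.assign(n, -1);
  std::vector<double> peak(n, 0.0);   // peak value of component root
  std::vector<char> seen(n, 0);
  int count = 0;
  double vmin = img[0];
  for (int i = 1; i < n; ++i) if (img[i] < vmin) vmin = img[i];
  const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int t = 0; t < n; ++t) {
    int i = idx[t];
    int r = i % nr, c = i / nr;
    double v = img[i];
    dsu.parent[i] = i; peak[i] = v; seen[i] = 1;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      if (!seen[j]) continue;
      int ri = dsu.find(i), rj = dsu.find(j);
      if (ri == rj) continue;
      // merge: the component with the lower peak dies at saddle level v
      int lo = (peak[ri] < peak[rj]) ? ri : rj;
      int hi = (lo == ri) ? rj : ri;
      if (peak[lo] - v > prominence) ++count;
      dsu.parent[lo] = hi;
    }
  }
  // surviving root(s): one component remains; prominence vs global minimum
  int root = dsu.find(idx[0]);
  if (peak[root] - vmin > prominence) ++count;
  return count;
}

// DBSCAN over 2-D points with Euclidean eps-neighborhoods; neighbourhood
// counts include the point itself. Grid-bucketed region queries.
// Returns integer labels: 0 = noise, clusters numbered from 1 in order of
// first core-point discovery (input order).
// [[Rcpp::export]]
IntegerVector cpp_dbscan(const NumericVector& x, const NumericVector& y,
                         double eps, int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  const double eps2 = eps * eps;
  double xmin = x[0], ymin = y[0];
  for (int i = 0; i < n; ++i) { if (x[i] < xmin) xmin = x[i]; if (y[i] < ymin) ymin = y[i]; }
  // hash grid with cell size eps
  std::vector<long long> cell(n);
  std::vector<int> order(n);
  auto cell_of = [&](double px, double py) {
    long long cx = (long long)std::floor((px - xmin) / eps);
    long long cy = (long long)std::floor((py - ymin) / eps);
    return cx * 2000003LL + cy;
  };
  for (int i = 0; i < n; ++i) { cell[i] = cell_of(x[i], y[i]); order[i] = i; }
  std::sort(order.begin(), order.end(), [&](int a, int b) { return cell[a] < cell[b]; });
  std::vector<long long> ucell; std::vector<int> start;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || cell[order[t]] != cell[order[t-1]]) { ucell.push_back(cell[order[t]]); start.push_back(t); }
  }
  start.push_back(n);
  auto bucket = [&](long long key, std::vector<int>& out) {
    int lo = std::lower_bound(ucell.begin(), ucell.end(), key) - ucell.begin();
    if (lo < (int)ucell.size() && ucell[lo] == key)
      for (int t = start[lo]; t < start[lo+1]; ++t) out.push_back(order[t]);
  };
  auto region_query = [&](int i, std::vector<int>& nb) {
    nb.clear();
    long long cx = (long long)std::floor((x[i] - xmin) / eps);
    long long cy = (long long)std::floor((y[i] - ymin) / eps);
    std::vector<int> cand;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        bucket((cx + dx) * 2000003LL + (cy + dy), cand);
    for (int j : cand) {
      double ddx = x[i] - x[j], ddy = y[i] - y[j];
      if (ddx * ddx + ddy * ddy <= eps2) nb.push_back(j);
    }
    std::sort(nb.begin(), nb.end());
  };
  std::vector<char> visited(n, 0);
  int cl = 0;
  std::vector<int> nb, nb2;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    region_query(i, nb);
    if ((int)nb.size() < min_pts) continue;  // noise (may later become border)
    ++cl;
    labels[i] = cl;
    std::queue<int> seeds;
    for (int j : nb) if (j != i) seeds.push(j);
    while (!seeds.empty()) {
      int j = seeds.front(); seeds.pop();
      if (labels[j] == 0) labels[j] = cl;    // border or core joins cluster
      if (visited[j]) continue;
      visited[j] = 1;
      region_query(j, nb2);
      if ((int)nb2.size() >= min_pts)
        for (int k : nb2) if (!visited[k] || labels[k] == 0) seeds.push(k);
    }
  }
  return labels;
}
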