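#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Pixel convention throughout: x = column index, y = row index, both 1-based
// on the R side. Matrices are row-major images (nrow = height).

// [[Rcpp::export]]
LogicalMatrix cpp_stamp_disks(int nrow, int ncol, NumericVector x,
                              NumericVector y, NumericVector r) {
  LogicalMatrix out(nrow, ncol);
  int n = x.size();
  for (int k = 0; k < n; ++k) {
    double cx = x[k], cy = y[k], rad = r[k];
    if (rad < 0) rad = 0;
    int r0 = (int)std::floor(cy - rad), r1 = (int)std::ceil(cy + rad);
    int c0 = (int)std::floor(cx - rad), c1 = (int)std::ceil(cx + rad);
    if (r0 < 1) r0 = 1; if (r1 > nrow) r1 = nrow;
    if (c0 < 1) c0 = 1; if (c1 > ncol) c1 = ncol;
    double r2 = rad * rad;
    for (int i = r0; i <= r1; ++i) {
      double dy = i - cy;
      for (int j = c0; j <= c1; ++j) {
        double dx = j - cx;
        if (dx * dx + dy * dy <= r2) out(i - 1, j - 1) = true;
      }
    }
    // always mark the centre pixel so a zero-radius tail tip stays connected
    int ci = (int)std::lround(cy), cj = (int)std::lround(cx);
    if (ci >= 1 && ci <= nrow && cj >= 1 && cj <= ncol)
      out(ci - 1, cj - 1) = true;
  }
  return out;
}

// Zhang-Suen thinning to a 1-px-wide, 8-connected skeleton. The input is
// assumed to have an empty 1-px border (the R wrapper pads).
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  int h = img.nrow(), w = img.ncol();
  LogicalMatrix a = clone(img);
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int i = 1; i < h - 1; ++i) {
        for (int j = 1; j < w - 1; ++j) {
          if (!a(i, j)) continue;
          int p2 = a(i - 1, j), p3 = a(i - 1, j + 1), p4 = a(i, j + 1),
              p5 = a(i + 1, j + 1), p6 = a(i + 1, j), p7 = a(i + 1, j - 1),
              p8 = a(i, j - 1), p9 = a(i - 1, j - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int at = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                   (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                   (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                   (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (at != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        a(kill[k].first, kill[k].second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return a;
}

// 8-connected component labelling (BFS); labels 1..n in discovery order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix img) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!img(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(i + j * h);
      while (!q.empty()) {
        int v = q.front(); q.pop();
        int vi = v % h, vj = v / h;
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            int ni = vi + di, nj = vj + dj;
            if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
            if (img(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              q.push(ni + nj * h);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Dijkstra over skeleton pixels (8-neighbourhood, diagonal cost sqrt(2))
// from the skeleton pixel nearest (x0,y0) to the one nearest (x1,y1).
// Returns an n x 2 matrix of (x, y) 1-based coordinates ordered source ->
// target, or a 0-row matrix when no path exists.
// [[Rcpp::export]]
NumericMatrix cpp_skeleton_path(LogicalMatrix skel, double x0, double y0,
                                double x1, double y1) {
  int h = skel.nrow(), w = skel.ncol();
  int src = -1, dst = -1;
  double dsrc = R_PosInf, ddst = R_PosInf;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!skel(i, j)) continue;
      double dx = (j + 1) - x0, dy = (i + 1) - y0;
      double d = dx * dx + dy * dy;
      if (d < dsrc) { dsrc = d; src = i + j * h; }
      dx = (j + 1) - x1; dy = (i + 1) - y1;
      d = dx * dx + dy * dy;
      if (d < ddst) { ddst = d; dst = i + j * h; }
    }
  }
  if (src < 0 || dst < 0) return NumericMatrix(0, 2);
  std::vector<double> dist(h * w, R_PosInf);
  std::vector<int> prev(h * w, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[src] = 0; pq.push(std::make_pair(0.0, src));
  const double SQ2 = std::sqrt(2.0);
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int v = nd.second;
    if (nd.first > dist[v]) continue;
    if (v == dst) break;
    int vi = v % h, vj = v / h;
    for (int di = -1; di <= 1; ++di) {
      for (int dj = -1; dj <= 1; ++dj) {
        if (!di && !dj) continue;
        int ni = vi + di, nj = vj + dj;
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        if (!skel(ni, nj)) continue;
        int u = ni + nj * h;
        double nd2 = dist[v] + ((di && dj) ? SQ2 : 1.0);
        if (nd2 < dist[u]) {
          dist[u] = nd2; prev[u] = v;
          pq.push(std::make_pair(nd2, u));
        }
      }
    }
  }
  if (!std::isfinite(dist[dst])) return NumericMatrix(0, 2);
  std::vector<int> path;
  for (int v = dst; v != -1; v = prev[v]) path.push_back(v);
  int n = path.size();
  NumericMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    int v = path[n - 1 - k];
    out(k, 0) = v / h + 1;  // x (col)
    out(k, 1) = v % h + 1;  // y (row)
  }
  return out;
}

// Two-sided exact test on a 2 x K table conditional on both margins:
// enumerate the multivariate hypergeometric support and sum the
// probabilities of all tables no more probable than the observed one
// (with the customary 1 + 1e-7 relative slack on the comparison).
static void fisher_rec(int j, int rem, double lp,
                       const std::vector<int> &colsum,
                       const std::vector<int> &suffix,
                       double lp_obs, double &acc) {
  int K = colsum.size();
  if (j == K) {
    if (rem == 0 && lp <= lp_obs) acc += std::exp(lp);
    return;
  }
  int lo = rem - suffix[j + 1]; if (lo < 0) lo = 0;
  int hi = colsum[j] < rem ? colsum[j] : rem;
  for (int a = lo; a <= hi; ++a) {
    double lpa = lp + Rf_lchoose(colsum[j], a);
    // prune: remaining log-choose terms are <= sum lchoose(c_k, c_k/2)
    fisher_rec(j + 1, rem - a, lpa, colsum, suffix, lp_obs, acc);
  }
}

// [[Rcpp::export]]
double cpp_fisher_2xk(IntegerVector row1, IntegerVector colsum) {
  int K = colsum.size();
  std::vector<int> cs(K), suffix(K + 1, 0);
  int n = 0, r1 = 0;
  for (int j = 0; j < K; ++j) {
    cs[j] = colsum[j]; n += cs[j]; r1 += row1[j];
  }
  for (int j = K - 1; j >= 0; --j) suffix[j] = suffix[j + 1] + cs[j];
  double lden = Rf_lchoose(n, r1);
  double lp_obs = -lden;
  for (int j = 0; j < K; ++j) lp_obs += Rf_lchoose(cs[j], row1[j]);
  double acc = 0.0;
  // log-space analogue of the conventional p <= p_obs * (1 + 1e-7) rule
  fisher_rec(0, r1, -lden, cs, suffix, lp_obs + 1e-7, acc);
  double p = acc;
  if (p > 1) p = 1;
  return p;
}
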