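// Exact word-mover distance: earth-mover distance between normalized
// word-frequency distributions with cosine ground cost, solved by the
// transportation simplex (NW-corner start + MODI pivoting). Supports are
// small (documents are capped upstream), so the dense simplex is fast.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct Cell { int i, j; double x; };

// min sum c_ij x_ij  s.t.  rows sum to a, cols sum to b, x >= 0.
// a and b must have equal totals; a tiny perturbation keeps the basis
// non-degenerate.
double transport_simplex(std::vector<double> a, std::vector<double> b,
                         const arma::mat& C) {
  const int m = a.size(), n = b.size();
  if (m == 1) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += b[j] * C(0, j);
    return s;
  }
  if (n == 1) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += a[i] * C(i, 0);
    return s;
  }
  const double eps = 1e-12;
  for (int i = 0; i < m; ++i) a[i] += eps;
  b[n - 1] += m * eps;

  // north-west corner initial basis
  std::vector<Cell> basis;
  basis.reserve(m + n - 1);
  {
    int i = 0, j = 0;
    double ar = a[0], br = b[0];
    while (true) {
      double x = std::min(ar, br);
      basis.push_back({i, j, x});
      ar -= x; br -= x;
      if (i == m - 1 && j == n - 1) break;
      if (ar <= br && i < m - 1) { ++i; ar = a[i]; }
      else { ++j; br = b[j]; }
    }
  }

  std::vector<double> u(m), v(n);
  std::vector<char> useen(m), vseen(n);
  // adjacency: node ids 0..m-1 rows, m..m+n-1 cols; edge = basis index
  std::vector<std::vector<int>> adj(m + n);
  std::vector<int> parent_node(m + n), parent_edge(m + n);

  const int max_iter = 100 * (m + n) * (m + n);
  for (int iter = 0; iter < max_iter; ++iter) {
    // duals by tree traversal
    for (auto& vv : adj) vv.clear();
    for (int e = 0; e < (int)basis.size(); ++e) {
      adj[basis[e].i].push_back(e);
      adj[m + basis[e].j].push_back(e);
    }
    std::fill(useen.begin(), useen.end(), 0);
    std::fill(vseen.begin(), vseen.end(), 0);
    std::vector<int> stack = {0};
    u[0] = 0.0; useen[0] = 1;
    while (!stack.empty()) {
      int node = stack.back(); stack.pop_back();
      for (int e : adj[node]) {
        const Cell& c = basis[e];
        if (node < m) {
          if (!vseen[c.j]) {
            v[c.j] = C(c.i, c.j) - u[c.i];
            vseen[c.j] = 1;
            stack.push_back(m + c.j);
          }
        } else {
          if (!useen[c.i]) {
            u[c.i] = C(c.i, c.j) - v[c.j];
            useen[c.i] = 1;
            stack.push_back(c.i);
          }
        }
      }
    }

    // entering cell: most negative reduced cost
    int bi = -1, bj = -1;
    double best = -1e-11;
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j) {
        double r = C(i, j) - u[i] - v[j];
        if (r < best) { best = r; bi = i; bj = j; }
      }
    if (bi < 0) break;  // optimal

    // cycle: tree path from row bi to col bj
    std::fill(parent_node.begin(), parent_node.end(), -2);
    parent_node[bi] = -1;
    stack.assign(1, bi);
    while (!stack.empty()) {
      int node = stack.back(); stack.pop_back();
      if (node == m + bj) break;
      for (int e : adj[node]) {
        const Cell& c = basis[e];
        int other = (node < m) ? (m + c.j) : c.i;
        if (parent_node[other] == -2) {
          parent_node[other] = node;
          parent_edge[other] = e;
          stack.push_back(other);
        }
      }
    }
    std::vector<int> path;  // basis edge indices from bi to bj
    for (int node = m + bj; parent_node[node] != -1;
         node = parent_node[node]) {
      path.push_back(parent_edge[node]);
    }
    std::reverse(path.begin(), path.end());

    // signs alternate: entering cell is '+', first path edge (sharing row
    // bi) is '-', and so on
    double theta = std::numeric_limits<double>::infinity();
    int leave_pos = -1;
    for (size_t p = 0; p < path.size(); p += 2) {
      if (basis[path[p]].x < theta) {
        theta = basis[path[p]].x;
        leave_pos = (int)p;
      }
    }
    for (size_t p = 0; p < path.size(); ++p) {
      basis[path[p]].x += (p % 2 == 0) ? -theta : theta;
    }
    int leave_edge = path[leave_pos];
    basis[leave_edge] = {bi, bj, theta};
  }

  double cost = 0.0;
  for (const Cell& c : basis) cost += c.x * C(c.i, c.j);
  return std::max(0.0, cost);
}

// cosine ground-cost matrix between two sets of rows of the (already
// L2-normalized) embedding matrix
arma::mat cost_matrix(const arma::mat& emb, const arma::uvec& ia,
                      const arma::uvec& ib) {
  arma::mat C = 1.0 - emb.rows(ia) * emb.rows(ib).t();
  C.clamp(0.0, 2.0);
  return C;
}

}  // namespace

// [[Rcpp::export]]
double wmd_pair_cpp(const arma::uvec& idx_a, const arma::vec& w_a,
                    const arma::uvec& idx_b, const arma::vec& w_b,
                    const arma::mat& emb_norm) {
  arma::mat C = cost_matrix(emb_norm, idx_a, idx_b);
  std::vector<double> a(w_a.begin(), w_a.end());
  std::vector<double> b(w_b.begin(), w_b.end());
  return transport_simplex(a, b, C);
}

// [[Rcpp::export]]
arma::vec wmd_one_vs_many_cpp(const arma::uvec& idx_a, const arma::vec& w_a,
                              const Rcpp::List& docs_idx,
                              const Rcpp::List& docs_w,
                              const arma::mat& emb_norm) {
  const int n = docs_idx.size();
  arma::vec out(n);
  std::vector<double> a(w_a.begin(), w_a.end());
  for (int d = 0; d < n; ++d) {
    arma::uvec ib = docs_idx[d];
    arma::vec wb = docs_w[d];
    if (ib.n_elem == 0) { out[d] = arma::datum::nan; continue; }
    arma::mat C = cost_matrix(emb_norm, idx_a, ib);
    std::vector<double> b(wb.begin(), wb.end());
    out[d] = transport_simplex(a, b, C);
  }
  return out;
}

// relaxed WMD lower bound (drop one marginal constraint, take the larger
// of the two one-sided relaxations) of the query doc against every doc
// [[Rcpp::export]]
arma::vec rwmd_one_vs_many_cpp(const arma::uvec& idx_a, const arma::vec& w_a,
                               const Rcpp::List& docs_idx,
                               const Rcpp::List& docs_w,
                               const arma::mat& emb_norm) {
  const int n = docs_idx.size();
  // cost from each query word to the whole vocabulary
  arma::mat Cq = 1.0 - emb_norm.rows(idx_a) * emb_norm.t();
  Cq.clamp(0.0, 2.0);
  arma::rowvec colmin = arma::min(Cq, 0);
  arma::vec out(n);
  for (int d = 0; d < n; ++d) {
    arma::uvec ib = docs_idx[d];
    arma::vec wb = docs_w[d];
    if (ib.n_elem == 0) { out[d] = arma::datum::nan; continue; }
    arma::mat Csub = Cq.cols(ib);
    double r1 = arma::dot(w_a, arma::min(Csub, 1));
    double r2 = 0.0;
    for (arma::uword t = 0; t < ib.n_elem; ++t) r2 += wb[t] * colmin[ib[t]];
    out[d] = std::max(r1, r2);
  }
  return out;
}

// exact k-nearest-neighbour WMD query with prefetch-and-prune: exact
// transport is solved only for documents whose relaxed lower bound cannot
// rule them out of the top k. Returns the distance vector (exact where
// solved, lower bound elsewhere) plus the solved mask.
// [[Rcpp::export]]
Rcpp::List wmd_knn_cpp(const arma::uvec& idx_a, const arma::vec& w_a,
                       const Rcpp::List& docs_idx, const Rcpp::List& docs_w,
                       const arma::mat& emb_norm, int self, int k) {
  const int n = docs_idx.size();
  arma::vec lb = rwmd_one_vs_many_cpp(idx_a, w_a, docs_idx, docs_w,
                                      emb_norm);
  arma::vec dist = lb;
  std::vector<char> solved(n, 0);
  std::vector<double> a(w_a.begin(), w_a.end());
  if (self >= 0 && self < n) { dist[self] = 0.0; solved[self] = 1; }

  arma::uvec ord = arma::stable_sort_index(
      lb.replace(arma::datum::nan, arma::datum::inf));
  auto solve_one = [&](int d) {
    if (solved[d] || !arma::is_finite(lb[d])) return;
    arma::uvec ib = docs_idx[d];
    arma::vec wb = docs_w[d];
    arma::mat C = cost_matrix(emb_norm, idx_a, ib);
    std::vector<double> b(wb.begin(), wb.end());
    dist[d] = transport_simplex(a, b, C);
    solved[d] = 1;
  };

  // kth-smallest exact distance among non-self docs tracked via max-heap
  std::priority_queue<double> heap;
  auto push_exact = [&](int d) {
    if (d == self) return;
    if ((int)heap.size() < k) heap.push(dist[d]);
    else if (dist[d] < heap.top()) { heap.pop(); heap.push(dist[d]); }
  };

  int prefetch = std::min<int>(n, 2 * k + 1);
  int taken = 0;
  for (arma::uword p = 0; p < ord.n_elem && taken < prefetch; ++p) {
    int d = ord[p];
    if (!arma::is_finite(lb[d])) break;
    solve_one(d);
    push_exact(d);
    ++taken;
  }
  for (arma::uword p = 0; p < ord.n_elem; ++p) {
    int d = ord[p];
    if (!arma::is_finite(lb[d])) break;
    double thr = ((int)heap.size() >= k) ? heap.top()
                                         : arma::datum::inf;
    if (solved[d]) continue;
    if (lb[d] >= thr + 1e-12) break;  // lb sorted: nothing later can enter
    solve_one(d);
    push_exact(d);
  }
  return Rcpp::List::create(
      Rcpp::Named("dist") = dist,
      Rcpp::Named("solved") = Rcpp::LogicalVector(solved.begin(),
                                                  solved.end()));
}
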