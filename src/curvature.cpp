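// Principal-curvature estimation by local quadric fitting.
//
// For every vertex a geodesic neighbourhood is collected by a local
// Dijkstra walk over the edge graph (edge weights = Euclidean lengths),
// the neighbours are expressed in the vertex tangent frame, and a quadric
// height patch z = a x^2 + b xy + c y^2 + d x + e y is fitted by least
// squares.  k_min/k_max are the eigenvalues of the shape operator of the
// fitted patch, with the sign convention that a convex bump (surface
// curving away from the outward normal) has positive curvature.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// CSR-style vertex adjacency from a triangle list (0-based faces).
static void build_adjacency(const arma::imat& F, int nv,
                            std::vector<std::vector<int>>& adj) {
  adj.assign(nv, {});
  const arma::uword nf = F.n_rows;
  for (arma::uword f = 0; f < nf; ++f) {
    int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
}

// Area-weighted vertex normals.
static arma::mat vertex_normals(const arma::mat& V, const arma::imat& F) {
  arma::mat N(V.n_rows, 3, arma::fill::zeros);
  for (arma::uword f = 0; f < F.n_rows; ++f) {
    int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    arma::rowvec e1 = V.row(b) - V.row(a);
    arma::rowvec e2 = V.row(c) - V.row(a);
    arma::rowvec fn = arma::cross(e1, e2);  // 2 * area * unit normal
    N.row(a) += fn; N.row(b) += fn; N.row(c) += fn;
  }
  for (arma::uword i = 0; i < N.n_rows; ++i) {
    double len = arma::norm(N.row(i));
    if (len > 1e-300) N.row(i) /= len;
  }
  return N;
}

// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix V_, IntegerMatrix F_) {
  arma::mat V(V_.begin(), V_.nrow(), V_.ncol(), false);
  arma::imat F(F_.nrow(), 3);
  for (int i = 0; i < F_.nrow(); ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = F_(i, j);
  arma::mat N = vertex_normals(V, F);
  return wrap(N);
}

// Neighbourhood collection: pop vertices in increasing geodesic distance,
// stop once distance exceeds `radius` AND at least `minpts` collected.
// Hard cap keeps degenerate meshes from blowing up.
static void geodesic_patch(int src, double radius, int minpts, int maxpts,
                           const arma::mat& V,
                           const std::vector<std::vector<int>>& adj,
                           std::vector<int>& out,
                           std::vector<double>& dist_scratch,
                           std::vector<int>& touched) {
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  out.clear();
  touched.clear();
  dist_scratch[src] = 0.0;
  touched.push_back(src);
  pq.push({0.0, src});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist_scratch[u] + 1e-12) continue;
    if ((d > radius && (int)out.size() >= minpts) ||
        (int)out.size() >= maxpts) break;
    out.push_back(u);
    for (int w : adj[u]) {
      double nd = d + arma::norm(V.row(u) - V.row(w));
      if (dist_scratch[w] < 0) { touched.push_back(w); dist_scratch[w] = nd; pq.push({nd, w}); }
      else if (nd < dist_scratch[w] - 1e-12) { dist_scratch[w] = nd; pq.push({nd, w}); }
    }
  }
  for (int t : touched) dist_scratch[t] = -1.0;
}

// [[Rcpp::export]]
List cpp_quadric_curvatures(NumericMatrix V_, IntegerMatrix F_,
                            double radius, int minpts) {
  const int nv = V_.nrow();
  arma::mat V(V_.begin(), nv, 3, false);
  arma::imat F(F_.nrow(), 3);
  for (int i = 0; i < F_.nrow(); ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = F_(i, j);

  std::vector<std::vector<int>> adj;
  build_adjacency(F, nv, adj);
  arma::mat N = vertex_normals(V, F);

  NumericVector kmin(nv), kmax(nv);
  LogicalVector fallback(nv);
  std::vector<double> dist_scratch(nv, -1.0);
  std::vector<int> patch, touched;
  patch.reserve(512); touched.reserve(1024);

  for (int i = 0; i < nv; ++i) {
    if (adj[i].empty()) {  // isolated vertex
      kmin[i] = 0.0; kmax[i] = 0.0; fallback[i] = true;
      continue;
    }
    geodesic_patch(i, radius, minpts, 1000, V, adj, patch, dist_scratch, touched);
    // Cap the fit at a fixed sample count (stratified over the
    // distance-ordered patch) so the estimator has the same statistical
    // behaviour on fine and coarse meshes of the same surface.
    const int maxfit = 24;
    if ((int)patch.size() > maxfit) {
      std::vector<int> sub(maxfit);
      double step = (double)(patch.size() - 1) / (maxfit - 1);
      for (int k = 0; k < maxfit; ++k)
        sub[k] = patch[(size_t)std::lround(k * step)];
      patch.swap(sub);
    }

    arma::rowvec n = N.row(i);
    // orthonormal tangent frame
    arma::rowvec ref = (std::abs(n(0)) < 0.9) ? arma::rowvec({1, 0, 0})
                                              : arma::rowvec({0, 1, 0});
    arma::rowvec e1 = arma::normalise(arma::cross(n, ref));
    arma::rowvec e2 = arma::cross(n, e1);

    const int m = (int)patch.size();
    arma::mat A(m, 5);
    arma::vec z(m);
    // Gaussian distance weights (bandwidth = radius / 2): standard local
    // regression weighting, keeps the effective support tight around the
    // vertex while still using every collected sample
    const double bw2 = 2.0 * (radius / 2.0) * (radius / 2.0);
    for (int k = 0; k < m; ++k) {
      arma::rowvec p = V.row(patch[k]) - V.row(i);
      double x = arma::dot(p, e1), y = arma::dot(p, e2);
      double w = std::sqrt(std::exp(-(x * x + y * y) / bw2));
      A(k, 0) = w * x * x; A(k, 1) = w * x * y; A(k, 2) = w * y * y;
      A(k, 3) = w * x;     A(k, 4) = w * y;
      z(k) = w * arma::dot(p, n);
    }
    arma::vec coef;
    bool ok = m >= 5 && arma::solve(coef, A, z, arma::solve_opts::no_approx);
    if (!ok) { kmin[i] = NA_REAL; kmax[i] = NA_REAL; fallback[i] = true; continue; }
    double a = coef(0), b = coef(1), c = coef(2), d = coef(3), e = coef(4);

    // fundamental forms of z = f(x, y) at the origin, gradient (d, e)
    double w = std::sqrt(1.0 + d * d + e * e);
    arma::mat22 I1 = {{1 + d * d, d * e}, {d * e, 1 + e * e}};
    arma::mat22 II = {{2 * a / w, b / w}, {b / w, 2 * c / w}};
    arma::mat22 S = arma::solve(I1, II);
    // eigenvalues of the (similar-to-symmetric) shape operator
    double tr = S(0, 0) + S(1, 1);
    double det = S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
    double disc = tr * tr / 4.0 - det;
    if (disc < 0) disc = 0;
    double r = std::sqrt(disc);
    double l1 = tr / 2.0 - r, l2 = tr / 2.0 + r;
    // height measured along the outward normal: convex cap has negative
    // quadric coefficients, so flip to get positive-convex curvature
    double kk1 = -l2, kk2 = -l1;
    kmin[i] = std::min(kk1, kk2);
    kmax[i] = std::max(kk1, kk2);
    fallback[i] = false;
  }
  return List::create(_["k_min"] = kmin, _["k_max"] = kmax,
                      _["fallback"] = fallback);
}

// Edge-weighted geodesic ball from several seeds (brush selection core).
// [[Rcpp::export]]
IntegerVector cpp_geodesic_ball(NumericMatrix V_, IntegerMatrix F_,
                                IntegerVector seeds, double radius) {
  const int nv = V_.nrow();
  arma::mat V(V_.begin(), nv, 3, false);
  arma::imat F(F_.nrow(), 3);
  for (int i = 0; i < F_.nrow(); ++i)
    for (int j = 0; j < 3; ++j) F(i, j) = F_(i, j);
  std::vector<std::vector<int>> adj;
  build_adjacency(F, nv, adj);

  std::vector<double> dist(nv, R_PosInf);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (int s : seeds) { dist[s] = 0.0; pq.push({0.0, s}); }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u] + 1e-12 || d > radius) continue;
    for (int w : adj[u]) {
      double nd = d + arma::norm(V.row(u) - V.row(w));
      if (nd < dist[w] - 1e-12 && nd <= radius) { dist[w] = nd; pq.push({nd, w}); }
    }
  }
  std::vector<int> sel;
  for (int i = 0; i < nv; ++i) if (dist[i] <= radius) sel.push_back(i + 1);
  return wrap(sel);
}
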