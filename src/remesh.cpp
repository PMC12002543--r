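// Isotropic explicit remeshing to a target edge length, in the spirit of
// Botsch & Kobbelt (2004): repeated passes of (1) long-edge splitting with
// red/green style face templates, (2) short-edge collapsing to edge
// midpoints with link-condition and length guards, (3) tangential Laplacian
// relaxation.  Boundary vertices are never collapsed or moved, so open
// fixtures (planes, open cylinders) keep their outline.

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef std::array<int, 3> Tri;

static inline long long ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (long long)a * 0x40000000LL + b;
}

static double edge_len(const std::vector<double>& X,
                       const std::vector<double>& Y,
                       const std::vector<double>& Z, int a, int b) {
  double dx = X[a] - X[b], dy = Y[a] - Y[b], dz = Z[a] - Z[b];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
List cpp_isotropic_remesh(NumericMatrix V_, IntegerMatrix F_,
                          double target, int iters) {
  int nv = V_.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) { X[i] = V_(i, 0); Y[i] = V_(i, 1); Z[i] = V_(i, 2); }
  std::vector<Tri> faces(F_.nrow());
  for (int f = 0; f < F_.nrow(); ++f)
    faces[f] = {F_(f, 0), F_(f, 1), F_(f, 2)};

  const double hi = 4.0 / 3.0 * target;
  const double lo = 4.0 / 5.0 * target;

  for (int pass = 0; pass < iters; ++pass) {
    // ---- split long edges (template refinement, shared midpoints) ----
    {
      std::unordered_map<long long, int> midpoint;
      std::vector<Tri> out;
      out.reserve(faces.size() * 2);
      for (const Tri& t : faces) {
        int vids[3] = {t[0], t[1], t[2]};
        int mids[3];  // midpoint of edge (k, k+1), -1 if not split
        int nsplit = 0;
        for (int k = 0; k < 3; ++k) {
          int a = vids[k], b = vids[(k + 1) % 3];
          if (edge_len(X, Y, Z, a, b) > hi) {
            long long key = ekey(a, b);
            auto it = midpoint.find(key);
            int m;
            if (it == midpoint.end()) {
              m = (int)X.size();
              X.push_back(0.5 * (X[a] + X[b]));
              Y.push_back(0.5 * (Y[a] + Y[b]));
              Z.push_back(0.5 * (Z[a] + Z[b]));
              midpoint[key] = m;
            } else m = it->second;
            mids[k] = m; ++nsplit;
          } else mids[k] = -1;
        }
        if (nsplit == 0) { out.push_back(t); continue; }
        if (nsplit == 3) {
          out.push_back({vids[0], mids[0], mids[2]});
          out.push_back({vids[1], mids[1], mids[0]});
          out.push_back({vids[2], mids[2], mids[1]});
          out.push_back({mids[0], mids[1], mids[2]});
          continue;
        }
        // rotate so that edge 0 is split
        int r = 0;
        while (mids[r] == -1) ++r;
        int a = vids[r], b = vids[(r + 1) % 3], c = vids[(r + 2) % 3];
        int m0 = mids[r], m1 = mids[(r + 1) % 3], m2 = mids[(r + 2) % 3];
        if (nsplit == 1) {
          out.push_back({a, m0, c});
          out.push_back({m0, b, c});
        } else {  // two split edges: either (0,1) or (0,2) after rotation
          if (m1 != -1) {
            out.push_back({b, m1, m0});
            out.push_back({a, m0, m1});
            out.push_back({a, m1, c});
          } else {
            out.push_back({a, m0, m2});
            out.push_back({m0, b, m2});
            out.push_back({m2, b, c});
          }
        }
      }
      faces.swap(out);
      nv = (int)X.size();
    }

    // ---- adjacency and boundary flags ----
    std::vector<std::vector<int>> adj(nv);
    std::unordered_map<long long, int> ecount;
    for (const Tri& t : faces)
      for (int k = 0; k < 3; ++k) {
        int a = t[k], b = t[(k + 1) % 3];
        ecount[ekey(a, b)]++;
      }
    std::vector<char> boundary(nv, 0);
    for (auto& kv : ecount)
      if (kv.second == 1) {
        int a = (int)(kv.first / 0x40000000LL), b = (int)(kv.first % 0x40000000LL);
        boundary[a] = 1; boundary[b] = 1;
      }
    for (const Tri& t : faces)
      for (int k = 0; k < 3; ++k) {
        adj[t[k]].push_back(t[(k + 1) % 3]);
        adj[t[k]].push_back(t[(k + 2) % 3]);
      }
    for (int i = 0; i < nv; ++i) {
      std::sort(adj[i].begin(), adj[i].end());
      adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
    }

    // ---- collapse short edges ----
    {
      struct SE { double len; int a, b; };
      std::vector<SE> shorts;
      for (auto& kv : ecount) {
        int a = (int)(kv.first / 0x40000000LL), b = (int)(kv.first % 0x40000000LL);
        double L = edge_len(X, Y, Z, a, b);
        if (L < lo) shorts.push_back({L, a, b});
      }
      std::sort(shorts.begin(), shorts.end(),
                [](const SE& u, const SE& v) { return u.len < v.len; });
      std::vector<char> locked(nv, 0);
      std::vector<int> remap(nv);
      for (int i = 0; i < nv; ++i) remap[i] = i;
      for (const SE& s : shorts) {
        int a = s.a, b = s.b;
        if (locked[a] || locked[b] || boundary[a] || boundary[b]) continue;
        // link condition: common neighbours must be <= 2 (the two wings)
        int common = 0;
        {
          size_t i = 0, j = 0;
          const std::vector<int>& na = adj[a];
          const std::vector<int>& nb = adj[b];
          while (i < na.size() && j < nb.size()) {
            if (na[i] == nb[j]) { ++common; ++i; ++j; }
            else if (na[i] < nb[j]) ++i;
            else ++j;
          }
        }
        if (common > 2) continue;
        double mx = 0.5 * (X[a] + X[b]), my = 0.5 * (Y[a] + Y[b]),
               mz = 0.5 * (Z[a] + Z[b]);
        // refuse collapses that would create overlong edges
        bool bad = false;
        for (int u : adj[a]) {
          if (u == b) continue;
          double dx = mx - X[u], dy = my - Y[u], dz = mz - Z[u];
          if (std::sqrt(dx * dx + dy * dy + dz * dz) > hi) { bad = true; break; }
        }
        if (!bad)
          for (int u : adj[b]) {
            if (u == a) continue;
            double dx = mx - X[u], dy = my - Y[u], dz = mz - Z[u];
            if (std::sqrt(dx * dx + dy * dy + dz * dz) > hi) { bad = true; break; }
          }
        if (bad) continue;
        X[a] = mx; Y[a] = my; Z[a] = mz;
        remap[b] = a;
        locked[a] = 1; locked[b] = 1;
        for (int u : adj[a]) locked[u] = 1;
        for (int u : adj[b]) locked[u] = 1;
      }
      std::vector<Tri> kept;
      kept.reserve(faces.size());
      for (Tri t : faces) {
        for (int k = 0; k < 3; ++k) t[k] = remap[t[k]];
        if (t[0] != t[1] && t[1] != t[2] && t[0] != t[2]) kept.push_back(t);
      }
      faces.swap(kept);
    }

    // ---- drop unreferenced vertices ----
    {
      std::vector<int> newid(nv, -1);
      int cnt = 0;
      for (const Tri& t : faces)
        for (int k = 0; k < 3; ++k)
          if (newid[t[k]] < 0) newid[t[k]] = cnt++;
      std::vector<double> X2(cnt), Y2(cnt), Z2(cnt);
      for (int i = 0; i < nv; ++i)
        if (newid[i] >= 0) { X2[newid[i]] = X[i]; Y2[newid[i]] = Y[i]; Z2[newid[i]] = Z[i]; }
      for (Tri& t : faces)
        for (int k = 0; k < 3; ++k) t[k] = newid[t[k]];
      X.swap(X2); Y.swap(Y2); Z.swap(Z2);
      nv = cnt;
    }

    // ---- tangential relaxation (boundary pinned) ----
    {
      std::vector<std::vector<int>> adj2(nv);
      std::unordered_map<long long, int> ec2;
      for (const Tri& t : faces)
        for (int k = 0; k < 3; ++k) {
          adj2[t[k]].push_back(t[(k + 1) % 3]);
          adj2[t[k]].push_back(t[(k + 2) % 3]);
          ec2[ekey(t[k], t[(k + 1) % 3])]++;
        }
      std::vector<char> bnd2(nv, 0);
      for (auto& kv : ec2)
        if (kv.second == 1) {
          bnd2[(int)(kv.first / 0x40000000LL)] = 1;
          bnd2[(int)(kv.first % 0x40000000LL)] = 1;
        }
      for (int i = 0; i < nv; ++i) {
        std::sort(adj2[i].begin(), adj2[i].end());
        adj2[i].erase(std::unique(adj2[i].begin(), adj2[i].end()), adj2[i].end());
      }
      // vertex normals (area weighted)
      std::vector<double> NX(nv, 0), NY(nv, 0), NZ(nv, 0);
      for (const Tri& t : faces) {
        double ux = X[t[1]] - X[t[0]], uy = Y[t[1]] - Y[t[0]], uz = Z[t[1]] - Z[t[0]];
        double vx = X[t[2]] - X[t[0]], vy = Y[t[2]] - Y[t[0]], vz = Z[t[2]] - Z[t[0]];
        double nx = uy * vz - uz * vy, ny = uz * vx - ux * vz, nz = ux * vy - uy * vx;
        for (int k = 0; k < 3; ++k) { NX[t[k]] += nx; NY[t[k]] += ny; NZ[t[k]] += nz; }
      }
      std::vector<double> X2(X), Y2(Y), Z2(Z);
      for (int i = 0; i < nv; ++i) {
        if (bnd2[i] || adj2[i].empty()) continue;
        double cx = 0, cy = 0, cz = 0;
        for (int u : adj2[i]) { cx += X[u]; cy += Y[u]; cz += Z[u]; }
        double m = (double)adj2[i].size();
        cx = cx / m - X[i]; cy = cy / m - Y[i]; cz = cz / m - Z[i];
        double nl = std::sqrt(NX[i] * NX[i] + NY[i] * NY[i] + NZ[i] * NZ[i]);
        if (nl > 1e-300) {
          double nx = NX[i] / nl, ny = NY[i] / nl, nz = NZ[i] / nl;
          double dn = cx * nx + cy * ny + cz * nz;
          cx -= dn * nx; cy -= dn * ny; cz -= dn * nz;
        }
        X2[i] = X[i] + 0.5 * cx; Y2[i] = Y[i] + 0.5 * cy; Z2[i] = Z[i] + 0.5 * cz;
      }
      X.swap(X2); Y.swap(Y2); Z.swap(Z2);
    }
  }

  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) { Vout(i, 0) = X[i]; Vout(i, 1) = Y[i]; Vout(i, 2) = Z[i]; }
  IntegerMatrix Fout((int)faces.size(), 3);
  for (int f = 0; f < (int)faces.size(); ++f)
    for (int k = 0; k < 3; ++k) Fout(f, k) = faces[f][k];
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// Taubin lambda/mu smoothing with uniform Laplacian; boundary vertices are
// pinned so open meshes keep their outline and a flat grid is a fixed point.
// [[Rcpp::export]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V_, IntegerMatrix F_,
                                int iterations, double lambda, double mu) {
  const int nv = V_.nrow();
  arma::mat V(V_.begin(), nv, 3);
  std::vector<std::vector<int>> adj(nv);
  std::unordered_map<long long, int> ecount;
  for (int f = 0; f < F_.nrow(); ++f)
    for (int k = 0; k < 3; ++k) {
      int a = F_(f, k), b = F_(f, (k + 1) % 3);
      adj[a].push_back(b); adj[b].push_back(a);
      ecount[ekey(a, b)]++;
    }
  std::vector<char> bnd(nv, 0);
  for (auto& kv : ecount)
    if (kv.second == 1) {
      bnd[(int)(kv.first / 0x40000000LL)] = 1;
      bnd[(int)(kv.first % 0x40000000LL)] = 1;
    }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  arma::mat W = V;
  for (int it = 0; it < iterations; ++it) {
    for (int step = 0; step < 2; ++step) {
      double fac = (step == 0) ? lambda : mu;
      for (int i = 0; i < nv; ++i) {
        if (bnd[i] || adj[i].empty()) { W.row(i) = V.row(i); continue; }
        arma::rowvec cen(3, arma::fill::zeros);
        for (int u : adj[i]) cen += V.row(u);
        cen /= (double)adj[i].size();
        W.row(i) = V.row(i) + fac * (cen - V.row(i));
      }
      V = W;
    }
  }
  return wrap(V);
}
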