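#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// 3D SLIC over a single intensity channel.
//
// Distance D^2 = (dI)^2 + m^2 * (ds^2 / S^2), with S the nominal cluster
// spacing and m the compactness; intensities are expected in [0,1].
// Deterministic: centers start on a regular grid (no random perturbation).
// After the k-means iterations, connectivity is enforced by keeping the
// largest 6-connected component of each cluster and absorbing every other
// component into an adjacent resolved cluster; labels are then compacted
// to 1..K in first-occurrence (raster) order, so K <= initial centers <=
// requested n.
// [[Rcpp::export]]
IntegerVector slic3d_cpp(NumericVector img, IntegerVector dims,
                         int n_segments, double compactness, int max_iter) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t V = (R_xlen_t)Z * Y * X;
  if (n_segments < 1) stop("n_segments must be >= 1");
  if ((R_xlen_t)n_segments > V) stop("n_segments exceeds voxel count");

  const double S = std::cbrt((double)V / n_segments);
  // greedy grid: split the dimension with the widest per-cell extent
  // until the next split would exceed n_segments; center count stays
  // <= n_segments but tracks it much closer than floor(dim/S)
  int nz = 1, ny = 1, nx = 1;
  for (;;) {
    int *dims_n[3] = {&nz, &ny, &nx};
    double ext[3] = {(double)Z / nz, (double)Y / ny, (double)X / nx};
    int ord[3] = {0, 1, 2};
    std::sort(ord, ord + 3, [&](int a, int b) { return ext[a] > ext[b]; });
    bool grew = false;
    for (int t = 0; t < 3 && !grew; ++t) {
      int *g = dims_n[ord[t]];
      long long next = (long long)nz * ny * nx / (*g) * (*g + 1);
      if (next <= n_segments) { ++(*g); grew = true; }
    }
    if (!grew) break;
  }
  const int K0 = nz * ny * nx;

  std::vector<double> cz(K0), cy(K0), cx(K0), ci(K0);
  {
    int k = 0;
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz, ++k) {
          cz[k] = (iz + 0.5) * Z / nz;
          cy[k] = (iy + 0.5) * Y / ny;
          cx[k] = (ix + 0.5) * X / nx;
          int vz = std::min(Z - 1, (int)cz[k]);
          int vy = std::min(Y - 1, (int)cy[k]);
          int vx = std::min(X - 1, (int)cx[k]);
          ci[k] = img[vz + (R_xlen_t)Z * (vy + (R_xlen_t)Y * vx)];
        }
  }

  const double wz = (double)Z / nz + 1.0, wy = (double)Y / ny + 1.0,
               wx = (double)X / nx + 1.0;
  const double m2S2 = (compactness * compactness) / (S * S);

  std::vector<int> lab(V, -1);
  std::vector<double> dist(V);

  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), std::numeric_limits<double>::max());
    for (int k = 0; k < K0; ++k) {
      int z0 = std::max(0, (int)std::floor(cz[k] - wz));
      int z1 = std::min(Z - 1, (int)std::ceil(cz[k] + wz));
      int y0 = std::max(0, (int)std::floor(cy[k] - wy));
      int y1 = std::min(Y - 1, (int)std::ceil(cy[k] + wy));
      int x0 = std::max(0, (int)std::floor(cx[k] - wx));
      int x1 = std::min(X - 1, (int)std::ceil(cx[k] + wx));
      for (int x = x0; x <= x1; ++x)
        for (int y = y0; y <= y1; ++y)
          for (int z = z0; z <= z1; ++z) {
            R_xlen_t idx = z + (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
            double dz = z + 0.5 - cz[k], dy = y + 0.5 - cy[k],
                   dx = x + 0.5 - cx[k];
            double dI = img[idx] - ci[k];
            double d2 = dI * dI + m2S2 * (dz * dz + dy * dy + dx * dx);
            if (d2 < dist[idx]) { dist[idx] = d2; lab[idx] = k; }
          }
    }
    // update centers
    std::vector<double> sz(K0, 0), sy(K0, 0), sx(K0, 0), si(K0, 0), cnt(K0, 0);
    R_xlen_t idx = 0;
    for (int x = 0; x < X; ++x)
      for (int y = 0; y < Y; ++y)
        for (int z = 0; z < Z; ++z, ++idx) {
          int k = lab[idx];
          sz[k] += z + 0.5; sy[k] += y + 0.5; sx[k] += x + 0.5;
          si[k] += img[idx]; cnt[k] += 1.0;
        }
    for (int k = 0; k < K0; ++k)
      if (cnt[k] > 0) {
        cz[k] = sz[k] / cnt[k]; cy[k] = sy[k] / cnt[k];
        cx[k] = sx[k] / cnt[k]; ci[k] = si[k] / cnt[k];
      }
  }

  // --- connectivity enforcement ---
  std::vector<int> comp(V, -1);
  std::vector<int> comp_lab, comp_size;
  int ncomp = 0;
  {
    std::vector<R_xlen_t> stack;
    for (R_xlen_t s = 0; s < V; ++s) {
      if (comp[s] != -1) continue;
      int k = lab[s];
      comp.at(s) = ncomp;
      stack.push_back(s);
      int size = 0;
      while (!stack.empty()) {
        R_xlen_t v = stack.back(); stack.pop_back();
        ++size;
        int z = (int)(v % Z), y = (int)((v / Z) % Y), x = (int)(v / ((R_xlen_t)Z * Y));
        const int dz[6] = {-1, 1, 0, 0, 0, 0};
        const int dy[6] = {0, 0, -1, 1, 0, 0};
        const int dx[6] = {0, 0, 0, 0, -1, 1};
        for (int d = 0; d < 6; ++d) {
          int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
          if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X)
            continue;
          R_xlen_t w = zz + (R_xlen_t)Z * (yy + (R_xlen_t)Y * xx);
          if (comp[w] == -1 && lab[w] == k) { comp[w] = ncomp; stack.push_back(w); }
        }
      }
      comp_lab.push_back(k);
      comp_size.push_back(size);
      ++ncomp;
    }
  }

  // keep the largest component per cluster
  std::vector<int> best_comp(K0, -1);
  for (int c = 0; c < ncomp; ++c) {
    int k = comp_lab[c];
    if (best_comp[k] == -1 || comp_size[c] > comp_size[best_comp[k]])
      best_comp[k] = c;
  }
  std::vector<int> resolved(ncomp, -1);  // final cluster id per component
  for (int k = 0; k < K0; ++k)
    if (best_comp[k] != -1) resolved[best_comp[k]] = k;

  // absorb orphan components into an adjacent resolved cluster (majority
  // boundary contact); iterate until all resolved
  bool changed = true;
  while (changed) {
    changed = false;
    std::vector<int> newly(ncomp, -1);
    std::vector<char> done(ncomp, 0);
    for (R_xlen_t v = 0; v < V; ++v) {
      int c = comp[v];
      if (c < 0 || resolved[c] != -1 || done[c]) continue;
      done[c] = 1;
      // BFS over this orphan component, tallying boundary contact with
      // resolved neighbours; mark visited by offsetting comp, then restore
      std::vector<int> votes;
      std::vector<int> vote_cnt;
      std::vector<R_xlen_t> members;
      std::vector<R_xlen_t> q{v};
      comp[v] = -2 - c;
      while (!q.empty()) {
        R_xlen_t u = q.back(); q.pop_back();
        members.push_back(u);
        int z = (int)(u % Z), y = (int)((u / Z) % Y), x = (int)(u / ((R_xlen_t)Z * Y));
        const int dz[6] = {-1, 1, 0, 0, 0, 0};
        const int dy[6] = {0, 0, -1, 1, 0, 0};
        const int dx[6] = {0, 0, 0, 0, -1, 1};
        for (int d = 0; d < 6; ++d) {
          int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
          if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X)
            continue;
          R_xlen_t w = zz + (R_xlen_t)Z * (yy + (R_xlen_t)Y * xx);
          if (comp[w] == c) { comp[w] = -2 - c; q.push_back(w); }
          else if (comp[w] >= 0 && resolved[comp[w]] != -1) {
            int rk = resolved[comp[w]];
            bool found = false;
            for (size_t t = 0; t < votes.size(); ++t)
              if (votes[t] == rk) { ++vote_cnt[t]; found = true; break; }
            if (!found) { votes.push_back(rk); vote_cnt.push_back(1); }
          }
        }
      }
      for (R_xlen_t u : members) comp[u] = c;  // restore
      if (!votes.empty()) {
        int best = 0;
        for (size_t t = 1; t < votes.size(); ++t)
          if (vote_cnt[t] > vote_cnt[best]) best = (int)t;
        newly[c] = votes[best];
      }
    }
    for (int c = 0; c < ncomp; ++c)
      if (newly[c] != -1) { resolved[c] = newly[c]; changed = true; }
  }

  // write final labels, compacting to 1..K in first-occurrence raster order
  IntegerVector out(V);
  std::vector<int> remap(K0, 0);
  int K = 0;
  for (R_xlen_t v = 0; v < V; ++v) {
    int k = resolved[comp[v]];
    if (remap[k] == 0) remap[k] = ++K;
    out[v] = remap[k];
  }
  out.attr("dim") = dims;
  return out;
}
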