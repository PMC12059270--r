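#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Texture-matrix accumulation on integer gray-level volumes.
// Levels are 1..Ng inside the ROI and 0 (or NA) outside; voxels are
// addressed on a regular (nx, ny, nz) grid and all offsets are in voxels.

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

static inline int at(const IntegerVector &lev, int x, int y, int z,
                     int nx, int ny) {
  int v = lev[x + nx * (y + ny * z)];
  return v == NA_INTEGER ? 0 : v;
}

// Symmetric gray-level co-occurrence counts at distance 1 for each offset.
// Returns an ng x ng x ndir array of pair counts (each pair counted in both
// orientations, i.e. the matrix is already symmetric).
// [[Rcpp::export]]
NumericVector glcm_counts_cpp(IntegerVector lev, IntegerVector dims, int ng,
                              IntegerMatrix offs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nd = offs.nrow();
  NumericVector out(ng * ng * nd);
  for (int d = 0; d < nd; ++d) {
    const int ox = offs(d, 0), oy = offs(d, 1), oz = offs(d, 2);
    const int base = d * ng * ng;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = at(lev, x, y, z, nx, ny);
          if (li <= 0) continue;
          int xx = x + ox, yy = y + oy, zz = z + oz;
          if (!inside(xx, yy, zz, nx, ny, nz)) continue;
          int lj = at(lev, xx, yy, zz, nx, ny);
          if (lj <= 0) continue;
          out[base + (lj - 1) * ng + (li - 1)] += 1.0;
          out[base + (li - 1) * ng + (lj - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  return out;
}

// Gray-level runs: one record per maximal run of equal-level in-ROI voxels
// along each direction. Out-of-ROI voxels break runs.
// [[Rcpp::export]]
List glrlm_runs_cpp(IntegerVector lev, IntegerVector dims, IntegerMatrix offs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nd = offs.nrow();
  std::vector<int> rdir, rlev, rlen;
  for (int d = 0; d < nd; ++d) {
    const int ox = offs(d, 0), oy = offs(d, 1), oz = offs(d, 2);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = at(lev, x, y, z, nx, ny);
          if (li <= 0) continue;
          int px = x - ox, py = y - oy, pz = z - oz;
          if (inside(px, py, pz, nx, ny, nz) &&
              at(lev, px, py, pz, nx, ny) == li)
            continue;  // not the start of a run
          int len = 1, cx = x + ox, cy = y + oy, cz = z + oz;
          while (inside(cx, cy, cz, nx, ny, nz) &&
                 at(lev, cx, cy, cz, nx, ny) == li) {
            ++len; cx += ox; cy += oy; cz += oz;
          }
          rdir.push_back(d + 1);
          rlev.push_back(li);
          rlen.push_back(len);
        }
  }
  return List::create(_["dir"] = wrap(rdir), _["level"] = wrap(rlev),
                      _["length"] = wrap(rlen));
}

// Connected same-level zones (connectivity given by the full offset set,
// i.e. 8 neighbours in-plane / 26 in 3D). One record per zone.
// [[Rcpp::export]]
List glszm_zones_cpp(IntegerVector lev, IntegerVector dims, IntegerMatrix offs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nd = offs.nrow();
  const int n = lev.size();
  std::vector<char> visited(n, 0);
  std::vector<int> stack, zlev, zsize;
  for (int v = 0; v < n; ++v) {
    int lv = lev[v] == NA_INTEGER ? 0 : lev[v];
    if (lv <= 0 || visited[v]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(v);
    visited[v] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int d = 0; d < nd; ++d) {
        int xx = cx + offs(d, 0), yy = cy + offs(d, 1), zz = cz + offs(d, 2);
        if (!inside(xx, yy, zz, nx, ny, nz)) continue;
        int w = xx + nx * (yy + ny * zz);
        int lw = lev[w] == NA_INTEGER ? 0 : lev[w];
        if (lw == lv && !visited[w]) {
          visited[w] = 1;
          stack.push_back(w);
        }
      }
    }
    zlev.push_back(lv);
    zsize.push_back(size);
  }
  return List::create(_["level"] = wrap(zlev), _["size"] = wrap(zsize));
}

// Neighbourhood gray-tone difference sums: for each level i, n[i] = number of
// in-ROI voxels with that level and s[i] = sum of |i - mean(level of in-ROI
// neighbours)|; voxels without in-ROI neighbours contribute 0 to s.
// [[Rcpp::export]]
List ngtdm_counts_cpp(IntegerVector lev, IntegerVector dims, int ng,
                      IntegerMatrix offs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nd = offs.nrow();
  NumericVector n(ng), s(ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = at(lev, x, y, z, nx, ny);
        if (li <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int d = 0; d < nd; ++d) {
          int xx = x + offs(d, 0), yy = y + offs(d, 1), zz = z + offs(d, 2);
          if (!inside(xx, yy, zz, nx, ny, nz)) continue;
          int lj = at(lev, xx, yy, zz, nx, ny);
          if (lj <= 0) continue;
          sum += lj;
          ++cnt;
        }
        n[li - 1] += 1.0;
        if (cnt > 0) s[li - 1] += std::abs(li - sum / cnt);
      }
  return List::create(_["n"] = n, _["s"] = s);
}

// Per-voxel gray-level dependence: number of in-ROI neighbours whose level
// differs from the centre level by at most alpha. Returns (level, dependence)
// per in-ROI voxel.
// [[Rcpp::export]]
IntegerMatrix gldm_pairs_cpp(IntegerVector lev, IntegerVector dims,
                             IntegerMatrix offs, int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nd = offs.nrow();
  std::vector<int> plev, pdep;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = at(lev, x, y, z, nx, ny);
        if (li <= 0) continue;
        int dep = 0;
        for (int d = 0; d < nd; ++d) {
          int xx = x + offs(d, 0), yy = y + offs(d, 1), zz = z + offs(d, 2);
          if (!inside(xx, yy, zz, nx, ny, nz)) continue;
          int lj = at(lev, xx, yy, zz, nx, ny);
          if (lj <= 0) continue;
          if (std::abs(lj - li) <= alpha) ++dep;
        }
        plev.push_back(li);
        pdep.push_back(dep);
      }
  IntegerMatrix out(plev.size(), 2);
  for (int i = 0; i < (int)plev.size(); ++i) {
    out(i, 0) = plev[i];
    out(i, 1) = pdep[i];
  }
  return out;
}
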