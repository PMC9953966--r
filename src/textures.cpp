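#include <Rcpp.h>
#include <queue>
#include <array>
#include <cmath>
using namespace Rcpp;

// All functions take a 3D integer array `levels` with gray levels 1..ng for
// in-ROI voxels and 0 outside the ROI. Offsets are in voxel units; spacing
// anisotropy is deliberately ignored (matrices are defined on the voxel grid).

static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{-1,1,1}
};

static const int NB26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},
  {-1,1,-1},{-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},
  {0,0,-1},{0,0,1},{0,1,-1},{0,1,0},{0,1,1},{1,-1,-1},
  {1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},{1,1,-1},{1,1,0},{1,1,1}
};

inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Ordered co-occurrence counts over the 13 unique directions; the caller
// symmetrizes (M + t(M)) to obtain the direction-merged symmetric GLCM.
// [[Rcpp::export]]
NumericMatrix glcm_counts_cpp(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix M(ng, ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        for (int d = 0; d < 13; ++d) {
          int xx = x + DIR13[d][0], yy = y + DIR13[d][1], zz = z + DIR13[d][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int lj = levels[idx3(xx, yy, zz, nx, ny)];
          if (lj == 0) continue;
          M(li - 1, lj - 1) += 1.0;
        }
      }
  return M;
}

// Run-length counts: maximal constant-level in-ROI runs along each of the
// 13 directions, merged into one ng x max_run matrix. A run starts where the
// backward neighbor is outside the grid, outside the ROI, or a different level.
// [[Rcpp::export]]
NumericMatrix glrlm_counts_cpp(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int rmax = std::max(nx, std::max(ny, nz));
  NumericMatrix M(ng, rmax);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          int px = x - dx, py = y - dy, pz = z - dz;
          bool starts = px < 0 || py < 0 || pz < 0 || px >= nx || py >= ny ||
                        pz >= nz || levels[idx3(px, py, pz, nx, ny)] != li;
          if (!starts) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cy >= 0 && cz >= 0 && cx < nx && cy < ny &&
                 cz < nz && levels[idx3(cx, cy, cz, nx, ny)] == li) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          M(li - 1, len - 1) += 1.0;
        }
  }
  return M;
}

// Connected-component labeling of the nonzero voxels of `grid`.
// If same_value is true, components join only voxels of equal value (GLSZM
// zones); otherwise any nonzero voxels connect (cluster-extent filtering).
// connectivity must be 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector grid, int connectivity,
                                   bool same_value) {
  IntegerVector dim = grid.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;

  std::vector<std::array<int,3> > offs;
  for (int k = 0; k < 26; ++k) {
    int a = std::abs(NB26[k][0]) + std::abs(NB26[k][1]) + std::abs(NB26[k][2]);
    if ((connectivity == 6 && a == 1) ||
        (connectivity == 18 && a <= 2) ||
        (connectivity == 26))
      offs.push_back({{NB26[k][0], NB26[k][1], NB26[k][2]}});
  }

  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (grid[i] == 0 || lab[i] != 0) continue;
    int val = grid[i];
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (size_t d = 0; d < offs.size(); ++d) {
        int xx = cx + offs[d][0], yy = cy + offs[d][1], zz = cz + offs[d][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        int j = idx3(xx, yy, zz, nx, ny);
        if (lab[j] != 0 || grid[j] == 0) continue;
        if (same_value && grid[j] != val) continue;
        lab[j] = next;
        q.push(j);
      }
    }
  }
  return lab;
}

// NGTDM accumulators: for each voxel with >=1 in-ROI 26-neighbor, add
// |level - mean(neighbor levels)| to s[level] and count it in nvox[level].
// [[Rcpp::export]]
NumericMatrix ngtdm_accum_cpp(IntegerVector levels, int ng) {
  IntegerVector dim = levels.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // col 0: n_i, col 1: s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int k = 0; k < 26; ++k) {
          int xx = x + NB26[k][0], yy = y + NB26[k][1], zz = z + NB26[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int lj = levels[idx3(xx, yy, zz, nx, ny)];
          if (lj == 0) continue;
          sum += lj; ++cnt;
        }
        if (cnt == 0) continue;
        out(li - 1, 0) += 1.0;
        out(li - 1, 1) += std::fabs((double)li - sum / cnt);
      }
  return out;
}
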