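#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Out-of-volume neighbours are clamped to the nearest in-volume voxel
// (replicate padding). For vessel volumes this treats structures truncated
// by the crop as continuing beyond it, which avoids artificial erosion of
// vessel ends at subvolume faces.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".median_filter3_cpp")]]
NumericVector median_filter3_cpp(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  std::vector<double> win(27);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = clampi(z + dz, 0, nz - 1);
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = clampi(y + dy, 0, ny - 1);
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = clampi(x + dx, 0, nx - 1);
              win[k++] = vol[xx + (size_t)nx * (yy + (size_t)ny * zz)];
            }
          }
        }
        std::nth_element(win.begin(), win.begin() + 13, win.end());
        out[x + (size_t)nx * (y + (size_t)ny * z)] = win[13];
      }
    }
  }
  return out;
}

// --- 3D homotopic thinning ------------------------------------------------
//
// A foreground voxel is "simple" (deletable without changing topology) when
// (a) the foreground voxels of its 26-neighbourhood form exactly one
//     26-connected component, and
// (b) the background voxels of its 18-neighbourhood that are 6-adjacent to
//     the centre form exactly one 6-connected component within N18.
// Curve endpoints (<= 1 foreground neighbour) are never deleted, so
// centerlines keep their full extent.

static inline bool getv(const std::vector<char> &m, int x, int y, int z,
                        int nx, int ny, int nz) {
  x = clampi(x, 0, nx - 1); y = clampi(y, 0, ny - 1); z = clampi(z, 0, nz - 1);
  return m[x + (size_t)nx * (y + (size_t)ny * z)] != 0;
}

// offsets of the 26-neighbourhood, index = (dx+1) + 3*(dy+1) + 9*(dz+1)
static bool nbhd27[27];

static void load_neighbourhood(const std::vector<char> &m, int x, int y, int z,
                               int nx, int ny, int nz) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nbhd27[(dx + 1) + 3 * (dy + 1) + 9 * (dz + 1)] =
          getv(m, x + dx, y + dy, z + dz, nx, ny, nz);
}

static inline int idx27(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static int count_fg_neighbours() {
  int n = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nbhd27[i]) ++n;
  return n;
}

// number of 26-connected components of foreground among the 26 neighbours
static int fg_components26() {
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nbhd27[i] || seen[i]) continue;
    ++comp;
    int top = 0; stack[top++] = i; seen[i] = true;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 > 2 || y2 < 0 || y2 > 2 || z2 < 0 || z2 > 2) continue;
            int j = x2 + 3 * y2 + 9 * z2;
            if (j == 13 || j == c || seen[j] || !nbhd27[j]) continue;
            seen[j] = true; stack[top++] = j;
          }
    }
  }
  return comp;
}

// number of 6-connected components of background within the 18-neighbourhood
// that touch a face neighbour of the centre
static int bg_components6() {
  // N18 members: offsets with 1 <= |dx|+|dy|+|dz| <= 2
  bool in18[27] = {false};
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s >= 1 && s <= 2) in18[idx27(dx, dy, dz)] = true;
      }
  bool seen[27] = {false};
  int comp = 0, stack[27];
  // seeds: the six face neighbours
  const int faces[6] = {idx27(-1,0,0), idx27(1,0,0), idx27(0,-1,0),
                        idx27(0,1,0),  idx27(0,0,-1), idx27(0,0,1)};
  for (int f = 0; f < 6; ++f) {
    int i = faces[f];
    if (nbhd27[i] || seen[i]) continue;
    ++comp;
    int top = 0; stack[top++] = i; seen[i] = true;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int s = 0; s < 6; ++s) {
        int x2 = cx + step[s][0], y2 = cy + step[s][1], z2 = cz + step[s][2];
        if (x2 < -1 || x2 > 1 || y2 < -1 || y2 > 1 || z2 < -1 || z2 > 1) continue;
        int j = idx27(x2, y2, z2);
        if (j == 13 || !in18[j] || seen[j] || nbhd27[j]) continue;
        seen[j] = true; stack[top++] = j;
      }
    }
  }
  return comp;
}

static bool is_simple(const std::vector<char> &m, int x, int y, int z,
                      int nx, int ny, int nz) {
  load_neighbourhood(m, x, y, z, nx, ny, nz);
  if (fg_components26() != 1) return false;
  if (bg_components6() != 1) return false;
  return true;
}

static bool is_endpoint(const std::vector<char> &m, int x, int y, int z,
                        int nx, int ny, int nz) {
  load_neighbourhood(m, x, y, z, nx, ny, nz);
  return count_fg_neighbours() <= 1;
}

// [[Rcpp::export(name = ".skeletonize3_cpp")]]
LogicalVector skeletonize3_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool changed = true;
  std::vector<size_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t i = x + (size_t)nx * (y + (size_t)ny * z);
            if (!m[i]) continue;
            // border in direction d (clamped lookup: face voxels whose
            // neighbour is clamped back onto themselves are not border)
            if (getv(m, x + dirs[d][0], y + dirs[d][1], z + dirs[d][2],
                     nx, ny, nz)) continue;
            if (is_endpoint(m, x, y, z, nx, ny, nz)) continue;
            if (is_simple(m, x, y, z, nx, ny, nz)) cand.push_back(i);
          }
      // sequential re-checked deletion keeps topology exact
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t i = cand[k];
        int x = i % nx, y = (i / nx) % ny, z = i / ((size_t)nx * ny);
        if (is_endpoint(m, x, y, z, nx, ny, nz)) continue;
        if (is_simple(m, x, y, z, nx, ny, nz)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}
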