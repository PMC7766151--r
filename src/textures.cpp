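#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The 13 unique 3D direction vectors (lexicographically positive half of the
// 26-neighbourhood). Pair counting over +d and -d makes GLCMs symmetric.
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// levels: integer volume, 0 outside mask, 1..ng inside.

// [[Rcpp::export]]
List cpp_glcm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  List out(13);
  for (int d = 0; d < 13; ++d) {
    NumericMatrix m(ng, ng);
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[idx3(x, y, z, nx, ny)];
          if (li == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int lj = levels[idx3(x2, y2, z2, nx, ny)];
          if (lj == 0) continue;
          m(li - 1, lj - 1) += 1.0;  // count both orders -> symmetric
          m(lj - 1, li - 1) += 1.0;
        }
    out[d] = m;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  List out(13);
  for (int d = 0; d < 13; ++d) {
    NumericMatrix m(ng, maxlen);
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          // start of a line: predecessor lies outside the array
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz)
            continue;
          int cur = 0, len = 0;
          int cx = x, cy = y, cz = z;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
            int l = levels[idx3(cx, cy, cz, nx, ny)];
            if (l == cur) {
              if (cur != 0) ++len;
            } else {
              if (cur != 0) m(cur - 1, len - 1) += 1.0;
              cur = l;
              len = 1;
            }
            cx += dx; cy += dy; cz += dz;
          }
          if (cur != 0) m(cur - 1, len - 1) += 1.0;
        }
    out[d] = m;
  }
  return out;
}

// 26-connected component labelling of a logical volume (iterative stack).
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int q = idx3(x2, y2, z2, nx, ny);
            if (mask[q] && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// Size-zone matrix: zones are 26-connected components of equal gray level.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<int> lab(n, 0);
  std::vector<int> stack;
  std::vector<int> zlevel, zsize;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (levels[i] == 0 || lab[i] != 0) continue;
    int lv = levels[i];
    ++next;
    lab[i] = next;
    int size = 0;
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      ++size;
      int x = p % nx, y = (p / nx) % ny, z = p / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int q = idx3(x2, y2, z2, nx, ny);
            if (levels[q] == lv && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
    zlevel.push_back(lv);
    zsize.push_back(size);
  }
  int maxsize = 1;
  for (size_t k = 0; k < zsize.size(); ++k)
    if (zsize[k] > maxsize) maxsize = zsize[k];
  NumericMatrix m(ng, maxsize);
  for (size_t k = 0; k < zsize.size(); ++k)
    m(zlevel[k] - 1, zsize[k] - 1) += 1.0;
  return m;
}

// Dependence matrix: dependence of a voxel = 1 + number of in-mask
// 26-neighbours with the same gray level (alpha = 0, distance 1).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              if (levels[idx3(x2, y2, z2, nx, ny)] == li) ++dep;
            }
        m(li - 1, dep - 1) += 1.0;
      }
  return m;
}

// NGTDM: per gray level i returns n_i (voxel count) and
// s_i = sum over voxels of |i - mean level of in-mask 26-neighbours|.
// Voxels without any in-mask neighbour contribute 0 to s_i.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix m(ng, 2);  // columns: n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[idx3(x, y, z, nx, ny)];
        if (li == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int l2 = levels[idx3(x2, y2, z2, nx, ny)];
              if (l2 != 0) { sum += l2; ++cnt; }
            }
        m(li - 1, 0) += 1.0;
        if (cnt > 0) m(li - 1, 1) += std::fabs(li - sum / cnt);
      }
  return m;
}
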