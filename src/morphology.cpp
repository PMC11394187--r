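#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Neighbourhood machinery
// ---------------------------------------------------------------------------

// Offsets of the 3x3x3 neighbourhood (excluding the centre) that belong to a
// given adjacency system: 6 (faces), 18 (faces+edges), 26 (all).
static void adjacency_offsets(int adjacency, std::vector<int> &dx,
                              std::vector<int> &dy, std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if (adjacency == 6 && m > 1) continue;
        if (adjacency == 18 && m > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
}

// Union-find with minimum-label roots: the representative of every class is
// its smallest member, honouring the "assign the minimum value" rule.
struct UnionFind {
  std::vector<int> parent;
  UnionFind() { parent.push_back(0); } // label 0 unused
  int make() { parent.push_back((int)parent.size()); return (int)parent.size() - 1; }
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nx = parent[x]; parent[x] = r; x = nx; }
    return r;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (a < b) parent[b] = a; else parent[a] = b;
  }
};

// ---------------------------------------------------------------------------
// Two-pass connected-component labeling
// ---------------------------------------------------------------------------

// First raster scan: provisional labels from already-visited neighbours with
// equivalences recorded in a union-find table; second scan: resolve every
// voxel to its equivalence-class minimum; then relabel consecutively 1..n.
// [[Rcpp::export(name = ".ccl_two_pass")]]
List ccl_two_pass(LogicalVector mask, IntegerVector dim, int adjacency) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<int> dx, dy, dz;
  adjacency_offsets(adjacency, dx, dy, dz);
  // Keep only the "already visited" half of the neighbourhood (smaller linear
  // index in x-fastest raster order).
  std::vector<int> px, py, pz;
  for (size_t k = 0; k < dx.size(); ++k) {
    if (dz[k] < 0 || (dz[k] == 0 && dy[k] < 0) ||
        (dz[k] == 0 && dy[k] == 0 && dx[k] < 0)) {
      px.push_back(dx[k]); py.push_back(dy[k]); pz.push_back(dz[k]);
    }
  }

  UnionFind uf;
  std::vector<int> nb; nb.reserve(13);

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
        if (!mask[idx]) continue;
        nb.clear();
        for (size_t k = 0; k < px.size(); ++k) {
          int xx = x + px[k], yy = y + py[k], zz = z + pz[k];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int lab = labels[(R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz)];
          if (lab > 0) nb.push_back(lab);
        }
        if (nb.empty()) {
          labels[idx] = uf.make();
        } else {
          int mn = nb[0];
          for (size_t k = 1; k < nb.size(); ++k) if (nb[k] < mn) mn = nb[k];
          labels[idx] = mn;
          for (size_t k = 0; k < nb.size(); ++k) uf.unite(mn, nb[k]);
        }
      }

  // Second pass: resolve equivalences, relabel consecutively in order of
  // first appearance (which is also increasing class-minimum order).
  std::vector<int> remap(uf.parent.size(), 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int lab = labels[i];
    if (lab == 0) continue;
    int r = uf.find(lab);
    if (remap[r] == 0) remap[r] = ++next;
    labels[i] = remap[r];
  }
  return List::create(_["labels"] = labels, _["n_components"] = next);
}

// ---------------------------------------------------------------------------
// 3D topological thinning
// ---------------------------------------------------------------------------

// Local 3x3x3 configuration helpers. Positions are encoded 0..26 as
// p = (cx+1) + 3*(cy+1) + 9*(cz+1); centre = 13.

static inline int pos_code(int cx, int cy, int cz) {
  return (cx + 1) + 3 * (cy + 1) + 9 * (cz + 1);
}

// Number of 26-connected components of the foreground among the 26 neighbours
// (centre excluded).
static int count_fg26(const bool nbr[27]) {
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nbr[i] || comp[i] >= 0) continue;
    int top = 0; stack[top++] = i; comp[i] = ncomp;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int zz = -1; zz <= 1; ++zz)
        for (int yy = -1; yy <= 1; ++yy)
          for (int xx = -1; xx <= 1; ++xx) {
            int px = cx + xx, py = cy + yy, pz = cz + zz;
            if (px < -1 || px > 1 || py < -1 || py > 1 || pz < -1 || pz > 1)
              continue;
            int q = pos_code(px, py, pz);
            if (q == 13 || q == c || !nbr[q] || comp[q] >= 0) continue;
            comp[q] = ncomp; stack[top++] = q;
          }
    }
    ++ncomp;
  }
  return ncomp;
}

// Number of 6-connected components of the background restricted to the
// 18-neighbourhood (faces+edges) that touch a face neighbour of the centre
// (Bertrand-Malandain simple-point characterisation).
static int count_bg6(const bool nbr[27]) {
  static const int face[6] = { pos_code(-1,0,0), pos_code(1,0,0),
                               pos_code(0,-1,0), pos_code(0,1,0),
                               pos_code(0,0,-1), pos_code(0,0,1) };
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
    int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
    in18[i] = (i != 13) && m <= 2;
  }
  int comp[27]; for (int i = 0; i < 27; ++i) comp[i] = -1;
  int ncomp = 0, counted = 0;
  int stack[27];
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (nbr[s] || comp[s] >= 0) continue; // must be background, unvisited
    int top = 0; stack[top++] = s; comp[s] = ncomp;
    while (top > 0) {
      int c = stack[--top];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      const int d6[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
      for (int k = 0; k < 6; ++k) {
        int px = cx + d6[k][0], py = cy + d6[k][1], pz = cz + d6[k][2];
        if (px < -1 || px > 1 || py < -1 || py > 1 || pz < -1 || pz > 1)
          continue;
        int q = pos_code(px, py, pz);
        if (q == 13 || !in18[q] || nbr[q] || comp[q] >= 0) continue;
        comp[q] = ncomp; stack[top++] = q;
      }
    }
    ++ncomp; ++counted;
  }
  return counted;
}

static inline void gather_neighbourhood(const int *img, int nx, int ny, int nz,
                                        int x, int y, int z, bool nbr[27]) {
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int xx = x + cx, yy = y + cy, zz = z + cz;
        bool v = false;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          v = img[(R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz)] != 0;
        nbr[pos_code(cx, cy, cz)] = v;
      }
}

static inline int n_fg_neighbours(const bool nbr[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nbr[i]) ++c;
  return c;
}

static inline bool is_simple(const bool nbr[27]) {
  return count_fg26(nbr) == 1 && count_bg6(nbr) == 1;
}

// Curve thinning by directional boundary peeling: for each of the six face
// directions in turn, collect foreground voxels whose face neighbour in that
// direction is background, then delete them sequentially, re-checking at
// deletion time that the point is still simple and not a curve endpoint
// (<= 1 foreground 26-neighbour). Repeated until a full cycle removes nothing;
// sequential re-checking guarantees topology preservation.
// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = { {0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0} };
  bool nbr[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            R_xlen_t idx = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
            if (!img[idx]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            bool border = true;
            if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
              border = img[(R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz)] == 0;
            if (border) cand.push_back(idx);
          }
      // Two checkerboard subfields per direction: processing alternating
      // parities separately interrupts the lengthwise deletion cascades that
      // sequential peeling otherwise suffers on grid-symmetric 2-wide bars.
      for (int parity = 0; parity < 2; ++parity) {
        for (size_t k = 0; k < cand.size(); ++k) {
          R_xlen_t idx = cand[k];
          if (!img[idx]) continue;
          int x = (int)(idx % nx);
          int y = (int)((idx / nx) % ny);
          int z = (int)(idx / ((R_xlen_t)nx * ny));
          if (((x + y + z) & 1) != parity) continue;
          gather_neighbourhood(img.data(), nx, ny, nz, x, y, z, nbr);
          if (n_fg_neighbours(nbr) <= 1) continue; // endpoint or isolated
          if (!is_simple(nbr)) continue;
          img[idx] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear sampling
// ---------------------------------------------------------------------------

// Sample a volume at arbitrary continuous 0-based voxel coordinates (one row
// per point). Points outside the grid return `background`.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector vol, IntegerVector dim,
                               NumericMatrix pts, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 || pz > nz - 1) {
      out[i] = background; continue;
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fx = px - x0, fy = py - y0, fz = pz - z0;
    #define V(a,b,c) vol[(R_xlen_t)(a) + nx * ((R_xlen_t)(b) + (R_xlen_t)ny * (c))]
    double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
    double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
    double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
    double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
    #undef V
    double c0 = c00 * (1-fy) + c10 * fy;
    double c1 = c01 * (1-fy) + c11 * fy;
    out[i] = c0 * (1-fz) + c1 * fz;
  }
  return out;
}
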