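#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// Topology-preserving 3D thinning to a unit-width curve skeleton.
//
// Border voxels are deleted iteratively in six directional sub-iterations
// (up/down/north/south/east/west) if they are "simple" (their removal
// preserves both foreground 26-connectivity and background 6-connectivity in
// the 3x3x3 neighbourhood; Bertrand-Malandain characterisation) and are not
// curve endpoints (exactly one foreground 26-neighbour). Deletion is
// sequential, re-checking simplicity, so topology is preserved exactly.

namespace {

struct Tables {
  std::vector<std::vector<int>> adj26; // 26-adjacency between 3x3x3 positions
  std::vector<std::vector<int>> adj6;  // 6-adjacency restricted to N18 positions
  std::vector<int> n18;                // positions with order 1 or 2
  std::vector<int> faces;              // the 6 face-neighbour positions
  Tables() : adj26(27), adj6(27) {
    auto coord = [](int p, int &x, int &y, int &z) {
      x = p % 3 - 1; y = (p / 3) % 3 - 1; z = p / 9 - 1;
    };
    for (int p = 0; p < 27; ++p) {
      if (p == 13) continue;
      int px, py, pz; coord(p, px, py, pz);
      int ord = std::abs(px) + std::abs(py) + std::abs(pz);
      if (ord <= 2) n18.push_back(p);
      if (ord == 1) faces.push_back(p);
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || q == p) continue;
        int qx, qy, qz; coord(q, qx, qy, qz);
        int dx = std::abs(px - qx), dy = std::abs(py - qy), dz = std::abs(pz - qz);
        if (std::max(dx, std::max(dy, dz)) == 1) adj26[p].push_back(q);
        int ordq = std::abs(qx) + std::abs(qy) + std::abs(qz);
        if (ord <= 2 && ordq <= 2 && dx + dy + dz == 1) adj6[p].push_back(q);
      }
    }
  }
};

const Tables &tables() {
  static Tables t;
  return t;
}

class Grid {
public:
  Grid(std::vector<char> &fg, int nx, int ny, int nz)
      : fg_(fg), nx_(nx), ny_(ny), nz_(nz) {}
  inline bool at(int x, int y, int z) const {
    if (x < 0 || x >= nx_ || y < 0 || y >= ny_ || z < 0 || z >= nz_) return false;
    return fg_[x + static_cast<R_xlen_t>(nx_) * (y + static_cast<R_xlen_t>(ny_) * z)];
  }
  void neighbourhood(int x, int y, int z, bool nb[27]) const {
    int p = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++p)
          nb[p] = at(x + dx, y + dy, z + dz);
  }
private:
  std::vector<char> &fg_;
  int nx_, ny_, nz_;
};

int fg_neighbour_count(const bool nb[27]) {
  int c = 0;
  for (int p = 0; p < 27; ++p)
    if (p != 13 && nb[p]) ++c;
  return c;
}

// exactly one 26-component of foreground in the punctured neighbourhood
bool one_fg_component(const bool nb[27]) {
  const Tables &t = tables();
  int seen[27] = {0};
  int comp = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb[p] || seen[p]) continue;
    ++comp;
    if (comp > 1) return false;
    std::vector<int> st{p};
    seen[p] = 1;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      for (int q : t.adj26[v])
        if (nb[q] && !seen[q]) { seen[q] = 1; st.push_back(q); }
    }
  }
  return comp == 1;
}

// exactly one 6-component of background within N18 touching a face neighbour
bool one_bg_component(const bool nb[27]) {
  const Tables &t = tables();
  int seen[27] = {0};
  int comp = 0;
  for (int f : t.faces) {
    if (nb[f] || seen[f]) continue;
    ++comp;
    if (comp > 1) return false;
    std::vector<int> st{f};
    seen[f] = 1;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      for (int q : t.adj6[v])
        if (!nb[q] && !seen[q]) { seen[q] = 1; st.push_back(q); }
    }
  }
  return comp == 1;
}

bool is_simple(const bool nb[27]) {
  return one_fg_component(nb) && one_bg_component(nb);
}

} // namespace

// [[Rcpp::export]]
LogicalVector thin_3d_cpp(LogicalVector img, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<char> fg(n), in_border(n, 0);
  for (R_xlen_t s = 0; s < n; ++s) fg[s] = img[s] ? 1 : 0;
  Grid g(fg, nx, ny, nz);

  // directional border offsets: U, D, N, S, E, W
  const int dirs[6][3] = {{0, 0, 1},  {0, 0, -1}, {0, 1, 0},
                          {0, -1, 0}, {1, 0, 0},  {-1, 0, 0}};

  // only voxels touching the background can ever be deleted; track that
  // border set and grow it from the neighbours of deleted voxels
  std::vector<R_xlen_t> border;
  bool nb[27];
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!fg[s]) continue;
    int x = s % nx, y = (s / nx) % ny, z = s / (static_cast<R_xlen_t>(nx) * ny);
    bool bdry = false;
    for (int d = 0; d < 6 && !bdry; ++d)
      if (!g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) bdry = true;
    if (bdry) {
      border.push_back(s);
      in_border[s] = 1;
    }
  }

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      const size_t n_border = border.size(); // snapshot; grows as voxels die
      for (size_t t = 0; t < n_border; ++t) {
        R_xlen_t s = border[t];
        if (!fg[s]) continue;
        int x = s % nx, y = (s / nx) % ny, z = s / (static_cast<R_xlen_t>(nx) * ny);
        if (g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
        g.neighbourhood(x, y, z, nb);
        int c = fg_neighbour_count(nb);
        if (c <= 1) continue; // endpoint or isolated voxel: keep
        if (is_simple(nb)) cand.push_back(s);
      }
      // sequential re-check of simplicity only (the endpoint test applies at
      // collection time): exact topology preservation without freezing voxels
      // that became line tips mid-batch
      for (R_xlen_t s : cand) {
        int x = s % nx, y = (s / nx) % ny, z = s / (static_cast<R_xlen_t>(nx) * ny);
        g.neighbourhood(x, y, z, nb);
        if (fg_neighbour_count(nb) == 0) continue;
        if (is_simple(nb)) {
          fg[s] = 0;
          changed = true;
          // newly exposed foreground neighbours join the border set
          int p = 0;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx, ++p) {
                if (p == 13 || !nb[p]) continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                  continue;
                R_xlen_t u = xx + static_cast<R_xlen_t>(nx) *
                                      (yy + static_cast<R_xlen_t>(ny) * zz);
                if (fg[u] && !in_border[u]) {
                  border.push_back(u);
                  in_border[u] = 1;
                }
              }
        }
      }
    }
    if (changed) {
      std::vector<R_xlen_t> keep;
      keep.reserve(border.size());
      for (R_xlen_t s : border)
        if (fg[s]) keep.push_back(s);
      border.swap(keep);
    }
  }

  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = fg[s] != 0;
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
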