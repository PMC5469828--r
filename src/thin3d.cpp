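#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// --- Simple-point test (26-connectivity object / 6-connectivity background)
//
// A voxel is "simple" when its removal preserves the topology of the object:
//  * exactly one 26-connected foreground component in the 26-neighborhood,
//  * exactly one 6-connected background component in the 18-neighborhood
//    that is 6-adjacent to the center (Bertrand & Malandain characterization).

namespace {

int adj26[26][26];     // adjacency among the 26 non-center offsets
int n_adj26[26];
int adj6_18[18][18];   // 6-adjacency among the 18-neighborhood offsets
int n_adj6_18[18];
int map27_to26[27];    // neighborhood slot -> index among the 26
int map27_to18[27];
int idx26_off[26];     // 26-neighborhood slot -> offset triple index (0..26)
int idx18_off[18];
bool face18[18];       // is this 18-neighborhood cell a face (6-) neighbor of center
bool tables_ready = false;

inline void triple(int s, int& da, int& db, int& dc) {
  da = s % 3 - 1; db = (s / 3) % 3 - 1; dc = s / 9 - 1;
}

void build_tables() {
  int c26 = 0, c18 = 0;
  for (int s = 0; s < 27; ++s) {
    map27_to26[s] = -1; map27_to18[s] = -1;
    if (s == 13) continue;
    int da, db, dc; triple(s, da, db, dc);
    map27_to26[s] = c26;
    idx26_off[c26] = s;
    ++c26;
    int ad = std::abs(da) + std::abs(db) + std::abs(dc);
    if (ad <= 2) { // 18-neighborhood (exclude corners)
      map27_to18[s] = c18;
      idx18_off[c18] = s;
      face18[c18] = (ad == 1);
      ++c18;
    }
  }
  for (int i = 0; i < 26; ++i) {
    n_adj26[i] = 0;
    int a1, b1, cc1; triple(idx26_off[i], a1, b1, cc1);
    for (int j = 0; j < 26; ++j) {
      if (i == j) continue;
      int a2, b2, cc2; triple(idx26_off[j], a2, b2, cc2);
      if (std::abs(a1 - a2) <= 1 && std::abs(b1 - b2) <= 1 && std::abs(cc1 - cc2) <= 1)
        adj26[i][n_adj26[i]++] = j;
    }
  }
  for (int i = 0; i < 18; ++i) {
    n_adj6_18[i] = 0;
    int a1, b1, cc1; triple(idx18_off[i], a1, b1, cc1);
    for (int j = 0; j < 18; ++j) {
      if (i == j) continue;
      int a2, b2, cc2; triple(idx18_off[j], a2, b2, cc2);
      if (std::abs(a1 - a2) + std::abs(b1 - b2) + std::abs(cc1 - cc2) == 1)
        adj6_18[i][n_adj6_18[i]++] = j;
    }
  }
  tables_ready = true;
}

// ng: 27 foreground flags of the 3x3x3 neighborhood (slot 13 = center)
bool is_simple(const bool* ng) {
  // foreground components among the 26 neighbors, 26-connectivity
  bool fg[26];
  int nfg = 0;
  for (int i = 0; i < 26; ++i) { fg[i] = ng[idx26_off[i]]; if (fg[i]) ++nfg; }
  if (nfg == 0) return false; // isolated: removal deletes a component
  int comp = 0;
  bool seen[26] = {false};
  int stack[26], ns;
  for (int i = 0; i < 26; ++i) {
    if (!fg[i] || seen[i]) continue;
    if (++comp > 1) return false;
    ns = 0; stack[ns++] = i; seen[i] = true;
    while (ns) {
      int p = stack[--ns];
      for (int t = 0; t < n_adj26[p]; ++t) {
        int q = adj26[p][t];
        if (fg[q] && !seen[q]) { seen[q] = true; stack[ns++] = q; }
      }
    }
  }
  // background components in the 18-neighborhood, 6-connectivity,
  // counted only if 6-adjacent to the center
  bool bg[18];
  for (int i = 0; i < 18; ++i) bg[i] = !ng[idx18_off[i]];
  bool seen18[18] = {false};
  int compb = 0;
  int stack18[18];
  for (int i = 0; i < 18; ++i) {
    if (!bg[i] || seen18[i] || !face18[i]) continue;
    // flood from an unvisited background face neighbor
    ++compb;
    if (compb > 1) return false;
    ns = 0; stack18[ns++] = i; seen18[i] = true;
    while (ns) {
      int p = stack18[--ns];
      for (int t = 0; t < n_adj6_18[p]; ++t) {
        int q = adj6_18[p][t];
        if (bg[q] && !seen18[q]) { seen18[q] = true; stack18[ns++] = q; }
      }
    }
  }
  if (compb == 0) return false; // interior voxel: removal opens a cavity
  return true;
}

} // namespace

// Sequential directional thinning to a curve skeleton.
//
// Each round performs six border-direction passes (U, D, N, S, E, W): the
// candidates of a pass - voxels whose neighbor in that direction is
// background - are collected *before* any removal (so erosion advances one
// layer per pass instead of cascading through the object), ordered by the
// distance-transform priority, and removed sequentially when they are
// simple points and not curve endpoints (<= 1 foreground 26-neighbor).
// Every removed voxel is simple at removal time, so connected components,
// loops and cavities of the input are preserved exactly.
// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask, IntegerVector dim, NumericVector priority) {
  if (!tables_ready) build_tables();
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out = clone(mask);

  auto neighborhood = [&](R_xlen_t p, bool* ng) {
    int a = (int)(p % n1);
    int b = (int)((p / n1) % n2);
    int c = (int)(p / ((R_xlen_t)n1 * n2));
    int s = 0;
    for (int dc = -1; dc <= 1; ++dc)
      for (int db = -1; db <= 1; ++db)
        for (int da = -1; da <= 1; ++da, ++s) {
          int aa = a + da, bb = b + db, cc = c + dc;
          if (aa < 0 || aa >= n1 || bb < 0 || bb >= n2 || cc < 0 || cc >= n3)
            ng[s] = false;
          else
            ng[s] = out[aa + (R_xlen_t)n1 * (bb + (R_xlen_t)n2 * cc)];
        }
  };

  static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

  // active set: track current foreground voxels to avoid full scans
  std::vector<R_xlen_t> active;
  for (R_xlen_t p = 0; p < nn; ++p)
    if (out[p]) active.push_back(p);

  std::vector<std::pair<double, R_xlen_t> > cand;
  bool ng[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      for (R_xlen_t p : active) {
        if (!out[p]) continue;
        int a = (int)(p % n1);
        int b = (int)((p / n1) % n2);
        int c = (int)(p / ((R_xlen_t)n1 * n2));
        int aa = a + d6[dir][0], bb = b + d6[dir][1], cc = c + d6[dir][2];
        bool bgn = true;
        if (aa >= 0 && aa < n1 && bb >= 0 && bb < n2 && cc >= 0 && cc < n3)
          bgn = !out[aa + (R_xlen_t)n1 * (bb + (R_xlen_t)n2 * cc)];
        if (!bgn) continue;
        // some foreground must exist in the opposite 3x3 neighborhood
        // layer: a voxel already one voxel thick along this direction is
        // not eroded further by this pass (prevents directional sweeps
        // from consuming thin sheets and lines end-on), while diagonally
        // offset strands still resolve to a single line
        bool fgo = false;
        for (int u = -1; u <= 1 && !fgo; ++u)
          for (int v = -1; v <= 1 && !fgo; ++v) {
            int a2 = a - d6[dir][0], b2 = b - d6[dir][1], c2 = c - d6[dir][2];
            if (d6[dir][0] != 0) { b2 += u; c2 += v; }
            else if (d6[dir][1] != 0) { a2 += u; c2 += v; }
            else { a2 += u; b2 += v; }
            if (a2 >= 0 && a2 < n1 && b2 >= 0 && b2 < n2 && c2 >= 0 && c2 < n3)
              fgo = out[a2 + (R_xlen_t)n1 * (b2 + (R_xlen_t)n2 * c2)];
          }
        if (fgo) cand.push_back(std::make_pair(priority[p], p));
      }
      std::sort(cand.begin(), cand.end());
      for (size_t i = 0; i < cand.size(); ++i) {
        R_xlen_t p = cand[i].second;
        if (!out[p]) continue;
        neighborhood(p, ng);
        int nf = 0;
        for (int s = 0; s < 27; ++s) if (s != 13 && ng[s]) ++nf;
        if (nf <= 1) continue; // curve endpoint (or isolated) - keep
        if (!is_simple(ng)) continue;
        out[p] = false;
        changed = true;
      }
    }
    if (changed) {
      // compact the active set
      std::vector<R_xlen_t> nxt;
      nxt.reserve(active.size());
      for (R_xlen_t p : active) if (out[p]) nxt.push_back(p);
      active.swap(nxt);
    }
  }
  return out;
}
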