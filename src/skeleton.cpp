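#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Morphological thinning and skeleton-graph tracing for neurite analysis.
// Masks are column-major logical/integer matrices; coordinates are 0-based
// (row, col) internally and returned 1-based where exposed to R.

static inline int idx(int r, int c, int nr) { return c * nr + r; }

// Zhang-Suen thinning: reduce a binary mask to an 8-connected, 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> img(nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) img[idx(r, c, nr)] = mask(r, c) ? 1 : 0;

  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 1; c < nc - 1; ++c) {
        for (int r = 1; r < nr - 1; ++r) {
          if (!img[idx(r, c, nr)]) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = img[idx(r - 1, c, nr)], p3 = img[idx(r - 1, c + 1, nr)];
          int p4 = img[idx(r, c + 1, nr)], p5 = img[idx(r + 1, c + 1, nr)];
          int p6 = img[idx(r + 1, c, nr)], p7 = img[idx(r + 1, c - 1, nr)];
          int p8 = img[idx(r, c - 1, nr)], p9 = img[idx(r - 1, c - 1, nr)];
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(idx(r, c, nr));
        }
      }
      if (!kill.empty()) changed = true;
      for (int k : kill) img[k] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) out(r, c) = img[idx(r, c, nr)] != 0;
  return out;
}

// m-adjacency: a diagonal step is used only when neither bridging orthogonal
// pixel is set, so staircases do not create spurious parallel edges.
static void neighbours(const std::vector<char>& img, int nr, int nc,
                       int r, int c, std::vector<int>& out_r,
                       std::vector<int>& out_c, std::vector<double>& out_w) {
  out_r.clear(); out_c.clear(); out_w.clear();
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  for (int k = 0; k < 4; ++k) {
    int rr = r + dr4[k], cc = c + dc4[k];
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    if (img[idx(rr, cc, nr)]) {
      out_r.push_back(rr); out_c.push_back(cc); out_w.push_back(1.0);
    }
  }
  const int drd[4] = {-1, -1, 1, 1}, dcd[4] = {-1, 1, -1, 1};
  for (int k = 0; k < 4; ++k) {
    int rr = r + drd[k], cc = c + dcd[k];
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    if (!img[idx(rr, cc, nr)]) continue;
    bool b1 = img[idx(r, cc, nr)] != 0;   // same row, neighbour col
    bool b2 = img[idx(rr, c, nr)] != 0;   // neighbour row, same col
    if (!b1 && !b2) {
      out_r.push_back(rr); out_c.push_back(cc); out_w.push_back(M_SQRT2);
    }
  }
}

// Trace a 1-px skeleton into branch segments: maximal paths between
// junction (degree >= 3) or end (degree 1) nodes. Step lengths are 1 for
// orthogonal and sqrt(2) for diagonal moves, in pixel units. Isolated
// cycles count as one segment; isolated pixels as a zero-length segment.
// [[Rcpp::export]]
List cpp_skeleton_segments(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> img(nr * nc);
  std::vector<int> px;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      img[idx(r, c, nr)] = mask(r, c) ? 1 : 0;
      if (mask(r, c)) px.push_back(idx(r, c, nr));
    }

  std::vector<int> nbr_r, nbr_c; std::vector<double> nbr_w;
  std::vector<int> degree(nr * nc, -1);
  for (int p : px) {
    int r = p % nr, c = p / nr;
    neighbours(img, nr, nc, r, c, nbr_r, nbr_c, nbr_w);
    degree[p] = (int)nbr_r.size();
  }

  std::unordered_set<long long> visited; // undirected edge keys
  auto ekey = [nr, nc](int a, int b) -> long long {
    long long lo = a < b ? a : b, hi = a < b ? b : a;
    return lo * (long long)(nr * nc) + hi;
  };

  std::vector<double> seg_lengths;

  auto walk = [&](int node, int first_r, int first_c, double w0) {
    int prev = node;
    int cur = idx(first_r, first_c, nr);
    if (visited.count(ekey(prev, cur))) return;
    visited.insert(ekey(prev, cur));
    double len = w0;
    while (degree[cur] == 2 && cur != node) {
      int r = cur % nr, c = cur / nr;
      neighbours(img, nr, nc, r, c, nbr_r, nbr_c, nbr_w);
      int nxt = -1; double w = 0;
      for (size_t k = 0; k < nbr_r.size(); ++k) {
        int cand = idx(nbr_r[k], nbr_c[k], nr);
        if (cand != prev && !visited.count(ekey(cur, cand))) {
          nxt = cand; w = nbr_w[k]; break;
        }
      }
      if (nxt < 0) break; // closed back onto a visited edge
      visited.insert(ekey(cur, nxt));
      prev = cur; cur = nxt; len += w;
    }
    seg_lengths.push_back(len);
  };

  // segments emanating from nodes (degree != 2)
  for (int p : px) {
    if (degree[p] == 2) continue;
    if (degree[p] == 0) { seg_lengths.push_back(0.0); continue; }
    int r = p % nr, c = p / nr;
    neighbours(img, nr, nc, r, c, nbr_r, nbr_c, nbr_w);
    // copy: walk() reuses the shared neighbour buffers internally
    std::vector<int> vr = nbr_r, vc = nbr_c;
    std::vector<double> vw = nbr_w;
    for (size_t k = 0; k < vr.size(); ++k)
      walk(p, vr[k], vc[k], vw[k]);
  }
  // remaining pure cycles (every pixel degree 2, no incident edge visited)
  for (int p : px) {
    if (degree[p] != 2) continue;
    int r = p % nr, c = p / nr;
    neighbours(img, nr, nc, r, c, nbr_r, nbr_c, nbr_w);
    bool any_unvisited = false;
    for (size_t k = 0; k < nbr_r.size(); ++k)
      if (!visited.count(ekey(p, idx(nbr_r[k], nbr_c[k], nr)))) any_unvisited = true;
    if (!any_unvisited) continue;
    walk(p, nbr_r[0], nbr_c[0], nbr_w[0]);
  }

  double total = 0;
  for (double l : seg_lengths) total += l;
  return List::create(_["segment_lengths"] = wrap(seg_lengths),
                      _["n_segments"] = (int)seg_lengths.size(),
                      _["total_length"] = total);
}
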