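#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Zhang-Suen thinning of a binary image to a 1-px-wide 8-connected
// centerline. Border pixels are treated as background.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix &mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) img[i + j * nr] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[i + j * nr];
  };

  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + j * nr]) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img[kill[k].first + kill[k].second * nr] = 0;
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = img[i + j * nr] == 1;
  return out;
}

// Stamp filled discs of radius r[k] at (row[k], col[k]) (1-based, may be
// fractional) into an nr x nc logical canvas. Radii below 0.5 still mark
// the nearest pixel.
// [[Rcpp::export]]
LogicalMatrix cpp_stamp_discs(int nr, int nc, const NumericVector &row,
                              const NumericVector &col, const NumericVector &r) {
  LogicalMatrix out(nr, nc);
  int n = row.size();
  for (int k = 0; k < n; ++k) {
    double rr = r[k] < 0.5 ? 0.5 : r[k];
    double cy = row[k] - 1.0, cx = col[k] - 1.0;
    int i0 = (int)std::floor(cy - rr), i1 = (int)std::ceil(cy + rr);
    int j0 = (int)std::floor(cx - rr), j1 = (int)std::ceil(cx + rr);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0;
    if (i1 >= nr) i1 = nr - 1; if (j1 >= nc) j1 = nc - 1;
    double r2 = rr * rr + 1e-9;
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double d2 = (i - cy) * (i - cy) + (j - cx) * (j - cx);
        if (d2 <= r2) out(i, j) = true;
      }
  }
  return out;
}

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Decompose a 1-px skeleton into branches. Junction pixels are skeleton
// pixels whose circular crossing number (0->1 transitions in the p2..p9
// ring) is >= 3 -- the crossing number is robust against the L-corner
// artifacts of thinned staircases that inflate the plain neighbour
// count. Endpoints have crossing number <= 1. The remaining pixels form
// simple path segments (8-connected), each traced in order and extended
// by one adjacent junction pixel at each end when present. Junction
// pixels are additionally clustered (8-connected) into junction nodes.
// Returns ordered (row, col) paths, a closed-loop flag per branch, an
// endpoint-flag pair per branch, and the junction node / endpoint
// coordinate lists.
// [[Rcpp::export]]
List cpp_trace_branches(const LogicalMatrix &skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<signed char> sk(nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) sk[i + j * nr] = skel(i, j) ? 1 : 0;

  auto on = [&](int i, int j) -> bool {
    return i >= 0 && i < nr && j >= 0 && j < nc && sk[i + j * nr];
  };
  // ring order p2..p9 clockwise from north
  static const int RR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int RC[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  auto crossing = [&](int i, int j) -> int {
    int x = 0;
    for (int k = 0; k < 8; ++k) {
      int a = on(i + RR[k], j + RC[k]);
      int b = on(i + RR[(k + 1) % 8], j + RC[(k + 1) % 8]);
      x += (a == 0 && b == 1);
    }
    return x;
  };

  std::vector<std::pair<int, int> > junctions, endpoints;
  std::vector<char> isjun(nr * nc, 0), isend(nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      if (!sk[idx]) continue;
      int x = crossing(i, j);
      if (x >= 3) { isjun[idx] = 1; junctions.push_back(std::make_pair(i, j)); }
      else if (x <= 1) { isend[idx] = 1; endpoints.push_back(std::make_pair(i, j)); }
    }

  // a diagonal move between two non-junction pixels that both touch the
  // same junction pixel is a corner cut across the junction; segment
  // connectivity must route through the junction instead
  auto diag_blocked = [&](int i, int j, int ni, int nj) -> bool {
    if (i == ni || j == nj) return false;
    return (on(i, nj) && isjun[i + nj * nr]) ||
           (on(ni, j) && isjun[ni + j * nr]);
  };

  // label non-junction skeleton pixels into 8-connected segments
  std::vector<int> lab(nr * nc, 0);
  int nseg = 0;
  std::vector<std::vector<std::pair<int, int> > > segs;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      if (!sk[idx] || isjun[idx] || lab[idx]) continue;
      ++nseg;
      segs.push_back(std::vector<std::pair<int, int> >());
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(i, j));
      lab[idx] = nseg;
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        segs[nseg - 1].push_back(p);
        for (int k = 0; k < 8; ++k) {
          int ni = p.first + DR[k], nj = p.second + DC[k];
          if (!on(ni, nj)) continue;
          int nidx = ni + nj * nr;
          if (isjun[nidx] || lab[nidx]) continue;
          if (diag_blocked(p.first, p.second, ni, nj)) continue;
          lab[nidx] = nseg;
          q.push(std::make_pair(ni, nj));
        }
      }
    }

  List paths(nseg);
  LogicalVector closed(nseg);
  LogicalMatrix free_end(nseg, 2);
  for (int s = 0; s < nseg; ++s) {
    std::vector<std::pair<int, int> > &px = segs[s];
    int m = (int)px.size();
    // in-segment degree; a path end has <= 1 same-segment neighbour
    int start = -1;
    for (int k = 0; k < m && start < 0; ++k) {
      int d = 0;
      for (int t = 0; t < 8; ++t) {
        int ni = px[k].first + DR[t], nj = px[k].second + DC[t];
        if (on(ni, nj) && lab[ni + nj * nr] == s + 1 &&
            !diag_blocked(px[k].first, px[k].second, ni, nj)) ++d;
      }
      if (d <= 1) start = k;
    }
    bool is_cycle = (start < 0);
    if (is_cycle) start = 0;

    std::vector<std::pair<int, int> > ordered;
    std::vector<char> used(m, 0);
    // walk from start, always moving to an unvisited same-segment neighbour
    std::pair<int, int> cur = px[start];
    // map coordinates to local index for the visited flags
    // (segments are small; linear search is fine)
    auto find_local = [&](int i, int j) -> int {
      for (int k = 0; k < m; ++k)
        if (px[k].first == i && px[k].second == j) return k;
      return -1;
    };
    int cidx = start;
    while (cidx >= 0) {
      used[cidx] = 1;
      ordered.push_back(px[cidx]);
      int nxt = -1;
      for (int t = 0; t < 8 && nxt < 0; ++t) {
        int ni = px[cidx].first + DR[t], nj = px[cidx].second + DC[t];
        if (!on(ni, nj) || lab[ni + nj * nr] != s + 1) continue;
        if (diag_blocked(px[cidx].first, px[cidx].second, ni, nj)) continue;
        int l = find_local(ni, nj);
        if (l >= 0 && !used[l]) nxt = l;
      }
      cidx = nxt;
    }

    // extend ends with an adjacent junction pixel, if any
    std::vector<std::pair<int, int> > full;
    std::pair<int, int> head = ordered.front(), tail = ordered.back();
    int hj = -1, tj = -1;
    for (int t = 0; t < 8; ++t) {
      int ni = head.first + DR[t], nj = head.second + DC[t];
      if (on(ni, nj) && isjun[ni + nj * nr]) { hj = ni + nj * nr; break; }
    }
    for (int t = 0; t < 8; ++t) {
      int ni = tail.first + DR[t], nj = tail.second + DC[t];
      if (on(ni, nj) && isjun[ni + nj * nr] && ni + nj * nr != hj) { tj = ni + nj * nr; break; }
    }
    if (!is_cycle && hj >= 0) full.push_back(std::make_pair(hj % nr, hj / nr));
    full.insert(full.end(), ordered.begin(), ordered.end());
    if (!is_cycle && tj >= 0) full.push_back(std::make_pair(tj % nr, tj / nr));
    if (is_cycle && (int)ordered.size() > 2) full.push_back(ordered.front());

    IntegerMatrix pm((int)full.size(), 2);
    for (int k = 0; k < (int)full.size(); ++k) {
      pm(k, 0) = full[k].first + 1;  // 1-based rows
      pm(k, 1) = full[k].second + 1;
    }
    paths[s] = pm;
    closed[s] = is_cycle;
    free_end(s, 0) = !is_cycle && hj < 0 &&
      isend[full.front().first + full.front().second * nr];
    free_end(s, 1) = !is_cycle && tj < 0 &&
      isend[full.back().first + full.back().second * nr];
  }

  // cluster junction pixels into 8-connected junction nodes (centroids)
  std::vector<int> jlab(nr * nc, 0);
  std::vector<double> jrow, jcol;
  int njun = 0;
  for (size_t k = 0; k < junctions.size(); ++k) {
    int i = junctions[k].first, j = junctions[k].second;
    if (jlab[i + j * nr]) continue;
    ++njun;
    double sr = 0, sc = 0; int cnt = 0;
    std::queue<std::pair<int, int> > q;
    q.push(junctions[k]);
    jlab[i + j * nr] = njun;
    while (!q.empty()) {
      std::pair<int, int> p = q.front(); q.pop();
      sr += p.first; sc += p.second; ++cnt;
      for (int t = 0; t < 8; ++t) {
        int ni = p.first + DR[t], nj = p.second + DC[t];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int nidx = ni + nj * nr;
        if (isjun[nidx] && !jlab[nidx]) {
          jlab[nidx] = njun;
          q.push(std::make_pair(ni, nj));
        }
      }
    }
    jrow.push_back(sr / cnt + 1.0);
    jcol.push_back(sc / cnt + 1.0);
  }

  NumericMatrix jm(njun, 2);
  IntegerMatrix em((int)endpoints.size(), 2);
  for (int k = 0; k < njun; ++k) { jm(k, 0) = jrow[k]; jm(k, 1) = jcol[k]; }
  for (size_t k = 0; k < endpoints.size(); ++k) {
    em(k, 0) = endpoints[k].first + 1; em(k, 1) = endpoints[k].second + 1;
  }
  return List::create(_["paths"] = paths, _["closed"] = closed,
                      _["free_end"] = free_end, _["junctions"] = jm,
                      _["endpoints"] = em);
}
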