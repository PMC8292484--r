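#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Decompose a 1-px skeleton into branches: connected runs of non-junction
// pixels (8-connectivity), each extended by one adjacent junction pixel at
// either end.  Junction pixels are those with >= 3 skeleton neighbours;
// adjacent junction pixels form one junction cluster.

static inline bool in(int i, int j, int nr, int nc) {
  return i >= 0 && j >= 0 && i < nr && j < nc;
}

// neighbour offsets: 4-neighbours first so path walking does not cut corners
static const int DR[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
static const int DC[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };

// [[Rcpp::export(name = ".trace_skeleton")]]
List trace_skeleton(LogicalMatrix sk) {
  int nr = sk.nrow(), nc = sk.ncol();
  IntegerMatrix nb(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (sk(i, j) != TRUE) continue;
      int B = 0;
      for (int q = 0; q < 8; ++q) {
        int r = i + DR[q], c = j + DC[q];
        if (in(r, c, nr, nc) && sk(r, c) == TRUE) ++B;
      }
      nb(i, j) = B;
    }
  LogicalMatrix junction(nr, nc), interior(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      junction(i, j) = sk(i, j) == TRUE && nb(i, j) >= 3;
      interior(i, j) = sk(i, j) == TRUE && nb(i, j) < 3;
    }
  // junction clusters (8-connected flood fill)
  int n_junctions = 0;
  {
    LogicalMatrix seen(nr, nc);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (junction(i, j) != TRUE || seen(i, j) == TRUE) continue;
        ++n_junctions;
        std::queue<std::pair<int,int>> q;
        q.push(std::make_pair(i, j)); seen(i, j) = TRUE;
        while (!q.empty()) {
          std::pair<int,int> p = q.front(); q.pop();
          for (int k = 0; k < 8; ++k) {
            int r = p.first + DR[k], c = p.second + DC[k];
            if (in(r, c, nr, nc) && junction(r, c) == TRUE && seen(r, c) != TRUE) {
              seen(r, c) = TRUE; q.push(std::make_pair(r, c));
            }
          }
        }
      }
  }
  // interior neighbour counts (within interior only)
  IntegerMatrix inb(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (interior(i, j) != TRUE) continue;
      int B = 0;
      for (int q = 0; q < 8; ++q) {
        int r = i + DR[q], c = j + DC[q];
        if (in(r, c, nr, nc) && interior(r, c) == TRUE) ++B;
      }
      inb(i, j) = B;
    }
  LogicalMatrix visited(nr, nc);
  std::vector<std::vector<int>> paths_r, paths_c;
  std::vector<int> head_j, tail_j;  // 1-based flags: junction attached
  // trace from a start pixel, walking unvisited interior neighbours
  std::vector<std::pair<int,int>> starts;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (interior(i, j) == TRUE && inb(i, j) <= 1)
        starts.push_back(std::make_pair(i, j));    // path endpoints first
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (interior(i, j) == TRUE)
        starts.push_back(std::make_pair(i, j));    // remaining cycles
  for (size_t s = 0; s < starts.size(); ++s) {
    int i = starts[s].first, j = starts[s].second;
    if (visited(i, j) == TRUE) continue;
    std::vector<int> pr, pc;
    int ci = i, cj = j;
    while (true) {
      visited(ci, cj) = TRUE;
      pr.push_back(ci); pc.push_back(cj);
      int ni = -1, nj = -1;
      for (int q = 0; q < 8; ++q) {
        int r = ci + DR[q], c = cj + DC[q];
        if (in(r, c, nr, nc) && interior(r, c) == TRUE && visited(r, c) != TRUE) {
          ni = r; nj = c; break;
        }
      }
      if (ni < 0) break;
      ci = ni; cj = nj;
    }
    // attach one adjacent junction pixel at each end
    int hj = 0, tj = 0;
    for (int q = 0; q < 8; ++q) {
      int r = pr.front() + DR[q], c = pc.front() + DC[q];
      if (in(r, c, nr, nc) && junction(r, c) == TRUE) {
        pr.insert(pr.begin(), r); pc.insert(pc.begin(), c); hj = 1; break;
      }
    }
    for (int q = 0; q < 8; ++q) {
      int r = pr.back() + DR[q], c = pc.back() + DC[q];
      if (in(r, c, nr, nc) && junction(r, c) == TRUE) {
        pr.push_back(r); pc.push_back(c); tj = 1; break;
      }
    }
    paths_r.push_back(pr); paths_c.push_back(pc);
    head_j.push_back(hj); tail_j.push_back(tj);
  }
  int nb_br = paths_r.size();
  List paths(nb_br);
  NumericVector arc(nb_br), chord(nb_br);
  IntegerVector n_diag(nb_br), n_straight(nb_br), head_att(nb_br), tail_att(nb_br);
  for (int b = 0; b < nb_br; ++b) {
    int n = paths_r[b].size();
    IntegerMatrix P(n, 2);
    int nd = 0, ns = 0;
    for (int k = 0; k < n; ++k) {
      P(k, 0) = paths_r[b][k] + 1;  // 1-based for R
      P(k, 1) = paths_c[b][k] + 1;
      if (k > 0) {
        int dr = std::abs(paths_r[b][k] - paths_r[b][k - 1]);
        int dc = std::abs(paths_c[b][k] - paths_c[b][k - 1]);
        if (dr + dc == 2) ++nd; else ++ns;
      }
    }
    double drr = paths_r[b][n - 1] - paths_r[b][0];
    double dcc = paths_c[b][n - 1] - paths_c[b][0];
    paths[b] = P;
    arc[b] = ns + nd * std::sqrt(2.0);
    chord[b] = std::sqrt(drr * drr + dcc * dcc);
    n_diag[b] = nd; n_straight[b] = ns;
    head_att[b] = head_j[b]; tail_att[b] = tail_j[b];
  }
  return List::create(_["paths"] = paths, _["arc"] = arc, _["chord"] = chord,
                      _["n_diag"] = n_diag, _["n_straight"] = n_straight,
                      _["head_att"] = head_att, _["tail_att"] = tail_att,
                      _["n_junctions"] = n_junctions);
}
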