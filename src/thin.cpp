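#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning followed by a sequential cleanup pass that removes
// remaining 8-simple pixels with >= 3 neighbours (diagonal ribbons of
// width 2 that the parallel passes cannot reduce).  Operates on a logical
// matrix; border pixels are never foreground candidates for deletion
// conditions that would index outside the image.

// [[Rcpp::export(name = ".zs_thin")]]
LogicalMatrix zs_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // padded raw buffer (1-px false border removes bound checks)
  int pr = nr + 2, pcn = nc + 2;
  std::vector<unsigned char> M((size_t) pr * pcn, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      M[(size_t)(j + 1) * pr + (i + 1)] = mask(i, j) == TRUE;
  const int oN = -1, oS = 1, oW = -pr, oE = pr;
  const int oNE = oN + oE, oSE = oS + oE, oSW = oS + oW, oNW = oN + oW;
  std::vector<size_t> kill;
  kill.reserve(4096);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int j = 1; j <= nc; ++j) {
        size_t base = (size_t) j * pr;
        for (int i = 1; i <= nr; ++i) {
          size_t k = base + i;
          if (!M[k]) continue;
          bool p2 = M[k + oN], p3 = M[k + oNE], p4 = M[k + oE], p5 = M[k + oSE];
          bool p6 = M[k + oS], p7 = M[k + oSW], p8 = M[k + oW], p9 = M[k + oNW];
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (!p2 && p3) + (!p3 && p4) + (!p4 && p5) + (!p5 && p6) +
                  (!p6 && p7) + (!p7 && p8) + (!p8 && p9) + (!p9 && p2);
          if (A != 1) continue;
          bool ok = step == 0 ? (!(p2 && p4 && p6) && !(p4 && p6 && p8))
                              : (!(p2 && p4 && p8) && !(p2 && p6 && p8));
          if (ok) kill.push_back(k);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t k = 0; k < kill.size(); ++k) M[kill[k]] = 0;
      }
    }
  }
  // sequential cleanup: Hilditch crossing number 1, >= 3 neighbours
  // circular order N NE E SE S SW W NW (4-neighbours at even positions)
  const int circ[8] = { oN, oNE, oE, oSE, oS, oSW, oW, oNW };
  bool removed = true;
  while (removed) {
    removed = false;
    for (int j = 1; j <= nc; ++j) {
      size_t base = (size_t) j * pr;
      for (int i = 1; i <= nr; ++i) {
        size_t k = base + i;
        if (!M[k]) continue;
        bool x[8];
        int B = 0;
        for (int q = 0; q < 8; ++q) { x[q] = M[k + circ[q]]; B += x[q]; }
        if (B < 3) continue;
        int xh = 0;
        for (int q = 0; q < 8; q += 2)
          if (!x[q] && (x[(q + 1) % 8] || x[(q + 2) % 8])) ++xh;
        if (xh == 1) { M[k] = 0; removed = true; }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = M[(size_t)(j + 1) * pr + (i + 1)] != 0;
  return out;
}

static inline bool at(const LogicalMatrix &M, int i, int j) {
  if (i < 0 || j < 0 || i >= M.nrow() || j >= M.ncol()) return false;
  return M(i, j) == TRUE;
}

// neighbour counts over the 8-neighbourhood of foreground pixels
// [[Rcpp::export(name = ".nb_count")]]
IntegerMatrix nb_count(LogicalMatrix M) {
  int nr = M.nrow(), nc = M.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (M(i, j) != TRUE) { out(i, j) = 0; continue; }
      int B = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          if ((di || dj) && at(M, i + di, j + dj)) ++B;
      out(i, j) = B;
    }
  return out;
}
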