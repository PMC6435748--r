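#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input/output: integer matrix of 0/1.
// Produces an 8-connected, one-pixel-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix thin_zhang_suen(IntegerMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix m = clone(img);
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return m(r, c);
  };
  bool changed = true;
  std::vector<std::pair<int,int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!m(r, c)) continue;
          // neighbours p2..p9 clockwise from north
          int p2 = at(r-1,c), p3 = at(r-1,c+1), p4 = at(r,c+1), p5 = at(r+1,c+1),
              p6 = at(r+1,c), p7 = at(r+1,c-1), p8 = at(r,c-1), p9 = at(r-1,c-1);
          int B = p2+p3+p4+p5+p6+p7+p8+p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2,p3,p4,p5,p6,p7,p8,p9,p2};
          int A = 0;
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k+1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2*p4*p6 != 0 || p4*p6*p8 != 0) continue;
          } else {
            if (p2*p4*p8 != 0 || p2*p6*p8 != 0) continue;
          }
          kill.push_back({r, c});
        }
      }
      for (auto &rc : kill) m(rc.first, rc.second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}

// Count of 8-neighbours that are set, per pixel of a 0/1 matrix.
// [[Rcpp::export]]
IntegerMatrix neighbour_count8(IntegerMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int n = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < H && cc >= 0 && cc < W && img(rr, cc)) ++n;
        }
      out(r, c) = n;
    }
  return out;
}

// 8-connected component labelling of a binary matrix (BFS).
// [[Rcpp::export]]
IntegerMatrix label8(IntegerMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!img(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(c0 * H + r0);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % H, c = idx / H;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (img(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(cc * H + rr);
            }
          }
      }
    }
  return lab;
}

// Rutovitz crossing number: 0->1 transitions in the circular sequence of
// 8-neighbours. 2 on a simple arc; >= 3 at a junction.
// [[Rcpp::export]]
IntegerMatrix crossing_number8(IntegerMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= H || c < 0 || c >= W) return 0;
    return img(r, c);
  };
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int p[9] = {at(r-1,c), at(r-1,c+1), at(r,c+1), at(r+1,c+1),
                  at(r+1,c), at(r+1,c-1), at(r,c-1), at(r-1,c-1), at(r-1,c)};
      int A = 0;
      for (int k = 0; k < 8; ++k) if (p[k] == 0 && p[k+1] == 1) ++A;
      out(r, c) = A;
    }
  return out;
}
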