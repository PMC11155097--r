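// Gray-level texture matrix construction. Level images are integer
// matrices with 0 marking pixels outside the ROI and in-mask levels in
// 1..n_levels. Feature formulas live in R; only the counting is here.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Co-occurrence counts for a single offset (dr, dc); not symmetrized.
// [[Rcpp::export]]
IntegerMatrix cpp_glcm(const IntegerMatrix& lv, int ng, int dr, int dc) {
  IntegerMatrix out(ng, ng);
  int H = lv.nrow(), W = lv.ncol();
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = lv(r, c);
      if (a == 0) continue;
      int r2 = r + dr, c2 = c + dc;
      if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
      int b = lv(r2, c2);
      if (b == 0) continue;
      out(a - 1, b - 1)++;
    }
  }
  return out;
}

// Run-length counts along direction (dr, dc); runs are maximal in-mask
// streaks of a constant level.
// [[Rcpp::export]]
IntegerMatrix cpp_glrlm(const IntegerMatrix& lv, int ng, int dr, int dc) {
  int H = lv.nrow(), W = lv.ncol();
  int maxrun = std::max(H, W);
  IntegerMatrix out(ng, maxrun);
  IntegerMatrix seen(H, W);
  // start pixels: those with no in-mask same-level predecessor at (-dr,-dc)
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = lv(r, c);
      if (a == 0) continue;
      int rp = r - dr, cp = c - dc;
      bool has_prev = rp >= 0 && rp < H && cp >= 0 && cp < W && lv(rp, cp) == a;
      if (has_prev) continue;
      int len = 0, rr = r, cc = c;
      while (rr >= 0 && rr < H && cc >= 0 && cc < W && lv(rr, cc) == a) {
        ++len; rr += dr; cc += dc;
      }
      out(a - 1, len - 1)++;
    }
  }
  return out;
}

// 8-connected (or 4-connected) component labels of a logical matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& m, int connectivity) {
  int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int,int>> offs;
  offs.push_back({0,1}); offs.push_back({0,-1});
  offs.push_back({1,0}); offs.push_back({-1,0});
  if (connectivity == 8) {
    offs.push_back({1,1}); offs.push_back({1,-1});
    offs.push_back({-1,1}); offs.push_back({-1,-1});
  }
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!m(r, c) || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      std::queue<std::pair<int,int>> q;
      q.push({r, c});
      while (!q.empty()) {
        auto p = q.front(); q.pop();
        for (auto& o : offs) {
          int r2 = p.first + o.first, c2 = p.second + o.second;
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (m(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push({r2, c2});
          }
        }
      }
    }
  }
  return lab;
}

// Size-zone counts: zones are 8-connected components of equal level.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(const IntegerMatrix& lv, int ng) {
  int H = lv.nrow(), W = lv.ncol();
  IntegerMatrix seen(H, W);
  std::vector<std::vector<int>> zones(ng); // zone sizes per level
  int offs[8][2] = {{0,1},{0,-1},{1,0},{-1,0},{1,1},{1,-1},{-1,1},{-1,-1}};
  int maxzone = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = lv(r, c);
      if (a == 0 || seen(r, c)) continue;
      int size = 0;
      std::queue<std::pair<int,int>> q;
      q.push({r, c}); seen(r, c) = 1;
      while (!q.empty()) {
        auto p = q.front(); q.pop(); ++size;
        for (auto& o : offs) {
          int r2 = p.first + o[0], c2 = p.second + o[1];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (!seen(r2, c2) && lv(r2, c2) == a) {
            seen(r2, c2) = 1;
            q.push({r2, c2});
          }
        }
      }
      zones[a - 1].push_back(size);
      if (size > maxzone) maxzone = size;
    }
  }
  IntegerMatrix out(ng, std::max(maxzone, 1));
  for (int i = 0; i < ng; ++i)
    for (int s : zones[i]) out(i, s - 1)++;
  return out;
}

// Dependence counts: for each in-mask pixel, d = number of in-mask
// neighbours within Chebyshev distance delta whose |level diff| <= alpha.
// Column j holds dependence d = j - 1 (0-based neighbour count).
// [[Rcpp::export]]
IntegerMatrix cpp_gldm(const IntegerMatrix& lv, int ng, int alpha, int delta) {
  int H = lv.nrow(), W = lv.ncol();
  int maxd = (2 * delta + 1) * (2 * delta + 1) - 1;
  IntegerMatrix out(ng, maxd + 1);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int a = lv(r, c);
      if (a == 0) continue;
      int d = 0;
      for (int dr = -delta; dr <= delta; ++dr) {
        for (int dc = -delta; dc <= delta; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          int b = lv(r2, c2);
          if (b == 0) continue;
          if (std::abs(a - b) <= alpha) ++d;
        }
      }
      out(a - 1, d)++;
    }
  }
  return out;
}
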