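#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Zhang-Suen morphological thinning of a binary image (0/1 integer matrix).
// Returns a 1-pixel-wide 8-connected skeleton. Standard two-subiteration
// scheme; iterates until no pixel changes.
// [[Rcpp::export]]
IntegerMatrix thin_binary(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(clone(img));
  std::vector<std::pair<int,int>> to_del;
  bool changed = true;
  // neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW (row = y, col = x)
  const int dr[8] = {-1,-1, 0, 1, 1, 1, 0,-1};
  const int dc[8] = { 0, 1, 1, 1, 0,-1,-1,-1};
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      to_del.clear();
      for (int r = 1; r < nr - 1; ++r) {
        for (int c = 1; c < nc - 1; ++c) {
          if (!out(r, c)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) p[k] = out(r + dr[k], c + dc[k]);
          int B = 0;
          for (int k = 0; k < 8; ++k) B += p[k];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k) if (!p[k] && p[(k + 1) % 8]) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          to_del.push_back({r, c});
        }
      }
      if (!to_del.empty()) changed = true;
      for (auto &rc : to_del) out(rc.first, rc.second) = 0;
    }
  }
  return out;
}

// 8-connected component labelling by BFS flood fill. Labels start at 1 in
// scan order; 0 stays background.
// [[Rcpp::export]]
IntegerMatrix label_components(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int>> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      q.push({r, c});
      while (!q.empty()) {
        auto rc = q.front(); q.pop();
        for (int dr2 = -1; dr2 <= 1; ++dr2) {
          for (int dc2 = -1; dc2 <= 1; ++dc2) {
            int rr = rc.first + dr2, cc = rc.second + dc2;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (img(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push({rr, cc});
            }
          }
        }
      }
    }
  }
  return lab;
}

// Scanline polygon fill (even-odd rule) at pixel centers. px/py: polygon
// vertices in 0-based pixel coordinates; nr/nc: image size (rows = y).
// [[Rcpp::export]]
IntegerMatrix fill_polygon(NumericVector px, NumericVector py,
                           int nr, int nc) {
  IntegerMatrix out(nr, nc);
  int n = px.size();
  std::vector<double> xs;
  for (int r = 0; r < nr; ++r) {
    double yc = (double)r;  // pixel-center y
    xs.clear();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double y1 = py[i], y2 = py[j];
      if ((y1 <= yc && y2 > yc) || (y2 <= yc && y1 > yc)) {
        double t = (yc - y1) / (y2 - y1);
        xs.push_back(px[i] + t * (px[j] - px[i]));
      }
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k] - 1e-9);
      int c1 = (int)std::floor(xs[k + 1] + 1e-9);
      if (c0 < 0) c0 = 0;
      if (c1 >= nc) c1 = nc - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = 1;
    }
  }
  return out;
}
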