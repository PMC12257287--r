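#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Zhang-Suen thinning: iteratively peels boundary pixels of a binary image
// until only a 1-px-wide skeleton remains. Neighbours indexed clockwise
// P2..P9 starting from the pixel above.
// [[Rcpp::export(name = ".thin_zhang_suen")]]
LogicalMatrix thin_zhang_suen(LogicalMatrix img) {
  int H = img.nrow(), W = img.ncol();
  std::vector<unsigned char> a((H + 2) * (W + 2), 0);
  int stride = W + 2;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      a[(r + 1) * stride + (c + 1)] = img(r, c) ? 1 : 0;

  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 1; r <= H; ++r) {
        for (int c = 1; c <= W; ++c) {
          int idx = r * stride + c;
          if (!a[idx]) continue;
          unsigned char p2 = a[idx - stride], p3 = a[idx - stride + 1],
                        p4 = a[idx + 1],      p5 = a[idx + stride + 1],
                        p6 = a[idx + stride], p7 = a[idx + stride - 1],
                        p8 = a[idx - 1],      p9 = a[idx - stride - 1];
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
          kill.push_back(idx);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) a[kill[k]] = 0;
    }
  }

  LogicalMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      out(r, c) = a[(r + 1) * stride + (c + 1)] != 0;
  return out;
}

// Progressive probabilistic Hough transform (Matas, Galambos & Kittler):
// randomly pops foreground pixels, votes each into a (rho, theta)
// accumulator, and whenever a bin passes `threshold` walks along the
// winning direction through the image (allowing gaps up to `line_gap`),
// removes the supporting pixels, and keeps the segment if it is at least
// `line_length` long. Randomness comes from R's RNG, so results are
// reproducible under set.seed(). Coordinates returned 1-based
// (x = column, y = row).
// [[Rcpp::export(name = ".hough_lines_prob")]]
IntegerMatrix hough_lines_prob(LogicalMatrix img, int threshold,
                               int line_length, int line_gap,
                               NumericVector theta) {
  int H = img.nrow(), W = img.ncol();
  int n_theta = theta.size();
  int max_dist = (int)std::ceil(std::sqrt((double)H * H + (double)W * W));
  int n_rho = 2 * max_dist + 1;

  std::vector<double> ctheta(n_theta), stheta(n_theta);
  for (int j = 0; j < n_theta; ++j) {
    ctheta[j] = std::cos(theta[j]);
    stheta[j] = std::sin(theta[j]);
  }

  std::vector<int> accum((size_t)n_rho * n_theta, 0);
  std::vector<unsigned char> mask((size_t)H * W, 0);
  std::vector<std::pair<int, int>> pts;  // (x, y), 0-based
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      if (img(r, c)) {
        mask[(size_t)r * W + c] = 1;
        pts.push_back(std::make_pair(c, r));
      }

  std::vector<int> sx1, sy1, sx2, sy2;
  int count = (int)pts.size();
  const int SHIFT = 16, ONE = 1 << SHIFT, HALF = ONE >> 1;

  while (count > 0) {
    int pick = (int)(unif_rand() * count);
    if (pick >= count) pick = count - 1;
    int x = pts[pick].first, y = pts[pick].second;
    pts[pick] = pts[count - 1];
    --count;
    if (!mask[(size_t)y * W + x]) continue;

    // vote and find the strongest orientation for this pixel
    int best = 0, best_j = 0;
    for (int j = 0; j < n_theta; ++j) {
      int rho = (int)std::lround(ctheta[j] * x + stheta[j] * y) + max_dist;
      int v = ++accum[(size_t)rho * n_theta + j];
      if (v > best) { best = v; best_j = j; }
    }
    if (best < threshold) continue;

    // direction along the candidate line (perpendicular to the normal)
    double a = -stheta[best_j], b = ctheta[best_j];
    int x0 = x, y0 = y;
    bool xflag = std::fabs(a) > std::fabs(b);
    int dx0, dy0, px0, py0;
    if (xflag) {
      dx0 = a > 0 ? 1 : -1;
      dy0 = (int)std::lround(b * ONE / std::fabs(a));
      px0 = x0; py0 = (y0 << SHIFT) + HALF;
    } else {
      dy0 = b > 0 ? 1 : -1;
      dx0 = (int)std::lround(a * ONE / std::fabs(b));
      py0 = y0; px0 = (x0 << SHIFT) + HALF;
    }

    int ex[2] = {x0, x0}, ey[2] = {y0, y0};
    for (int k = 0; k < 2; ++k) {
      int gap = 0;
      int dx = k ? -dx0 : dx0, dy = k ? -dy0 : dy0;
      int px = px0, py = py0;
      for (;;) {
        int x1, y1;
        if (xflag) { x1 = px; y1 = py >> SHIFT; }
        else       { x1 = px >> SHIFT; y1 = py; }
        if (x1 < 0 || x1 >= W || y1 < 0 || y1 >= H) break;
        if (mask[(size_t)y1 * W + x1]) {
          gap = 0;
          ex[k] = x1; ey[k] = y1;
        } else if (++gap > line_gap) break;
        px += dx; py += dy;
      }
    }

    bool good = std::abs(ex[1] - ex[0]) >= line_length ||
                std::abs(ey[1] - ey[0]) >= line_length;

    if (!good) continue;

    // remove the segment's supporting pixels and their accumulator votes
    for (int k = 0; k < 2; ++k) {
      int dx = k ? -dx0 : dx0, dy = k ? -dy0 : dy0;
      int px = px0, py = py0;
      for (;;) {
        int x1, y1;
        if (xflag) { x1 = px; y1 = py >> SHIFT; }
        else       { x1 = px >> SHIFT; y1 = py; }
        if (x1 < 0 || x1 >= W || y1 < 0 || y1 >= H) break;
        size_t m = (size_t)y1 * W + x1;
        if (mask[m]) {
          for (int j = 0; j < n_theta; ++j) {
            int rho = (int)std::lround(ctheta[j] * x1 + stheta[j] * y1) +
                      max_dist;
            --accum[(size_t)rho * n_theta + j];
          }
          mask[m] = 0;
        }
        if (x1 == ex[k] && y1 == ey[k]) break;
        px += dx; py += dy;
      }
    }

    if (good) {
      sx1.push_back(ex[0] + 1); sy1.push_back(ey[0] + 1);
      sx2.push_back(ex[1] + 1); sy2.push_back(ey[1] + 1);
    }
  }

  IntegerMatrix out((int)sx1.size(), 4);
  for (int i = 0; i < (int)sx1.size(); ++i) {
    out(i, 0) = sx1[i]; out(i, 1) = sy1[i];
    out(i, 2) = sx2[i]; out(i, 3) = sy2[i];
  }
  colnames(out) = CharacterVector::create("x1", "y1", "x2", "y2");
  return out;
}
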