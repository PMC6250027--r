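#include <Rcpp.h>
#include <cmath>
#include <queue>
using namespace Rcpp;

// SLIC superpixels on a precomputed L*a*b* raster.
//
// Matrices are indexed [x, y] (EBImage convention: dim1 = width).
// Distance in the joint [l a b x y] space: D^2 = d_lab^2 + (m/S)^2 * d_xy^2,
// where S = sqrt(N/k) is the sampling interval and m the compactness.
// A connectivity-enforcement pass relabels stray fragments to an adjacent
// superpixel so every output region is 4-connected; labels are 1..n.

// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                       int k, double compactness, int max_iter) {
  const int W = L.nrow(), H = L.ncol();
  const double N = (double)W * (double)H;
  const double S = std::sqrt(N / (double)k);

  // grid-initialised cluster centers
  int nx = std::max(1, (int)std::round(W / S));
  int ny = std::max(1, (int)std::round(H / S));
  const int nc = nx * ny;
  std::vector<double> cl(nc), ca(nc), cb(nc), cx(nc), cy(nc);
  {
    int c = 0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++c) {
        int x = std::min(W - 1, (int)((i + 0.5) * W / nx));
        int y = std::min(H - 1, (int)((j + 0.5) * H / ny));
        cx[c] = x; cy[c] = y;
        cl[c] = L(x, y); ca[c] = A(x, y); cb[c] = B(x, y);
      }
  }

  std::vector<int> lab(W * H, -1);
  std::vector<double> dist(W * H);
  const double mw = (compactness / S) * (compactness / S);
  const int R = (int)S + 1;  // standard 2S x 2S search window

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < nc; ++c) {
      int x0 = std::max(0, (int)cx[c] - R), x1 = std::min(W - 1, (int)cx[c] + R);
      int y0 = std::max(0, (int)cy[c] - R), y1 = std::min(H - 1, (int)cy[c] + R);
      for (int y = y0; y <= y1; ++y) {
        for (int x = x0; x <= x1; ++x) {
          double dl = L(x, y) - cl[c], da = A(x, y) - ca[c], db = B(x, y) - cb[c];
          double dx = x - cx[c], dy = y - cy[c];
          double d = dl * dl + da * da + db * db + mw * (dx * dx + dy * dy);
          int idx = y * W + x;
          if (d < dist[idx]) { dist[idx] = d; lab[idx] = c; }
        }
      }
    }
    // update centers
    std::vector<double> sl(nc, 0), sa(nc, 0), sb(nc, 0), sx(nc, 0), sy(nc, 0);
    std::vector<int> cnt(nc, 0);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int c = lab[y * W + x];
        if (c < 0) continue;
        sl[c] += L(x, y); sa[c] += A(x, y); sb[c] += B(x, y);
        sx[c] += x; sy[c] += y; ++cnt[c];
      }
    for (int c = 0; c < nc; ++c)
      if (cnt[c] > 0) {
        cl[c] = sl[c] / cnt[c]; ca[c] = sa[c] / cnt[c]; cb[c] = sb[c] / cnt[c];
        cx[c] = sx[c] / cnt[c]; cy[c] = sy[c] / cnt[c];
      }
  }

  // connectivity enforcement: flood-fill 4-connected fragments; only
  // fragments well below the nucleus scale (S*S/8) are absorbed by the
  // previously visited neighbour, so small colour-coherent regions keep
  // their own superpixel.
  const int minSize = std::max(1, (int)(S * S / 8.0));
  std::vector<int> out(W * H, -1);
  const int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
  int nlab = 0;
  std::vector<int> comp;
  comp.reserve(4 * minSize);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int idx = y * W + x;
      if (out[idx] >= 0) continue;
      int adj = -1;  // an already-labelled neighbouring component
      comp.clear();
      out[idx] = nlab;
      comp.push_back(idx);
      for (size_t q = 0; q < comp.size(); ++q) {
        int px = comp[q] % W, py = comp[q] / W;
        for (int d = 0; d < 4; ++d) {
          int qx = px + dx4[d], qy = py + dy4[d];
          if (qx < 0 || qx >= W || qy < 0 || qy >= H) continue;
          int qi = qy * W + qx;
          if (out[qi] < 0 && lab[qi] == lab[idx]) {
            out[qi] = nlab;
            comp.push_back(qi);
          } else if (out[qi] >= 0 && out[qi] != nlab) {
            adj = out[qi];
          }
        }
      }
      if ((int)comp.size() < minSize && adj >= 0) {
        for (size_t q = 0; q < comp.size(); ++q) out[comp[q]] = adj;
      } else {
        ++nlab;
      }
    }
  }

  // compact labels to 1..n
  std::vector<int> remap(nlab, -1);
  int next = 0;
  IntegerMatrix res(W, H);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int c = out[y * W + x];
      if (remap[c] < 0) remap[c] = next++;
      res(x, y) = remap[c] + 1;
    }
  return res;
}
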