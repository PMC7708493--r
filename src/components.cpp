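// 3-D connected-component labelling by breadth-first flood fill.
// Components are visited in increasing linear voxel index, so label ids are
// already ordered by the smallest linear index of each component.
#include <Rcpp.h>
#include <array>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3-D array");
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manhattan == 0) continue;
        if (connectivity == 6 && manhattan != 1) continue;
        if (connectivity == 18 && manhattan > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  int next_label = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || labels[start] != 0) continue;
    ++next_label;
    queue.clear();
    queue.push_back(start);
    labels[start] = next_label;
    size_t head = 0;
    while (head < queue.size()) {
      const R_xlen_t v = queue[head++];
      const int r = (int)(v % nr);
      const int c = (int)((v / nr) % nc);
      const int s = (int)(v / ((R_xlen_t)nr * nc));
      for (const auto& o : offs) {
        const int rr = r + o[0], cc = c + o[1], ss = s + o[2];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || ss < 0 || ss >= ns)
          continue;
        const R_xlen_t w = rr + (R_xlen_t)nr * (cc + (R_xlen_t)nc * ss);
        if (mask[w] != 0 && labels[w] == 0) {
          labels[w] = next_label;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Bilinear (images) and nearest-neighbour (labels) backward warping by a
// dense in-plane displacement field; samples are clamped at the border.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(NumericMatrix img, NumericMatrix dr,
                                NumericMatrix dc) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double sr = r + dr(r, c), sc = c + dc(r, c);
      sr = std::min(std::max(sr, 0.0), (double)(H - 1));
      sc = std::min(std::max(sc, 0.0), (double)(W - 1));
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
      const double fr = sr - r0, fc = sc - c0;
      out(r, c) = (1 - fr) * (1 - fc) * img(r0, c0) +
                  fr * (1 - fc) * img(r1, c0) +
                  (1 - fr) * fc * img(r0, c1) + fr * fc * img(r1, c1);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_nearest(NumericMatrix img, NumericMatrix dr,
                               NumericMatrix dc) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double sr = r + dr(r, c), sc = c + dc(r, c);
      int ri = (int)std::lround(std::min(std::max(sr, 0.0), (double)(H - 1)));
      int ci = (int)std::lround(std::min(std::max(sc, 0.0), (double)(W - 1)));
      out(r, c) = img(ri, ci);
    }
  }
  return out;
}
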