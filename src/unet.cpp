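// Compact 2.5D residual U-Net: im2col convolutions, max pooling, nearest
// upsampling with long skip concatenations, softmax cross-entropy, Adam.
// Single-sample (batch size one) training steps; all state lives behind an
// external pointer so the R side only handles sampling, augmentation and the
// learning-rate schedule.
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// im2col for a 3x3 kernel with zero padding 1. Feature maps are (C x H*W)
// with pixel index p = r + c*H (column-major in-plane, matching R arrays).
static mat im2col3(const mat& x, int H, int W) {
  const int C = x.n_rows;
  mat out(9 * C, H * W, fill::zeros);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int c = 0; c < W; ++c) {
        const int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        const int r0 = std::max(0, -dr);
        const int r1 = std::min(H - 1, H - 1 - dr);
        if (r0 > r1) continue;
        out.submat(k * C, c * H + r0, (k + 1) * C - 1, c * H + r1) =
            x.cols(cc * H + r0 + dr, cc * H + r1 + dr);
      }
      ++k;
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-accumulate column gradients back to the map.
static mat col2im3(const mat& dcol, int H, int W) {
  const int C = dcol.n_rows / 9;
  mat out(C, H * W, fill::zeros);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int c = 0; c < W; ++c) {
        const int cc = c + dc;
        if (cc < 0 || cc >= W) continue;
        const int r0 = std::max(0, -dr);
        const int r1 = std::min(H - 1, H - 1 - dr);
        if (r0 > r1) continue;
        out.cols(cc * H + r0 + dr, cc * H + r1 + dr) +=
            dcol.submat(k * C, c * H + r0, (k + 1) * C - 1, c * H + r1);
      }
      ++k;
    }
  }
  return out;
}

struct BlockCache {
  mat c1, h1, c2, out;
  int H = 0, W = 0;
};

struct Workspace {
  std::vector<BlockCache> enc, dec;
  std::vector<umat> poolidx;
  std::vector<mat> enc_out, dskip;
  std::vector<int> Hs, Ws;
  mat logits;
};

static mat relu(mat x) {
  x.elem(find(x < 0)).zeros();
  return x;
}

class UNet {
 public:
  std::vector<int> widths;
  int Cin, ncls;
  std::vector<std::string> keys;
  std::map<std::string, mat> P, M, V;
  long t = 0;

  UNet(std::vector<int> widths_, int Cin_, int ncls_)
      : widths(widths_), Cin(Cin_), ncls(ncls_) {
    const int L = (int)widths.size();
    int prev = Cin;
    for (int i = 0; i < L; ++i) {
      add_block("enc" + std::to_string(i), prev, widths[i]);
      prev = widths[i];
    }
    for (int i = L - 2; i >= 0; --i)
      add_block("dec" + std::to_string(i), widths[i] + widths[i + 1], widths[i]);
    add_param("out_W", ncls, widths[0], widths[0]);
    add_param("out_b", ncls, 1, 0);
  }

  int depth() const { return (int)widths.size(); }
  int factor() const { return 1 << (depth() - 1); }

  void add_param(const std::string& key, int rows, int cols, int fan_in) {
    mat w(rows, cols);
    if (fan_in > 0) {
      const double sd = std::sqrt(2.0 / fan_in);  // He initialisation
      for (uword j = 0; j < w.n_elem; ++j) w(j) = R::norm_rand() * sd;
    } else {
      w.zeros();
    }
    P[key] = w;
    M[key] = mat(rows, cols, fill::zeros);
    V[key] = mat(rows, cols, fill::zeros);
    keys.push_back(key);
  }

  void add_block(const std::string& name, int cin, int cout) {
    add_param(name + "_W1", cout, 9 * cin, 9 * cin);
    add_param(name + "_b1", cout, 1, 0);
    add_param(name + "_W2", cout, 9 * cout, 9 * cout);
    add_param(name + "_b2", cout, 1, 0);
  }

  // Two 3x3 convolutions with a short residual (identity) connection around
  // the second one: out = relu(h1 + conv2(h1)), h1 = relu(conv1(x)).
  mat block_fwd(const std::string& name, const mat& x, int H, int W,
                BlockCache& cc) {
    cc.H = H;
    cc.W = W;
    cc.c1 = im2col3(x, H, W);
    mat a1 = P[name + "_W1"] * cc.c1;
    a1.each_col() += P[name + "_b1"].col(0);
    cc.h1 = relu(a1);
    cc.c2 = im2col3(cc.h1, H, W);
    mat a2 = P[name + "_W2"] * cc.c2;
    a2.each_col() += P[name + "_b2"].col(0);
    cc.out = relu(cc.h1 + a2);
    return cc.out;
  }

  mat block_bwd(const std::string& name, const BlockCache& cc, mat dout,
                std::map<std::string, mat>& G) {
    dout.elem(find(cc.out <= 0)).zeros();
    G[name + "_W2"] = dout * cc.c2.t();
    G[name + "_b2"] = sum(dout, 1);
    mat dh1 = col2im3(P[name + "_W2"].t() * dout, cc.H, cc.W) + dout;
    dh1.elem(find(cc.h1 <= 0)).zeros();
    G[name + "_W1"] = dh1 * cc.c1.t();
    G[name + "_b1"] = sum(dh1, 1);
    return col2im3(P[name + "_W1"].t() * dh1, cc.H, cc.W);
  }

  static mat maxpool2(const mat& x, int H, int W, umat& idx) {
    const int C = x.n_rows, Ho = H / 2, Wo = W / 2;
    mat out(C, Ho * Wo);
    idx.set_size(C, Ho * Wo);
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int po = r + c * Ho;
        const int pp[4] = {2 * r + 2 * c * H, 2 * r + 1 + 2 * c * H,
                           2 * r + (2 * c + 1) * H, 2 * r + 1 + (2 * c + 1) * H};
        for (int ch = 0; ch < C; ++ch) {
          double best = x(ch, pp[0]);
          int bi = pp[0];
          for (int q = 1; q < 4; ++q)
            if (x(ch, pp[q]) > best) {
              best = x(ch, pp[q]);
              bi = pp[q];
            }
          out(ch, po) = best;
          idx(ch, po) = bi;
        }
      }
    }
    return out;
  }

  static mat maxunpool2(const mat& d, const umat& idx, int H, int W) {
    const int C = d.n_rows;
    mat out(C, H * W, fill::zeros);
    for (uword p = 0; p < d.n_cols; ++p)
      for (int ch = 0; ch < C; ++ch) out(ch, idx(ch, p)) += d(ch, p);
    return out;
  }

  static mat upsample2(const mat& x, int Hi, int Wi) {
    const int C = x.n_rows, Ho = 2 * Hi, Wo = 2 * Wi;
    mat out(C, Ho * Wo);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        out.col(r + c * Ho) = x.col(r / 2 + (c / 2) * Hi);
    return out;
  }

  static mat downsum2(const mat& d, int Hi, int Wi) {
    const int C = d.n_rows, Ho = 2 * Hi, Wo = 2 * Wi;
    mat out(C, Hi * Wi, fill::zeros);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        out.col(r / 2 + (c / 2) * Hi) += d.col(r + c * Ho);
    return out;
  }

  mat forward(const mat& x0, int H, int W, Workspace& ws) {
    const int L = depth();
    if (H % factor() != 0 || W % factor() != 0)
      stop("input dims (%d x %d) not divisible by the downsampling factor %d",
           H, W, factor());
    ws.enc.assign(L, BlockCache());
    ws.dec.assign(std::max(L - 1, 0), BlockCache());
    ws.poolidx.assign(std::max(L - 1, 0), umat());
    ws.enc_out.assign(L, mat());
    ws.Hs.assign(L, 0);
    ws.Ws.assign(L, 0);
    mat f = x0;
    int h = H, w = W;
    for (int i = 0; i < L; ++i) {
      ws.Hs[i] = h;
      ws.Ws[i] = w;
      f = block_fwd("enc" + std::to_string(i), f, h, w, ws.enc[i]);
      ws.enc_out[i] = f;
      if (i < L - 1) {
        f = maxpool2(f, h, w, ws.poolidx[i]);
        h /= 2;
        w /= 2;
      }
    }
    for (int i = L - 2; i >= 0; --i) {
      mat up = upsample2(f, ws.Hs[i + 1], ws.Ws[i + 1]);
      mat cat = join_cols(ws.enc_out[i], up);
      f = block_fwd("dec" + std::to_string(i), cat, ws.Hs[i], ws.Ws[i],
                    ws.dec[i]);
    }
    mat logits = P["out_W"] * f;
    logits.each_col() += P["out_b"].col(0);
    ws.logits = logits;
    return logits;
  }

  void backward(const mat& dlogits, Workspace& ws,
                std::map<std::string, mat>& G) {
    const int L = depth();
    const mat& feat = (L > 1) ? ws.dec[0].out : ws.enc[0].out;
    G["out_W"] = dlogits * feat.t();
    G["out_b"] = sum(dlogits, 1);
    mat df = P["out_W"].t() * dlogits;
    ws.dskip.assign(std::max(L - 1, 0), mat());
    for (int i = 0; i <= L - 2; ++i) {
      mat dcat = block_bwd("dec" + std::to_string(i), ws.dec[i], df, G);
      ws.dskip[i] = dcat.rows(0, widths[i] - 1);
      mat dup = dcat.rows(widths[i], widths[i] + widths[i + 1] - 1);
      df = downsum2(dup, ws.Hs[i + 1], ws.Ws[i + 1]);
    }
    mat d = df;
    for (int i = L - 1; i >= 0; --i) {
      mat dx = block_bwd("enc" + std::to_string(i), ws.enc[i], d, G);
      if (i > 0) {
        d = maxunpool2(dx, ws.poolidx[i - 1], ws.Hs[i - 1], ws.Ws[i - 1]);
        d += ws.dskip[i - 1];
      }
    }
  }

  void adam(std::map<std::string, mat>& G, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (const auto& key : keys) {
      M[key] = b1 * M[key] + (1.0 - b1) * G[key];
      V[key] = b2 * V[key] + (1.0 - b2) * square(G[key]);
      P[key] -= lr * (M[key] / c1) / (sqrt(V[key] / c2) + eps);
    }
  }
};

// (H, W, C) R array -> (C x H*W) matrix
static mat array_to_mat(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("input must be a 3-D array (H x W x channels)");
  const int H = d[0], W = d[1], C = d[2];
  mat out(C, H * W);
  for (int ch = 0; ch < C; ++ch)
    for (int p = 0; p < H * W; ++p) out(ch, p) = x[p + ch * H * W];
  return out;
}

// [[Rcpp::export]]
SEXP cpp_unet_create(IntegerVector widths, int in_channels, int n_classes) {
  if (widths.size() < 2) stop("at least two encoder stages are required");
  std::vector<int> w(widths.begin(), widths.end());
  XPtr<UNet> ptr(new UNet(w, in_channels, n_classes), true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_unet_nparams(SEXP model) {
  XPtr<UNet> net(model);
  double n = 0;
  for (const auto& key : net->keys) n += net->P[key].n_elem;
  return n;
}

// [[Rcpp::export]]
double cpp_unet_step(SEXP model, NumericVector x, IntegerVector y, double lr) {
  XPtr<UNet> net(model);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1];
  mat xm = array_to_mat(x);
  if ((int)xm.n_rows != net->Cin) stop("channel count mismatch");
  if (y.size() != H * W) stop("label size mismatch");
  Workspace ws;
  mat logits = net->forward(xm, H, W, ws);
  const int N = H * W, K = net->ncls;
  rowvec mx = max(logits, 0);
  mat E = exp(logits.each_row() - mx);
  rowvec S = sum(E, 0);
  mat prob = E.each_row() / S;
  double loss = 0;
  mat dlogits = prob;
  for (int p = 0; p < N; ++p) {
    const int cls = y[p];
    if (cls < 0 || cls >= K) stop("labels must lie in 0..%d", K - 1);
    loss -= std::log(std::max(prob(cls, p), 1e-12));
    dlogits(cls, p) -= 1.0;
  }
  loss /= N;
  dlogits /= N;
  std::map<std::string, mat> G;
  net->backward(dlogits, ws, G);
  net->adam(G, lr);
  return loss;
}

// [[Rcpp::export]]
NumericMatrix cpp_unet_predict(SEXP model, NumericVector x) {
  XPtr<UNet> net(model);
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1];
  mat xm = array_to_mat(x);
  if ((int)xm.n_rows != net->Cin) stop("channel count mismatch");
  Workspace ws;
  mat logits = net->forward(xm, H, W, ws);
  rowvec mx = max(logits, 0);
  mat E = exp(logits.each_row() - mx);
  rowvec S = sum(E, 0);
  // foreground probability (last class) as an H x W matrix
  NumericMatrix out(H, W);
  for (int p = 0; p < H * W; ++p)
    out[p] = E(net->ncls - 1, p) / S(p);
  return out;
}

// [[Rcpp::export]]
List cpp_unet_params(SEXP model) {
  XPtr<UNet> net(model);
  List out;
  for (const auto& key : net->keys) out[key] = wrap(net->P[key]);
  return out;
}

// [[Rcpp::export]]
void cpp_unet_set_params(SEXP model, List params, bool encoder_only) {
  XPtr<UNet> net(model);
  CharacterVector nm = params.names();
  for (int i = 0; i < params.size(); ++i) {
    std::string key = as<std::string>(nm[i]);
    if (encoder_only && key.rfind("enc", 0) != 0) continue;
    auto it = net->P.find(key);
    if (it == net->P.end()) stop("unknown parameter '%s'", key.c_str());
    mat w = as<mat>(params[i]);
    if (w.n_rows != it->second.n_rows || w.n_cols != it->second.n_cols)
      stop("shape mismatch for parameter '%s': expected %dx%d, got %dx%d",
           key.c_str(), (int)it->second.n_rows, (int)it->second.n_cols,
           (int)w.n_rows, (int)w.n_cols);
    it->second = w;
  }
}
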