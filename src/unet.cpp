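// Minimal 2-D U-Net (encoder/decoder with skip connections, ReLU, sigmoid
// head) with soft-Dice loss and Adam, implemented on Armadillo in single
// precision. Activations are stored as (H*W) x C matrices, one contiguous
// column-major image per channel column, so that 3x3 same-padding
// convolution becomes im2col (contiguous column copies) + one GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using fmat = arma::fmat;
using frow = arma::frowvec;

struct ConvSpec {
  int cin, cout, k;
};

static std::vector<ConvSpec> make_specs(int in_ch, int out_ch, int base,
                                        int levels) {
  std::vector<ConvSpec> sp;
  auto f = [&](int l) { return base << l; };
  int cin = in_ch;
  for (int l = 0; l < levels - 1; ++l) {
    sp.push_back({cin, f(l), 3});
    sp.push_back({f(l), f(l), 3});
    cin = f(l);
  }
  sp.push_back({cin, f(levels - 1), 3});
  sp.push_back({f(levels - 1), f(levels - 1), 3});
  for (int l = levels - 2; l >= 0; --l) {
    sp.push_back({f(l + 1), f(l), 3});  // post-upsample conv
    sp.push_back({2 * f(l), f(l), 3});  // after skip concat
    sp.push_back({f(l), f(l), 3});
  }
  sp.push_back({f(0), out_ch, 1});  // 1x1 sigmoid head
  return sp;
}

// Copy channel column `src` (an H x W image flattened column-major) shifted
// by (di, dj) into `dst`, zero-filling out-of-range pixels.
static void shift_column(const float* src, float* dst, int H, int W, int di,
                         int dj) {
  std::fill(dst, dst + (size_t)H * W, 0.0f);
  int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
  int i0 = std::max(0, -di), i1 = std::min(H, H - di);
  int len = i1 - i0;
  if (len <= 0) return;
  for (int j = j0; j < j1; ++j) {
    const float* s = src + (size_t)(j + dj) * H + (i0 + di);
    float* d = dst + (size_t)j * H + i0;
    std::copy(s, s + len, d);
  }
}

// Adjoint: accumulate `src` into `dst` such that dst(i+di, j+dj) += src(i, j)
// restricted to valid pixels (the reverse mapping of shift_column).
static void unshift_accum(const float* src, float* dst, int H, int W, int di,
                          int dj) {
  int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
  int i0 = std::max(0, -di), i1 = std::min(H, H - di);
  int len = i1 - i0;
  if (len <= 0) return;
  for (int j = j0; j < j1; ++j) {
    const float* s = src + (size_t)j * H + i0;
    float* d = dst + (size_t)(j + dj) * H + (i0 + di);
    for (int i = 0; i < len; ++i) d[i] += s[i];
  }
}

static const int OFF[9][2] = {{-1, -1}, {0, -1}, {1, -1}, {-1, 0}, {0, 0},
                              {1, 0},   {-1, 1}, {0, 1},  {1, 1}};

static fmat im2col3(const fmat& x, int H, int W) {
  const int C = x.n_cols;
  fmat out((size_t)H * W, 9 * C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 9; ++k) {
      shift_column(x.colptr(c), out.colptr((size_t)c * 9 + k), H, W, OFF[k][0],
                   OFF[k][1]);
    }
  }
  return out;
}

static fmat col2im3(const fmat& dcols, int H, int W, int C) {
  fmat dx((size_t)H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < 9; ++k) {
      unshift_accum(dcols.colptr((size_t)c * 9 + k), dx.colptr(c), H, W,
                    OFF[k][0], OFF[k][1]);
    }
  }
  return dx;
}

static fmat maxpool2(const fmat& x, int H, int W, arma::umat& argmax) {
  const int C = x.n_cols, h = H / 2, w = W / 2;
  fmat y((size_t)h * w, C);
  argmax.set_size((size_t)h * w, C);
  for (int c = 0; c < C; ++c) {
    const float* s = x.colptr(c);
    float* yo = y.colptr(c);
    arma::uword* am = argmax.colptr(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        size_t p00 = (size_t)(2 * j) * H + 2 * i;
        size_t p01 = p00 + H;
        size_t cand[4] = {p00, p00 + 1, p01, p01 + 1};
        size_t best = cand[0];
        for (int t = 1; t < 4; ++t) {
          if (s[cand[t]] > s[best]) best = cand[t];
        }
        yo[(size_t)j * h + i] = s[best];
        am[(size_t)j * h + i] = best;
      }
    }
  }
  return y;
}

static fmat maxpool2_backward(const fmat& dy, const arma::umat& argmax, int H,
                              int W) {
  const int C = dy.n_cols;
  fmat dx((size_t)H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* d = dx.colptr(c);
    const float* s = dy.colptr(c);
    const arma::uword* am = argmax.colptr(c);
    for (size_t p = 0; p < dy.n_rows; ++p) d[am[p]] += s[p];
  }
  return dx;
}

static fmat upsample2(const fmat& x, int H, int W) {
  const int C = x.n_cols, H2 = 2 * H, W2 = 2 * W;
  fmat y((size_t)H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const float* s = x.colptr(c);
    float* d = y.colptr(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        float v = s[(size_t)j * H + i];
        size_t b = (size_t)(2 * j) * H2 + 2 * i;
        d[b] = v;
        d[b + 1] = v;
        d[b + H2] = v;
        d[b + H2 + 1] = v;
      }
    }
  }
  return y;
}

static fmat upsample2_backward(const fmat& dy, int H2, int W2) {
  const int C = dy.n_cols, H = H2 / 2, W = W2 / 2;
  fmat dx((size_t)H * W, C);
  for (int c = 0; c < C; ++c) {
    const float* s = dy.colptr(c);
    float* d = dx.colptr(c);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        size_t b = (size_t)(2 * j) * H2 + 2 * i;
        d[(size_t)j * H + i] = s[b] + s[b + 1] + s[b + H2] + s[b + H2 + 1];
      }
    }
  }
  return dx;
}

struct UNet {
  int in_ch, out_ch, base, levels;
  std::vector<ConvSpec> specs;
  std::vector<fmat> W;
  std::vector<frow> b;
  std::vector<fmat> mW, vW, gW;
  std::vector<frow> mb, vb, gb;
  long step = 0;

  // per-sample forward caches
  std::vector<fmat> cols_cache, out_cache;
  std::vector<arma::umat> pool_idx;
  std::vector<std::pair<int, int>> pool_dims;

  UNet(int in_ch_, int out_ch_, int base_, int levels_, int seed)
      : in_ch(in_ch_), out_ch(out_ch_), base(base_), levels(levels_) {
    specs = make_specs(in_ch, out_ch, base, levels);
    std::mt19937 rng(seed);
    std::normal_distribution<double> nd(0.0, 1.0);
    for (const auto& sp : specs) {
      int fan_in = sp.k * sp.k * sp.cin;
      float sd = std::sqrt(2.0f / fan_in);
      fmat w(sp.k * sp.k * sp.cin, sp.cout);
      for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = sd * (float)nd(rng);
      W.push_back(w);
      b.push_back(frow(sp.cout, arma::fill::zeros));
      mW.push_back(fmat(arma::size(w), arma::fill::zeros));
      vW.push_back(fmat(arma::size(w), arma::fill::zeros));
      gW.push_back(fmat(arma::size(w), arma::fill::zeros));
      mb.push_back(frow(sp.cout, arma::fill::zeros));
      vb.push_back(frow(sp.cout, arma::fill::zeros));
      gb.push_back(frow(sp.cout, arma::fill::zeros));
    }
    // Sigmoid-head bias starts negative so initial foreground probability is
    // ~0.12 everywhere; the soft-Dice denominator then stays small and the
    // target-pixel gradient dominates from the first step (the usual
    // "background prior" initialisation for segmentation heads).
    b.back().fill(-2.0f);
  }

  fmat conv_fwd(const fmat& x, int H, int Wd, int li, bool relu, bool cache) {
    const ConvSpec& sp = specs[li];
    fmat cols = (sp.k == 3) ? im2col3(x, H, Wd) : x;
    fmat y = cols * W[li];
    y.each_row() += b[li];
    if (relu) y.transform([](float v) { return v > 0 ? v : 0.0f; });
    if (cache) {
      cols_cache[li] = std::move(cols);
      out_cache[li] = y;
    }
    return y;
  }

  fmat conv_bwd(fmat dy, int H, int Wd, int li, bool relu) {
    const ConvSpec& sp = specs[li];
    if (relu) {
      const fmat& out = out_cache[li];
      for (arma::uword i = 0; i < dy.n_elem; ++i) {
        if (out(i) <= 0) dy(i) = 0;
      }
    }
    gW[li] += cols_cache[li].t() * dy;
    gb[li] += arma::sum(dy, 0);
    fmat dcols = dy * W[li].t();
    return (sp.k == 3) ? col2im3(dcols, H, Wd, sp.cin) : dcols;
  }

  fmat forward(const fmat& x, int H, int Wd, bool cache) {
    if (cache) {
      cols_cache.assign(specs.size(), fmat());
      out_cache.assign(specs.size(), fmat());
      pool_idx.assign(levels - 1, arma::umat());
      pool_dims.assign(levels - 1, {0, 0});
    }
    std::vector<fmat> skips(levels - 1);
    std::vector<std::pair<int, int>> skip_dims(levels - 1);
    fmat cur = x;
    int li = 0, h = H, w = Wd;
    for (int l = 0; l < levels - 1; ++l) {
      cur = conv_fwd(cur, h, w, li++, true, cache);
      cur = conv_fwd(cur, h, w, li++, true, cache);
      skips[l] = cur;
      skip_dims[l] = {h, w};
      arma::umat am;
      cur = maxpool2(cur, h, w, am);
      if (cache) {
        pool_idx[l] = std::move(am);
        pool_dims[l] = {h, w};
      }
      h /= 2;
      w /= 2;
    }
    cur = conv_fwd(cur, h, w, li++, true, cache);
    cur = conv_fwd(cur, h, w, li++, true, cache);
    for (int l = levels - 2; l >= 0; --l) {
      cur = upsample2(cur, h, w);
      h *= 2;
      w *= 2;
      cur = conv_fwd(cur, h, w, li++, true, cache);
      cur = arma::join_rows(skips[l], cur);
      cur = conv_fwd(cur, h, w, li++, true, cache);
      cur = conv_fwd(cur, h, w, li++, true, cache);
    }
    fmat logits = conv_fwd(cur, h, w, li++, false, cache);
    logits.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
    return logits;  // probabilities
  }

  double backward_sample(const fmat& probs, const fmat& target, int H, int Wd,
                         double eps) {
    const int C = probs.n_cols;
    fmat dp(arma::size(probs));
    double loss = 1.0;
    for (int c = 0; c < C; ++c) {
      double spt = arma::dot(probs.col(c), target.col(c));
      double sp = arma::accu(probs.col(c));
      double st = arma::accu(target.col(c));
      double num = 2.0 * spt + eps, den = sp + st + eps;
      loss -= (num / den) / C;
      dp.col(c) = (float)(-1.0 / (den * den * C)) *
                  (2.0f * (float)den * target.col(c) - (float)num);
    }
    fmat dcur = dp % probs % (1.0f - probs);  // through the sigmoid

    int li = (int)specs.size() - 1;
    int h = H, w = Wd;
    dcur = conv_bwd(dcur, h, w, li--, false);
    std::vector<fmat> dskips(levels - 1);
    for (int l = 0; l <= levels - 2; ++l) {
      int c2 = li--, c1 = li--, up = li--;
      dcur = conv_bwd(dcur, h, w, c2, true);
      dcur = conv_bwd(dcur, h, w, c1, true);
      int fl = base << l;
      dskips[l] = dcur.cols(0, fl - 1);
      fmat dup = dcur.cols(fl, 2 * fl - 1);
      dup = conv_bwd(dup, h, w, up, true);
      dcur = upsample2_backward(dup, h, w);
      h /= 2;
      w /= 2;
    }
    dcur = conv_bwd(dcur, h, w, li--, true);
    dcur = conv_bwd(dcur, h, w, li--, true);
    for (int l = levels - 2; l >= 0; --l) {
      dcur = maxpool2_backward(dcur, pool_idx[l], pool_dims[l].first,
                               pool_dims[l].second);
      h = pool_dims[l].first;
      w = pool_dims[l].second;
      dcur += dskips[l];
      dcur = conv_bwd(dcur, h, w, li--, true);
      dcur = conv_bwd(dcur, h, w, li--, true);
    }
    return loss;
  }

  void zero_grad() {
    for (size_t i = 0; i < specs.size(); ++i) {
      gW[i].zeros();
      gb[i].zeros();
    }
  }

  void adam_step(double lr, double scale) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    ++step;
    float c1 = 1.0f - std::pow(b1, (float)step);
    float c2 = 1.0f - std::pow(b2, (float)step);
    for (size_t i = 0; i < specs.size(); ++i) {
      fmat g = gW[i] * (float)scale;
      mW[i] = b1 * mW[i] + (1 - b1) * g;
      vW[i] = b2 * vW[i] + (1 - b2) * (g % g);
      W[i] -= (float)lr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + eps);
      frow gbv = gb[i] * (float)scale;
      mb[i] = b1 * mb[i] + (1 - b1) * gbv;
      vb[i] = b2 * vb[i] + (1 - b2) * (gbv % gbv);
      b[i] -= (float)lr * (mb[i] / c1) / (arma::sqrt(vb[i] / c2) + eps);
    }
  }
};

// (H, W, C) block of a 4-D R array -> (H*W) x C float matrix.
static fmat slice_4d(const NumericVector& x, int H, int W, int C, int n) {
  fmat out((size_t)H * W, C);
  const double* p = x.begin() + (size_t)n * H * W * C;
  for (int c = 0; c < C; ++c) {
    float* d = out.colptr(c);
    const double* s = p + (size_t)c * H * W;
    for (size_t i = 0; i < (size_t)H * W; ++i) d[i] = (float)s[i];
  }
  return out;
}

// [[Rcpp::export]]
SEXP unet_create(int in_ch, int out_ch, int base, int levels, int seed) {
  if (levels < 2) stop("levels must be >= 2");
  Rcpp::XPtr<UNet> ptr(new UNet(in_ch, out_ch, base, levels, seed), true);
  return ptr;
}

// [[Rcpp::export]]
double unet_train_batch(SEXP net, NumericVector x, NumericVector y, double lr,
                        double dice_eps) {
  Rcpp::XPtr<UNet> p(net);
  IntegerVector dx = x.attr("dim");
  if (dx.size() != 4) stop("x must be a 4-D array (H, W, C, N)");
  int H = dx[0], Wd = dx[1], C = dx[2], N = dx[3];
  if (C != p->in_ch) stop("channel count mismatch");
  if (H % (1 << (p->levels - 1)) != 0 || Wd % (1 << (p->levels - 1)) != 0) {
    stop("input size must be divisible by 2^(levels-1)");
  }
  IntegerVector dy = y.attr("dim");
  if (dy.size() != 4 || dy[0] != H || dy[1] != Wd || dy[3] != N) {
    stop("label array does not match input array");
  }
  p->zero_grad();
  double total = 0.0;
  for (int n = 0; n < N; ++n) {
    fmat xi = slice_4d(x, H, Wd, C, n);
    fmat yi = slice_4d(y, H, Wd, dy[2], n);
    fmat probs = p->forward(xi, H, Wd, true);
    double loss = p->backward_sample(probs, yi, H, Wd, dice_eps);
    if (!std::isfinite(loss)) stop("non-finite training loss");
    total += loss;
  }
  p->adam_step(lr, 1.0 / N);
  return total / N;
}

// [[Rcpp::export]]
NumericVector unet_predict_probs(SEXP net, NumericVector x) {
  Rcpp::XPtr<UNet> p(net);
  IntegerVector dx = x.attr("dim");
  if (dx.size() != 3) stop("x must be a 3-D array (H, W, C)");
  int H = dx[0], Wd = dx[1], C = dx[2];
  fmat xi = slice_4d(x, H, Wd, C, 0);
  fmat probs = p->forward(xi, H, Wd, false);
  NumericVector out((size_t)H * Wd * p->out_ch);
  for (int c = 0; c < p->out_ch; ++c) {
    const float* s = probs.colptr(c);
    double* d = out.begin() + (size_t)c * H * Wd;
    for (size_t i = 0; i < (size_t)H * Wd; ++i) d[i] = s[i];
  }
  out.attr("dim") = IntegerVector::create(H, Wd, p->out_ch);
  return out;
}

// [[Rcpp::export]]
List unet_get_weights(SEXP net) {
  Rcpp::XPtr<UNet> p(net);
  List w(p->W.size()), bb(p->b.size());
  for (size_t i = 0; i < p->W.size(); ++i) {
    w[i] = wrap(arma::conv_to<arma::mat>::from(p->W[i]));
    bb[i] = wrap(arma::conv_to<arma::rowvec>::from(p->b[i]));
  }
  return List::create(_["W"] = w, _["b"] = bb);
}

// [[Rcpp::export]]
void unet_set_weights(SEXP net, List weights) {
  Rcpp::XPtr<UNet> p(net);
  List w = weights["W"], bb = weights["b"];
  if ((size_t)w.size() != p->W.size()) stop("weight list does not match architecture");
  for (size_t i = 0; i < p->W.size(); ++i) {
    fmat wi = arma::conv_to<fmat>::from(as<arma::mat>(w[i]));
    frow bi = arma::conv_to<frow>::from(as<arma::rowvec>(bb[i]));
    if (arma::size(wi) != arma::size(p->W[i])) stop("weight shape mismatch");
    p->W[i] = wi;
    p->b[i] = bi;
  }
}

// [[Rcpp::export]]
List unet_layer_spec(SEXP net) {
  Rcpp::XPtr<UNet> p(net);
  int n = (int)p->specs.size();
  IntegerVector cin(n), cout(n), k(n);
  for (int i = 0; i < n; ++i) {
    cin[i] = p->specs[i].cin;
    cout[i] = p->specs[i].cout;
    k[i] = p->specs[i].k;
  }
  double np = 0;
  for (size_t i = 0; i < p->W.size(); ++i) np += p->W[i].n_elem + p->b[i].n_elem;
  return List::create(_["cin"] = cin, _["cout"] = cout, _["k"] = k,
                      _["n_params"] = np);
}
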