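// A compact single-precision CNN engine for the two-pathway seed classifier.
//
// Feature batches are stored as Armadillo fmat with samples stacked along
// rows: a spatial layer holds (N*H*W, C) with sample s occupying rows
// [s*HW, (s+1)*HW) and spatial index r + c*H (column-major, matching R);
// once the spatial extent collapses to 1x1 the same layout reads (N, C).
// Convolutions run as im2col + BLAS sgemm; backward recomputes im2col
// instead of caching it, trading a little compute for a lot of memory.
#include <RcppArmadillo.h>
#include <random>
#include <memory>
#include <vector>
#include <cstring>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

namespace {

struct Optim {
  int type = 0;  // 0 = SGD with momentum, 1 = Adam
  float lr = 1e-3f, momentum = 0.9f;
  float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  long t = 1;  // Adam bias-correction step
};

struct Param {
  fmat w, g, m, v;
  void init(int rows, int cols) { w.zeros(rows, cols); g.zeros(rows, cols); }
  void step(const Optim& o) {
    if (o.type == 0) {
      if (m.is_empty()) m.zeros(arma::size(w));
      m = o.momentum * m - o.lr * g;
      w += m;
    } else {
      if (m.is_empty()) { m.zeros(arma::size(w)); v.zeros(arma::size(w)); }
      m = o.beta1 * m + (1.0f - o.beta1) * g;
      v = o.beta2 * v + (1.0f - o.beta2) * (g % g);
      const float bc1 = 1.0f - std::pow(o.beta1, (float)o.t);
      const float bc2 = 1.0f - std::pow(o.beta2, (float)o.t);
      w -= o.lr * (m / bc1) / (arma::sqrt(v / bc2) + o.eps);
    }
  }
  long n() const { return (long)w.n_elem; }
};

struct Dims { int C = 0, H = 0, W = 0; };

static float he_std(int fan_in) { return std::sqrt(2.0f / fan_in); }

static void fill_normal(fmat& w, float sd, std::mt19937& rng) {
  std::normal_distribution<float> d(0.0f, sd);
  for (arma::uword i = 0; i < w.n_elem; ++i) w[i] = d(rng);
}

// im2col for one sample, written into `col` starting at row row0. X points
// at the sample's first spatial element of channel 0; channels are
// chan_stride apart. col is (rows >= row0 + Ho*Wo, C*kh*kw) with column
// q = ci*kh*kw + kj*kh + ki.
static void im2col_into(const float* X, size_t chan_stride, int H, int W,
                        int C, int kh, int kw, int s, int p, int Ho, int Wo,
                        fmat& col, size_t row0) {
  const size_t HWo = (size_t)Ho * Wo;
  for (int ci = 0; ci < C; ++ci) {
    const float* Xc = X + (size_t)ci * chan_stride;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ci * kh * kw + kj * kh + ki;
        float* colq = col.colptr(q) + row0;
        int ro_lo = p - ki <= 0 ? 0 : (p - ki + s - 1) / s;
        int ro_hi = std::min(Ho - 1, (H - 1 + p - ki) / s);
        const bool full = ro_lo == 0 && ro_hi == Ho - 1;
        for (int co = 0; co < Wo; ++co) {
          const int cj = co * s - p + kj;
          float* dst = colq + (size_t)co * Ho;
          if (cj < 0 || cj >= W) {
            std::memset(dst, 0, (size_t)Ho * sizeof(float));
            continue;
          }
          const float* src = Xc + (size_t)cj * H;
          if (s == 1) {
            if (!full) std::memset(dst, 0, (size_t)Ho * sizeof(float));
            if (ro_hi >= ro_lo)
              std::memcpy(dst + ro_lo, src + (ro_lo - p + ki),
                          (size_t)(ro_hi - ro_lo + 1) * sizeof(float));
          } else {
            if (!full) std::memset(dst, 0, (size_t)Ho * sizeof(float));
            for (int ro = ro_lo; ro <= ro_hi; ++ro)
              dst[ro] = src[ro * s - p + ki];
          }
        }
      }
    }
  }
}

// scatter-accumulate of dcol rows [row0, row0 + Ho*Wo) back onto one
// sample's input gradient
static void col2im(const fmat& dcol, size_t row0, float* dX,
                   size_t chan_stride, int H, int W, int C, int kh, int kw,
                   int s, int p, int Ho, int Wo) {
  for (int ci = 0; ci < C; ++ci) {
    float* dXc = dX + (size_t)ci * chan_stride;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int q = ci * kh * kw + kj * kh + ki;
        const float* colq = dcol.colptr(q) + row0;
        int ro_lo = p - ki <= 0 ? 0 : (p - ki + s - 1) / s;
        int ro_hi = std::min(Ho - 1, (H - 1 + p - ki) / s);
        for (int co = 0; co < Wo; ++co) {
          const int cj = co * s - p + kj;
          if (cj < 0 || cj >= W) continue;
          float* dst = dXc + (size_t)cj * H;
          const float* src = colq + (size_t)co * Ho;
          for (int ro = ro_lo; ro <= ro_hi; ++ro)
            dst[ro * s - p + ki] += src[ro];
        }
      }
    }
  }
}

struct Layer {
  std::string type, stage, note;
  Dims in, out;
  virtual fmat forward(const fmat& x, int N, bool train) = 0;
  virtual fmat backward(const fmat& dy, int N) = 0;
  virtual void step(const Optim&) {}
  virtual long nparams() const { return 0; }
  virtual void collect(std::vector<fmat*>& ps) {}
  virtual void describe(List& rows) const {
    rows.push_back(List::create(
        _["type"] = type, _["stage"] = stage, _["note"] = note,
        _["out_channels"] = out.C, _["out_h"] = out.H, _["out_w"] = out.W,
        _["kernel"] = 0, _["stride"] = 1, _["params"] = (double)nparams()));
  }
  virtual ~Layer() = default;
};

struct Conv : Layer {
  int kh, kw, s, p;
  bool has_bias;
  bool input_layer = false;  // first conv of a branch: no input grad needed
  Param W, b;
  fmat Xc;
  Conv(Dims in_, int cout, int k, int s_, int p_, bool bias, std::mt19937& rng,
       const std::string& stage_, const std::string& note_ = "") {
    type = "conv"; stage = stage_; note = note_;
    in = in_; kh = kw = k; s = s_; p = p_; has_bias = bias;
    out.C = cout;
    out.H = (in.H + 2 * p - kh) / s + 1;
    out.W = (in.W + 2 * p - kw) / s + 1;
    if (out.H < 1 || out.W < 1) stop("convolution output collapses to zero");
    W.init(in.C * kh * kw, cout);
    fill_normal(W.w, he_std(in.C * kh * kw), rng);
    b.init(1, cout);
  }
  // samples are processed in chunks so the im2col product runs as one tall
  // GEMM per chunk (bounded to ~64 MB of scratch)
  int chunk_size(size_t HWo) const {
    const size_t K = (size_t)in.C * kh * kw;
    size_t g = (64u << 20) / sizeof(float) / std::max<size_t>(1, HWo * K);
    return (int)std::min<size_t>(std::max<size_t>(1, g), 64);
  }
  fmat forward(const fmat& x, int N, bool train) override {
    if (train) Xc = x; else Xc.reset();
    const size_t HW = (size_t)in.H * in.W, HWo = (size_t)out.H * out.W;
    const size_t cs = (size_t)N * HW;
    const int G = chunk_size(HWo);
    fmat y((size_t)N * HWo, out.C);
    fmat col;
    for (int s0 = 0; s0 < N; s0 += G) {
      const int g = std::min(G, N - s0);
      col.set_size((size_t)g * HWo, (size_t)in.C * kh * kw);
      for (int j = 0; j < g; ++j)
        im2col_into(x.memptr() + (s0 + j) * HW, cs, in.H, in.W, in.C,
                    kh, kw, s, p, out.H, out.W, col, (size_t)j * HWo);
      y.rows(s0 * HWo, (s0 + g) * HWo - 1) = col * W.w;
    }
    if (has_bias) y.each_row() += b.w;
    return y;
  }
  fmat backward(const fmat& dy, int N) override {
    const size_t HW = (size_t)in.H * in.W, HWo = (size_t)out.H * out.W;
    const size_t cs = (size_t)N * HW;
    const int G = chunk_size(HWo);
    fmat dx((size_t)N * HW, in.C, arma::fill::zeros);
    W.g.zeros();
    if (has_bias) b.g = arma::sum(dy, 0);
    fmat col;
    for (int s0 = 0; s0 < N; s0 += G) {
      const int g = std::min(G, N - s0);
      const fmat dys = dy.rows(s0 * HWo, (s0 + g) * HWo - 1);
      if (!input_layer) {
        fmat dcol = dys * W.w.t();
        for (int j = 0; j < g; ++j)
          col2im(dcol, (size_t)j * HWo, dx.memptr() + (s0 + j) * HW, cs,
                 in.H, in.W, in.C, kh, kw, s, p, out.H, out.W);
      }
      col.set_size((size_t)g * HWo, (size_t)in.C * kh * kw);
      for (int j = 0; j < g; ++j)
        im2col_into(Xc.memptr() + (s0 + j) * HW, cs, in.H, in.W, in.C,
                    kh, kw, s, p, out.H, out.W, col, (size_t)j * HWo);
      W.g += col.t() * dys;
    }
    Xc.reset();
    return dx;
  }
  void step(const Optim& o) override { W.step(o); if (has_bias) b.step(o); }
  long nparams() const override { return W.n() + (has_bias ? b.n() : 0); }
  void collect(std::vector<fmat*>& ps) override {
    ps.push_back(&W.w); ps.push_back(&b.w);
  }
  void describe(List& rows) const override {
    rows.push_back(List::create(
        _["type"] = type, _["stage"] = stage, _["note"] = note,
        _["out_channels"] = out.C, _["out_h"] = out.H, _["out_w"] = out.W,
        _["kernel"] = kh, _["stride"] = s, _["params"] = (double)nparams()));
  }
};

struct BatchNorm : Layer {
  Param gamma, beta;
  frowvec run_mean, run_var, invstd;
  float mom = 0.9f, eps = 1e-5f;
  fmat xhat;
  explicit BatchNorm(Dims d, const std::string& stage_) {
    type = "batchnorm"; stage = stage_;
    in = out = d;
    gamma.init(1, d.C); gamma.w.ones();
    beta.init(1, d.C);
    run_mean.zeros(d.C); run_var.ones(d.C);
  }
  fmat forward(const fmat& x, int N, bool train) override {
    if (train) {
      const float M = (float)x.n_rows;
      frowvec mu = arma::mean(x, 0);
      fmat xc = x.each_row() - mu;
      frowvec var = arma::sum(xc % xc, 0) / M;
      invstd = 1.0f / arma::sqrt(var + eps);
      xhat = xc.each_row() % invstd;
      run_mean = mom * run_mean + (1.0f - mom) * mu;
      run_var = mom * run_var + (1.0f - mom) * var;
      fmat y = xhat.each_row() % gamma.w;
      y.each_row() += beta.w;
      return y;
    }
    frowvec is = 1.0f / arma::sqrt(run_var + eps);
    fmat y = x.each_row() - run_mean;
    y.each_row() %= is % gamma.w;
    y.each_row() += beta.w;
    return y;
  }
  fmat backward(const fmat& dy, int N) override {
    const float M = (float)dy.n_rows;
    gamma.g = arma::sum(dy % xhat, 0);
    beta.g = arma::sum(dy, 0);
    fmat dx = dy * M;
    dx.each_row() -= beta.g;
    dx -= xhat.each_row() % gamma.g;
    dx.each_row() %= (gamma.w % invstd) / M;
    xhat.reset();
    return dx;
  }
  void step(const Optim& o) override { gamma.step(o); beta.step(o); }
  long nparams() const override { return gamma.n() + beta.n(); }
};

static inline void relu_inplace(fmat& x) {
  float* p = x.memptr();
  const arma::uword n = x.n_elem;
  for (arma::uword i = 0; i < n; ++i) p[i] = p[i] > 0.0f ? p[i] : 0.0f;
}

static inline void relu_mask_grad(fmat& dx, const fmat& y) {
  float* d = dx.memptr();
  const float* p = y.memptr();
  const arma::uword n = dx.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (p[i] <= 0.0f) d[i] = 0.0f;
}

struct ReLU : Layer {
  fmat y;
  explicit ReLU(Dims d, const std::string& stage_) {
    type = "relu"; stage = stage_; in = out = d;
  }
  fmat forward(const fmat& x, int N, bool train) override {
    fmat r = x;
    relu_inplace(r);
    if (train) y = r; else y.reset();
    return r;
  }
  fmat backward(const fmat& dy, int N) override {
    fmat dx = dy;
    relu_mask_grad(dx, y);
    y.reset();
    return dx;
  }
};

struct MaxPool : Layer {
  int k, s, p;
  arma::umat amax;
  MaxPool(Dims in_, int k_, int s_, int p_, const std::string& stage_) {
    type = "maxpool"; stage = stage_;
    in = in_; k = k_; s = s_; p = p_;
    out.C = in.C;
    out.H = (in.H + 2 * p - k) / s + 1;
    out.W = (in.W + 2 * p - k) / s + 1;
  }
  fmat forward(const fmat& x, int N, bool train) override {
    const size_t HW = (size_t)in.H * in.W, HWo = (size_t)out.H * out.W;
    fmat y((size_t)N * HWo, out.C);
    if (train) amax.set_size((size_t)N * HWo, out.C);
    for (int ci = 0; ci < in.C; ++ci) {
      const float* xc = x.colptr(ci);
      float* yc = y.colptr(ci);
      for (int sn = 0; sn < N; ++sn) {
        const float* xs = xc + (size_t)sn * HW;
        for (int co = 0; co < out.W; ++co) {
          const int c0 = std::max(0, co * s - p);
          const int c1 = std::min(in.W - 1, co * s - p + k - 1);
          for (int ro = 0; ro < out.H; ++ro) {
            const int r0 = std::max(0, ro * s - p);
            const int r1 = std::min(in.H - 1, ro * s - p + k - 1);
            float best = -1e30f; size_t barg = 0;
            for (int cc = c0; cc <= c1; ++cc)
              for (int rr = r0; rr <= r1; ++rr) {
                const float v = xs[(size_t)cc * in.H + rr];
                if (v > best) { best = v; barg = (size_t)cc * in.H + rr; }
              }
            const size_t oi = (size_t)sn * HWo + (size_t)co * out.H + ro;
            yc[oi] = best;
            if (train) amax(oi, ci) = barg;
          }
        }
      }
    }
    return y;
  }
  fmat backward(const fmat& dy, int N) override {
    const size_t HW = (size_t)in.H * in.W, HWo = (size_t)out.H * out.W;
    fmat dx((size_t)N * HW, in.C, arma::fill::zeros);
    for (int ci = 0; ci < in.C; ++ci) {
      const float* dyc = dy.colptr(ci);
      float* dxc = dx.colptr(ci);
      for (int sn = 0; sn < N; ++sn)
        for (size_t i = 0; i < HWo; ++i) {
          const size_t oi = (size_t)sn * HWo + i;
          dxc[(size_t)sn * HW + amax(oi, ci)] += dyc[oi];
        }
    }
    amax.reset();
    return dx;
  }
  void describe(List& rows) const override {
    rows.push_back(List::create(
        _["type"] = type, _["stage"] = stage, _["note"] = note,
        _["out_channels"] = out.C, _["out_h"] = out.H, _["out_w"] = out.W,
        _["kernel"] = k, _["stride"] = s, _["params"] = 0.0));
  }
};

struct GlobalAvgPool : Layer {
  explicit GlobalAvgPool(Dims in_, const std::string& stage_) {
    type = "gap"; stage = stage_;
    in = in_; out = {in.C, 1, 1};
  }
  fmat forward(const fmat& x, int N, bool train) override {
    const size_t HW = (size_t)in.H * in.W;
    fmat y(N, in.C);
    for (int sn = 0; sn < N; ++sn)
      y.row(sn) = arma::mean(x.rows(sn * HW, (sn + 1) * HW - 1), 0);
    return y;
  }
  fmat backward(const fmat& dy, int N) override {
    const size_t HW = (size_t)in.H * in.W;
    fmat dx((size_t)N * HW, in.C);
    for (int sn = 0; sn < N; ++sn)
      dx.rows(sn * HW, (sn + 1) * HW - 1) =
          arma::repmat(dy.row(sn) / (float)HW, HW, 1);
    return dx;
  }
};

struct Dense : Layer {
  Param W, b;
  fmat Xc;
  Dense(Dims in_, int cout, std::mt19937& rng, const std::string& stage_,
        const std::string& note_ = "") {
    type = "dense"; stage = stage_; note = note_;
    in = in_; out = {cout, 1, 1};
    W.init(in.C, cout);
    fill_normal(W.w, he_std(in.C), rng);
    b.init(1, cout);
  }
  fmat forward(const fmat& x, int N, bool train) override {
    if (train) Xc = x; else Xc.reset();
    fmat y = x * W.w;
    y.each_row() += b.w;
    return y;
  }
  fmat backward(const fmat& dy, int N) override {
    W.g = Xc.t() * dy;
    b.g = arma::sum(dy, 0);
    fmat dx = dy * W.w.t();
    Xc.reset();
    return dx;
  }
  void step(const Optim& o) override { W.step(o); b.step(o); }
  long nparams() const override { return W.n() + b.n(); }
  void collect(std::vector<fmat*>& ps) override {
    ps.push_back(&W.w); ps.push_back(&b.w);
  }
};

using LayerPtr = std::unique_ptr<Layer>;

static fmat run_forward(std::vector<LayerPtr>& L, fmat x, int N, bool train) {
  for (auto& l : L) x = l->forward(x, N, train);
  return x;
}
static fmat run_backward(std::vector<LayerPtr>& L, fmat g, int N) {
  for (auto it = L.rbegin(); it != L.rend(); ++it) g = (*it)->backward(g, N);
  return g;
}

// ResNet bottleneck: 1x1 -> BN -> ReLU -> 3x3(stride) -> BN -> ReLU -> 1x1
// -> BN, plus identity or projection shortcut, residual add, final ReLU.
struct Bottleneck : Layer {
  std::vector<LayerPtr> main, sc;
  fmat y;
  Bottleneck(Dims in_, int mid, int cout, int stride, std::mt19937& rng,
             const std::string& stage_) {
    type = "bottleneck"; stage = stage_;
    in = in_;
    Dims d = in;
    main.emplace_back(new Conv(d, mid, 1, 1, 0, false, rng, stage_));
    d = main.back()->out;
    main.emplace_back(new BatchNorm(d, stage_));
    main.emplace_back(new ReLU(d, stage_));
    main.emplace_back(new Conv(d, mid, 3, stride, 1, false, rng, stage_));
    d = main.back()->out;
    main.emplace_back(new BatchNorm(d, stage_));
    main.emplace_back(new ReLU(d, stage_));
    main.emplace_back(new Conv(d, cout, 1, 1, 0, false, rng, stage_));
    d = main.back()->out;
    main.emplace_back(new BatchNorm(d, stage_));
    out = d;
    if (stride != 1 || in.C != cout) {
      sc.emplace_back(new Conv(in, cout, 1, stride, 0, false, rng, stage_,
                               "projection"));
      sc.emplace_back(new BatchNorm(out, stage_));
    }
  }
  fmat forward(const fmat& x, int N, bool train) override {
    fmat a = run_forward(main, x, N, train);
    if (sc.empty()) a += x; else a += run_forward(sc, x, N, train);
    relu_inplace(a);
    if (train) y = a; else y.reset();
    return a;
  }
  fmat backward(const fmat& dy, int N) override {
    fmat dz = dy;
    relu_mask_grad(dz, y);
    y.reset();
    fmat dx = run_backward(main, dz, N);
    if (sc.empty()) dx += dz; else dx += run_backward(sc, dz, N);
    return dx;
  }
  void step(const Optim& o) override {
    for (auto& l : main) l->step(o);
    for (auto& l : sc) l->step(o);
  }
  long nparams() const override {
    long n = 0;
    for (auto& l : main) n += l->nparams();
    for (auto& l : sc) n += l->nparams();
    return n;
  }
  void collect(std::vector<fmat*>& ps) override {
    for (auto& l : main) l->collect(ps);
    for (auto& l : sc) l->collect(ps);
  }
  void describe(List& rows) const override {
    for (auto& l : main) l->describe(rows);
    for (auto& l : sc) l->describe(rows);
  }
};

static int wch(double c, double width) {
  return std::max(1, (int)std::lround(c * width));
}

struct CSN {
  std::vector<LayerPtr> vgg, res, head;
  int in_ch, in_size, ncls, embed;
  double width;
  long adam_t = 0;
  fmat probs_cache;

  CSN(int in_ch_, int in_size_, int ncls_, double width_, int embed_base,
      int seed)
      : in_ch(in_ch_), in_size(in_size_), ncls(ncls_), width(width_) {
    std::mt19937 rng((unsigned)seed);
    embed = wch(embed_base, width);
    Dims d0 = {in_ch, in_size, in_size};
    build_vgg(d0, rng);
    build_res(d0, rng);
    Dims fused = {2 * embed, 1, 1};
    head.emplace_back(new Dense(fused, ncls, rng, "fusion",
                                "softmax classification head"));
  }

  void build_vgg(Dims d0, std::mt19937& rng) {
    const int plan[] = {64, 64, -1, 128, 128, -1, 256, 256, 256, -1,
                        512, 512, 512, -1, 512, 512, 512, -1};
    Dims d = d0;
    bool first = true;
    for (int v : plan) {
      if (v < 0) {
        vgg.emplace_back(new MaxPool(d, 2, 2, 0, "trunk"));
      } else {
        auto* cv = new Conv(d, wch(v, width), 3, 1, 1, true, rng, "trunk");
        cv->input_layer = first; first = false;
        vgg.emplace_back(cv);
        d = vgg.back()->out;
        vgg.emplace_back(new ReLU(d, "trunk"));
        continue;
      }
      d = vgg.back()->out;
    }
    if (d.H != 7 || d.W != 7)
      stop("input size must yield a 7x7 map before the 7x7 convolution (use 224)");
    vgg.emplace_back(new Conv(d, wch(512, width), 7, 1, 0, true, rng, "head",
                              "7x7 valid convolution replacing the VGG16 FC head"));
    d = vgg.back()->out;
    vgg.emplace_back(new ReLU(d, "head"));
    vgg.emplace_back(new Dense(d, embed, rng, "head"));
    d = vgg.back()->out;
    vgg.emplace_back(new ReLU(d, "head"));
    vgg.emplace_back(new Dense(d, embed, rng, "head"));
    d = vgg.back()->out;
    vgg.emplace_back(new ReLU(d, "head"));
  }

  void build_res(Dims d0, std::mt19937& rng) {
    Dims d = d0;
    auto* stem = new Conv(d, wch(64, width), 7, 2, 3, false, rng, "trunk");
    stem->input_layer = true;
    res.emplace_back(stem);
    d = res.back()->out;
    res.emplace_back(new BatchNorm(d, "trunk"));
    res.emplace_back(new ReLU(d, "trunk"));
    res.emplace_back(new MaxPool(d, 3, 2, 1, "trunk"));
    d = res.back()->out;
    const int blocks[] = {3, 4, 6, 3};
    const int base[] = {64, 128, 256, 512};
    for (int st = 0; st < 4; ++st) {
      for (int bi = 0; bi < blocks[st]; ++bi) {
        const int stride = (st > 0 && bi == 0) ? 2 : 1;
        res.emplace_back(new Bottleneck(d, wch(base[st], width),
                                        wch(base[st] * 4, width), stride, rng,
                                        "trunk"));
        d = res.back()->out;
      }
    }
    res.emplace_back(new GlobalAvgPool(d, "trunk"));
    d = res.back()->out;
    res.emplace_back(new Dense(d, embed, rng, "head"));
    d = res.back()->out;
    res.emplace_back(new ReLU(d, "head"));
  }

  fmat forward(const fmat& x, int N, bool train) {
    fmat ev = run_forward(vgg, x, N, train);
    fmat er = run_forward(res, x, N, train);
    fmat fused = arma::join_rows(ev, er);
    fmat logits = run_forward(head, fused, N, train);
    // row-wise stable softmax
    fmat z = logits.each_col() - arma::max(logits, 1);
    z = arma::exp(z);
    z.each_col() /= arma::sum(z, 1);
    return z;
  }

  void backward(const fmat& dlogits, int N) {
    fmat dfused = run_backward(head, dlogits, N);
    fmat dv = dfused.cols(0, embed - 1);
    fmat dr = dfused.cols(embed, 2 * embed - 1);
    run_backward(vgg, dv, N);
    run_backward(res, dr, N);
  }

  void step(const Optim& o) {
    for (auto& l : vgg) l->step(o);
    for (auto& l : res) l->step(o);
    for (auto& l : head) l->step(o);
  }

  void all_layers(std::vector<Layer*>& out_) {
    for (auto& l : vgg) out_.push_back(l.get());
    for (auto& l : res) out_.push_back(l.get());
    for (auto& l : head) out_.push_back(l.get());
  }
};

// Batch conversion: R array (H, W, C, N) in [0, 255] -> fmat (N*H*W, C) / 255
static fmat to_batch(const NumericVector& x, int H, int W, int C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) {
    N = 1;
    if (d[0] != H || d[1] != W || d[2] != C) stop("chip has wrong dimensions");
  } else if (d.size() == 4) {
    N = d[3];
    if (d[0] != H || d[1] != W || d[2] != C) stop("chip batch has wrong dimensions");
  } else stop("expected an H x W x C (x N) array");
  const size_t HW = (size_t)H * W;
  fmat X((size_t)N * HW, C);
  const double* src = x.begin();
  for (int sn = 0; sn < N; ++sn)
    for (int ci = 0; ci < C; ++ci) {
      const double* s0 = src + (size_t)sn * HW * C + (size_t)ci * HW;
      float* dptr = X.colptr(ci) + (size_t)sn * HW;
      for (size_t i = 0; i < HW; ++i) dptr[i] = (float)(s0[i] / 255.0);
    }
  return X;
}

static double batch_loss(const fmat& probs, const IntegerVector& y,
                         double& acc) {
  const int N = probs.n_rows;
  double loss = 0; int correct = 0;
  for (int i = 0; i < N; ++i) {
    const int yi = y[i];
    if (yi < 0 || yi >= (int)probs.n_cols) stop("class index out of range");
    loss -= std::log(std::max(probs(i, yi), 1e-12f));
    if ((int)probs.row(i).index_max() == yi) ++correct;
  }
  acc = (double)correct / N;
  return loss / N;
}

static Optim parse_optim(const List& o, long t) {
  Optim op;
  std::string kind = as<std::string>(o["optimizer"]);
  op.type = (kind == "adam") ? 1 : 0;
  op.lr = (float)as<double>(o["learning_rate"]);
  if (o.containsElementNamed("momentum"))
    op.momentum = (float)as<double>(o["momentum"]);
  op.t = t;
  return op;
}

} // namespace

typedef Rcpp::XPtr<CSN> CSNPtr;

// [[Rcpp::export]]
SEXP csn_build_(int input_channels, int input_size, int n_classes,
                double width_multiplier, int branch_embed_dim, int seed) {
  CSN* m = new CSN(input_channels, input_size, n_classes, width_multiplier,
                   branch_embed_dim, seed);
  return CSNPtr(m, true);
}

// [[Rcpp::export]]
List csn_describe_(SEXP xp) {
  CSNPtr m(xp);
  List vr, rr, hr;
  for (auto& l : m->vgg) l->describe(vr);
  for (auto& l : m->res) l->describe(rr);
  for (auto& l : m->head) l->describe(hr);
  return List::create(
      _["vgg"] = vr, _["resnet"] = rr, _["head"] = hr,
      _["embed_dim"] = m->embed, _["fused_dim"] = 2 * m->embed,
      _["n_classes"] = m->ncls, _["input_channels"] = m->in_ch,
      _["input_size"] = m->in_size, _["width_multiplier"] = m->width);
}

// [[Rcpp::export]]
List csn_train_batch_(SEXP xp, NumericVector x, IntegerVector y, List opt) {
  CSNPtr m(xp);
  int N = 0;
  fmat X = to_batch(x, m->in_size, m->in_size, m->in_ch, N);
  if (y.size() != N) stop("labels do not match batch size");
  fmat probs = m->forward(X, N, true);
  double acc = 0;
  const double loss = batch_loss(probs, y, acc);
  if (!std::isfinite(loss))
    stop("training diverged: non-finite loss (try a smaller learning rate)");
  // "mean" divides the gradient by the batch size (framework convention);
  // "sum" follows the batch-summed loss formula
  bool mean_reduce = true;
  if (opt.containsElementNamed("loss_reduction"))
    mean_reduce = as<std::string>(opt["loss_reduction"]) != "sum";
  fmat dlogits = probs;
  for (int i = 0; i < N; ++i) dlogits(i, y[i]) -= 1.0f;
  if (mean_reduce) dlogits /= (float)N;
  m->backward(dlogits, N);
  m->adam_t += 1;
  Optim o = parse_optim(opt, m->adam_t);
  m->step(o);
  return List::create(_["loss"] = loss, _["accuracy"] = acc);
}

// [[Rcpp::export]]
List csn_eval_batch_(SEXP xp, NumericVector x, IntegerVector y) {
  CSNPtr m(xp);
  int N = 0;
  fmat X = to_batch(x, m->in_size, m->in_size, m->in_ch, N);
  if (y.size() != N) stop("labels do not match batch size");
  fmat probs = m->forward(X, N, false);
  double acc = 0;
  const double loss = batch_loss(probs, y, acc);
  return List::create(_["loss"] = loss, _["accuracy"] = acc);
}

// [[Rcpp::export]]
NumericMatrix csn_predict_(SEXP xp, NumericVector x) {
  CSNPtr m(xp);
  int N = 0;
  fmat X = to_batch(x, m->in_size, m->in_size, m->in_ch, N);
  fmat probs = m->forward(X, N, false);
  NumericMatrix out(N, m->ncls);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < m->ncls; ++j) out(i, j) = probs(i, j);
  return out;
}

// Weight export/import. BatchNorm running statistics are included so a
// restored checkpoint predicts identically.
// [[Rcpp::export]]
List csn_weights_(SEXP xp) {
  CSNPtr m(xp);
  std::vector<Layer*> ls;
  m->all_layers(ls);
  List out;
  std::function<void(Layer*)> grab = [&](Layer* l) {
    if (auto* c = dynamic_cast<Conv*>(l)) {
      out.push_back(wrap(arma::conv_to<arma::mat>::from(c->W.w)));
      out.push_back(wrap(arma::conv_to<arma::mat>::from(c->b.w)));
    } else if (auto* d = dynamic_cast<Dense*>(l)) {
      out.push_back(wrap(arma::conv_to<arma::mat>::from(d->W.w)));
      out.push_back(wrap(arma::conv_to<arma::mat>::from(d->b.w)));
    } else if (auto* b = dynamic_cast<BatchNorm*>(l)) {
      out.push_back(wrap(arma::conv_to<arma::mat>::from(b->gamma.w)));
      out.push_back(wrap(arma::conv_to<arma::mat>::from(b->beta.w)));
      out.push_back(wrap(arma::conv_to<arma::mat>::from(
          arma::fmat(b->run_mean))));
      out.push_back(wrap(arma::conv_to<arma::mat>::from(
          arma::fmat(b->run_var))));
    } else if (auto* bt = dynamic_cast<Bottleneck*>(l)) {
      for (auto& s : bt->main) grab(s.get());
      for (auto& s : bt->sc) grab(s.get());
    }
  };
  for (Layer* l : ls) grab(l);
  return out;
}

// [[Rcpp::export]]
void csn_set_weights_(SEXP xp, List ws) {
  CSNPtr m(xp);
  std::vector<Layer*> ls;
  m->all_layers(ls);
  R_xlen_t pos = 0;
  auto next = [&]() -> arma::fmat {
    if (pos >= ws.size()) stop("weight list too short for this architecture");
    arma::mat w = as<arma::mat>(ws[pos++]);
    return arma::conv_to<arma::fmat>::from(w);
  };
  std::function<void(Layer*)> put = [&](Layer* l) {
    if (auto* c = dynamic_cast<Conv*>(l)) {
      arma::fmat w = next(), b = next();
      if (arma::size(w) != arma::size(c->W.w)) stop("conv weight shape mismatch");
      c->W.w = w; c->b.w = b;
    } else if (auto* d = dynamic_cast<Dense*>(l)) {
      arma::fmat w = next(), b = next();
      if (arma::size(w) != arma::size(d->W.w)) stop("dense weight shape mismatch");
      d->W.w = w; d->b.w = b;
    } else if (auto* b = dynamic_cast<BatchNorm*>(l)) {
      b->gamma.w = next(); b->beta.w = next();
      b->run_mean = arma::frowvec(next());
      b->run_var = arma::frowvec(next());
    } else if (auto* bt = dynamic_cast<Bottleneck*>(l)) {
      for (auto& s : bt->main) put(s.get());
      for (auto& s : bt->sc) put(s.get());
    }
  };
  for (Layer* l : ls) put(l);
  if (pos != ws.size()) stop("weight list does not match this architecture");
}

// Wall-clock per-layer-type breakdown of one forward+backward pass
// (diagnostic aid for performance work).
// [[Rcpp::export]]
List csn_profile_(SEXP xp, NumericVector x, IntegerVector y) {
  CSNPtr m(xp);
  int N = 0;
  fmat X = to_batch(x, m->in_size, m->in_size, m->in_ch, N);
  std::map<std::string, double> fwd_t, bwd_t;
  arma::wall_clock clk;
  auto timed_fwd = [&](std::vector<LayerPtr>& L, fmat xx) {
    for (auto& l : L) {
      clk.tic();
      xx = l->forward(xx, N, true);
      fwd_t[l->type] += clk.toc();
    }
    return xx;
  };
  auto timed_bwd = [&](std::vector<LayerPtr>& L, fmat g) {
    for (auto it = L.rbegin(); it != L.rend(); ++it) {
      clk.tic();
      g = (*it)->backward(g, N);
      bwd_t[(*it)->type] += clk.toc();
    }
    return g;
  };
  fmat ev = timed_fwd(m->vgg, X);
  fmat er = timed_fwd(m->res, X);
  fmat fused = arma::join_rows(ev, er);
  fmat logits = timed_fwd(m->head, fused);
  fmat dl(logits.n_rows, logits.n_cols, arma::fill::randn);
  fmat dfused = timed_bwd(m->head, dl * 0.01f);
  timed_bwd(m->vgg, dfused.cols(0, m->embed - 1));
  timed_bwd(m->res, dfused.cols(m->embed, 2 * m->embed - 1));
  List out;
  for (auto& kv : fwd_t) out[std::string("fwd_") + kv.first] = kv.second;
  for (auto& kv : bwd_t) out[std::string("bwd_") + kv.first] = kv.second;
  return out;
}

// Behavioral check of the residual structure: in the first identity-shortcut
// bottleneck, zeroing the final main-path convolution makes the block the
// identity (ReLU of its non-negative input). Runs random data through that
// block alone and reports the maximum |output - input| with the weights
// zeroed (restoring them afterwards).
// [[Rcpp::export]]
double csn_residual_identity_gap_(SEXP xp, int n_pixels, int seed) {
  CSNPtr m(xp);
  Bottleneck* blk = nullptr;
  for (auto& l : m->res) {
    auto* b = dynamic_cast<Bottleneck*>(l.get());
    if (b && b->sc.empty()) { blk = b; break; }
  }
  if (!blk) stop("no identity-shortcut bottleneck found");
  Conv* c3 = nullptr;
  for (auto it = blk->main.rbegin(); it != blk->main.rend(); ++it)
    if ((c3 = dynamic_cast<Conv*>(it->get()))) break;
  fmat saved = c3->W.w;
  c3->W.w.zeros();
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> d(0.5f, 0.25f);
  // one synthetic sample of the block's input shape, non-negative like the
  // ReLU output it would receive
  int HW = blk->in.H * blk->in.W;
  fmat x(HW, blk->in.C);
  for (arma::uword i = 0; i < x.n_elem; ++i) x[i] = std::max(0.0f, d(rng));
  fmat y = blk->forward(x, 1, false);
  c3->W.w = saved;
  return (double)arma::abs(y - x).max();
}

// [[Rcpp::export]]
NumericMatrix csn_first_conv_weights_(SEXP xp, std::string branch) {
  CSNPtr m(xp);
  auto& L = branch == "vgg" ? m->vgg : m->res;
  Conv* c = dynamic_cast<Conv*>(L[0].get());
  return wrap(arma::conv_to<arma::mat>::from(c->W.w));
}

// [[Rcpp::export]]
void csn_set_first_conv_weights_(SEXP xp, std::string branch,
                                 NumericMatrix w) {
  CSNPtr m(xp);
  auto& L = branch == "vgg" ? m->vgg : m->res;
  Conv* c = dynamic_cast<Conv*>(L[0].get());
  arma::fmat fw = arma::conv_to<arma::fmat>::from(as<arma::mat>(w));
  if (arma::size(fw) != arma::size(c->W.w))
    stop("first-layer weight shape mismatch");
  c->W.w = fw;
}
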