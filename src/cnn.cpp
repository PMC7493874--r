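// Single-precision CNN engine for fingerprint classification.
//
// Networks are four conv(ReLU)+maxpool blocks followed by a dense
// 1024/512/256 ReLU head and one sigmoid output unit. Activations are held
// as C x (H*W*B) matrices (channel-major, column index s*H*W + h + H*w).
// Convolutions over flat (single-row) inputs run as per-sample shifted GEMMs
// — one GEMM per kernel offset, no patch matrix — while true 2D layers use
// im2col + GEMM. All buffers live in a workspace reused across batches; all
// arithmetic is float32, and weights cross the R boundary as double
// matrices.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using arma::fmat;
using arma::uword;
typedef arma::Mat<unsigned> argmat;

namespace {

struct ConvDims {
  int inC, inH, inW;
  int outC, kh, kw;
  int padh, padw;      // pad before (same padding), 0 for valid
  int outH, outW;      // post-conv
  int ph, pw;          // pool window
  int pH, pW;          // post-pool
  bool flat1d;         // single-row input and kernel: shifted-GEMM path
};

struct NetDims {
  std::vector<ConvDims> conv;
  std::vector<int> head;  // hidden unit counts
  int flat;               // flattened size after last pool
};

NetDims compute_dims(int in_rows, int in_cols,
                     const std::vector<int>& filters,
                     int kh, int kw, bool pad_same,
                     const std::vector<int>& head_units) {
  NetDims nd;
  int C = 1, H = in_rows, W = in_cols;
  for (size_t i = 0; i < filters.size(); ++i) {
    ConvDims d;
    d.inC = C; d.inH = H; d.inW = W;
    d.outC = filters[i];
    d.kh = kh; d.kw = kw;
    if (d.kh > H && (i == 0 || !pad_same)) {
      // the first kernel cannot extend across more fingerprint rows than the
      // input has; deeper layers with same padding pad the exhausted axis
      Rcpp::stop("conv layer %d: kernel row extent %d exceeds input rows %d",
                 (int)i + 1, d.kh, H);
    }
    if (pad_same) {
      d.padh = (d.kh - 1) / 2;
      d.padw = (d.kw - 1) / 2;
      d.outH = H;
      d.outW = W;
    } else {
      d.padh = d.padw = 0;
      d.outH = H - d.kh + 1;
      d.outW = W - d.kw + 1;
      if (d.outH < 1 || d.outW < 1)
        Rcpp::stop("conv layer %d: kernel (%d,%d) exceeds input (%d,%d) with valid padding",
                   (int)i + 1, d.kh, d.kw, H, W);
    }
    d.ph = (d.outH >= 2) ? 2 : 1;   // row pooling stops once rows are exhausted
    d.pw = (d.outW >= 2) ? 2 : 1;
    d.pH = d.outH / d.ph;
    d.pW = d.outW / d.pw;
    if (d.pH < 1 || d.pW < 1)
      Rcpp::stop("conv layer %d: pooled extent collapsed to zero", (int)i + 1);
    d.flat1d = (H == 1 && d.kh == 1);
    nd.conv.push_back(d);
    C = d.outC; H = d.pH; W = d.pW;
  }
  nd.flat = C * H * W;
  nd.head = head_units;
  return nd;
}

std::vector<int> as_int_vec(const Rcpp::IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

NetDims dims_from_spec(const Rcpp::List& spec) {
  return compute_dims(Rcpp::as<int>(spec["in_rows"]),
                      Rcpp::as<int>(spec["in_cols"]),
                      as_int_vec(spec["conv_filters"]),
                      Rcpp::as<int>(spec["kh"]),
                      Rcpp::as<int>(spec["kw"]),
                      Rcpp::as<bool>(spec["pad_same"]),
                      as_int_vec(spec["head_units"]));
}

// weights are stored flat: for each conv layer W (outC x inC*kh*kw), b
// (outC x 1); for each dense layer W (units x in), b; output w (1 x in), b.
std::vector<fmat> weights_from_list(const Rcpp::List& wl) {
  std::vector<fmat> w;
  for (R_xlen_t i = 0; i < wl.size(); ++i)
    w.push_back(arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(wl[i])));
  return w;
}

Rcpp::List weights_to_list(const std::vector<fmat>& w) {
  Rcpp::List out(w.size());
  for (size_t i = 0; i < w.size(); ++i)
    out[i] = Rcpp::wrap(arma::conv_to<arma::mat>::from(w[i]));
  return out;
}

inline void ensure_size(fmat& m, uword r, uword c, bool zero_on_alloc) {
  if (m.n_rows != r || m.n_cols != c) {
    if (zero_on_alloc) m.zeros(r, c); else m.set_size(r, c);
  }
}

// ---- im2col path (true 2D layers) -----------------------------------------
// P has C*kh*kw rows, outH*outW*B cols; column s*oHW + (oh + outH*ow).
// Padding cells are zeroed on (re)allocation only: for fixed dims the same
// cells are padding every batch, and all valid cells are rewritten.
void im2col(const fmat& A, const ConvDims& d, int B, fmat& P) {
  const int C = d.inC, H = d.inH, W = d.inW;
  const int oH = d.outH, oW = d.outW;
  ensure_size(P, (uword)C * d.kh * d.kw, (uword)oH * oW * B, true);
  const uword pstride = P.n_rows;
  for (int s = 0; s < B; ++s) {
    const uword acol0 = (uword)s * H * W;
    const uword pcol0 = (uword)s * oH * oW;
    for (int kwi = 0; kwi < d.kw; ++kwi) {
      for (int ow = 0; ow < oW; ++ow) {
        const int w = ow - d.padw + kwi;
        if (w < 0 || w >= W) continue;
        for (int khi = 0; khi < d.kh; ++khi) {
          const int oh0 = std::max(0, d.padh - khi);
          const int oh1 = std::min(oH - 1, H - 1 + d.padh - khi);
          if (oh1 < oh0) continue;
          const float* src = A.colptr(acol0 + (oh0 - d.padh + khi) +
                                      (uword)H * w);
          float* dst = P.colptr(pcol0 + oh0 + (uword)oH * ow) +
                       (uword)C * (khi + d.kh * kwi);
          for (int oh = oh0; oh <= oh1; ++oh, src += C, dst += pstride)
            std::memcpy(dst, src, sizeof(float) * C);
        }
      }
    }
  }
}

// scatter dP back onto the input activation gradient
void col2im(const fmat& dP, const ConvDims& d, int B, fmat& dA) {
  const int C = d.inC, H = d.inH, W = d.inW;
  const int oH = d.outH, oW = d.outW;
  dA.zeros(C, (uword)H * W * B);
  const uword pstride = dP.n_rows;
  for (int s = 0; s < B; ++s) {
    const uword acol0 = (uword)s * H * W;
    const uword pcol0 = (uword)s * oH * oW;
    for (int kwi = 0; kwi < d.kw; ++kwi) {
      for (int ow = 0; ow < oW; ++ow) {
        const int w = ow - d.padw + kwi;
        if (w < 0 || w >= W) continue;
        for (int khi = 0; khi < d.kh; ++khi) {
          const int oh0 = std::max(0, d.padh - khi);
          const int oh1 = std::min(oH - 1, H - 1 + d.padh - khi);
          if (oh1 < oh0) continue;
          float* dst = dA.colptr(acol0 + (oh0 - d.padh + khi) + (uword)H * w);
          const float* src = dP.colptr(pcol0 + oh0 + (uword)oH * ow) +
                             (uword)C * (khi + d.kh * kwi);
          for (int oh = oh0; oh <= oh1; ++oh, dst += C, src += pstride)
            for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// ---- shifted-GEMM path (single-row layers) --------------------------------
// For H = kh = 1 the kernel only slides along the bit axis, so each kernel
// offset contributes W_k * A over a contiguous column range; per-sample
// GEMMs keep sample boundaries exact.
struct ShiftRange {
  int lo, hi, off;  // output columns [lo,hi], input column = out + off
};

ShiftRange shift_range(const ConvDims& d, int kwi) {
  ShiftRange r;
  r.off = kwi - d.padw;
  r.lo = std::max(0, -r.off);
  r.hi = std::min(d.outW - 1, d.inW - 1 - r.off);
  return r;
}

void conv1d_forward(const fmat& A, const fmat& Wc, const ConvDims& d, int B,
                    fmat& Y) {
  const int C = d.inC, W = d.inW, oW = d.outW;
  ensure_size(Y, (uword)d.outC, (uword)oW * B, false);
  // the kwi = padw offset covers every output column: run it first with '='
  for (int pass = 0; pass < 2; ++pass) {
    for (int kwi = 0; kwi < d.kw; ++kwi) {
      const bool primary = (kwi == d.padw) || (d.padw >= d.kw && kwi == 0);
      if ((pass == 0) != primary) continue;
      const ShiftRange r = shift_range(d, kwi);
      if (r.hi < r.lo) continue;
      const fmat Wk = Wc.cols((uword)C * kwi, (uword)C * kwi + C - 1);
      for (int s = 0; s < B; ++s) {
        const uword y0 = (uword)s * oW, a0 = (uword)s * W;
        fmat Ys(Y.colptr(y0 + r.lo), d.outC, r.hi - r.lo + 1, false, true);
        const fmat As(const_cast<float*>(A.colptr(a0 + r.lo + r.off)), C,
                      r.hi - r.lo + 1, false, true);
        if (pass == 0) Ys = Wk * As; else Ys += Wk * As;
      }
      if (pass == 0) {
        // columns the primary offset cannot reach (valid padding edge) start
        // at zero
        if (r.lo > 0 || r.hi < oW - 1) {
          for (int s = 0; s < B; ++s) {
            const uword y0 = (uword)s * oW;
            for (int j = 0; j < r.lo; ++j)
              std::memset(Y.colptr(y0 + j), 0, sizeof(float) * d.outC);
            for (int j = r.hi + 1; j < oW; ++j)
              std::memset(Y.colptr(y0 + j), 0, sizeof(float) * d.outC);
          }
        }
      }
    }
  }
}

void conv1d_backward(const fmat& A, const fmat& dY, const fmat& Wc,
                     const ConvDims& d, int B, fmat& dW, fmat& dA,
                     bool need_dA) {
  const int C = d.inC, W = d.inW, oW = d.outW;
  dW.zeros(Wc.n_rows, Wc.n_cols);
  if (need_dA) dA.zeros(C, (uword)W * B);
  for (int kwi = 0; kwi < d.kw; ++kwi) {
    const ShiftRange r = shift_range(d, kwi);
    if (r.hi < r.lo) continue;
    fmat dWk(dW.colptr((uword)C * kwi), d.outC, C, false, true);
    const fmat Wk = Wc.cols((uword)C * kwi, (uword)C * kwi + C - 1);
    for (int s = 0; s < B; ++s) {
      const uword y0 = (uword)s * oW, a0 = (uword)s * W;
      const fmat dYs(const_cast<float*>(dY.colptr(y0 + r.lo)), d.outC,
                     r.hi - r.lo + 1, false, true);
      const fmat As(const_cast<float*>(A.colptr(a0 + r.lo + r.off)), C,
                    r.hi - r.lo + 1, false, true);
      dWk += dYs * As.t();
      if (need_dA) {
        fmat dAs(dA.colptr(a0 + r.lo + r.off), C, r.hi - r.lo + 1, false,
                 true);
        dAs += Wk.t() * dYs;
      }
    }
  }
}

// ---- pooling ---------------------------------------------------------------
void maxpool(const fmat& Y, const ConvDims& d, int B, fmat& out, argmat& arg,
             bool track) {
  const int C = d.outC, H = d.outH;
  const int pH = d.pH, pW = d.pW;
  ensure_size(out, (uword)C, (uword)pH * pW * B, false);
  if (track && ((int)arg.n_rows != C || arg.n_cols != out.n_cols))
    arg.set_size(C, out.n_cols);
  for (int s = 0; s < B; ++s) {
    const uword y0 = (uword)s * H * d.outW;
    const uword o0 = (uword)s * pH * pW;
    for (int pw_ = 0; pw_ < pW; ++pw_) {
      for (int ph_ = 0; ph_ < pH; ++ph_) {
        const uword ocol = o0 + ph_ + (uword)pH * pw_;
        const uword ycol0 = y0 + (uword)(ph_ * d.ph) +
                            (uword)H * (pw_ * d.pw);
        float* oc = out.colptr(ocol);
        std::memcpy(oc, Y.colptr(ycol0), sizeof(float) * C);
        unsigned* ac = nullptr;
        if (track) {
          ac = arg.colptr(ocol);
          for (int c = 0; c < C; ++c) ac[c] = (unsigned)ycol0;
        }
        for (int j = 0; j < d.pw; ++j) {
          for (int i = 0; i < d.ph; ++i) {
            if (i == 0 && j == 0) continue;
            const uword ycol = y0 + (uword)(ph_ * d.ph + i) +
                               (uword)H * (pw_ * d.pw + j);
            const float* yc = Y.colptr(ycol);
            if (track) {
              for (int c = 0; c < C; ++c)
                if (yc[c] > oc[c]) { oc[c] = yc[c]; ac[c] = (unsigned)ycol; }
            } else {
              for (int c = 0; c < C; ++c)
                if (yc[c] > oc[c]) oc[c] = yc[c];
            }
          }
        }
      }
    }
  }
}

inline void relu_inplace(fmat& m) {
  float* p = m.memptr();
  const uword n = m.n_elem;
  for (uword i = 0; i < n; ++i) p[i] = p[i] > 0.0f ? p[i] : 0.0f;
}

// zero gradient wherever the activation was clipped
inline void relu_mask(fmat& grad, const fmat& act) {
  float* g = grad.memptr();
  const float* a = act.memptr();
  const uword n = grad.n_elem;
  for (uword i = 0; i < n; ++i) if (a[i] == 0.0f) g[i] = 0.0f;
}

struct Workspace {
  std::vector<fmat> P;        // im2col patches (2D layers)
  std::vector<fmat> Y;        // post-ReLU conv activations (pre-pool)
  std::vector<argmat> arg;
  std::vector<fmat> pooled;   // post-pool activations
  fmat flat;                  // flattened features (flat x B)
  std::vector<fmat> h;        // dense hidden activations
  std::vector<fmat> dropmask; // inverted dropout masks
  arma::frowvec p;            // output probabilities
  std::vector<fmat> dY, dA;   // conv backward scratch
  std::vector<fmat> g;        // gradients, laid out like the weights
};

class Net {
public:
  NetDims nd;
  std::vector<fmat> w;  // interleaved W, b
  float dropout = 0.0f;

  Net(const NetDims& nd_, const std::vector<fmat>& w_, float drop)
      : nd(nd_), w(w_), dropout(drop) {}

  int n_conv() const { return (int)nd.conv.size(); }
  int n_dense() const { return (int)nd.head.size(); }
  fmat& Wc(int i) { return w[2 * i]; }
  fmat& bc(int i) { return w[2 * i + 1]; }
  fmat& Wd(int j) { return w[2 * n_conv() + 2 * j]; }
  fmat& bd(int j) { return w[2 * n_conv() + 2 * j + 1]; }
  fmat& Wo() { return w[w.size() - 2]; }
  fmat& bo() { return w[w.size() - 1]; }

  // X: (H*W) x B sample columns (column-major alias works as the 1 x (HW*B)
  // channel-major activation of a single input channel)
  void forward(const fmat& X, int B, Workspace& ws, bool training,
               std::mt19937* rng) {
    const int nc = n_conv();
    ws.P.resize(nc); ws.Y.resize(nc); ws.arg.resize(nc);
    ws.pooled.resize(nc);
    const fmat* A = &X;
    fmat Ain(const_cast<float*>(X.memptr()), 1,
             (uword)X.n_rows * B, false, true);
    A = &Ain;
    for (int i = 0; i < nc; ++i) {
      const ConvDims& d = nd.conv[i];
      if (d.flat1d) {
        conv1d_forward(*A, Wc(i), d, B, ws.Y[i]);
      } else {
        im2col(*A, d, B, ws.P[i]);
        ensure_size(ws.Y[i], (uword)d.outC, (uword)d.outH * d.outW * B,
                    false);
        ws.Y[i] = Wc(i) * ws.P[i];
      }
      ws.Y[i].each_col() += bc(i).col(0);
      relu_inplace(ws.Y[i]);
      maxpool(ws.Y[i], d, B, ws.pooled[i], ws.arg[i], training);
      A = &ws.pooled[i];
    }
    // flatten: per sample, channel-major over spatial positions
    const ConvDims& dl = nd.conv.back();
    const int C = dl.outC, sp = dl.pH * dl.pW;
    ensure_size(ws.flat, (uword)C * sp, (uword)B, false);
    for (int s = 0; s < B; ++s)
      std::memcpy(ws.flat.colptr(s), ws.pooled[nc - 1].colptr((uword)s * sp),
                  sizeof(float) * C * sp);
    // dense head
    const int ndense = n_dense();
    ws.h.resize(ndense);
    ws.dropmask.assign(ndense, fmat());
    const fmat* Hh = &ws.flat;
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    for (int j = 0; j < ndense; ++j) {
      ws.h[j] = Wd(j) * (*Hh);
      ws.h[j].each_col() += bd(j).col(0);
      relu_inplace(ws.h[j]);
      if (training && dropout > 0.0f && rng) {
        fmat mask(ws.h[j].n_rows, ws.h[j].n_cols);
        const float keep = 1.0f - dropout;
        float* mp = mask.memptr();
        for (uword t = 0; t < mask.n_elem; ++t)
          mp[t] = (unif(*rng) < keep) ? 1.0f / keep : 0.0f;
        ws.h[j] %= mask;
        ws.dropmask[j] = std::move(mask);
      }
      Hh = &ws.h[j];
    }
    fmat z = Wo() * (*Hh);
    z.each_col() += bo().col(0);
    ws.p.set_size(B);
    for (int s = 0; s < B; ++s)
      ws.p[s] = 1.0f / (1.0f + std::exp(-z.at(0, s)));
  }

  void backward(const fmat& X, int B, Workspace& ws, const arma::frowvec& y) {
    const int nc = n_conv(), ndense = n_dense();
    if (ws.g.size() != w.size()) {
      ws.g.resize(w.size());
      for (size_t i = 0; i < w.size(); ++i)
        ws.g[i].set_size(w[i].n_rows, w[i].n_cols);
    }
    ws.dY.resize(nc); ws.dA.resize(nc);
    // output layer: dL/dz = (p - y)/B
    fmat dz(1, B);
    for (int s = 0; s < B; ++s) dz.at(0, s) = (ws.p[s] - y[s]) / B;
    const fmat& hlast = ndense > 0 ? ws.h[ndense - 1] : ws.flat;
    ws.g[w.size() - 2] = dz * hlast.t();
    ws.g[w.size() - 1].at(0, 0) = arma::accu(dz);
    fmat dH = Wo().t() * dz;
    for (int j = ndense - 1; j >= 0; --j) {
      if (ws.dropmask[j].n_elem) dH %= ws.dropmask[j];
      relu_mask(dH, ws.h[j]);
      const fmat& prev = j > 0 ? ws.h[j - 1] : ws.flat;
      ws.g[2 * nc + 2 * j] = dH * prev.t();
      ws.g[2 * nc + 2 * j + 1] = arma::sum(dH, 1);
      dH = Wd(j).t() * dH;
    }
    // unflatten dH (flat x B) into the gradient w.r.t. the last pooled map
    const ConvDims& dl = nd.conv.back();
    {
      const int C = dl.outC, sp = dl.pH * dl.pW;
      fmat& dPool = ws.dA[nc - 1];
      ensure_size(dPool, (uword)C, (uword)sp * B, false);
      for (int s = 0; s < B; ++s)
        std::memcpy(dPool.colptr((uword)s * sp), dH.colptr(s),
                    sizeof(float) * C * sp);
    }
    fmat Ain(const_cast<float*>(X.memptr()), 1, (uword)X.n_rows * B, false,
             true);
    for (int i = nc - 1; i >= 0; --i) {
      const ConvDims& d = nd.conv[i];
      const fmat& dPool = ws.dA[i];
      // pool backward: scatter onto the argmax cells
      fmat& dY = ws.dY[i];
      dY.zeros(d.outC, (uword)d.outH * d.outW * B);
      const argmat& arg = ws.arg[i];
      float* dyp = dY.memptr();
      const uword nC = d.outC;
      for (uword col = 0; col < dPool.n_cols; ++col) {
        const float* dac = dPool.colptr(col);
        const unsigned* ac = arg.colptr(col);
        for (uword c = 0; c < nC; ++c) dyp[c + nC * ac[c]] += dac[c];
      }
      relu_mask(dY, ws.Y[i]);
      const fmat& A = (i > 0) ? ws.pooled[i - 1] : Ain;
      if (d.flat1d) {
        conv1d_backward(A, dY, Wc(i), d, B, ws.g[2 * i],
                        i > 0 ? ws.dA[i - 1] : ws.dY[i] /*unused*/, i > 0);
      } else {
        ws.g[2 * i] = dY * ws.P[i].t();
        if (i > 0) {
          fmat dP = Wc(i).t() * dY;
          col2im(dP, d, B, ws.dA[i - 1]);
        }
      }
      ws.g[2 * i + 1] = arma::sum(dY, 1);
    }
  }
};

struct Optimizer {
  std::string kind;
  float lr;
  std::vector<fmat> m, v;
  long t = 0;

  void init(const std::vector<fmat>& w) {
    m.clear(); v.clear();
    for (auto& x : w) {
      m.push_back(fmat(x.n_rows, x.n_cols, arma::fill::zeros));
      v.push_back(fmat(x.n_rows, x.n_cols, arma::fill::zeros));
    }
  }

  void step(std::vector<fmat>& w, const std::vector<fmat>& g) {
    ++t;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
    if (kind == "sgd") {
      for (size_t i = 0; i < w.size(); ++i) w[i] -= lr * g[i];
      return;
    }
    const float bc1 = 1.0f - std::pow(b1, (float)t);
    const float bc2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < w.size(); ++i) {
      float* wp = w[i].memptr();
      float* mp = m[i].memptr();
      float* vp = v[i].memptr();
      const float* gp = g[i].memptr();
      const uword n = w[i].n_elem;
      if (kind == "adam") {
        for (uword j = 0; j < n; ++j) {
          mp[j] = b1 * mp[j] + (1.0f - b1) * gp[j];
          vp[j] = b2 * vp[j] + (1.0f - b2) * gp[j] * gp[j];
          wp[j] -= lr * (mp[j] / bc1) /
                   (std::sqrt(vp[j] / bc2) + eps);
        }
      } else if (kind == "adamax") {
        for (uword j = 0; j < n; ++j) {
          mp[j] = b1 * mp[j] + (1.0f - b1) * gp[j];
          vp[j] = std::max(b2 * vp[j], std::fabs(gp[j]));
          wp[j] -= (lr / bc1) * mp[j] / (vp[j] + eps);
        }
      } else {
        Rcpp::stop("unsupported optimizer '%s'", kind.c_str());
      }
    }
  }
};

double bce(const arma::frowvec& p, const arma::frowvec& y) {
  double s = 0.0;
  for (uword i = 0; i < p.n_elem; ++i) {
    double pi = std::min(std::max((double)p[i], 1e-7), 1.0 - 1e-7);
    s += y[i] > 0.5f ? -std::log(pi) : -std::log(1.0 - pi);
  }
  return s / p.n_elem;
}

arma::frowvec predict_all(Net& net, const fmat& X, Workspace& ws,
                          int chunk = 64) {
  const int n = (int)X.n_cols;
  arma::frowvec out(n);
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int B = std::min(chunk, n - s0);
    const fmat Xb(const_cast<float*>(X.colptr(s0)), X.n_rows, B, false, true);
    net.forward(Xb, B, ws, false, nullptr);
    out.subvec(s0, s0 + B - 1) = ws.p;
  }
  return out;
}

fmat to_fmat_samples(const arma::mat& X) {
  // R passes samples in rows; engine wants feature columns
  return arma::conv_to<fmat>::from(X.t());
}

}  // namespace

// [[Rcpp::export(name = ".cnn_dims")]]
Rcpp::List cnn_dims_cpp(Rcpp::List spec) {
  NetDims nd = dims_from_spec(spec);
  const int nc = (int)nd.conv.size();
  Rcpp::IntegerVector outH(nc), outW(nc), pH(nc), pW(nc), outC(nc);
  for (int i = 0; i < nc; ++i) {
    outC[i] = nd.conv[i].outC;
    outH[i] = nd.conv[i].outH; outW[i] = nd.conv[i].outW;
    pH[i] = nd.conv[i].pH; pW[i] = nd.conv[i].pW;
  }
  return Rcpp::List::create(
      Rcpp::Named("out_channels") = outC, Rcpp::Named("conv_h") = outH,
      Rcpp::Named("conv_w") = outW, Rcpp::Named("pool_h") = pH,
      Rcpp::Named("pool_w") = pW, Rcpp::Named("flat") = nd.flat);
}

// [[Rcpp::export(name = ".cnn_init")]]
Rcpp::List cnn_init_cpp(Rcpp::List spec, int seed) {
  NetDims nd = dims_from_spec(spec);
  std::mt19937 rng((unsigned)seed);
  std::vector<fmat> w;
  // Glorot uniform throughout
  auto uniform_init = [&](int rows, int cols, int fan_in, int fan_out) {
    const float lim = std::sqrt(6.0f / (fan_in + fan_out));
    std::uniform_real_distribution<float> u(-lim, lim);
    fmat W(rows, cols);
    for (uword i = 0; i < W.n_elem; ++i) W[i] = u(rng);
    return W;
  };
  for (auto& d : nd.conv) {
    const int fin = d.inC * d.kh * d.kw, fout = d.outC * d.kh * d.kw;
    w.push_back(uniform_init(d.outC, fin, fin, fout));
    w.push_back(fmat(d.outC, 1, arma::fill::zeros));
  }
  int in = nd.flat;
  for (int u : nd.head) {
    w.push_back(uniform_init(u, in, in, u));
    w.push_back(fmat(u, 1, arma::fill::zeros));
    in = u;
  }
  w.push_back(uniform_init(1, in, in, 1));
  w.push_back(fmat(1, 1, arma::fill::zeros));
  return weights_to_list(w);
}

// [[Rcpp::export(name = ".cnn_predict")]]
Rcpp::NumericVector cnn_predict_cpp(Rcpp::List weights, Rcpp::List spec,
                                    arma::mat X) {
  NetDims nd = dims_from_spec(spec);
  const int expected = nd.conv[0].inH * nd.conv[0].inW;
  if ((int)X.n_cols != expected)
    Rcpp::stop("input has %d features per compound but the model expects %d",
               (int)X.n_cols, expected);
  Net net(nd, weights_from_list(weights), 0.0f);
  if (X.n_rows == 0) return Rcpp::NumericVector(0);
  fmat Xf = to_fmat_samples(X);
  Workspace ws;
  arma::frowvec p = predict_all(net, Xf, ws);
  return Rcpp::NumericVector(p.begin(), p.end());
}

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, Rcpp::List spec, arma::mat X,
                         Rcpp::NumericVector y, arma::mat Xv,
                         Rcpp::NumericVector yv, int max_epochs, int patience,
                         int batch_size, double lr, std::string optimizer,
                         double dropout, int seed, bool monitor_bacc,
                         bool verbose) {
  NetDims nd = dims_from_spec(spec);
  Net net(nd, weights_from_list(weights), (float)dropout);
  fmat Xf = to_fmat_samples(X), Xvf = to_fmat_samples(Xv);
  arma::frowvec yf(X.n_rows), yvf(Xv.n_rows);
  for (uword i = 0; i < yf.n_elem; ++i) yf[i] = (float)y[i];
  for (uword i = 0; i < yvf.n_elem; ++i) yvf[i] = (float)yv[i];

  Optimizer opt; opt.kind = optimizer; opt.lr = (float)lr;
  opt.init(net.w);
  std::mt19937 rng((unsigned)seed);
  const int n = (int)Xf.n_cols;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> h_train, h_val, h_bacc;
  std::vector<fmat> best_w = net.w;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0;
  Workspace ws, ws_val;
  fmat Xb(Xf.n_rows, std::min(batch_size, n));
  arma::frowvec yb;

  for (int e = 1; e <= max_epochs; ++e) {
    Rcpp::checkUserInterrupt();
    std::shuffle(idx.begin(), idx.end(), rng);
    double tloss = 0.0;
    int nb = 0;
    for (int s0 = 0; s0 < n; s0 += batch_size) {
      const int B = std::min(batch_size, n - s0);
      ensure_size(Xb, Xf.n_rows, (uword)B, false);
      yb.set_size(B);
      for (int j = 0; j < B; ++j) {
        std::memcpy(Xb.colptr(j), Xf.colptr(idx[s0 + j]),
                    sizeof(float) * Xf.n_rows);
        yb[j] = yf[idx[s0 + j]];
      }
      net.forward(Xb, B, ws, true, &rng);
      tloss += bce(ws.p, yb);
      ++nb;
      net.backward(Xb, B, ws, yb);
      opt.step(net.w, ws.g);
    }
    tloss /= std::max(nb, 1);
    if (!std::isfinite(tloss))
      Rcpp::stop("training diverged: non-finite loss at epoch %d (lr=%g, optimizer=%s)",
                 e, lr, optimizer.c_str());
    arma::frowvec pv = predict_all(net, Xvf, ws_val);
    const double vloss = bce(pv, yvf);
    // balanced accuracy on the validation set at the 0.5 threshold
    double tp = 0, fn = 0, tn = 0, fp = 0;
    for (uword i = 0; i < pv.n_elem; ++i) {
      const bool pred = pv[i] > 0.5f, truth = yvf[i] > 0.5f;
      if (truth) { if (pred) ++tp; else ++fn; }
      else { if (pred) ++fp; else ++tn; }
    }
    double bacc = NA_REAL;
    if (tp + fn > 0 && tn + fp > 0)
      bacc = 0.5 * (tp / (tp + fn) + tn / (tn + fp));
    h_train.push_back(tloss); h_val.push_back(vloss); h_bacc.push_back(bacc);
    if (verbose)
      Rcpp::Rcout << "epoch " << e << " train_loss=" << tloss
                  << " val_loss=" << vloss << " val_bacc=" << bacc << "\n";
    // the monitored quantity, as a score to minimize
    const double score = monitor_bacc
        ? (std::isnan(bacc) ? vloss : -bacc)
        : vloss;
    if (score < best_val) {
      best_val = score;
      best_epoch = e;
      best_w = net.w;
      wait = 0;
    } else {
      ++wait;
      if (wait > patience) break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_list(best_w),
      Rcpp::Named("train_loss") = h_train, Rcpp::Named("val_loss") = h_val,
      Rcpp::Named("val_bacc") = h_bacc, Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("epochs_run") = (int)h_train.size(),
      Rcpp::Named("best_val_loss") =
          best_epoch > 0 ? h_val[best_epoch - 1] : NA_REAL);
}
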