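// Small residual convolutional network for recurrence-image classification.
//
// Single-precision forward/backward written against Armadillo so the conv
// layers reduce to im2col + sgemm. Activations are stored as (channels x
// batch*H*W) matrices with image pixels in row-major spatial order; the
// im2col patch matrix keeps the channel index fastest so packing and
// unpacking are contiguous copies.
//
// Architecture (input side must be a multiple of 8, >= 32):
//   conv 7x7 stride 2 -> BN -> ReLU
//   8 residual blocks of two 3x3 convs each (BN before every ReLU,
//   1x1 projection shortcut when the channel count changes); 2x2 max
//   pooling after the first two blocks
//   global average pooling -> dense -> 3-way softmax
// The second BN of every block starts at gamma = 0 so the network begins
// as an identity-like shallow net and the residual branches fade in.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.9f;

struct Param {
  fmat w, m, v;
  void init(int r, int c) { w.zeros(r, c); m.zeros(r, c); v.zeros(r, c); }
  void adam(float lr, float b1, float b2, float eps, long t, const fmat& g) {
    m = b1 * m + (1.0f - b1) * g;
    v = b2 * v + (1.0f - b2) * square(g);
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
};

// Convolution via im2col; patch row index = (dy*k + dx) * in_c + c.
struct Conv {
  int in_c, out_c, k, stride, pad;
  Param W;                      // (out_c, k*k*in_c)
  fmat cols;                    // im2col cache
  int H_in, W_in, H_out, W_out, B;

  void init(int ic, int oc, int kk, int s, int p, std::mt19937& rng) {
    in_c = ic; out_c = oc; k = kk; stride = s; pad = p;
    W.init(oc, kk * kk * ic);
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / (ic * kk * kk)));
    for (uword i = 0; i < W.w.n_elem; ++i) W.w(i) = nd(rng);
  }

  void im2col(const fmat& X, int B_, int H, int Wd) {
    B = B_; H_in = H; W_in = Wd;
    H_out = (H + 2 * pad - k) / stride + 1;
    W_out = (Wd + 2 * pad - k) / stride + 1;
    cols.zeros((size_t)in_c * k * k, (size_t)B * H_out * W_out);
    const int HW = H * Wd, HWo = H_out * W_out;
    const float* xp = X.memptr();
    float* cp = cols.memptr();
    const size_t crows = cols.n_rows;
    for (int b = 0; b < B; ++b) {
      for (int yo = 0; yo < H_out; ++yo) {
        for (int xo = 0; xo < W_out; ++xo) {
          const size_t oc_col = (size_t)b * HWo + (size_t)yo * W_out + xo;
          float* dst0 = cp + oc_col * crows;
          for (int dy = 0; dy < k; ++dy) {
            const int yi = yo * stride - pad + dy;
            if (yi < 0 || yi >= H) continue;
            for (int dx = 0; dx < k; ++dx) {
              const int xi = xo * stride - pad + dx;
              if (xi < 0 || xi >= Wd) continue;
              const size_t ic_col = (size_t)b * HW + (size_t)yi * Wd + xi;
              std::memcpy(dst0 + (size_t)(dy * k + dx) * in_c,
                          xp + ic_col * in_c, in_c * sizeof(float));
            }
          }
        }
      }
    }
  }

  fmat forward(const fmat& X, int B_, int H, int Wd) {
    im2col(X, B_, H, Wd);
    return W.w * cols;
  }

  // gradient into gW; returns dX unless need_dx is false
  fmat backward(const fmat& dY, fmat& gW, bool need_dx = true) {
    gW = dY * cols.t();
    fmat dX;
    if (!need_dx) return dX;
    fmat dcols = W.w.t() * dY;
    dX.zeros(in_c, (size_t)B * H_in * W_in);
    const int HW = H_in * W_in, HWo = H_out * W_out;
    float* xp = dX.memptr();
    const float* cp = dcols.memptr();
    const size_t crows = dcols.n_rows;
    for (int b = 0; b < B; ++b) {
      for (int yo = 0; yo < H_out; ++yo) {
        for (int xo = 0; xo < W_out; ++xo) {
          const size_t oc_col = (size_t)b * HWo + (size_t)yo * W_out + xo;
          const float* src0 = cp + oc_col * crows;
          for (int dy = 0; dy < k; ++dy) {
            const int yi = yo * stride - pad + dy;
            if (yi < 0 || yi >= H_in) continue;
            for (int dx = 0; dx < k; ++dx) {
              const int xi = xo * stride - pad + dx;
              if (xi < 0 || xi >= W_in) continue;
              float* dst = xp + ((size_t)b * HW + (size_t)yi * W_in + xi) * in_c;
              const float* src = src0 + (size_t)(dy * k + dx) * in_c;
              for (int c = 0; c < in_c; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
    return dX;
  }
};

struct BN {
  Param gamma, beta;
  fvec run_mean, run_var;
  fmat xhat;
  fvec inv_std;

  void init(int c, float gamma0) {
    gamma.init(c, 1); beta.init(c, 1);
    gamma.w.fill(gamma0);
    run_mean.zeros(c); run_var.ones(c);
  }

  fmat forward(const fmat& X, bool train) {
    if (train) {
      fvec mu = mean(X, 1);
      fvec va = var(X, 1, 1);   // biased
      inv_std = 1.0f / sqrt(va + BN_EPS);
      xhat = X.each_col() - mu;
      xhat.each_col() %= inv_std;
      run_mean = BN_MOMENTUM * run_mean + (1.0f - BN_MOMENTUM) * mu;
      run_var = BN_MOMENTUM * run_var + (1.0f - BN_MOMENTUM) * va;
      fmat Y = xhat.each_col() % gamma.w.col(0);
      Y.each_col() += beta.w.col(0);
      return Y;
    }
    fvec is = 1.0f / sqrt(run_var + BN_EPS);
    fmat Y = X.each_col() - run_mean;
    Y.each_col() %= (is % gamma.w.col(0));
    Y.each_col() += beta.w.col(0);
    return Y;
  }

  fmat backward(const fmat& dY, fmat& gGamma, fmat& gBeta) {
    float N = (float)dY.n_cols;
    fvec dg = sum(dY % xhat, 1);
    fvec db = sum(dY, 1);
    gGamma = dg; gBeta = db;
    fmat dX = N * dY;
    dX.each_col() -= db;
    dX -= xhat.each_col() % dg;
    dX.each_col() %= (gamma.w.col(0) % inv_std) / N;
    return dX;
  }
};

struct Block {
  Conv c1, c2, proj;
  BN bn1, bn2, bnp;
  bool has_proj, pool_after;
  // caches
  fmat relu1_mask, out_mask, in_cache;
  uvec pool_idx;
  int H, W_sp, B;

  void init(int ic, int oc, bool pool, std::mt19937& rng) {
    has_proj = ic != oc;
    pool_after = pool;
    c1.init(ic, oc, 3, 1, 1, rng);
    c2.init(oc, oc, 3, 1, 1, rng);
    bn1.init(oc, 1.0f);
    bn2.init(oc, 0.0f);       // residual branch fades in
    if (has_proj) { proj.init(ic, oc, 1, 1, 0, rng); bnp.init(oc, 1.0f); }
  }
};

struct Net {
  int side, n_classes;
  std::vector<int> widths;    // conv1 width then per-block output widths
  Conv conv1;
  BN bn1;
  fmat relu1_mask;
  std::vector<Block> blocks;
  Param Wd, bd;
  fmat gap_in, gap_feat;
  int gap_H, gap_B;
  long adam_t = 0;
  std::mt19937 rng;

  Net(int side_, std::vector<int> widths_, int seed)
      : side(side_), n_classes(3), widths(widths_), rng(seed) {
    if (side < 32 || side % 8 != 0)
      Rcpp::stop("input side %d incompatible with the stride/pooling schedule "
                 "of conv1 (stride 2) and the two max-pooling stages: side "
                 "must be a multiple of 8 and at least 32", side);
    conv1.init(1, widths[0], 7, 2, 3, rng);
    bn1.init(widths[0], 1.0f);
    int prev = widths[0];
    for (size_t i = 1; i < widths.size(); ++i) {
      Block b;
      b.init(prev, widths[i], i <= 2, rng);  // pool after first two blocks
      blocks.push_back(b);
      prev = widths[i];
    }
    Wd.init(n_classes, prev);
    bd.init(n_classes, 1);
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / prev));
    for (uword i = 0; i < Wd.w.n_elem; ++i) Wd.w(i) = nd(rng);
  }

  static fmat maxpool(const fmat& X, int B, int H, int W, uvec& idx) {
    int Ho = H / 2, Wo = W / 2, C = X.n_rows;
    fmat Y(C, (size_t)B * Ho * Wo);
    idx.set_size((size_t)C * B * Ho * Wo);
    for (int b = 0; b < B; ++b) {
      for (int yo = 0; yo < Ho; ++yo) {
        for (int xo = 0; xo < Wo; ++xo) {
          size_t co = (size_t)b * Ho * Wo + (size_t)yo * Wo + xo;
          size_t p00 = (size_t)b * H * W + (size_t)(2 * yo) * W + 2 * xo;
          size_t cand[4] = {p00, p00 + 1, p00 + W, p00 + W + 1};
          for (int c = 0; c < C; ++c) {
            float best = X(c, cand[0]); size_t bi = cand[0];
            for (int q = 1; q < 4; ++q) {
              if (X(c, cand[q]) > best) { best = X(c, cand[q]); bi = cand[q]; }
            }
            Y(c, co) = best;
            idx(c + co * C) = bi;
          }
        }
      }
    }
    return Y;
  }

  static fmat maxpool_back(const fmat& dY, const uvec& idx, int C,
                           size_t in_cols) {
    fmat dX(C, in_cols, fill::zeros);
    for (size_t co = 0; co < dY.n_cols; ++co) {
      for (int c = 0; c < C; ++c) {
        dX(c, idx(c + co * C)) += dY(c, co);
      }
    }
    return dX;
  }

  static fmat relu_mask(const fmat& A) {
    return conv_to<fmat>::from(A > 0.0f);
  }

  // forward to class probabilities; caches populated when train = true
  fmat forward(const fmat& X0, int B, bool train) {
    int H = side;
    fmat A = conv1.forward(X0, B, H, H);
    H = conv1.H_out;
    A = bn1.forward(A, train);
    relu1_mask = relu_mask(A);
    A %= relu1_mask;
    for (auto& bl : blocks) {
      bl.B = B; bl.H = H; bl.W_sp = H;
      fmat Z = bl.c1.forward(A, B, H, H);
      Z = bl.bn1.forward(Z, train);
      bl.relu1_mask = relu_mask(Z);
      Z %= bl.relu1_mask;
      Z = bl.c2.forward(Z, B, H, H);
      Z = bl.bn2.forward(Z, train);
      fmat sc;
      if (bl.has_proj) {
        sc = bl.proj.forward(A, B, H, H);
        sc = bl.bnp.forward(sc, train);
      } else {
        sc = A;
      }
      Z += sc;
      bl.out_mask = relu_mask(Z);
      Z %= bl.out_mask;
      if (bl.pool_after) {
        Z = maxpool(Z, B, H, H, bl.pool_idx);
        H /= 2;
      }
      A = Z;
    }
    gap_H = H; gap_B = B; gap_in = A;
    int HW = H * H, C = A.n_rows;
    fmat F(C, B);
    for (int b = 0; b < B; ++b) {
      F.col(b) = mean(A.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1), 1);
    }
    fmat logits = Wd.w * F;
    logits.each_col() += bd.w.col(0);
    fmat P = logits;
    for (int b = 0; b < B; ++b) {
      fvec l = P.col(b);
      l -= l.max();
      fvec e = exp(l);
      P.col(b) = e / accu(e);
    }
    gap_feat = F;
    return P;
  }

  // one optimisation step; returns mean loss, adds correct-count to *correct
  float train_step(const fmat& X0, const ivec& y, float lr, int* correct) {
    int B = y.n_elem;
    fmat P = forward(X0, B, true);
    float loss = 0.0f;
    fmat dlog = P;
    for (int b = 0; b < B; ++b) {
      loss -= std::log(std::max(P(y(b), b), 1e-12f));
      dlog(y(b), b) -= 1.0f;
      if ((int)P.col(b).index_max() == y(b)) (*correct)++;
    }
    loss /= B;
    dlog /= (float)B;

    adam_t++;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

    fmat gWd = dlog * gap_feat.t();
    fmat gbd = sum(dlog, 1);
    fmat dF = Wd.w.t() * dlog;
    Wd.adam(lr, b1, b2, eps, adam_t, gWd);
    bd.adam(lr, b1, b2, eps, adam_t, gbd);

    int H = gap_H, HW = H * H;
    fmat dA(gap_in.n_rows, (size_t)B * HW);
    for (int b = 0; b < B; ++b) {
      dA.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1) =
        repmat(dF.col(b) / (float)HW, 1, HW);
    }

    for (int i = (int)blocks.size() - 1; i >= 0; --i) {
      Block& bl = blocks[i];
      if (bl.pool_after) {
        dA = maxpool_back(dA, bl.pool_idx, dA.n_rows,
                          (size_t)bl.B * bl.H * bl.W_sp);
      }
      dA %= bl.out_mask;
      fmat d_shortcut = dA;
      fmat g1, g2;
      fmat dZ = bl.bn2.backward(dA, g1, g2);
      bl.bn2.gamma.adam(lr, b1, b2, eps, adam_t, g1);
      bl.bn2.beta.adam(lr, b1, b2, eps, adam_t, g2);
      fmat gW;
      dZ = bl.c2.backward(dZ, gW);
      bl.c2.W.adam(lr, b1, b2, eps, adam_t, gW);
      dZ %= bl.relu1_mask;
      dZ = bl.bn1.backward(dZ, g1, g2);
      bl.bn1.gamma.adam(lr, b1, b2, eps, adam_t, g1);
      bl.bn1.beta.adam(lr, b1, b2, eps, adam_t, g2);
      fmat dIn = bl.c1.backward(dZ, gW);
      bl.c1.W.adam(lr, b1, b2, eps, adam_t, gW);
      if (bl.has_proj) {
        fmat dS = bl.bnp.backward(d_shortcut, g1, g2);
        bl.bnp.gamma.adam(lr, b1, b2, eps, adam_t, g1);
        bl.bnp.beta.adam(lr, b1, b2, eps, adam_t, g2);
        fmat gP;
        dIn += bl.proj.backward(dS, gP);
        bl.proj.W.adam(lr, b1, b2, eps, adam_t, gP);
      } else {
        dIn += d_shortcut;
      }
      dA = dIn;
    }
    dA %= relu1_mask;
    fmat g1, g2;
    dA = bn1.backward(dA, g1, g2);
    bn1.gamma.adam(lr, b1, b2, eps, adam_t, g1);
    bn1.beta.adam(lr, b1, b2, eps, adam_t, g2);
    fmat gW;
    conv1.backward(dA, gW, false);   // input gradient not needed
    conv1.W.adam(lr, b1, b2, eps, adam_t, gW);
    return loss;
  }

  long param_count() const {
    long n = conv1.W.w.n_elem + 2L * bn1.gamma.w.n_elem;
    for (const auto& bl : blocks) {
      n += bl.c1.W.w.n_elem + bl.c2.W.w.n_elem;
      n += 2L * bl.bn1.gamma.w.n_elem + 2L * bl.bn2.gamma.w.n_elem;
      if (bl.has_proj) n += bl.proj.W.w.n_elem + 2L * bl.bnp.gamma.w.n_elem;
    }
    n += Wd.w.n_elem + bd.w.n_elem;
    return n;
  }
};

static fmat images_to_mat(const Rcpp::NumericVector& imgs, int side,
                          const std::vector<int>& pick) {
  // imgs: array (side, side, N), column-major; output (1, B*side*side)
  // with pixel index y*side + x (row y, col x), i.e. row-major spatial.
  Rcpp::IntegerVector dims = imgs.attr("dim");
  if (dims.size() != 3 || dims[0] != side || dims[1] != side)
    Rcpp::stop("images must be a side x side x n array matching the model side");
  int HW = side * side;
  fmat X(1, (size_t)pick.size() * HW);
  for (size_t b = 0; b < pick.size(); ++b) {
    size_t base = (size_t)pick[b] * HW;
    for (int y = 0; y < side; ++y) {
      for (int x = 0; x < side; ++x) {
        X(0, b * HW + (size_t)y * side + x) = (float)imgs[base + (size_t)x * side + y];
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
SEXP rpnet_new(int side, Rcpp::IntegerVector widths, int seed) {
  std::vector<int> w(widths.begin(), widths.end());
  Rcpp::XPtr<Net> p(new Net(side, w, seed), true);
  return p;
}

// [[Rcpp::export]]
double rpnet_param_count(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  return (double)p->param_count();
}

// [[Rcpp::export]]
Rcpp::NumericMatrix rpnet_predict_cpp(SEXP ptr, Rcpp::NumericVector imgs) {
  Rcpp::XPtr<Net> p(ptr);
  Rcpp::IntegerVector dims = imgs.attr("dim");
  int n = dims[2];
  Rcpp::NumericMatrix out(n, 3);
  int chunk = 16;   // bound memory during inference
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(n, start + chunk);
    std::vector<int> pick;
    for (int i = start; i < end; ++i) pick.push_back(i);
    fmat X = images_to_mat(imgs, p->side, pick);
    fmat P = p->forward(X, (int)pick.size(), false);
    for (size_t b = 0; b < pick.size(); ++b) {
      for (int k = 0; k < 3; ++k) out(pick[b], k) = P(k, b);
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List rpnet_train_cpp(SEXP ptr, Rcpp::NumericVector imgs,
                           Rcpp::IntegerVector labels,
                           Rcpp::IntegerVector train_idx,
                           Rcpp::IntegerVector val_idx,
                           int epochs, int batch, double lr, int seed) {
  Rcpp::XPtr<Net> p(ptr);
  std::mt19937 rng(seed);
  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(val_idx.begin(), val_idx.end());
  Rcpp::NumericVector tr_loss(epochs), tr_acc(epochs), va_acc(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    // step decay: drop to lr/10 for the last third of training
    float lr_ep = (float)lr * (ep >= (2 * epochs) / 3 ? 0.1f : 1.0f);
    std::shuffle(tr.begin(), tr.end(), rng);
    double ep_loss = 0; int n_batches = 0, correct = 0, seen = 0;
    for (size_t start = 0; start < tr.size(); start += batch) {
      size_t end = std::min(tr.size(), start + batch);
      std::vector<int> pick(tr.begin() + start, tr.begin() + end);
      if (pick.size() < 2) continue;   // BN needs > 1 sample
      fmat X = images_to_mat(imgs, p->side, pick);
      ivec y(pick.size());
      for (size_t b = 0; b < pick.size(); ++b) y(b) = labels[pick[b]];
      ep_loss += p->train_step(X, y, lr_ep, &correct);
      seen += pick.size();
      n_batches++;
    }
    tr_loss[ep] = ep_loss / std::max(1, n_batches);
    tr_acc[ep] = seen > 0 ? (double)correct / seen : NA_REAL;
    if (va.empty()) {
      va_acc[ep] = NA_REAL;
    } else {
      int vcorrect = 0;
      for (size_t start = 0; start < va.size(); start += 16) {
        size_t end = std::min(va.size(), start + 16);
        std::vector<int> pick(va.begin() + start, va.begin() + end);
        fmat X = images_to_mat(imgs, p->side, pick);
        fmat P = p->forward(X, (int)pick.size(), false);
        for (size_t b = 0; b < pick.size(); ++b) {
          if ((int)P.col(b).index_max() == labels[pick[b]]) vcorrect++;
        }
      }
      va_acc[ep] = (double)vcorrect / va.size();
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("train_loss") = tr_loss,
                            Rcpp::Named("train_acc") = tr_acc,
                            Rcpp::Named("val_acc") = va_acc);
}

// Weight (de)serialization: fixed traversal order.
static void collect(Net* p, std::vector<fmat*>& ws, std::vector<fvec*>& rs) {
  ws.push_back(&p->conv1.W.w);
  ws.push_back(&p->bn1.gamma.w); ws.push_back(&p->bn1.beta.w);
  rs.push_back(&p->bn1.run_mean); rs.push_back(&p->bn1.run_var);
  for (auto& bl : p->blocks) {
    ws.push_back(&bl.c1.W.w);
    ws.push_back(&bl.bn1.gamma.w); ws.push_back(&bl.bn1.beta.w);
    rs.push_back(&bl.bn1.run_mean); rs.push_back(&bl.bn1.run_var);
    ws.push_back(&bl.c2.W.w);
    ws.push_back(&bl.bn2.gamma.w); ws.push_back(&bl.bn2.beta.w);
    rs.push_back(&bl.bn2.run_mean); rs.push_back(&bl.bn2.run_var);
    if (bl.has_proj) {
      ws.push_back(&bl.proj.W.w);
      ws.push_back(&bl.bnp.gamma.w); ws.push_back(&bl.bnp.beta.w);
      rs.push_back(&bl.bnp.run_mean); rs.push_back(&bl.bnp.run_var);
    }
  }
  ws.push_back(&p->Wd.w); ws.push_back(&p->bd.w);
}

// [[Rcpp::export]]
Rcpp::List rpnet_get_weights(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  std::vector<fmat*> ws; std::vector<fvec*> rs;
  collect(p, ws, rs);
  Rcpp::List W(ws.size()), R(rs.size());
  for (size_t i = 0; i < ws.size(); ++i) {
    Rcpp::NumericMatrix m(ws[i]->n_rows, ws[i]->n_cols);
    for (uword j = 0; j < ws[i]->n_elem; ++j) m[j] = (*ws[i])(j);
    W[i] = m;
  }
  for (size_t i = 0; i < rs.size(); ++i) {
    Rcpp::NumericVector v(rs[i]->n_elem);
    for (uword j = 0; j < rs[i]->n_elem; ++j) v[j] = (*rs[i])(j);
    R[i] = v;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = W,
                            Rcpp::Named("running") = R);
}

// [[Rcpp::export]]
void rpnet_set_weights(SEXP ptr, Rcpp::List state) {
  Rcpp::XPtr<Net> p(ptr);
  std::vector<fmat*> ws; std::vector<fvec*> rs;
  collect(p, ws, rs);
  Rcpp::List W = state["weights"], R = state["running"];
  if ((size_t)W.size() != ws.size() || (size_t)R.size() != rs.size())
    Rcpp::stop("weight list does not match the model architecture");
  for (size_t i = 0; i < ws.size(); ++i) {
    Rcpp::NumericMatrix m = W[i];
    if ((uword)m.nrow() != ws[i]->n_rows || (uword)m.ncol() != ws[i]->n_cols)
      Rcpp::stop("weight %d has wrong shape", (int)i + 1);
    for (uword j = 0; j < ws[i]->n_elem; ++j) (*ws[i])(j) = (float)m[j];
  }
  for (size_t i = 0; i < rs.size(); ++i) {
    Rcpp::NumericVector v = R[i];
    for (uword j = 0; j < rs[i]->n_elem; ++j) (*rs[i])(j) = (float)v[j];
  }
}

// [[Rcpp::export]]
void rpnet_scale_residual(SEXP ptr, double factor) {
  // Scales every residual-branch output BN (gamma and beta) by `factor`;
  // with factor = 0 the network computes the shortcut-only map.
  Rcpp::XPtr<Net> p(ptr);
  for (auto& bl : p->blocks) {
    bl.bn2.gamma.w *= (float)factor;
    bl.bn2.beta.w *= (float)factor;
  }
}
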