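// Full pre-activation residual network (BN -> ReLU -> conv, twice per unit;
// identity skip except 1x1 projections at stage boundaries), trained with
// softmax cross-entropy and Adam. Single precision; convolutions via
// im2col + GEMM. The parameter list layout is shared with the R builder:
//   stem_w,
//   per unit: bn1_g, bn1_b, conv1_w, bn2_g, bn2_b, conv2_w, [proj_w],
//   bnf_g, bnf_b, fc_w, fc_b
// BN running-state layout: per unit bn1_mean, bn1_var, bn2_mean, bn2_var;
// then bnf_mean, bnf_var.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-5f;

struct Arch {
  int S, n_per_stage, n_classes, H;
  std::vector<int> widths;
};

static Arch parse_arch(List arch) {
  Arch a;
  IntegerVector w = arch["widths"];
  a.widths.assign(w.begin(), w.end());
  a.S = a.widths.size();
  a.n_per_stage = as<int>(arch["units_per_stage"]);
  a.n_classes = as<int>(arch["n_classes"]);
  a.H = as<int>(arch["input_size"]);
  return a;
}

static fmat asF(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

static NumericMatrix toR(const fmat &m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (size_t j = 0; j < m.n_cols; ++j)
    for (size_t i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}

static std::vector<fmat> list_to_f(List l) {
  std::vector<fmat> v(l.size());
  for (int i = 0; i < l.size(); ++i) v[i] = asF(l[i]);
  return v;
}

static List f_to_list(const std::vector<fmat> &v, CharacterVector names) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = toR(v[i]);
  out.attr("names") = names;
  return out;
}

// im2col for kxk conv, padding p, stride s, on activation A (C, B*H*W)
// with spatial column index w*H + h per image. Rows are kernel-major
// ((kx*k+ky)*C + c) so each kernel offset contributes one contiguous
// C-float block per output position.
static fmat im2col(const fmat &A, int B, int H, int W, int k, int p, int s) {
  int C = A.n_rows;
  int Ho = (H + 2 * p - k) / s + 1, Wo = (W + 2 * p - k) / s + 1;
  fmat cols(C * k * k, (size_t)B * Ho * Wo, arma::fill::none);
  for (int b = 0; b < B; ++b) {
    size_t in_off = (size_t)b * H * W, out_off = (size_t)b * Ho * Wo;
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky) {
        size_t row0 = (size_t)(kx * k + ky) * C;
        // valid yo range for this ky; outside it the padding contributes 0
        int yo_lo = std::max(0, (p - ky + s - 1) / s);
        int yo_hi = std::min(Ho - 1, (H - 1 + p - ky) / s);
        for (int xo = 0; xo < Wo; ++xo) {
          int x = xo * s - p + kx;
          size_t co = out_off + (size_t)xo * Ho;
          if (x < 0 || x >= W) {
            for (int yo = 0; yo < Ho; ++yo)
              std::memset(cols.colptr(co + yo) + row0, 0, sizeof(float) * C);
            continue;
          }
          for (int yo = 0; yo < yo_lo; ++yo)
            std::memset(cols.colptr(co + yo) + row0, 0, sizeof(float) * C);
          for (int yo = yo_lo; yo <= yo_hi; ++yo)
            std::memcpy(cols.colptr(co + yo) + row0,
                        A.colptr(in_off + (size_t)x * H + yo * s - p + ky),
                        sizeof(float) * C);
          for (int yo = yo_hi + 1; yo < Ho; ++yo)
            std::memset(cols.colptr(co + yo) + row0, 0, sizeof(float) * C);
        }
      }
  }
  return cols;
}

// scatter-add transpose of im2col: dcols (C*k*k, B*Ho*Wo) -> dA (C, B*H*W)
static fmat col2im(const fmat &dcols, int C, int B, int H, int W, int k, int p,
                   int s) {
  int Ho = (H + 2 * p - k) / s + 1, Wo = (W + 2 * p - k) / s + 1;
  fmat dA(C, (size_t)B * H * W, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    size_t in_off = (size_t)b * H * W, out_off = (size_t)b * Ho * Wo;
    for (int kx = 0; kx < k; ++kx)
      for (int ky = 0; ky < k; ++ky) {
        size_t row0 = (size_t)(kx * k + ky) * C;
        for (int xo = 0; xo < Wo; ++xo) {
          int x = xo * s - p + kx;
          if (x < 0 || x >= W) continue;
          int yo_lo = std::max(0, (p - ky + s - 1) / s);
          int yo_hi = std::min(Ho - 1, (H - 1 + p - ky) / s);
          for (int yo = yo_lo; yo <= yo_hi; ++yo) {
            int y = yo * s - p + ky;
            const float *src =
                dcols.colptr(out_off + (size_t)xo * Ho + yo) + row0;
            float *dst = dA.colptr(in_off + (size_t)x * H + y);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
  }
  return dA;
}

// zero the entries of d wherever the stored post-ReLU activation is zero
static void relu_backward(fmat &d, const fmat &act) {
  const float *a = act.memptr();
  float *p = d.memptr();
  size_t n = d.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (a[i] <= 0.0f) p[i] = 0.0f;
}

struct BNCache {
  fmat xhat;
  fvec var, gamma;
};

// Train-mode batch norm over columns, rows = channels; updates running stats.
static fmat bn_forward_train(const fmat &X, const fmat &g, const fmat &b,
                             fmat &run_mean, fmat &run_var, float momentum,
                             BNCache &cache) {
  fvec mu = arma::mean(X, 1);
  fvec va = arma::var(X, 1, 1);  // biased (1/m)
  cache.xhat = X.each_col() - mu;
  fvec inv = 1.0f / arma::sqrt(va + BN_EPS);
  cache.xhat.each_col() %= inv;
  cache.var = va;
  cache.gamma = g.col(0);
  run_mean.col(0) = momentum * run_mean.col(0) + (1.0f - momentum) * mu;
  run_var.col(0) = momentum * run_var.col(0) + (1.0f - momentum) * va;
  fmat out = cache.xhat.each_col() % g.col(0);
  out.each_col() += b.col(0);
  return out;
}

static fmat bn_forward_infer(const fmat &X, const fmat &g, const fmat &b,
                             const fmat &run_mean, const fmat &run_var) {
  fvec inv = 1.0f / arma::sqrt(run_var.col(0) + BN_EPS);
  fmat out = X.each_col() - run_mean.col(0);
  out.each_col() %= (inv % g.col(0));
  out.each_col() += b.col(0);
  return out;
}

static fmat bn_backward(const fmat &dY, const BNCache &cache, fmat &dg,
                        fmat &db) {
  float m = (float)dY.n_cols;
  dg = arma::sum(dY % cache.xhat, 1);
  db = arma::sum(dY, 1);
  fvec inv = 1.0f / arma::sqrt(cache.var + BN_EPS);
  fmat dX = dY * m;
  dX.each_col() -= db.col(0);
  dX -= cache.xhat.each_col() % dg.col(0);
  dX.each_col() %= (cache.gamma % inv) / m;
  return dX;
}

struct UnitDesc {
  int c_in, c_out, h_in, h_out, stride;
  bool proj;
  // parameter indices in the flat list
  int i_bn1g, i_bn1b, i_conv1, i_bn2g, i_bn2b, i_conv2, i_proj;
  int s_bn1, s_bn2;  // bn-state indices (mean at s, var at s+1)
};

struct Net {
  Arch a;
  std::vector<UnitDesc> units;
  int i_stem, i_bnfg, i_bnfb, i_fcw, i_fcb, s_bnf;
  int n_params, n_bn, h_final, c_final;
};

static Net build_net(const Arch &a) {
  Net net;
  net.a = a;
  net.i_stem = 0;
  int pi = 1, si = 0;
  int c_in = a.widths[0], h = a.H;
  for (int s = 0; s < a.S; ++s) {
    int c_out = a.widths[s];
    for (int u = 0; u < a.n_per_stage; ++u) {
      UnitDesc d;
      d.stride = (s > 0 && u == 0) ? 2 : 1;
      d.c_in = c_in;
      d.c_out = c_out;
      d.h_in = h;
      d.h_out = (h + 2 - 3) / d.stride + 1;
      d.proj = (d.stride != 1 || c_in != c_out);
      d.i_bn1g = pi++; d.i_bn1b = pi++; d.i_conv1 = pi++;
      d.i_bn2g = pi++; d.i_bn2b = pi++; d.i_conv2 = pi++;
      d.i_proj = d.proj ? pi++ : -1;
      d.s_bn1 = si; si += 2;
      d.s_bn2 = si; si += 2;
      net.units.push_back(d);
      c_in = c_out;
      h = d.h_out;
    }
  }
  net.i_bnfg = pi++; net.i_bnfb = pi++;
  net.i_fcw = pi++; net.i_fcb = pi++;
  net.s_bnf = si; si += 2;
  net.n_params = pi;
  net.n_bn = si;
  net.h_final = h;
  net.c_final = c_in;
  return net;
}

static fmat gather_batch(const NumericVector &X, const std::vector<int> &idx,
                         int H, int C) {
  int B = idx.size();
  size_t HW = (size_t)H * H;
  fmat A(C, (size_t)B * HW);
  for (int b = 0; b < B; ++b) {
    size_t base = (size_t)idx[b] * HW * C;
    for (int c = 0; c < C; ++c)
      for (size_t p = 0; p < HW; ++p)
        A(c, (size_t)b * HW + p) =
            (float)(X[base + (size_t)c * HW + p] / 255.0 - 0.5);
  }
  return A;
}

struct UnitCache {
  fmat x_in, a1, t2;
  fmat c1, c2, cp;  // im2col matrices cached for the backward pass
  BNCache bn1, bn2;
};

// Forward pass; train mode uses batch statistics and fills caches.
static fmat net_forward(const Net &net, std::vector<fmat> &P,
                        std::vector<fmat> &BNS, const fmat &input, int B,
                        bool train, float momentum,
                        std::vector<UnitCache> *caches, fmat *stem_cols,
                        fmat *head_cache_xhat, BNCache *bnf_cache,
                        fmat *pooled_out,
                        List *debug = nullptr) {
  const Arch &a = net.a;
  fmat cols = im2col(input, B, a.H, a.H, 3, 1, 1);
  if (stem_cols) *stem_cols = cols;
  fmat x = P[net.i_stem] * cols;
  List dbg_in, dbg_F;
  for (size_t ui = 0; ui < net.units.size(); ++ui) {
    const UnitDesc &d = net.units[ui];
    UnitCache uc;
    if (caches) uc.x_in = x;
    if (debug) dbg_in.push_back(toR(x));
    fmat t;
    if (train)
      t = bn_forward_train(x, P[d.i_bn1g], P[d.i_bn1b], BNS[d.s_bn1],
                           BNS[d.s_bn1 + 1], momentum, uc.bn1);
    else
      t = bn_forward_infer(x, P[d.i_bn1g], P[d.i_bn1b], BNS[d.s_bn1],
                           BNS[d.s_bn1 + 1]);
    t.transform([](float v) { return v > 0 ? v : 0.0f; });
    if (caches) uc.a1 = t;
    fmat c1 = im2col(t, B, d.h_in, d.h_in, 3, 1, d.stride);
    fmat z1 = P[d.i_conv1] * c1;
    if (caches) uc.c1 = std::move(c1);
    fmat t2;
    if (train)
      t2 = bn_forward_train(z1, P[d.i_bn2g], P[d.i_bn2b], BNS[d.s_bn2],
                            BNS[d.s_bn2 + 1], momentum, uc.bn2);
    else
      t2 = bn_forward_infer(z1, P[d.i_bn2g], P[d.i_bn2b], BNS[d.s_bn2],
                            BNS[d.s_bn2 + 1]);
    t2.transform([](float v) { return v > 0 ? v : 0.0f; });
    if (caches) uc.t2 = t2;
    fmat c2 = im2col(t2, B, d.h_out, d.h_out, 3, 1, 1);
    fmat F = P[d.i_conv2] * c2;
    if (caches) uc.c2 = std::move(c2);
    fmat skip;
    if (d.proj) {
      fmat cp = im2col(t, B, d.h_in, d.h_in, 1, 0, d.stride);
      skip = P[d.i_proj] * cp;
      if (caches) uc.cp = std::move(cp);
    } else {
      skip = x;
    }
    if (debug) dbg_F.push_back(toR(F));
    x = F + skip;
    if (caches) (*caches)[ui] = std::move(uc);
  }
  fmat h;
  if (train)
    h = bn_forward_train(x, P[net.i_bnfg], P[net.i_bnfb], BNS[net.s_bnf],
                         BNS[net.s_bnf + 1], momentum, *bnf_cache);
  else {
    BNCache dummy;
    h = bn_forward_infer(x, P[net.i_bnfg], P[net.i_bnfb], BNS[net.s_bnf],
                         BNS[net.s_bnf + 1]);
  }
  if (head_cache_xhat) *head_cache_xhat = x;  // pre-BN final activation
  h.transform([](float v) { return v > 0 ? v : 0.0f; });
  // global average pool: (C, B)
  size_t HW = (size_t)net.h_final * net.h_final;
  fmat pooled(net.c_final, B);
  for (int b = 0; b < B; ++b)
    pooled.col(b) =
        arma::mean(h.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1), 1);
  if (pooled_out) *pooled_out = pooled;
  fmat logits = P[net.i_fcw] * pooled;
  logits.each_col() += P[net.i_fcb].col(0);
  if (debug) {
    (*debug)["unit_inputs"] = dbg_in;
    (*debug)["branch_outputs"] = dbg_F;
    (*debug)["final_preact"] = toR(x);
  }
  return logits;
}

static fmat softmax_cols(const fmat &logits) {
  fmat p = logits;
  for (size_t j = 0; j < p.n_cols; ++j) {
    fvec c = p.col(j);
    c -= c.max();
    c = arma::exp(c);
    p.col(j) = c / arma::accu(c);
  }
  return p;
}

// One optimisation epoch with Adam. Returns updated state plus mean
// training loss/accuracy.
// [[Rcpp::export]]
List resnet_train_epoch_cpp(List params, List adam_m, List adam_v, int t_step,
                            List bn_state, NumericVector X, IntegerVector y,
                            List arch, double lr, int batch_size,
                            IntegerVector order, double bn_momentum,
                            double beta1, double beta2, double adam_eps) {
  Arch a = parse_arch(arch);
  Net net = build_net(a);
  std::vector<fmat> P = list_to_f(params), M = list_to_f(adam_m),
                    V = list_to_f(adam_v), BNS = list_to_f(bn_state);
  int N = order.size();
  double tot_loss = 0.0;
  int tot_correct = 0, tot_seen = 0;
  float mom = (float)bn_momentum;

  for (int start = 0; start < N; start += batch_size) {
    int B = std::min(batch_size, N - start);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = order[start + b];
    fmat input = gather_batch(X, idx, a.H, 3);

    std::vector<UnitCache> caches(net.units.size());
    fmat stem_cols, final_preact, pooled;
    BNCache bnf_cache;
    fmat logits = net_forward(net, P, BNS, input, B, true, mom, &caches,
                              &stem_cols, &final_preact, &bnf_cache, &pooled);
    fmat probs = softmax_cols(logits);
    for (int b = 0; b < B; ++b) {
      int yy = y[idx[b]];
      tot_loss += -std::log(std::max(probs(yy, b), 1e-12f));
      if ((int)probs.col(b).index_max() == yy) ++tot_correct;
    }
    tot_seen += B;

    // ---- backward ----
    std::vector<fmat> G(net.n_params);
    fmat dlogits = probs;
    for (int b = 0; b < B; ++b) dlogits(y[idx[b]], b) -= 1.0f;
    dlogits /= (float)B;
    G[net.i_fcw] = dlogits * pooled.t();
    G[net.i_fcb] = arma::sum(dlogits, 1);
    fmat dpooled = P[net.i_fcw].t() * dlogits;  // (C, B)
    size_t HW = (size_t)net.h_final * net.h_final;
    fmat dh(net.c_final, (size_t)B * HW);
    for (int b = 0; b < B; ++b)
      dh.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1) =
          arma::repmat(dpooled.col(b) / (float)HW, 1, HW);
    // head relu mask: recompute bnf output sign from cache
    fmat bnf_out = bnf_cache.xhat.each_col() % P[net.i_bnfg].col(0);
    bnf_out.each_col() += P[net.i_bnfb].col(0);
    relu_backward(dh, bnf_out);
    fmat dgf, dbf;
    fmat dx = bn_backward(dh, bnf_cache, dgf, dbf);
    G[net.i_bnfg] = dgf;
    G[net.i_bnfb] = dbf;

    for (int ui = (int)net.units.size() - 1; ui >= 0; --ui) {
      const UnitDesc &d = net.units[ui];
      UnitCache &uc = caches[ui];
      // x = F + skip; dF = dx, dskip = dx
      G[d.i_conv2] = dx * uc.c2.t();
      fmat dt2 = col2im(P[d.i_conv2].t() * dx, d.c_out, B, d.h_out, d.h_out,
                        3, 1, 1);
      relu_backward(dt2, uc.t2);
      fmat dg2, db2;
      fmat dz1 = bn_backward(dt2, uc.bn2, dg2, db2);
      G[d.i_bn2g] = dg2;
      G[d.i_bn2b] = db2;
      G[d.i_conv1] = dz1 * uc.c1.t();
      fmat dt = col2im(P[d.i_conv1].t() * dz1, d.c_in, B, d.h_in, d.h_in, 3,
                       1, d.stride);
      if (d.proj) {
        G[d.i_proj] = dx * uc.cp.t();
        dt += col2im(P[d.i_proj].t() * dx, d.c_in, B, d.h_in, d.h_in, 1, 0,
                     d.stride);
      }
      relu_backward(dt, uc.a1);
      fmat dg1, db1;
      fmat dxin = bn_backward(dt, uc.bn1, dg1, db1);
      G[d.i_bn1g] = dg1;
      G[d.i_bn1b] = db1;
      if (!d.proj) dxin += dx;  // identity skip
      dx = dxin;
    }
    G[net.i_stem] = dx * stem_cols.t();

    // ---- Adam ----
    ++t_step;
    float b1t = 1.0f - std::pow((float)beta1, (float)t_step);
    float b2t = 1.0f - std::pow((float)beta2, (float)t_step);
    for (int i = 0; i < net.n_params; ++i) {
      M[i] = (float)beta1 * M[i] + (1.0f - (float)beta1) * G[i];
      V[i] = (float)beta2 * V[i] + (1.0f - (float)beta2) * (G[i] % G[i]);
      fmat mhat = M[i] / b1t, vhat = V[i] / b2t;
      P[i] -= (float)lr * mhat / (arma::sqrt(vhat) + (float)adam_eps);
    }
  }

  CharacterVector pn = params.attr("names");
  CharacterVector bn = bn_state.attr("names");
  return List::create(_["params"] = f_to_list(P, pn),
                      _["adam_m"] = f_to_list(M, pn),
                      _["adam_v"] = f_to_list(V, pn),
                      _["t_step"] = t_step,
                      _["bn_state"] = f_to_list(BNS, bn),
                      _["train_loss"] = tot_loss / tot_seen,
                      _["train_acc"] = (double)tot_correct / tot_seen);
}

// Inference-mode class probabilities, batched.
// [[Rcpp::export]]
NumericMatrix resnet_predict_cpp(List params, List bn_state, NumericVector X,
                                 List arch, int batch_size) {
  Arch a = parse_arch(arch);
  Net net = build_net(a);
  std::vector<fmat> P = list_to_f(params), BNS = list_to_f(bn_state);
  IntegerVector dims = X.attr("dim");
  int N = dims[3];
  NumericMatrix out(N, a.n_classes);
  for (int start = 0; start < N; start += batch_size) {
    int B = std::min(batch_size, N - start);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = start + b;
    fmat input = gather_batch(X, idx, a.H, 3);
    BNCache dummy;
    fmat logits = net_forward(net, P, BNS, input, B, false, 0.9f, nullptr,
                              nullptr, nullptr, &dummy, nullptr);
    fmat probs = softmax_cols(logits);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < a.n_classes; ++k) out(start + b, k) = probs(k, b);
  }
  return out;
}

// Inference forward that records every residual unit's input activation and
// branch output, for checking the additive skip-path identity
// x_L = x_l + sum_i F_i numerically.
// [[Rcpp::export]]
List resnet_forward_debug_cpp(List params, List bn_state, NumericVector X,
                              List arch) {
  Arch a = parse_arch(arch);
  Net net = build_net(a);
  std::vector<fmat> P = list_to_f(params), BNS = list_to_f(bn_state);
  IntegerVector dims = X.attr("dim");
  int N = dims[3];
  std::vector<int> idx(N);
  for (int b = 0; b < N; ++b) idx[b] = b;
  fmat input = gather_batch(X, idx, a.H, 3);
  List debug;
  BNCache dummy;
  fmat logits = net_forward(net, P, BNS, input, N, false, 0.9f, nullptr,
                            nullptr, nullptr, &dummy, nullptr, &debug);
  debug["logits"] = toR(logits);
  return debug;
}

// Train-mode loss and parameter gradients on one batch (no update); used by
// finite-difference gradient checks.
// [[Rcpp::export]]
List resnet_loss_grad_cpp(List params, List bn_state, NumericVector X,
                          IntegerVector y, List arch) {
  Arch a = parse_arch(arch);
  Net net = build_net(a);
  std::vector<fmat> P = list_to_f(params), BNS = list_to_f(bn_state);
  IntegerVector dims = X.attr("dim");
  int B = dims[3];
  std::vector<int> idx(B);
  for (int b = 0; b < B; ++b) idx[b] = b;
  fmat input = gather_batch(X, idx, a.H, 3);
  std::vector<UnitCache> caches(net.units.size());
  fmat stem_cols, final_preact, pooled;
  BNCache bnf_cache;
  fmat logits = net_forward(net, P, BNS, input, B, true, 1.0f, &caches,
                            &stem_cols, &final_preact, &bnf_cache, &pooled);
  fmat probs = softmax_cols(logits);
  double loss = 0.0;
  for (int b = 0; b < B; ++b)
    loss += -std::log(std::max(probs(y[b], b), 1e-12f));
  loss /= B;

  std::vector<fmat> G(net.n_params);
  fmat dlogits = probs;
  for (int b = 0; b < B; ++b) dlogits(y[b], b) -= 1.0f;
  dlogits /= (float)B;
  G[net.i_fcw] = dlogits * pooled.t();
  G[net.i_fcb] = arma::sum(dlogits, 1);
  fmat dpooled = P[net.i_fcw].t() * dlogits;
  size_t HW = (size_t)net.h_final * net.h_final;
  fmat dh(net.c_final, (size_t)B * HW);
  for (int b = 0; b < B; ++b)
    dh.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1) =
        arma::repmat(dpooled.col(b) / (float)HW, 1, HW);
  fmat bnf_out = bnf_cache.xhat.each_col() % P[net.i_bnfg].col(0);
  bnf_out.each_col() += P[net.i_bnfb].col(0);
  relu_backward(dh, bnf_out);
  fmat dgf, dbf;
  fmat dx = bn_backward(dh, bnf_cache, dgf, dbf);
  G[net.i_bnfg] = dgf;
  G[net.i_bnfb] = dbf;
  for (int ui = (int)net.units.size() - 1; ui >= 0; --ui) {
    const UnitDesc &d = net.units[ui];
    UnitCache &uc = caches[ui];
    G[d.i_conv2] = dx * uc.c2.t();
    fmat dt2 =
        col2im(P[d.i_conv2].t() * dx, d.c_out, B, d.h_out, d.h_out, 3, 1, 1);
    relu_backward(dt2, uc.t2);
    fmat dg2, db2;
    fmat dz1 = bn_backward(dt2, uc.bn2, dg2, db2);
    G[d.i_bn2g] = dg2;
    G[d.i_bn2b] = db2;
    G[d.i_conv1] = dz1 * uc.c1.t();
    fmat dt =
        col2im(P[d.i_conv1].t() * dz1, d.c_in, B, d.h_in, d.h_in, 3, 1, d.stride);
    if (d.proj) {
      G[d.i_proj] = dx * uc.cp.t();
      dt += col2im(P[d.i_proj].t() * dx, d.c_in, B, d.h_in, d.h_in, 1, 0,
                   d.stride);
    }
    relu_backward(dt, uc.a1);
    fmat dg1, db1;
    fmat dxin = bn_backward(dt, uc.bn1, dg1, db1);
    G[d.i_bn1g] = dg1;
    G[d.i_bn1b] = db1;
    if (!d.proj) dxin += dx;
    dx = dxin;
  }
  G[net.i_stem] = dx * stem_cols.t();
  CharacterVector pn = params.attr("names");
  return List::create(_["loss"] = loss, _["grads"] = f_to_list(G, pn));
}
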