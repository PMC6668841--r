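// Convolutional / recurrent networks over visual-timeline images.
//
// Three architectures share this file:
//   standard_cnn : conv3x3 -> pool2x2 -> conv3x3 -> pool2x2 -> dense -> logit
//   rnn          : GRU over the H hourly column vectors -> logit
//   cnn_rl       : conv3x3 -> pool2x1 -> conv3x3 -> pool2x1 (variable axis
//                  only, time axis preserved) -> per-time-step features ->
//                  GRU -> logit
// Forward, backward (weighted binary cross-entropy), and the Grad-CAM hook
// (activations of the final conv layer and d logit / d activations) are
// implemented by hand; all heavy lifting is BLAS matrix products.
//
// Shapes: images are V x H x N cubes; conv weights are (F x 9*Cin) with
// 3x3 kernels and same-padding; GRU matrices are (Hd x D) / (Hd x Hd).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// ---- conv primitives -------------------------------------------------------

// im2col for 3x3 same-padding, transposed layout: x is V x H x C,
// result is (V*H) x (9C) so every patch column is written contiguously.
static mat im2col3(const cube& x) {
  const uword V = x.n_rows, H = x.n_cols, C = x.n_slices;
  mat out(V * H, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    uword k = 0;
    for (int dj = -1; dj <= 1; ++dj) {       // column (time) offset
      for (int di = -1; di <= 1; ++di) {     // row (variable) offset
        const uword r0 = di > 0 ? di : 0, r1 = di < 0 ? V + di : V;
        const uword c0 = dj > 0 ? dj : 0, c1 = dj < 0 ? H + dj : H;
        double* dst = out.colptr(c * 9 + k);
        const mat& src = x.slice(c);
        for (uword j = c0; j < c1; ++j) {
          const double* s = src.colptr(j - dj) + (r0 - di);
          std::copy(s, s + (r1 - r0), dst + j * V + r0);
        }
        ++k;
      }
    }
  }
  return out;
}

// scatter-add transpose of im2col3: dcol (V*H x 9C) -> V x H x C
static cube col2im3(const mat& dcol, uword V, uword H, uword C) {
  cube dx(V, H, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    uword k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword r0 = di > 0 ? di : 0, r1 = di < 0 ? V + di : V;
        const uword c0 = dj > 0 ? dj : 0, c1 = dj < 0 ? H + dj : H;
        const double* src = dcol.colptr(c * 9 + k);
        mat& dst = dx.slice(c);
        for (uword j = c0; j < c1; ++j) {
          double* d = dst.colptr(j - dj) + (r0 - di);
          const double* s = src + j * V + r0;
          for (uword i = 0; i < r1 - r0; ++i) d[i] += s[i];
        }
        ++k;
      }
    }
  }
  return dx;
}

// conv forward: col = im2col3(x); a = relu(col * W' + b), reshaped V x H x F
static cube conv_relu(const cube& x, const mat& W, const vec& b, mat& col) {
  col = im2col3(x);                          // (VH x 9C)
  mat a = col * W.t();                       // (VH x F)
  a.each_row() += b.t();
  a = clamp(a, 0.0, datum::inf);
  cube out(x.n_rows, x.n_cols, W.n_rows);
  std::copy(a.memptr(), a.memptr() + a.n_elem, out.memptr());
  return out;
}

// backward through relu+conv. dOut: V x H x F. Returns dX; accumulates dW,db.
static cube conv_relu_bwd(const cube& a, const cube& dOut, const mat& W,
                          const mat& col, uword Cin, mat& dW, vec& db) {
  const uword V = a.n_rows, H = a.n_cols, F = a.n_slices;
  mat dA(V * H, F);
  for (uword f = 0; f < F; ++f) {
    const double* av = a.slice(f).memptr();
    const double* dv = dOut.slice(f).memptr();
    double* out = dA.colptr(f);
    for (uword i = 0; i < V * H; ++i) out[i] = av[i] > 0 ? dv[i] : 0.0;
  }
  dW += dA.t() * col;                        // (F x 9C)
  db += sum(dA, 0).t();
  mat dcol = dA * W;                         // (VH x 9C)
  return col2im3(dcol, V, H, Cin);
}

// max-pool with window (ph, pw); records argmax linear indices per window
static cube maxpool(const cube& x, uword ph, uword pw, umat& idx) {
  const uword V = x.n_rows / ph, H = x.n_cols / pw, F = x.n_slices;
  cube out(V, H, F);
  idx.set_size(V * H, F);
  for (uword f = 0; f < F; ++f) {
    const mat& s = x.slice(f);
    for (uword j = 0; j < H; ++j) {
      for (uword i = 0; i < V; ++i) {
        uword bi = i * ph, bj = j * pw;
        double best = s(bi, bj); uword bl = bi + bj * x.n_rows;
        for (uword dj = 0; dj < pw; ++dj)
          for (uword di = 0; di < ph; ++di) {
            double v = s(bi + di, bj + dj);
            if (v > best) { best = v; bl = (bi + di) + (bj + dj) * x.n_rows; }
          }
        out(i, j, f) = best;
        idx(i + j * V, f) = bl;
      }
    }
  }
  return out;
}

static cube maxpool_bwd(const cube& dOut, const umat& idx, uword V0,
                        uword H0) {
  const uword V = dOut.n_rows, H = dOut.n_cols, F = dOut.n_slices;
  cube dx(V0, H0, F, fill::zeros);
  for (uword f = 0; f < F; ++f) {
    for (uword j = 0; j < H; ++j)
      for (uword i = 0; i < V; ++i)
        dx.slice(f)(idx(i + j * V, f)) += dOut(i, j, f);
  }
  return dx;
}

// ---- GRU -------------------------------------------------------------------

struct GruParams {
  mat Wz, Uz, Wr, Ur, Wh, Uh;
  vec bz, br, bh;
};

struct GruCache {
  std::vector<mat> x, z, r, hh, h;  // h has T+1 entries (h[0] = 0)
};

static mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// xs: T matrices of D x N. Returns h_T (Hd x N).
static mat gru_forward(const std::vector<mat>& xs, const GruParams& P,
                       GruCache& C) {
  const uword T = xs.size(), N = xs[0].n_cols, Hd = P.Wz.n_rows;
  C.x = xs;
  C.z.resize(T); C.r.resize(T); C.hh.resize(T); C.h.resize(T + 1);
  C.h[0] = mat(Hd, N, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat az = P.Wz * xs[t] + P.Uz * C.h[t]; az.each_col() += P.bz;
    mat ar = P.Wr * xs[t] + P.Ur * C.h[t]; ar.each_col() += P.br;
    C.z[t] = sigm(az);
    C.r[t] = sigm(ar);
    mat ah = P.Wh * xs[t] + P.Uh * (C.r[t] % C.h[t]); ah.each_col() += P.bh;
    C.hh[t] = tanh(ah);
    C.h[t + 1] = (1.0 - C.z[t]) % C.h[t] + C.z[t] % C.hh[t];
  }
  return C.h[T];
}

// BPTT from dh_T; fills param grads and per-step input grads dxs.
static void gru_backward(const mat& dhT, const GruParams& P,
                         const GruCache& C, GruParams& G,
                         std::vector<mat>& dxs, bool want_dx) {
  const uword T = C.x.size();
  if (want_dx) dxs.resize(T);
  mat dh = dhT;
  for (uword tt = T; tt-- > 0;) {
    const mat& z = C.z[tt];
    const mat& r = C.r[tt];
    const mat& hh = C.hh[tt];
    const mat& hp = C.h[tt];
    mat dz  = dh % (hh - hp);
    mat dhh = dh % z;
    mat dah = dhh % (1.0 - hh % hh);
    mat daz = dz % z % (1.0 - z);
    mat drh = P.Uh.t() * dah;                 // grad wrt (r % h_prev)
    mat dar = (drh % hp) % r % (1.0 - r);
    G.Wh += dah * C.x[tt].t();
    G.Uh += dah * (r % hp).t();
    G.bh += sum(dah, 1);
    G.Wz += daz * C.x[tt].t();
    G.Uz += daz * hp.t();
    G.bz += sum(daz, 1);
    G.Wr += dar * C.x[tt].t();
    G.Ur += dar * hp.t();
    G.br += sum(dar, 1);
    if (want_dx)
      dxs[tt] = P.Wz.t() * daz + P.Wr.t() * dar + P.Wh.t() * dah;
    dh = dh % (1.0 - z) + P.Uz.t() * daz + P.Ur.t() * dar + drh % r;
  }
}

// ---- helpers ---------------------------------------------------------------

static mat getM(const List& p, const char* nm) {
  return Rcpp::as<mat>(p[nm]);
}
static vec getV(const List& p, const char* nm) {
  return Rcpp::as<vec>(p[nm]);
}

static GruParams gru_from(const List& p) {
  GruParams P;
  P.Wz = getM(p, "Wz"); P.Uz = getM(p, "Uz"); P.bz = getV(p, "bz");
  P.Wr = getM(p, "Wr"); P.Ur = getM(p, "Ur"); P.br = getV(p, "br");
  P.Wh = getM(p, "Wh"); P.Uh = getM(p, "Uh"); P.bh = getV(p, "bh");
  return P;
}

static GruParams gru_zeros(const GruParams& P) {
  GruParams G;
  G.Wz = zeros<mat>(size(P.Wz)); G.Uz = zeros<mat>(size(P.Uz));
  G.Wr = zeros<mat>(size(P.Wr)); G.Ur = zeros<mat>(size(P.Ur));
  G.Wh = zeros<mat>(size(P.Wh)); G.Uh = zeros<mat>(size(P.Uh));
  G.bz = zeros<vec>(P.bz.n_elem); G.br = zeros<vec>(P.br.n_elem);
  G.bh = zeros<vec>(P.bh.n_elem);
  return G;
}

// ---- main entry ------------------------------------------------------------

// Runs one batch through the network. If y is given, computes weighted BCE
// loss and (optionally) parameter gradients. If gradcam is requested (conv
// architectures only), also returns the final-conv-layer activations A, the
// per-sample gradients dA = d logit / dA, and the Grad-CAM map
// relu(sum_k alpha_k A_k) with alpha_k the spatial mean of dA_k.
// [[Rcpp::export(name = ".nn_run")]]
List nn_run(std::string arch, List params, arma::cube X,
            Rcpp::Nullable<Rcpp::NumericVector> y_ = R_NilValue,
            Rcpp::Nullable<Rcpp::NumericVector> w_ = R_NilValue,
            Rcpp::Nullable<Rcpp::NumericMatrix> dropmask_ = R_NilValue,
            bool want_grads = false, bool want_gradcam = false) {
  const uword V = X.n_rows, H = X.n_cols, N = X.n_slices;
  const bool has_conv = arch != "rnn";
  if (want_gradcam && !has_conv)
    Rcpp::stop("Grad-CAM needs a convolutional layer; the rnn architecture has none");

  // ---- forward -------------------------------------------------------------
  mat W1, W2, Wd, Wo;
  vec b1, b2, bd, bo;
  GruParams GP;
  const bool has_gru = arch != "standard_cnn";
  if (has_conv) {
    W1 = getM(params, "W1"); b1 = getV(params, "b1");
    W2 = getM(params, "W2"); b2 = getV(params, "b2");
  }
  if (arch == "standard_cnn") { Wd = getM(params, "Wd"); bd = getV(params, "bd"); }
  if (has_gru) GP = gru_from(params);
  Wo = getM(params, "Wo"); bo = getV(params, "bo");

  const uword ph2 = (arch == "standard_cnn") ? 2 : 1;   // time-axis pooling
  std::vector<mat> col1(N), col2(N);
  std::vector<cube> a1(N), p1(N), a2(N), p2(N);
  std::vector<umat> i1(N), i2(N);
  uword Vq = 0, Hq = 0, F2 = 0;

  mat feat;                      // penultimate features (d x N)
  std::vector<mat> xs;           // GRU inputs
  GruCache GC;

  if (has_conv) {
    for (uword n = 0; n < N; ++n) {
      cube x0(V, H, 1);
      x0.slice(0) = X.slice(n);
      a1[n] = conv_relu(x0, W1, b1, col1[n]);
      p1[n] = maxpool(a1[n], 2, ph2, i1[n]);
      a2[n] = conv_relu(p1[n], W2, b2, col2[n]);
      p2[n] = maxpool(a2[n], 2, ph2, i2[n]);
    }
    Vq = p2[0].n_rows; Hq = p2[0].n_cols; F2 = p2[0].n_slices;
  }

  if (arch == "standard_cnn") {
    mat flat(Vq * Hq * F2, N);
    for (uword n = 0; n < N; ++n) flat.col(n) = vectorise(p2[n]);
    mat hid = Wd * flat;
    hid.each_col() += bd;
    hid = clamp(hid, 0.0, datum::inf);
    feat = hid;
    // stash for backward
    GC.x.clear();
    GC.h.resize(1);
    GC.h[0] = flat;     // reuse: flat input to dense
  } else if (arch == "rnn") {
    xs.resize(H);
    for (uword t = 0; t < H; ++t) {
      mat xt(V, N);
      for (uword n = 0; n < N; ++n) xt.col(n) = X.slice(n).col(t);
      xs[t] = xt;
    }
    feat = gru_forward(xs, GP, GC);
  } else { // cnn_rl: time axis preserved, features per time step
    const uword D = Vq * F2;
    xs.assign(Hq, mat(D, N));
    for (uword n = 0; n < N; ++n) {
      for (uword f = 0; f < F2; ++f)
        for (uword t = 0; t < Hq; ++t)
          xs[t].col(n).subvec(f * Vq, (f + 1) * Vq - 1) = p2[n].slice(f).col(t);
    }
    feat = gru_forward(xs, GP, GC);
  }

  mat fdrop = feat;
  mat dropmask;
  if (dropmask_.isNotNull()) {
    dropmask = Rcpp::as<mat>(dropmask_);
    fdrop = feat % dropmask;
  }
  rowvec logit = Wo * fdrop;  // Wo is 1 x d
  logit += bo(0);
  rowvec prob = 1.0 / (1.0 + exp(-logit));

  List out;
  out["logits"] = Rcpp::NumericVector(logit.begin(), logit.end());
  out["probs"] = Rcpp::NumericVector(prob.begin(), prob.end());

  // ---- loss / gradient seed ------------------------------------------------
  rowvec dlogit;
  bool need_backward = want_grads || want_gradcam;
  if (y_.isNotNull()) {
    rowvec y = Rcpp::as<rowvec>(y_);
    rowvec w(N, fill::ones);
    if (w_.isNotNull()) w = Rcpp::as<rowvec>(w_);
    rowvec p = clamp(prob, 1e-12, 1.0 - 1e-12);
    double wsum = accu(w);
    double loss = -accu(w % (y % log(p) + (1.0 - y) % log(1.0 - p))) / wsum;
    out["loss"] = loss;
    dlogit = w % (prob - y) / wsum;
  } else if (need_backward) {
    dlogit = rowvec(N, fill::ones);  // d logit / d logit, per sample
  }
  if (!need_backward) return out;

  // ---- backward ------------------------------------------------------------
  mat dW1, dW2, dWd, dWo;
  vec db1, db2, dbd;
  double dbo = 0.0;
  GruParams GG;
  if (has_conv) {
    dW1 = zeros<mat>(size(W1)); db1 = zeros<vec>(b1.n_elem);
    dW2 = zeros<mat>(size(W2)); db2 = zeros<vec>(b2.n_elem);
  }
  if (arch == "standard_cnn") {
    dWd = zeros<mat>(size(Wd)); dbd = zeros<vec>(bd.n_elem);
  }
  if (has_gru) GG = gru_zeros(GP);

  dWo = dlogit.n_elem ? (fdrop * dlogit.t()).t() : mat();
  dbo = accu(dlogit);
  mat dfeat = Wo.t() * dlogit;        // d x N
  if (dropmask.n_elem) dfeat = dfeat % dropmask;

  cube dA_all;                        // d logit / d conv2-activations
  if (want_gradcam) dA_all.set_size(a2[0].n_rows, a2[0].n_cols, F2 * N);

  std::vector<mat> dxs;
  if (arch == "standard_cnn") {
    mat dhid = dfeat % conv_to<mat>::from(feat > 0);
    dWd = dhid * GC.h[0].t();
    dbd = sum(dhid, 1);
    mat dflat = Wd.t() * dhid;
    for (uword n = 0; n < N; ++n) {
      cube dp2(Vq, Hq, F2);
      for (uword f = 0; f < F2; ++f)
        dp2.slice(f) = reshape(dflat.col(n).subvec(f * Vq * Hq,
                                                   (f + 1) * Vq * Hq - 1),
                               Vq, Hq);
      cube da2 = maxpool_bwd(dp2, i2[n], a2[n].n_rows, a2[n].n_cols);
      if (want_gradcam)
        for (uword f = 0; f < F2; ++f)
          dA_all.slice(n * F2 + f) = da2.slice(f);
      if (want_grads) {
        cube dp1 = conv_relu_bwd(a2[n], da2, W2, col2[n], W1.n_rows, dW2, db2);
        cube da1 = maxpool_bwd(dp1, i1[n], a1[n].n_rows, a1[n].n_cols);
        conv_relu_bwd(a1[n], da1, W1, col1[n], 1, dW1, db1);
      }
    }
  } else if (arch == "rnn") {
    gru_backward(dfeat, GP, GC, GG, dxs, false);
  } else { // cnn_rl
    gru_backward(dfeat, GP, GC, GG, dxs, true);
    for (uword n = 0; n < N; ++n) {
      cube dp2(Vq, Hq, F2);
      for (uword f = 0; f < F2; ++f)
        for (uword t = 0; t < Hq; ++t)
          dp2.slice(f).col(t) = dxs[t].col(n).subvec(f * Vq, (f + 1) * Vq - 1);
      cube da2 = maxpool_bwd(dp2, i2[n], a2[n].n_rows, a2[n].n_cols);
      if (want_gradcam)
        for (uword f = 0; f < F2; ++f)
          dA_all.slice(n * F2 + f) = da2.slice(f);
      if (want_grads) {
        cube dp1 = conv_relu_bwd(a2[n], da2, W2, col2[n], W1.n_rows, dW2, db2);
        cube da1 = maxpool_bwd(dp1, i1[n], a1[n].n_rows, a1[n].n_cols);
        conv_relu_bwd(a1[n], da1, W1, col1[n], 1, dW1, db1);
      }
    }
  }

  if (want_grads) {
    List g;
    if (has_conv) {
      g["W1"] = dW1; g["b1"] = db1; g["W2"] = dW2; g["b2"] = db2;
    }
    if (arch == "standard_cnn") { g["Wd"] = dWd; g["bd"] = dbd; }
    if (has_gru) {
      g["Wz"] = GG.Wz; g["Uz"] = GG.Uz; g["bz"] = GG.bz;
      g["Wr"] = GG.Wr; g["Ur"] = GG.Ur; g["br"] = GG.br;
      g["Wh"] = GG.Wh; g["Uh"] = GG.Uh; g["bh"] = GG.bh;
    }
    g["Wo"] = dWo; g["bo"] = dbo;
    out["grads"] = g;
  }

  if (want_gradcam) {
    // A: conv2 post-ReLU activations, stacked sample-major
    cube A_all(a2[0].n_rows, a2[0].n_cols, F2 * N);
    cube cam(a2[0].n_rows, a2[0].n_cols, N, fill::zeros);
    for (uword n = 0; n < N; ++n) {
      mat m(a2[0].n_rows, a2[0].n_cols, fill::zeros);
      for (uword f = 0; f < F2; ++f) {
        A_all.slice(n * F2 + f) = a2[n].slice(f);
        double alpha = accu(dA_all.slice(n * F2 + f)) /
          double(a2[0].n_rows * a2[0].n_cols);
        m += alpha * a2[n].slice(f);
      }
      cam.slice(n) = clamp(m, 0.0, datum::inf);
    }
    out["A"] = A_all;
    out["dA"] = dA_all;
    out["cam"] = cam;
    out["n_filters"] = (int)F2;
  }
  return out;
}
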