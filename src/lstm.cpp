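// LSTM sequence classifier: forward pass, backpropagation through time,
// Adam updates, MAE loss. Architecture: LSTM (returning the full hidden
// sequence) -> per-timestep affine map -> flatten -> affine -> sigmoid.
//
// All randomness (weight init, minibatch shuffling) lives on the R side;
// this translation unit is purely deterministic. Gate ordering in the
// packed 4u-wide weight blocks is (input, forget, candidate, output).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmWeights {
  mat Wx;    // C x 4u
  mat Wh;    // u x 4u
  rowvec b;  // 4u
  mat Wd;    // u x d
  rowvec bd; // d
  vec Wo;    // T*d
  double bo;
};

static LstmWeights unpack(const Rcpp::List& W) {
  LstmWeights p;
  p.Wx = Rcpp::as<mat>(W["Wx"]);
  p.Wh = Rcpp::as<mat>(W["Wh"]);
  p.b  = Rcpp::as<rowvec>(W["b"]);
  p.Wd = Rcpp::as<mat>(W["Wd"]);
  p.bd = Rcpp::as<rowvec>(W["bd"]);
  p.Wo = Rcpp::as<vec>(W["Wo"]);
  p.bo = Rcpp::as<double>(W["bo"]);
  return p;
}

static Rcpp::List pack(const LstmWeights& p) {
  return Rcpp::List::create(
    Rcpp::Named("Wx") = p.Wx, Rcpp::Named("Wh") = p.Wh,
    Rcpp::Named("b") = p.b, Rcpp::Named("Wd") = p.Wd,
    Rcpp::Named("bd") = p.bd, Rcpp::Named("Wo") = p.Wo,
    Rcpp::Named("bo") = p.bo);
}

// Activations stored for BPTT (all B x u x T).
struct Trace {
  cube I, F, G, O, C, Th, H;
  mat D; // B x (T*d), flattened per-step dense outputs (timestep-major)
};

// Forward pass over a batch. mask is B x T with 1 = real timestep,
// 0 = padded; a masked step carries h and c through unchanged and
// contributes zero features.
static vec forward(const cube& X, const mat& mask, const LstmWeights& w,
                   Trace* tr) {
  const uword B = X.n_rows, T = X.n_cols, C = X.n_slices;
  const uword u = w.Wh.n_rows, d = w.Wd.n_cols;

  mat Hprev(B, u, fill::zeros), Cprev(B, u, fill::zeros);
  mat D(B, T * d, fill::zeros);
  if (tr) {
    tr->I.set_size(B, u, T); tr->F.set_size(B, u, T);
    tr->G.set_size(B, u, T); tr->O.set_size(B, u, T);
    tr->C.set_size(B, u, T); tr->Th.set_size(B, u, T);
    tr->H.set_size(B, u, T);
  }
  mat Xt(B, C);
  for (uword t = 0; t < T; ++t) {
    for (uword c = 0; c < C; ++c) Xt.col(c) = X.slice(c).col(t);
    mat A = Xt * w.Wx + Hprev * w.Wh;
    A.each_row() += w.b;
    mat i = sigm(A.cols(0, u - 1));
    mat f = sigm(A.cols(u, 2 * u - 1));
    mat g = tanh(A.cols(2 * u, 3 * u - 1));
    mat o = sigm(A.cols(3 * u, 4 * u - 1));
    mat Cnew = f % Cprev + i % g;
    mat Thc = tanh(Cnew);
    mat Hnew = o % Thc;

    vec m = mask.col(t);
    mat M = repmat(m, 1, u);
    mat Ct = M % Cnew + (1.0 - M) % Cprev;
    mat Ht = M % Hnew + (1.0 - M) % Hprev;

    mat Dt = Ht * w.Wd;
    Dt.each_row() += w.bd;
    Dt.each_col() %= m; // padded steps contribute zero features
    D.cols(t * d, (t + 1) * d - 1) = Dt;

    if (tr) {
      tr->I.slice(t) = i; tr->F.slice(t) = f; tr->G.slice(t) = g;
      tr->O.slice(t) = o; tr->C.slice(t) = Ct; tr->Th.slice(t) = Thc;
      tr->H.slice(t) = Ht;
    }
    Hprev = Ht; Cprev = Ct;
  }
  if (tr) tr->D = D;
  vec s = D * w.Wo + w.bo;
  return 1.0 / (1.0 + exp(-s));
}

struct Grads {
  mat Wx, Wh, Wd;
  rowvec b, bd;
  vec Wo;
  double bo;
};

// dLdp: dLoss/dprob per sample. Returns parameter gradients.
static Grads backward(const cube& X, const mat& mask, const LstmWeights& w,
                      const Trace& tr, const vec& p, const vec& dLdp) {
  const uword B = X.n_rows, T = X.n_cols, C = X.n_slices;
  const uword u = w.Wh.n_rows, d = w.Wd.n_cols;

  Grads g;
  g.Wx.zeros(C, 4 * u); g.Wh.zeros(u, 4 * u); g.b.zeros(4 * u);
  g.Wd.zeros(u, d); g.bd.zeros(d); g.Wo.zeros(T * d); g.bo = 0.0;

  vec ds = dLdp % p % (1.0 - p);
  g.Wo = tr.D.t() * ds;
  g.bo = accu(ds);
  mat dD = ds * w.Wo.t(); // B x (T*d)

  mat dHnext(B, u, fill::zeros), dCnext(B, u, fill::zeros);
  mat Xt(B, C);
  for (uword t = T; t-- > 0;) {
    vec m = mask.col(t);
    mat M = repmat(m, 1, u);

    mat dDt = dD.cols(t * d, (t + 1) * d - 1);
    dDt.each_col() %= m;
    const mat& Ht = tr.H.slice(t);
    g.Wd += Ht.t() * dDt;
    g.bd += sum(dDt, 0);

    mat dH = dHnext + dDt * w.Wd.t();
    mat dC = dCnext;

    // split the carried gradient between the gated path (real step) and
    // the passthrough (padded step)
    mat dHg = M % dH, dCg = M % dC;
    mat dHcarry = (1.0 - M) % dH, dCcarry = (1.0 - M) % dC;

    const mat& i = tr.I.slice(t); const mat& f = tr.F.slice(t);
    const mat& gg = tr.G.slice(t); const mat& o = tr.O.slice(t);
    const mat& Thc = tr.Th.slice(t);
    mat Cprev = (t == 0) ? mat(B, u, fill::zeros) : tr.C.slice(t - 1);
    mat Hprev = (t == 0) ? mat(B, u, fill::zeros) : tr.H.slice(t - 1);

    mat do_ = dHg % Thc % o % (1.0 - o);
    mat dCtot = dCg + dHg % o % (1.0 - Thc % Thc);
    mat di = dCtot % gg % i % (1.0 - i);
    mat dg = dCtot % i % (1.0 - gg % gg);
    mat df = dCtot % Cprev % f % (1.0 - f);

    mat dA(B, 4 * u);
    dA.cols(0, u - 1) = di;
    dA.cols(u, 2 * u - 1) = df;
    dA.cols(2 * u, 3 * u - 1) = dg;
    dA.cols(3 * u, 4 * u - 1) = do_;

    for (uword c = 0; c < C; ++c) Xt.col(c) = X.slice(c).col(t);
    g.Wx += Xt.t() * dA;
    g.Wh += Hprev.t() * dA;
    g.b += sum(dA, 0);

    dHnext = dA * w.Wh.t() + dHcarry;
    dCnext = dCtot % f + dCcarry;
  }
  return g;
}

struct AdamState {
  LstmWeights m, v;
  long step = 0;
  void init(const LstmWeights& w) {
    m.Wx.zeros(size(w.Wx)); v.Wx.zeros(size(w.Wx));
    m.Wh.zeros(size(w.Wh)); v.Wh.zeros(size(w.Wh));
    m.b.zeros(size(w.b));   v.b.zeros(size(w.b));
    m.Wd.zeros(size(w.Wd)); v.Wd.zeros(size(w.Wd));
    m.bd.zeros(size(w.bd)); v.bd.zeros(size(w.bd));
    m.Wo.zeros(size(w.Wo)); v.Wo.zeros(size(w.Wo));
    m.bo = 0.0; v.bo = 0.0;
  }
};

template <typename M>
static void adam_one(M& theta, M& m, M& v, const M& grad, double lr,
                     double b1, double b2, double eps, double bc1,
                     double bc2) {
  m = b1 * m + (1.0 - b1) * grad;
  v = b2 * v + (1.0 - b2) * (grad % grad);
  theta -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

static void adam_update(LstmWeights& w, AdamState& st, const Grads& g,
                        double lr, double b1, double b2, double eps) {
  st.step += 1;
  double bc1 = 1.0 - std::pow(b1, (double)st.step);
  double bc2 = 1.0 - std::pow(b2, (double)st.step);
  adam_one(w.Wx, st.m.Wx, st.v.Wx, g.Wx, lr, b1, b2, eps, bc1, bc2);
  adam_one(w.Wh, st.m.Wh, st.v.Wh, g.Wh, lr, b1, b2, eps, bc1, bc2);
  adam_one(w.b,  st.m.b,  st.v.b,  g.b,  lr, b1, b2, eps, bc1, bc2);
  adam_one(w.Wd, st.m.Wd, st.v.Wd, g.Wd, lr, b1, b2, eps, bc1, bc2);
  adam_one(w.bd, st.m.bd, st.v.bd, g.bd, lr, b1, b2, eps, bc1, bc2);
  adam_one(w.Wo, st.m.Wo, st.v.Wo, g.Wo, lr, b1, b2, eps, bc1, bc2);
  st.m.bo = b1 * st.m.bo + (1.0 - b1) * g.bo;
  st.v.bo = b2 * st.v.bo + (1.0 - b2) * g.bo * g.bo;
  w.bo -= lr * (st.m.bo / bc1) / (std::sqrt(st.v.bo / bc2) + eps);
}

static cube as_cube(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector dim = x.attr("dim");
  return cube(const_cast<double*>(x.begin()), dim[0], dim[1], dim[2],
              false, true);
}

static cube rows_of(const cube& X, const uvec& idx) {
  cube out(idx.n_elem, X.n_cols, X.n_slices);
  for (uword c = 0; c < X.n_slices; ++c) out.slice(c) = X.slice(c).rows(idx);
  return out;
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::NumericVector x, arma::vec y,
                          arma::mat mask, Rcpp::List weights,
                          arma::imat shuffle, int epochs, int batch_size,
                          double lr, double beta1, double beta2, double eps,
                          double threshold,
                          Rcpp::Nullable<Rcpp::NumericVector> xval,
                          Rcpp::Nullable<Rcpp::NumericVector> yval,
                          Rcpp::Nullable<Rcpp::NumericVector> maskval) {
  cube X = as_cube(x);
  const uword n = X.n_rows;
  if (y.n_elem != n) Rcpp::stop("x/y size mismatch");

  LstmWeights w = unpack(weights);
  AdamState st; st.init(w);

  bool has_val = xval.isNotNull();
  cube Xv; vec yv; mat mv;
  if (has_val) {
    Rcpp::NumericVector xv_(xval);
    Xv = as_cube(xv_);
    yv = Rcpp::as<vec>(yval);
    mv = Rcpp::as<mat>(Rcpp::NumericVector(maskval));
  }

  mat history(epochs, has_val ? 4 : 2);
  Trace tr;
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0.0; uword correct = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, n) - 1;
      uvec idx(stop - start + 1);
      for (uword k = 0; k < idx.n_elem; ++k)
        idx[k] = (uword)shuffle(e, start + k);
      cube Xb = rows_of(X, idx);
      mat mb = mask.rows(idx);
      vec yb = y(idx);

      vec p = forward(Xb, mb, w, &tr);
      if (!p.is_finite())
        Rcpp::stop("non-finite loss at epoch %d", e + 1);
      vec resid = p - yb;
      loss_sum += accu(abs(resid));
      correct += accu((p >= threshold) == (yb >= 0.5));

      vec dLdp = sign(resid) / (double)yb.n_elem;
      Grads g = backward(Xb, mb, w, tr, p, dLdp);
      adam_update(w, st, g, lr, beta1, beta2, eps);
    }
    history(e, 0) = loss_sum / n;
    history(e, 1) = (double)correct / n;
    if (has_val) {
      vec pv = forward(Xv, mv, w, nullptr);
      history(e, 2) = accu(abs(pv - yv)) / yv.n_elem;
      history(e, 3) = accu((pv >= threshold) == (yv >= 0.5)) /
        (double)yv.n_elem;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = pack(w),
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(Rcpp::NumericVector x, arma::mat mask,
                           Rcpp::List weights) {
  cube X = as_cube(x);
  LstmWeights w = unpack(weights);
  return forward(X, mask, w, nullptr);
}

// Full-batch MAE gradients; testing hook for finite-difference checks.
// [[Rcpp::export]]
Rcpp::List lstm_grads_cpp(Rcpp::NumericVector x, arma::vec y,
                          arma::mat mask, Rcpp::List weights) {
  cube X = as_cube(x);
  LstmWeights w = unpack(weights);
  Trace tr;
  vec p = forward(X, mask, w, &tr);
  vec dLdp = sign(p - y) / (double)y.n_elem;
  Grads g = backward(X, mask, w, tr, p, dLdp);
  return Rcpp::List::create(
    Rcpp::Named("Wx") = g.Wx, Rcpp::Named("Wh") = g.Wh,
    Rcpp::Named("b") = g.b, Rcpp::Named("Wd") = g.Wd,
    Rcpp::Named("bd") = g.bd, Rcpp::Named("Wo") = g.Wo,
    Rcpp::Named("bo") = g.bo,
    Rcpp::Named("loss") = accu(abs(p - y)) / y.n_elem);
}
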