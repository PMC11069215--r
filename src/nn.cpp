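// Neural hazard models: transformer encoder and per-event feed-forward
// (DeepHit-style) networks mapping a covariate vector to an E x T matrix of
// discrete-time cause-specific hazards. Forward, analytic backward and the
// collapsed log-likelihood loss are implemented here; optimization loops and
// parameter initialization live in R.
//
// Internal layout: token sequences are stored as d x (n*L) matrices, one
// column per token, tokens of patient i occupying columns [i*L, (i+1)*L).
// Token index l = e*T + t (0-based, event-major). Hazards are returned as
// L x n matrices; the R side reshapes to an (n, E, T) array.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double LN_EPS = 1e-5;

// ---------------------------------------------------------------- utilities

static mat sigmoid_mat(const mat& z) {
  return 1.0 / (1.0 + exp(-z));
}

static mat relu_fwd(const mat& x)  { return clamp(x, 0.0, datum::inf); }
static mat relu_grad(const mat& x) { return conv_to<mat>::from(x > 0); }

// sinusoidal positional encoding, d rows x L cols
static mat positional_encoding(int d, int L) {
  mat pe(d, L, fill::zeros);
  for (int r = 0; r < d; r += 2) {
    double freq = std::pow(10000.0, -(double)r / (double)d);
    for (int l = 0; l < L; ++l) {
      pe(r, l) = std::sin(l * freq);
      if (r + 1 < d) pe(r + 1, l) = std::cos(l * freq);
    }
  }
  return pe;
}

// layer norm over the feature dimension (per column)
static mat ln_fwd(const mat& x, const vec& g, const vec& b, mat& xhat, rowvec& istd) {
  rowvec mu = mean(x, 0);
  mat xc = x.each_row() - mu;
  rowvec v = mean(square(xc), 0);
  istd = 1.0 / sqrt(v + LN_EPS);
  xhat = xc.each_row() % istd;
  mat y = xhat.each_col() % g;
  y.each_col() += b;
  return y;
}

static mat ln_bwd(const mat& dy, const mat& xhat, const rowvec& istd, const vec& g,
                  vec& dg, vec& db) {
  dg += sum(dy % xhat, 1);
  db += sum(dy, 1);
  mat dxhat = dy.each_col() % g;
  rowvec m1 = mean(dxhat, 0);
  rowvec m2 = mean(dxhat % xhat, 0);
  mat dx = dxhat.each_row() - m1;
  dx -= xhat.each_row() % m2;
  return dx.each_row() % istd;
}

// --------------------------------------------------------------- transformer

struct TFConfig {
  int p, E, T, d_cov, d_emb, n_layers, n_heads, ffn_dim;
  int d() const { return d_cov + d_emb; }
  int L() const { return E * T; }
};

static TFConfig tf_config(const Rcpp::List& cfg) {
  TFConfig c;
  c.p = cfg["p"]; c.E = cfg["n_events"]; c.T = cfg["horizon"];
  c.d_cov = cfg["d_cov"]; c.d_emb = cfg["d_emb"];
  c.n_layers = cfg["n_layers"]; c.n_heads = cfg["n_heads"];
  c.ffn_dim = cfg["ffn_dim"];
  if (c.d() % c.n_heads != 0)
    Rcpp::stop("model width (d_cov + d_emb) must be divisible by n_heads");
  return c;
}

struct TFParams {
  mat Wx;  vec bx;   // covariate encoder
  mat Emb;           // d_emb x L learned token-index embedding
  std::vector<mat> Wq, Wk, Wv, Wo, W1, W2;
  std::vector<vec> bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
  rowvec wout; double bout;
};

static TFParams tf_params(const Rcpp::List& P, const TFConfig& c) {
  TFParams out;
  out.Wx  = Rcpp::as<mat>(P["Wx"]);
  out.bx  = Rcpp::as<vec>(P["bx"]);
  out.Emb = Rcpp::as<mat>(P["Emb"]);
  for (int i = 0; i < c.n_layers; ++i) {
    std::string pr = "enc" + std::to_string(i + 1) + "_";
    out.Wq.push_back(Rcpp::as<mat>(P[pr + "Wq"]));
    out.Wk.push_back(Rcpp::as<mat>(P[pr + "Wk"]));
    out.Wv.push_back(Rcpp::as<mat>(P[pr + "Wv"]));
    out.Wo.push_back(Rcpp::as<mat>(P[pr + "Wo"]));
    out.W1.push_back(Rcpp::as<mat>(P[pr + "W1"]));
    out.W2.push_back(Rcpp::as<mat>(P[pr + "W2"]));
    out.bq.push_back(Rcpp::as<vec>(P[pr + "bq"]));
    out.bk.push_back(Rcpp::as<vec>(P[pr + "bk"]));
    out.bv.push_back(Rcpp::as<vec>(P[pr + "bv"]));
    out.bo.push_back(Rcpp::as<vec>(P[pr + "bo"]));
    out.b1.push_back(Rcpp::as<vec>(P[pr + "b1"]));
    out.b2.push_back(Rcpp::as<vec>(P[pr + "b2"]));
    out.g1.push_back(Rcpp::as<vec>(P[pr + "g1"]));
    out.be1.push_back(Rcpp::as<vec>(P[pr + "be1"]));
    out.g2.push_back(Rcpp::as<vec>(P[pr + "g2"]));
    out.be2.push_back(Rcpp::as<vec>(P[pr + "be2"]));
  }
  out.wout = Rcpp::as<rowvec>(P["wout"]);
  out.bout = Rcpp::as<double>(P["bout"]);
  return out;
}

struct TFLayerCache {
  mat Hin, Q, K, V, Attn, H1, U, G;
  mat xhat1, xhat2;
  rowvec istd1, istd2;
  cube A;  // L x L x (n * n_heads) attention weights
};

struct TFCache {
  mat H0, Hfinal;
  std::vector<TFLayerCache> layers;
};

// forward pass; caches kept only when cache != nullptr
static rowvec tf_forward_core(const mat& X, const TFParams& P, const TFConfig& c,
                              TFCache* cache) {
  const int n = X.n_rows, L = c.L(), d = c.d(), nh = c.n_heads, dh = d / nh;
  const double sc = 1.0 / std::sqrt((double)dh);

  mat pe = positional_encoding(d, L);
  mat base = join_cols(zeros<mat>(c.d_cov, L), P.Emb) + pe;
  mat Cov = P.Wx * X.t();
  Cov.each_col() += P.bx;

  mat H(d, n * L);
  for (int i = 0; i < n; ++i) {
    mat blk = base;
    blk.rows(0, c.d_cov - 1).each_col() += Cov.col(i);
    H.cols(i * L, (i + 1) * L - 1) = blk;
  }
  if (cache) { cache->H0 = H; cache->layers.resize(c.n_layers); }

  for (int li = 0; li < c.n_layers; ++li) {
    TFLayerCache* lc = cache ? &cache->layers[li] : nullptr;
    if (lc) lc->Hin = H;

    mat Q = P.Wq[li] * H; Q.each_col() += P.bq[li];
    mat K = P.Wk[li] * H; K.each_col() += P.bk[li];
    mat V = P.Wv[li] * H; V.each_col() += P.bv[li];
    mat Attn(d, n * L);
    if (lc) lc->A.set_size(L, L, n * nh);

    for (int i = 0; i < n; ++i) {
      const uword c0 = i * L, c1 = (i + 1) * L - 1;
      for (int h = 0; h < nh; ++h) {
        const uword r0 = h * dh, r1 = (h + 1) * dh - 1;
        mat S = (K.submat(r0, c0, r1, c1).t() * Q.submat(r0, c0, r1, c1)) * sc;
        S.each_row() -= max(S, 0);
        mat A = exp(S);
        A.each_row() /= sum(A, 0);
        Attn.submat(r0, c0, r1, c1) = V.submat(r0, c0, r1, c1) * A;
        if (lc) lc->A.slice(i * nh + h) = A;
      }
    }
    if (lc) { lc->Q = Q; lc->K = K; lc->V = V; lc->Attn = Attn; }

    mat O = P.Wo[li] * Attn; O.each_col() += P.bo[li];
    mat xhat1; rowvec istd1;
    mat H1 = ln_fwd(H + O, P.g1[li], P.be1[li], xhat1, istd1);

    mat U = P.W1[li] * H1; U.each_col() += P.b1[li];
    mat G = relu_fwd(U);
    mat F = P.W2[li] * G; F.each_col() += P.b2[li];
    mat xhat2; rowvec istd2;
    mat H2 = ln_fwd(H1 + F, P.g2[li], P.be2[li], xhat2, istd2);

    if (lc) {
      lc->H1 = H1; lc->U = U; lc->G = G;
      lc->xhat1 = xhat1; lc->istd1 = istd1;
      lc->xhat2 = xhat2; lc->istd2 = istd2;
    }
    H = H2;
  }
  if (cache) cache->Hfinal = H;
  rowvec logits = P.wout * H + P.bout;
  return logits;
}

struct TFGrads {
  mat Wx; vec bx; mat Emb;
  std::vector<mat> Wq, Wk, Wv, Wo, W1, W2;
  std::vector<vec> bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
  rowvec wout; double bout;
  mat dX;
};

static void tf_backward_core(const rowvec& dlogits, const mat& X, const TFParams& P,
                             const TFConfig& c, const TFCache& cache, TFGrads& Gd) {
  const int n = X.n_rows, L = c.L(), d = c.d(), nh = c.n_heads, dh = d / nh;
  const double sc = 1.0 / std::sqrt((double)dh);

  Gd.wout = dlogits * cache.Hfinal.t();
  Gd.bout = accu(dlogits);
  mat dH = P.wout.t() * dlogits;

  for (int li = c.n_layers - 1; li >= 0; --li) {
    const TFLayerCache& lc = cache.layers[li];

    mat dH2pre = ln_bwd(dH, lc.xhat2, lc.istd2, P.g2[li], Gd.g2[li], Gd.be2[li]);
    // FFN branch
    Gd.W2[li] += dH2pre * lc.G.t();
    Gd.b2[li] += sum(dH2pre, 1);
    mat dG = P.W2[li].t() * dH2pre;
    mat dU = dG % relu_grad(lc.U);
    Gd.W1[li] += dU * lc.H1.t();
    Gd.b1[li] += sum(dU, 1);
    mat dH1 = dH2pre + P.W1[li].t() * dU;

    mat dH1pre = ln_bwd(dH1, lc.xhat1, lc.istd1, P.g1[li], Gd.g1[li], Gd.be1[li]);
    // attention branch
    Gd.Wo[li] += dH1pre * lc.Attn.t();
    Gd.bo[li] += sum(dH1pre, 1);
    mat dAttn = P.Wo[li].t() * dH1pre;

    mat dQ(d, n * L), dK(d, n * L), dV(d, n * L);
    for (int i = 0; i < n; ++i) {
      const uword c0 = i * L, c1 = (i + 1) * L - 1;
      for (int h = 0; h < nh; ++h) {
        const uword r0 = h * dh, r1 = (h + 1) * dh - 1;
        const mat& A = lc.A.slice(i * nh + h);
        mat dOut = dAttn.submat(r0, c0, r1, c1);
        mat Vh = lc.V.submat(r0, c0, r1, c1);
        mat Qh = lc.Q.submat(r0, c0, r1, c1);
        mat Kh = lc.K.submat(r0, c0, r1, c1);
        dV.submat(r0, c0, r1, c1) = dOut * A.t();
        mat dA = Vh.t() * dOut;
        rowvec cs = sum(dA % A, 0);
        mat dS = ((dA.each_row() - cs) % A) * sc;
        dQ.submat(r0, c0, r1, c1) = Kh * dS;
        dK.submat(r0, c0, r1, c1) = Qh * dS.t();
      }
    }
    Gd.Wq[li] += dQ * lc.Hin.t(); Gd.bq[li] += sum(dQ, 1);
    Gd.Wk[li] += dK * lc.Hin.t(); Gd.bk[li] += sum(dK, 1);
    Gd.Wv[li] += dV * lc.Hin.t(); Gd.bv[li] += sum(dV, 1);
    dH = dH1pre + P.Wq[li].t() * dQ + P.Wk[li].t() * dK + P.Wv[li].t() * dV;
  }

  // token construction backward
  mat dCov(c.d_cov, n);
  mat dEmb(c.d_emb, L, fill::zeros);
  for (int i = 0; i < n; ++i) {
    mat blk = dH.cols(i * L, (i + 1) * L - 1);
    dCov.col(i) = sum(blk.rows(0, c.d_cov - 1), 1);
    dEmb += blk.rows(c.d_cov, d - 1);
  }
  Gd.Emb = dEmb;
  Gd.Wx = dCov * X;
  Gd.bx = sum(dCov, 1);
  Gd.dX = (P.Wx.t() * dCov).t();
}

static TFGrads tf_grads_zero(const TFParams& P, const TFConfig& c) {
  TFGrads g;
  g.Wx.zeros(size(P.Wx)); g.bx.zeros(P.bx.n_elem); g.Emb.zeros(size(P.Emb));
  for (int i = 0; i < c.n_layers; ++i) {
    g.Wq.push_back(zeros<mat>(size(P.Wq[i])));
    g.Wk.push_back(zeros<mat>(size(P.Wk[i])));
    g.Wv.push_back(zeros<mat>(size(P.Wv[i])));
    g.Wo.push_back(zeros<mat>(size(P.Wo[i])));
    g.W1.push_back(zeros<mat>(size(P.W1[i])));
    g.W2.push_back(zeros<mat>(size(P.W2[i])));
    g.bq.push_back(zeros<vec>(P.bq[i].n_elem));
    g.bk.push_back(zeros<vec>(P.bk[i].n_elem));
    g.bv.push_back(zeros<vec>(P.bv[i].n_elem));
    g.bo.push_back(zeros<vec>(P.bo[i].n_elem));
    g.b1.push_back(zeros<vec>(P.b1[i].n_elem));
    g.b2.push_back(zeros<vec>(P.b2[i].n_elem));
    g.g1.push_back(zeros<vec>(P.g1[i].n_elem));
    g.be1.push_back(zeros<vec>(P.be1[i].n_elem));
    g.g2.push_back(zeros<vec>(P.g2[i].n_elem));
    g.be2.push_back(zeros<vec>(P.be2[i].n_elem));
  }
  g.wout.zeros(P.wout.n_elem); g.bout = 0.0;
  return g;
}

static Rcpp::List tf_grads_list(const TFGrads& g, const TFConfig& c) {
  Rcpp::List out;
  out["Wx"] = g.Wx; out["bx"] = g.bx; out["Emb"] = g.Emb;
  for (int i = 0; i < c.n_layers; ++i) {
    std::string pr = "enc" + std::to_string(i + 1) + "_";
    out[pr + "Wq"] = g.Wq[i]; out[pr + "bq"] = g.bq[i];
    out[pr + "Wk"] = g.Wk[i]; out[pr + "bk"] = g.bk[i];
    out[pr + "Wv"] = g.Wv[i]; out[pr + "bv"] = g.bv[i];
    out[pr + "Wo"] = g.Wo[i]; out[pr + "bo"] = g.bo[i];
    out[pr + "W1"] = g.W1[i]; out[pr + "b1"] = g.b1[i];
    out[pr + "W2"] = g.W2[i]; out[pr + "b2"] = g.b2[i];
    out[pr + "g1"] = g.g1[i]; out[pr + "be1"] = g.be1[i];
    out[pr + "g2"] = g.g2[i]; out[pr + "be2"] = g.be2[i];
  }
  out["wout"] = g.wout; out["bout"] = g.bout;
  return out;
}

// ------------------------------------------------- collapsed log-likelihood

// Mean negative collapsed log-likelihood over patients, plus the gradient of
// that mean with respect to the pre-sigmoid logits. Observed event (e > 0):
// cells (j, k) for all events j and k <= t contribute, with target 1 only at
// (e, t). Censored (e = 0): cells with k < t contribute, all targets 0.
static double nll_and_dlogits(const mat& haz, const Rcpp::IntegerVector& ev,
                              const Rcpp::IntegerVector& tm, int E, int T,
                              mat* dlog) {
  const int n = haz.n_cols;
  const double clip = 1e-7;
  double total = 0.0;
  if (dlog) dlog->zeros(E * T, n);
  for (int i = 0; i < n; ++i) {
    const int e = ev[i], t = tm[i];
    const int kmax = (e > 0) ? t : t - 1;  // inclusive upper bound
    for (int j = 0; j < E; ++j) {
      for (int k = 0; k <= kmax; ++k) {
        const int l = j * T + k;
        const double lam = haz(l, i);
        const double lamc = std::min(std::max(lam, clip), 1.0 - clip);
        const double y = (e > 0 && j == e - 1 && k == t) ? 1.0 : 0.0;
        total += y * std::log(lamc) + (1.0 - y) * std::log(1.0 - lamc);
        if (dlog) (*dlog)(l, i) = (lam - y) / n;
      }
    }
  }
  return -total / n;
}

// [[Rcpp::export]]
double cpp_collapsed_nll(const arma::mat& haz, Rcpp::IntegerVector events,
                         Rcpp::IntegerVector times, int n_events, int horizon) {
  return nll_and_dlogits(haz, events, times, n_events, horizon, nullptr);
}

// ------------------------------------------------------- transformer exports

// [[Rcpp::export]]
arma::mat cpp_tf_forward(const arma::mat& X, Rcpp::List params, Rcpp::List cfg) {
  TFConfig c = tf_config(cfg);
  TFParams P = tf_params(params, c);
  rowvec logits = tf_forward_core(X, P, c, nullptr);
  mat haz = sigmoid_mat(reshape(logits, c.L(), X.n_rows));
  return haz;
}

// [[Rcpp::export]]
Rcpp::List cpp_tf_loss_grad(const arma::mat& X, Rcpp::IntegerVector events,
                            Rcpp::IntegerVector times, Rcpp::List params,
                            Rcpp::List cfg) {
  TFConfig c = tf_config(cfg);
  TFParams P = tf_params(params, c);
  TFCache cache;
  rowvec logits = tf_forward_core(X, P, c, &cache);
  mat haz = sigmoid_mat(reshape(logits, c.L(), X.n_rows));
  mat dlog;
  double loss = nll_and_dlogits(haz, events, times, c.E, c.T, &dlog);
  TFGrads g = tf_grads_zero(P, c);
  rowvec dl = vectorise(dlog).t();  // column-major: matches token column order
  tf_backward_core(dl, X, P, c, cache, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = tf_grads_list(g, c),
                            Rcpp::Named("hazard") = haz);
}

// [[Rcpp::export]]
Rcpp::List cpp_tf_vjp(const arma::mat& X, Rcpp::List params, Rcpp::List cfg,
                      const arma::mat& dhaz) {
  TFConfig c = tf_config(cfg);
  TFParams P = tf_params(params, c);
  TFCache cache;
  rowvec logits = tf_forward_core(X, P, c, &cache);
  mat haz = sigmoid_mat(reshape(logits, c.L(), X.n_rows));
  mat dlog = dhaz % haz % (1.0 - haz);
  TFGrads g = tf_grads_zero(P, c);
  rowvec dl = vectorise(dlog).t();
  tf_backward_core(dl, X, P, c, cache, g);
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("hazard") = haz,
                                      Rcpp::Named("grads") = tf_grads_list(g, c),
                                      Rcpp::Named("dX") = g.dX);
  return out;
}

// ---------------------------------------------------------- deephit exports

struct DHConfig { int p, E, T, hidden; };

static DHConfig dh_config(const Rcpp::List& cfg) {
  DHConfig c;
  c.p = cfg["p"]; c.E = cfg["n_events"]; c.T = cfg["horizon"];
  c.hidden = cfg["hidden_units"];
  return c;
}

// [[Rcpp::export]]
arma::mat cpp_dh_forward(const arma::mat& X, Rcpp::List params, Rcpp::List cfg) {
  DHConfig c = dh_config(cfg);
  const int n = X.n_rows;
  mat Xt = X.t();
  mat haz(c.E * c.T, n);
  for (int e = 0; e < c.E; ++e) {
    std::string pr = "ev" + std::to_string(e + 1) + "_";
    mat W1 = Rcpp::as<mat>(params[pr + "W1"]); vec b1 = Rcpp::as<vec>(params[pr + "b1"]);
    mat W2 = Rcpp::as<mat>(params[pr + "W2"]); vec b2 = Rcpp::as<vec>(params[pr + "b2"]);
    mat U = W1 * Xt; U.each_col() += b1;
    mat R = clamp(U, 0.0, datum::inf);
    mat Z = W2 * R; Z.each_col() += b2;
    haz.rows(e * c.T, (e + 1) * c.T - 1) = sigmoid_mat(Z);
  }
  return haz;
}

// shared backward for the per-event subnetworks given d(loss)/d(logits)
static Rcpp::List dh_backward(const arma::mat& X, Rcpp::List params,
                              const DHConfig& c, const mat& dlog, mat& dX) {
  const int n = X.n_rows;
  mat Xt = X.t();
  mat dXt(c.p, n, fill::zeros);
  Rcpp::List grads;
  for (int e = 0; e < c.E; ++e) {
    std::string pr = "ev" + std::to_string(e + 1) + "_";
    mat W1 = Rcpp::as<mat>(params[pr + "W1"]); vec b1 = Rcpp::as<vec>(params[pr + "b1"]);
    mat W2 = Rcpp::as<mat>(params[pr + "W2"]); vec b2 = Rcpp::as<vec>(params[pr + "b2"]);
    mat U = W1 * Xt; U.each_col() += b1;
    mat R = clamp(U, 0.0, datum::inf);
    mat dZ = dlog.rows(e * c.T, (e + 1) * c.T - 1);
    mat dW2 = dZ * R.t();
    vec db2 = sum(dZ, 1);
    mat dR = W2.t() * dZ;
    mat dU = dR % conv_to<mat>::from(U > 0);
    mat dW1 = dU * Xt.t();
    vec db1 = sum(dU, 1);
    dXt += W1.t() * dU;
    grads[pr + "W1"] = dW1; grads[pr + "b1"] = db1;
    grads[pr + "W2"] = dW2; grads[pr + "b2"] = db2;
  }
  dX = dXt.t();
  return grads;
}

// [[Rcpp::export]]
Rcpp::List cpp_dh_loss_grad(const arma::mat& X, Rcpp::IntegerVector events,
                            Rcpp::IntegerVector times, Rcpp::List params,
                            Rcpp::List cfg) {
  DHConfig c = dh_config(cfg);
  mat haz = cpp_dh_forward(X, params, cfg);
  mat dlog;
  double loss = nll_and_dlogits(haz, events, times, c.E, c.T, &dlog);
  mat dX;
  Rcpp::List grads = dh_backward(X, params, c, dlog, dX);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("hazard") = haz);
}

// [[Rcpp::export]]
Rcpp::List cpp_dh_vjp(const arma::mat& X, Rcpp::List params, Rcpp::List cfg,
                      const arma::mat& dhaz) {
  DHConfig c = dh_config(cfg);
  mat haz = cpp_dh_forward(X, params, cfg);
  mat dlog = dhaz % haz % (1.0 - haz);
  mat dX;
  Rcpp::List grads = dh_backward(X, params, c, dlog, dX);
  return Rcpp::List::create(Rcpp::Named("hazard") = haz,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("dX") = dX);
}
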