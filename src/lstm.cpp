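// Stacked-LSTM segment classifier: forward pass, backpropagation
// through time, and Adam training loop.
//
// Layout conventions:
//  - A batch of segments is an R array of dim (B, C, T): slice t is the
//    B x C matrix of sample t across the batch.
//  - Per LSTM layer, parameters are Wx (d x 4u), Wh (u x 4u), b (4u),
//    gate column order [i | f | o | g]; the dense head is Wd (u4 x K),
//    bd (K). The flat parameter list is (Wx1, Wh1, b1, ..., Wd, bd).
//  - Gates use the logistic function; the cell/candidate activation is
//    selectable (0 = tanh, 1 = logistic) because the architecture uses
//    the logistic function for both activations while the printed cell
//    equations use tanh.
//  - All randomness (shuffling, recurrent-dropout masks) is drawn from
//    R's RNG so set.seed() governs training exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static inline mat cell_act(const mat& x, int act) {
  if (act == 0) return tanh(x);
  return sigm(x);
}
// derivative expressed through the activated value
static inline mat cell_act_deriv(const mat& a, int act) {
  if (act == 0) return 1.0 - square(a);
  return a % (1.0 - a);
}

struct LayerCache {
  cube I, F, O, G, Cprev, TC, Hd; // B x u x T each
  cube H;                         // layer output sequence
};

// Forward one LSTM layer over a batch. rmask is the (already inverted-
// -scaled) recurrent dropout mask, B x u; pass an empty matrix for
// inference.
static cube layer_forward(const cube& in, const mat& Wx, const mat& Wh,
                          const rowvec& b, int act, const mat& rmask,
                          LayerCache* cache) {
  const uword B = in.n_rows, T = in.n_slices;
  const uword u = Wh.n_rows;
  cube H(B, u, T);
  mat h(B, u, fill::zeros), c(B, u, fill::zeros);
  const bool drop = rmask.n_elem > 0;
  if (cache) {
    cache->I.set_size(B, u, T); cache->F.set_size(B, u, T);
    cache->O.set_size(B, u, T); cache->G.set_size(B, u, T);
    cache->Cprev.set_size(B, u, T); cache->TC.set_size(B, u, T);
    cache->Hd.set_size(B, u, T);
  }
  for (uword t = 0; t < T; ++t) {
    mat hd = drop ? mat(h % rmask) : h;
    mat Z = in.slice(t) * Wx + hd * Wh;
    Z.each_row() += b;
    mat i = sigm(Z.cols(0, u - 1));
    mat f = sigm(Z.cols(u, 2 * u - 1));
    mat o = sigm(Z.cols(2 * u, 3 * u - 1));
    mat g = cell_act(Z.cols(3 * u, 4 * u - 1), act);
    mat cprev = c;
    c = f % cprev + i % g;
    mat tc = cell_act(c, act);
    if (cache) {
      cache->I.slice(t) = i; cache->F.slice(t) = f;
      cache->O.slice(t) = o; cache->G.slice(t) = g;
      cache->Cprev.slice(t) = cprev; cache->TC.slice(t) = tc;
      cache->Hd.slice(t) = hd;
    }
    h = tc % o;
    H.slice(t) = h;
  }
  if (cache) cache->H = H;
  return H;
}

// Backward one LSTM layer; dH holds dL/dh_t for every t. Returns
// dL/d(input sequence) and accumulates parameter gradients.
static cube layer_backward(const cube& in, const mat& Wx, const mat& Wh,
                           int act, const mat& rmask, const LayerCache& cc,
                           const cube& dH, mat& gWx, mat& gWh, rowvec& gb) {
  const uword B = in.n_rows, d = in.n_cols, T = in.n_slices;
  const uword u = Wh.n_rows;
  const bool drop = rmask.n_elem > 0;
  gWx.zeros(d, 4 * u); gWh.zeros(u, 4 * u); gb.zeros(4 * u);
  cube dIn(B, d, T);
  mat dc(B, u, fill::zeros), dh_carry(B, u, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat dh = dH.slice(t) + dh_carry;
    const mat& i = cc.I.slice(t); const mat& f = cc.F.slice(t);
    const mat& o = cc.O.slice(t); const mat& g = cc.G.slice(t);
    const mat& tc = cc.TC.slice(t);
    mat do_ = dh % tc;
    dc += dh % o % cell_act_deriv(tc, act);
    mat di = dc % g;
    mat dg = dc % i;
    mat df = dc % cc.Cprev.slice(t);
    mat dc_prev = dc % f;
    mat dZ(B, 4 * u);
    dZ.cols(0, u - 1)         = di % i % (1.0 - i);
    dZ.cols(u, 2 * u - 1)     = df % f % (1.0 - f);
    dZ.cols(2 * u, 3 * u - 1) = do_ % o % (1.0 - o);
    dZ.cols(3 * u, 4 * u - 1) = dg % cell_act_deriv(g, act);
    gWx += in.slice(t).t() * dZ;
    gWh += cc.Hd.slice(t).t() * dZ;
    gb += sum(dZ, 0);
    mat dh_prev = dZ * Wh.t();
    if (drop) dh_prev %= rmask;
    dh_carry = dh_prev;
    dIn.slice(t) = dZ * Wx.t();
    dc = dc_prev;
  }
  return dIn;
}

// Non-overlapping temporal max pooling; argmax stored for backprop.
static cube pool_forward(const cube& in, int p, ucube* argmax) {
  const uword B = in.n_rows, u = in.n_cols;
  const uword T2 = in.n_slices / p;
  cube out(B, u, T2);
  if (argmax) argmax->set_size(B, u, T2);
  for (uword t = 0; t < T2; ++t) {
    mat m = in.slice(t * p);
    umat am(B, u, fill::zeros);
    for (int k = 1; k < p; ++k) {
      const mat& s = in.slice(t * p + k);
      am.elem(find(s > m)).fill((uword)k);
      m = arma::max(m, s);
    }
    out.slice(t) = m;
    if (argmax) argmax->slice(t) = am;
  }
  return out;
}

static cube pool_backward(const cube& dOut, const ucube& argmax, int p,
                          uword T_in) {
  const uword B = dOut.n_rows, u = dOut.n_cols, T2 = dOut.n_slices;
  cube dIn(B, u, T_in, fill::zeros);
  for (uword t = 0; t < T2; ++t)
    for (uword j = 0; j < u; ++j)
      for (uword i = 0; i < B; ++i)
        dIn(i, j, t * p + argmax(i, j, t)) += dOut(i, j, t);
  return dIn;
}

struct Params {
  std::vector<mat> Wx, Wh;
  std::vector<rowvec> b;
  mat Wd;
  rowvec bd;
};

static Params unpack(const Rcpp::List& params) {
  Params P;
  int n = params.size();
  int L = (n - 2) / 3;
  for (int l = 0; l < L; ++l) {
    P.Wx.push_back(Rcpp::as<mat>(params[3 * l]));
    P.Wh.push_back(Rcpp::as<mat>(params[3 * l + 1]));
    P.b.push_back(Rcpp::as<rowvec>(params[3 * l + 2]));
  }
  P.Wd = Rcpp::as<mat>(params[n - 2]);
  P.bd = Rcpp::as<rowvec>(params[n - 1]);
  return P;
}

static Rcpp::List pack(const Params& P) {
  Rcpp::List out;
  for (size_t l = 0; l < P.Wx.size(); ++l) {
    out.push_back(P.Wx[l]); out.push_back(P.Wh[l]); out.push_back(P.b[l]);
  }
  out.push_back(P.Wd); out.push_back(P.bd);
  return out;
}

// Forward through the whole stack. Sequence layers are all but the
// last; a pool of size `pool` sits after each sequence layer; the last
// layer contributes only its final hidden state, which feeds the dense
// sigmoid head.
static mat stack_forward(const Params& P, const cube& X, int pool, int act,
                         const std::vector<mat>& rmasks,
                         std::vector<LayerCache>* caches,
                         std::vector<cube>* inputs,
                         std::vector<ucube>* argmaxes, mat* hT_out) {
  const size_t L = P.Wx.size();
  cube cur = X;
  for (size_t l = 0; l < L; ++l) {
    if (inputs) inputs->push_back(cur);
    const mat rm = rmasks.empty() ? mat() : rmasks[l];
    LayerCache cc;
    cube H = layer_forward(cur, P.Wx[l], P.Wh[l], P.b[l], act, rm,
                           caches ? &cc : nullptr);
    if (caches) caches->push_back(std::move(cc));
    if (l + 1 < L) {
      ucube am;
      cur = pool_forward(H, pool, argmaxes ? &am : nullptr);
      if (argmaxes) argmaxes->push_back(std::move(am));
      if (cur.n_slices == 0)
        Rcpp::stop("time axis collapsed to zero after pooling");
    } else {
      cur = H;
    }
  }
  mat hT = cur.slice(cur.n_slices - 1);
  if (hT_out) *hT_out = hT;
  mat logits = hT * P.Wd;
  logits.each_row() += P.bd;
  return sigm(logits);
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(Rcpp::List params, arma::cube X, int pool,
                           int act) {
  Params P = unpack(params);
  return stack_forward(P, X, pool, act, {}, nullptr, nullptr, nullptr,
                       nullptr);
}

// Single-layer sequence forward, used to cross-check the recurrence
// against an independent per-step implementation.
// [[Rcpp::export]]
arma::cube lstm_layer_forward_cpp(arma::mat Wx, arma::mat Wh,
                                  arma::rowvec b, arma::cube X, int act) {
  return layer_forward(X, Wx, Wh, b, act, mat(), nullptr);
}

// Temporal max pooling over non-overlapping windows (exposed for
// property tests).
// [[Rcpp::export]]
arma::cube max_pool_cpp(arma::cube X, int p) {
  return pool_forward(X, p, nullptr);
}

static double mse_loss(const mat& yhat, const mat& y) {
  return accu(square(yhat - y)) / yhat.n_elem;
}

static double stack_backward(const Params& P, const cube& X, const mat& Y,
                             int pool, int act,
                             const std::vector<mat>& rmasks, Params& G) {
  std::vector<LayerCache> caches;
  std::vector<cube> inputs;
  std::vector<ucube> argmaxes;
  mat hT;
  mat yhat = stack_forward(P, X, pool, act, rmasks, &caches, &inputs,
                           &argmaxes, &hT);
  const double loss = mse_loss(yhat, Y);
  const size_t L = P.Wx.size();

  mat dyhat = 2.0 * (yhat - Y) / yhat.n_elem;
  mat dlogit = dyhat % yhat % (1.0 - yhat);
  G.Wd = hT.t() * dlogit;
  G.bd = sum(dlogit, 0);
  mat dhT = dlogit * P.Wd.t();

  G.Wx.resize(L); G.Wh.resize(L); G.b.resize(L);
  cube dH(caches[L - 1].H.n_rows, caches[L - 1].H.n_cols,
          caches[L - 1].H.n_slices, fill::zeros);
  dH.slice(dH.n_slices - 1) = dhT;
  for (size_t l = L; l-- > 0;) {
    const mat rm = rmasks.empty() ? mat() : rmasks[l];
    cube dIn = layer_backward(inputs[l], P.Wx[l], P.Wh[l], act, rm,
                              caches[l], dH, G.Wx[l], G.Wh[l], G.b[l]);
    if (l > 0) {
      // dIn is the gradient at the pooled output of layer l-1
      dH = pool_backward(dIn, argmaxes[l - 1], pool,
                         caches[l - 1].H.n_slices);
    }
  }
  return loss;
}

// Loss and gradients without dropout: used by finite-difference checks.
// [[Rcpp::export]]
Rcpp::List lstm_grad_cpp(Rcpp::List params, arma::cube X, arma::mat Y,
                         int pool, int act) {
  Params P = unpack(params);
  Params G;
  double loss = stack_backward(P, X, Y, pool, act, {}, G);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(G));
}

struct AdamState {
  std::vector<mat> m, v;
  double t = 0;
};

static void adam_step(std::vector<mat*>& par, std::vector<mat>& grad,
                      AdamState& st, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  if (st.m.empty()) {
    for (auto* p : par) {
      st.m.push_back(mat(p->n_rows, p->n_cols, fill::zeros));
      st.v.push_back(mat(p->n_rows, p->n_cols, fill::zeros));
    }
  }
  st.t += 1;
  const double c1 = 1.0 - std::pow(b1, st.t);
  const double c2 = 1.0 - std::pow(b2, st.t);
  for (size_t k = 0; k < par.size(); ++k) {
    st.m[k] = b1 * st.m[k] + (1 - b1) * grad[k];
    st.v[k] = b2 * st.v[k] + (1 - b2) * square(grad[k]);
    *par[k] -= lr * (st.m[k] / c1) / (sqrt(st.v[k] / c2) + eps);
  }
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(Rcpp::List params, arma::cube X, arma::mat Y,
                          arma::cube Xval, arma::mat Yval, int pool,
                          int act, double rec_dropout, double lr,
                          int epochs, int batch_size, int patience,
                          bool verbose) {
  Params P = unpack(params);
  const uword n = X.n_rows;
  const size_t L = P.Wx.size();
  const bool has_val = Xval.n_rows > 0;

  // separate Adam states for weight matrices and biases (biases are
  // carried as 1 x n matrices through the shared update)
  AdamState st, stb;

  Rcpp::NumericVector train_hist(epochs), val_hist(epochs);
  double best_val = datum::inf;
  Params best = P;
  int since_best = 0, used_epochs = 0;

  for (int e = 0; e < epochs; ++e) {
    // epoch shuffle from R's RNG
    uvec perm(n);
    {
      Rcpp::IntegerVector idx = Rcpp::sample((int)n, (int)n, false);
      for (uword i = 0; i < n; ++i) perm(i) = idx[i] - 1;
    }
    double epoch_loss = 0; uword seen = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword end = std::min<uword>(start + batch_size, n) - 1;
      uvec sel = perm.subvec(start, end);
      const uword B = sel.n_elem;
      cube Xb(B, X.n_cols, X.n_slices);
      for (uword t = 0; t < X.n_slices; ++t)
        Xb.slice(t) = X.slice(t).rows(sel);
      mat Yb = Y.rows(sel);

      // one recurrent-dropout mask per layer per minibatch, constant
      // across time steps, inverted scaling
      std::vector<mat> rmasks;
      if (rec_dropout > 0) {
        for (size_t l = 0; l < L; ++l) {
          mat m(B, P.Wh[l].n_rows);
          const double keep = 1.0 - rec_dropout;
          for (uword ii = 0; ii < m.n_elem; ++ii)
            m(ii) = (unif_rand() < rec_dropout) ? 0.0 : 1.0 / keep;
          rmasks.push_back(m);
        }
      }
      Params G;
      double loss = stack_backward(P, Xb, Yb, pool, act, rmasks, G);
      epoch_loss += loss * B; seen += B;

      std::vector<mat*> pp; std::vector<mat> gg;
      for (size_t l = 0; l < L; ++l) {
        pp.push_back(&P.Wx[l]); gg.push_back(G.Wx[l]);
        pp.push_back(&P.Wh[l]); gg.push_back(G.Wh[l]);
      }
      pp.push_back(&P.Wd); gg.push_back(G.Wd);
      adam_step(pp, gg, st, lr);
      std::vector<mat> bpar, bgrad;
      for (size_t l = 0; l < L; ++l) {
        bpar.push_back(conv_to<mat>::from(P.b[l]));
        bgrad.push_back(conv_to<mat>::from(G.b[l]));
      }
      bpar.push_back(conv_to<mat>::from(P.bd));
      bgrad.push_back(conv_to<mat>::from(G.bd));
      std::vector<mat*> bpp;
      for (auto& m2 : bpar) bpp.push_back(&m2);
      adam_step(bpp, bgrad, stb, lr);
      for (size_t l = 0; l < L; ++l) P.b[l] = bpar[l].row(0);
      P.bd = bpar[L].row(0);
      Rcpp::checkUserInterrupt();
    }
    train_hist[e] = epoch_loss / seen;

    double vloss = train_hist[e];
    if (has_val) {
      mat yv = stack_forward(P, Xval, pool, act, {}, nullptr, nullptr,
                             nullptr, nullptr);
      vloss = mse_loss(yv, Yval);
    }
    val_hist[e] = vloss;
    used_epochs = e + 1;
    if (vloss < best_val - 1e-6) {
      best_val = vloss; best = P; since_best = 0;
    } else if (++since_best >= patience && patience > 0) {
      break;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << e + 1 << " train " << train_hist[e]
                  << " val " << vloss << "\n";
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = pack(best),
    Rcpp::Named("train_loss") = train_hist[Rcpp::Range(0, used_epochs - 1)],
    Rcpp::Named("val_loss") = val_hist[Rcpp::Range(0, used_epochs - 1)],
    Rcpp::Named("best_val") = best_val,
    Rcpp::Named("epochs_run") = used_epochs);
}
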