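// Two-layer LSTM sequence classifier: batched forward pass, softmax
// cross-entropy loss and full backpropagation through time. The gate
// layout inside each 4H-wide block is [input, forget, candidate, output].
// Dropout between the two recurrent layers uses R's RNG (inverted
// dropout), so training is reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmParams {
  mat W1, U1, W2, U2, Wd;
  rowvec b1, b2, bd;
};

static LstmParams unpack(const Rcpp::List& params) {
  LstmParams p;
  p.W1 = Rcpp::as<mat>(params["W1"]);
  p.U1 = Rcpp::as<mat>(params["U1"]);
  p.b1 = Rcpp::as<rowvec>(params["b1"]);
  p.W2 = Rcpp::as<mat>(params["W2"]);
  p.U2 = Rcpp::as<mat>(params["U2"]);
  p.b2 = Rcpp::as<rowvec>(params["b2"]);
  p.Wd = Rcpp::as<mat>(params["Wd"]);
  p.bd = Rcpp::as<rowvec>(params["bd"]);
  return p;
}

// Per-layer stored activations for BPTT.
struct LayerCache {
  std::vector<mat> i, f, g, o, c, tanhc, h, x;  // per time step
};

// Run one LSTM layer forward over all time steps.
// X: per-step inputs (each B x D). Returns hidden sequence in cache.h.
static void lstm_layer_forward(const std::vector<mat>& X, const mat& W,
                               const mat& U, const rowvec& b, int H,
                               LayerCache& cache) {
  const int T = (int)X.size();
  const int B = (int)X[0].n_rows;
  mat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  cache.i.resize(T); cache.f.resize(T); cache.g.resize(T);
  cache.o.resize(T); cache.c.resize(T); cache.tanhc.resize(T);
  cache.h.resize(T); cache.x = X;
  for (int t = 0; t < T; ++t) {
    mat Z = X[t] * W + h_prev * U;
    Z.each_row() += b;
    mat gi = sigmoid(Z.cols(0, H - 1));
    mat gf = sigmoid(Z.cols(H, 2 * H - 1));
    mat gg = tanh(Z.cols(2 * H, 3 * H - 1));
    mat go = sigmoid(Z.cols(3 * H, 4 * H - 1));
    mat c  = gf % c_prev + gi % gg;
    mat tc = tanh(c);
    mat h  = go % tc;
    cache.i[t] = gi; cache.f[t] = gf; cache.g[t] = gg; cache.o[t] = go;
    cache.c[t] = c; cache.tanhc[t] = tc; cache.h[t] = h;
    h_prev = h; c_prev = c;
  }
}

// Backpropagate one layer. dH_ext: per-step external gradients w.r.t. the
// layer's hidden outputs (may be zero except at the last step). Fills
// gradients and per-step gradients w.r.t. the layer inputs.
static void lstm_layer_backward(const LayerCache& cache, const mat& W,
                                const mat& U, int H,
                                const std::vector<mat>& dH_ext,
                                mat& dW, mat& dU, rowvec& db,
                                std::vector<mat>& dX) {
  const int T = (int)cache.h.size();
  const int B = (int)cache.h[0].n_rows;
  dW.zeros(W.n_rows, W.n_cols);
  dU.zeros(U.n_rows, U.n_cols);
  db.zeros(4 * H);
  dX.assign(T, mat());
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat dh = dH_ext[t] + dh_next;
    const mat& gi = cache.i[t]; const mat& gf = cache.f[t];
    const mat& gg = cache.g[t]; const mat& go = cache.o[t];
    const mat& tc = cache.tanhc[t];
    mat c_prev = (t == 0) ? mat(B, H, fill::zeros) : cache.c[t - 1];
    mat h_prev = (t == 0) ? mat(B, H, fill::zeros) : cache.h[t - 1];
    mat dgo = dh % tc;
    mat dc  = dc_next + dh % go % (1.0 - tc % tc);
    mat dgi = dc % gg;
    mat dgg = dc % gi;
    mat dgf = dc % c_prev;
    dc_next = dc % gf;
    mat dZ(B, 4 * H);
    dZ.cols(0, H - 1)         = dgi % gi % (1.0 - gi);
    dZ.cols(H, 2 * H - 1)     = dgf % gf % (1.0 - gf);
    dZ.cols(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
    dZ.cols(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
    dW += cache.x[t].t() * dZ;
    dU += h_prev.t() * dZ;
    db += sum(dZ, 0);
    dX[t] = dZ * W.t();
    dh_next = dZ * U.t();
  }
}

// Softmax over rows.
static mat softmax_rows(mat logits) {
  logits.each_col() -= max(logits, 1);
  mat e = exp(logits);
  e.each_col() /= sum(e, 1);
  return e;
}

// Forward pass to class probabilities (no dropout; inference path).
// X: cube B x D x T; slices are time steps.
// [[Rcpp::export]]
arma::mat lstm_forward_probs(const arma::cube& X, const Rcpp::List& params) {
  LstmParams p = unpack(params);
  const int T = (int)X.n_slices;
  const int H1 = (int)p.U1.n_rows, H2 = (int)p.U2.n_rows;
  std::vector<mat> x1(T);
  for (int t = 0; t < T; ++t) x1[t] = X.slice(t);
  LayerCache c1, c2;
  lstm_layer_forward(x1, p.W1, p.U1, p.b1, H1, c1);
  lstm_layer_forward(c1.h, p.W2, p.U2, p.b2, H2, c2);
  mat logits = c2.h[T - 1] * p.Wd;
  logits.each_row() += p.bd;
  return softmax_rows(logits);
}

// Loss and gradients for one minibatch.
// X: cube B x D x T; y: 1-based class index per batch row; dropout_p in
// [0,1) applied between the layers (inverted dropout, drawn from R's RNG
// when train = true).
// [[Rcpp::export]]
Rcpp::List lstm_loss_grad(const arma::cube& X,
                          const arma::ivec& y,
                          const Rcpp::List& params,
                          const double dropout_p,
                          const bool train) {
  LstmParams p = unpack(params);
  const int T = (int)X.n_slices;
  const int B = (int)X.n_rows;
  const int H1 = (int)p.U1.n_rows, H2 = (int)p.U2.n_rows;
  const int K = (int)p.Wd.n_cols;

  std::vector<mat> x1(T);
  for (int t = 0; t < T; ++t) x1[t] = X.slice(t);
  LayerCache c1;
  lstm_layer_forward(x1, p.W1, p.U1, p.b1, H1, c1);

  // dropout on the inter-layer connection only (not the recurrence)
  std::vector<mat> mask(T), x2(T);
  for (int t = 0; t < T; ++t) {
    if (train && dropout_p > 0.0) {
      mat m(B, H1);
      for (uword j = 0; j < m.n_elem; ++j) {
        m(j) = (R::unif_rand() < dropout_p) ? 0.0 : 1.0 / (1.0 - dropout_p);
      }
      mask[t] = m;
      x2[t] = c1.h[t] % m;
    } else {
      mask[t] = mat(B, H1, fill::ones);
      x2[t] = c1.h[t];
    }
  }

  LayerCache c2;
  lstm_layer_forward(x2, p.W2, p.U2, p.b2, H2, c2);

  mat logits = c2.h[T - 1] * p.Wd;
  logits.each_row() += p.bd;
  mat probs = softmax_rows(logits);

  double loss = 0.0;
  mat dlogits = probs;
  for (int i = 0; i < B; ++i) {
    const int k = y(i) - 1;
    loss -= std::log(std::max(probs(i, k), 1e-300));
    dlogits(i, k) -= 1.0;
  }
  loss /= B;
  dlogits /= B;

  mat dWd = c2.h[T - 1].t() * dlogits;
  rowvec dbd = sum(dlogits, 0);
  mat dH2T = dlogits * p.Wd.t();

  std::vector<mat> dH2_ext(T, mat(B, H2, fill::zeros));
  dH2_ext[T - 1] = dH2T;
  mat dW2, dU2; rowvec db2; std::vector<mat> dX2;
  lstm_layer_backward(c2, p.W2, p.U2, H2, dH2_ext, dW2, dU2, db2, dX2);

  std::vector<mat> dH1_ext(T);
  for (int t = 0; t < T; ++t) dH1_ext[t] = dX2[t] % mask[t];
  mat dW1, dU1; rowvec db1; std::vector<mat> dX1;
  lstm_layer_backward(c1, p.W1, p.U1, H1, dH1_ext, dW1, dU1, db1, dX1);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("probs") = probs,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = dW1, Rcpp::Named("U1") = dU1,
      Rcpp::Named("b1") = db1, Rcpp::Named("W2") = dW2,
      Rcpp::Named("U2") = dU2, Rcpp::Named("b2") = db2,
      Rcpp::Named("Wd") = dWd, Rcpp::Named("bd") = dbd));
}
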