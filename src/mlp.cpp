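// Minimal feed-forward network used by the behavioral-state classifier:
// fully connected ReLU layers, softmax output, categorical cross-entropy
// with an L2 weight penalty, trained by minibatch Adam. A private mt19937
// stream (seeded per call) drives initialization and batch shuffling so
// training is reproducible and independent of R's RNG state.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat relu(const arma::mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

static arma::mat softmax_rows(const arma::mat& z) {
  arma::mat s = z.each_col() - arma::max(z, 1);
  s = arma::exp(s);
  s.each_col() /= arma::sum(s, 1);
  return s;
}

// Forward pass through all layers; activations returned when requested.
static arma::mat forward(const arma::mat& X,
                         const std::vector<arma::mat>& W,
                         const std::vector<arma::rowvec>& b,
                         std::vector<arma::mat>* acts = nullptr) {
  arma::mat a = X;
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    arma::mat z = a * W[l];
    z.each_row() += b[l];
    a = (l + 1 == L) ? softmax_rows(z) : relu(z);
    if (acts) acts->push_back(a);
  }
  return a;
}

// Glorot-uniform initialization of one weight set.
// [[Rcpp::export(name = ".mlp_init")]]
List mlp_init(int n_in, IntegerVector hidden, int n_out, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<int> dims;
  dims.push_back(n_in);
  for (int h : hidden) dims.push_back(h);
  dims.push_back(n_out);
  List Ws(dims.size() - 1), bs(dims.size() - 1);
  for (size_t l = 0; l + 1 < dims.size(); ++l) {
    double lim = std::sqrt(6.0 / (dims[l] + dims[l + 1]));
    std::uniform_real_distribution<double> unif(-lim, lim);
    arma::mat w(dims[l], dims[l + 1]);
    for (arma::uword j = 0; j < w.n_cols; ++j)
      for (arma::uword i = 0; i < w.n_rows; ++i) w(i, j) = unif(rng);
    Ws[l] = w;
    bs[l] = arma::rowvec(dims[l + 1], arma::fill::zeros);
  }
  return List::create(_["W"] = Ws, _["b"] = bs);
}

static void unpack(const List& weights, std::vector<arma::mat>& W,
                   std::vector<arma::rowvec>& b) {
  List Ws = weights["W"], bs = weights["b"];
  for (int l = 0; l < Ws.size(); ++l) {
    W.push_back(as<arma::mat>(Ws[l]));
    b.push_back(as<arma::rowvec>(bs[l]));
  }
}

// [[Rcpp::export(name = ".mlp_forward")]]
arma::mat mlp_forward(const arma::mat& X, List weights) {
  std::vector<arma::mat> W; std::vector<arma::rowvec> b;
  unpack(weights, W, b);
  return forward(X, W, b);
}

// Minibatch Adam on categorical cross-entropy + l2 * sum(w^2) (biases
// excluded from the penalty). y is 0-based class index. Returns final
// weights plus per-pass mean training loss and full-set accuracy.
// [[Rcpp::export(name = ".mlp_train")]]
List mlp_train(const arma::mat& X, const arma::ivec& y, List weights,
               double lr, double l2, int passes, int batch_size, int seed) {
  std::vector<arma::mat> W; std::vector<arma::rowvec> b;
  unpack(weights, W, b);
  const size_t L = W.size();
  const arma::uword n = X.n_rows;
  const arma::uword k = W[L - 1].n_cols;

  arma::mat Y(n, k, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) Y(i, y[i]) = 1.0;

  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(W[l])); vW[l].zeros(arma::size(W[l]));
    mb[l].zeros(arma::size(b[l])); vb[l].zeros(arma::size(b[l]));
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  arma::vec pass_loss(passes), pass_acc(passes);

  for (int pass = 0; pass < passes; ++pass) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int n_batches = 0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword last = std::min<arma::uword>(start + batch_size, n) - 1;
      arma::uvec idx(last - start + 1);
      for (arma::uword i = start; i <= last; ++i) idx[i - start] = order[i];
      arma::mat Xb = X.rows(idx), Yb = Y.rows(idx);
      const double m = static_cast<double>(Xb.n_rows);

      std::vector<arma::mat> acts;
      arma::mat P = forward(Xb, W, b, &acts);

      double ce = -arma::accu(Yb % arma::log(P + 1e-12)) / m;
      double pen = 0.0;
      for (size_t l = 0; l < L; ++l) pen += arma::accu(arma::square(W[l]));
      loss_sum += ce + l2 * pen;
      ++n_batches;
      if (!std::isfinite(ce)) Rcpp::stop("training loss is not finite; check feature scaling / learning rate");

      // backprop: delta at softmax+CE is (P - Y)/m
      arma::mat delta = (P - Yb) / m;
      ++t;
      const double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
      for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
        const arma::mat& a_prev = (l == 0) ? Xb : acts[l - 1];
        arma::mat gW = a_prev.t() * delta + 2.0 * l2 * W[l];
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<arma::mat>::from(acts[l - 1] > 0);
        }
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * arma::square(gW);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gb);
        W[l] -= lr * (mW[l] / bc1) / (arma::sqrt(vW[l] / bc2) + eps);
        b[l] -= lr * (mb[l] / bc1) / (arma::sqrt(vb[l] / bc2) + eps);
      }
    }
    pass_loss[pass] = loss_sum / n_batches;
    arma::mat P = forward(X, W, b);
    arma::uvec pred = arma::index_max(P, 1);
    double acc = 0.0;
    for (arma::uword i = 0; i < n; ++i) if (pred[i] == static_cast<arma::uword>(y[i])) acc += 1.0;
    pass_acc[pass] = acc / n;
  }

  List Ws(L), bs(L);
  for (size_t l = 0; l < L; ++l) { Ws[l] = W[l]; bs[l] = b[l]; }
  return List::create(_["W"] = Ws, _["b"] = bs,
                      _["loss"] = pass_loss, _["accuracy"] = pass_acc);
}
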