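// Windowed dense network: forward passes, Monte Carlo dropout passes and
// mini-batch Adam training. All randomness (batch shuffling, dropout masks)
// is drawn from R's RNG so results are reproducible from set.seed() on the
// R side, single-threaded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct NetParams {
  std::vector<arma::mat> Wb;  // per-window block weights (w x u)
  std::vector<arma::rowvec> bb;
  arma::mat Wh;               // concat x head
  arma::rowvec bh;
  arma::vec Wo;               // head x 1
  double bo;
};

NetParams unpack(const List& weights) {
  NetParams P;
  List Wb = weights["W_blocks"], bb = weights["b_blocks"];
  for (int k = 0; k < Wb.size(); ++k) {
    P.Wb.push_back(as<arma::mat>(Wb[k]));
    P.bb.push_back(as<arma::rowvec>(bb[k]));
  }
  P.Wh = as<arma::mat>(weights["W_head"]);
  P.bh = as<arma::rowvec>(weights["b_head"]);
  P.Wo = as<arma::vec>(weights["W_out"]);
  P.bo = as<double>(weights["b_out"]);
  return P;
}

List pack(const NetParams& P) {
  List Wb(P.Wb.size()), bb(P.bb.size());
  for (size_t k = 0; k < P.Wb.size(); ++k) {
    Wb[k] = wrap(P.Wb[k]);
    bb[k] = wrap(P.bb[k]);
  }
  return List::create(_["W_blocks"] = Wb, _["b_blocks"] = bb,
                      _["W_head"] = P.Wh, _["b_head"] = P.bh,
                      _["W_out"] = P.Wo, _["b_out"] = P.bo);
}

arma::mat bernoulli_mask(arma::uword r, arma::uword c, double keep) {
  arma::mat M(r, c);
  for (arma::uword j = 0; j < c; ++j)
    for (arma::uword i = 0; i < r; ++i)
      M(i, j) = (unif_rand() < keep) ? 1.0 : 0.0;
  return M;
}

// Forward pass through the network. mode: 0 = deterministic (dropout scaled
// into activations), 1 = stochastic (Bernoulli mask, used for training and
// MC-dropout inference). Intermediate activations are written to the
// pointers when non-null (training needs them for backprop).
arma::vec forward(const arma::mat& X, const arma::imat& windows,
                  const NetParams& P, double p, int dropout_site, int mode,
                  bool sigmoid_out,
                  arma::mat* Xin_out = nullptr, arma::mat* H_out = nullptr,
                  arma::mat* A_out = nullptr, arma::mat* maskH_out = nullptr,
                  arma::mat* maskX_out = nullptr) {
  const arma::uword B = X.n_rows;
  const int K = windows.n_rows;
  const arma::uword u = P.Wb[0].n_cols;
  arma::mat Xin = X;
  if (p > 0 && dropout_site == 1) {
    if (mode == 1) {
      arma::mat M = bernoulli_mask(B, X.n_cols, 1.0 - p);
      Xin %= M;
      if (maskX_out) *maskX_out = M;
    } else {
      Xin *= (1.0 - p);
    }
  }
  arma::mat H(B, K * u);
  for (int k = 0; k < K; ++k) {
    arma::mat Hk = Xin.cols(windows(k, 0), windows(k, 1)) * P.Wb[k];
    Hk.each_row() += P.bb[k];
    H.cols(k * u, (k + 1) * u - 1) = arma::clamp(Hk, 0.0, arma::datum::inf);
  }
  arma::mat A = H * P.Wh;
  A.each_row() += P.bh;
  A = arma::clamp(A, 0.0, arma::datum::inf);
  if (p > 0 && dropout_site == 0) {
    if (mode == 1) {
      arma::mat M = bernoulli_mask(B, A.n_cols, 1.0 - p);
      A %= M;
      if (maskH_out) *maskH_out = M;
    } else {
      A *= (1.0 - p);
    }
  }
  arma::vec z = A * P.Wo + P.bo;
  if (Xin_out) *Xin_out = Xin;
  if (H_out) *H_out = H;
  if (A_out) *A_out = A;
  if (sigmoid_out) z = 1.0 / (1.0 + arma::exp(-z));
  return z;
}

}  // namespace

// [[Rcpp::export]]
arma::vec cpp_net_forward(const arma::mat& X, const arma::imat& windows,
                          const List& weights, double p, int dropout_site,
                          bool stochastic, bool sigmoid_out) {
  NetParams P = unpack(weights);
  return forward(X, windows, P, p, dropout_site, stochastic ? 1 : 0,
                 sigmoid_out);
}

// [[Rcpp::export]]
arma::mat cpp_net_mc(const arma::mat& X, const arma::imat& windows,
                     const List& weights, double p, int dropout_site,
                     int T, bool sigmoid_out) {
  NetParams P = unpack(weights);
  arma::mat out(X.n_rows, T);
  for (int t = 0; t < T; ++t)
    out.col(t) = forward(X, windows, P, p, dropout_site, 1, sigmoid_out);
  return out;
}

// [[Rcpp::export]]
List cpp_net_train(const arma::mat& X, const arma::vec& y,
                   const arma::imat& windows, const List& weights,
                   double p, int dropout_site, int epochs, int batch_size,
                   double lr, bool sigmoid_out) {
  if (!sigmoid_out)
    stop("training requires the sigmoid output head");
  NetParams P = unpack(weights);
  const int n = X.n_rows;
  const int K = windows.n_rows;
  const arma::uword u = P.Wb[0].n_cols;

  // Adam state, one slot per parameter tensor (blocks, head, out).
  std::vector<arma::mat> mWb(K), vWb(K);
  std::vector<arma::rowvec> mbb(K), vbb(K);
  for (int k = 0; k < K; ++k) {
    mWb[k].zeros(P.Wb[k].n_rows, P.Wb[k].n_cols); vWb[k] = mWb[k];
    mbb[k].zeros(P.bb[k].n_cols); vbb[k] = mbb[k];
  }
  arma::mat mWh(arma::size(P.Wh), arma::fill::zeros), vWh = mWh;
  arma::rowvec mbh(P.bh.n_cols, arma::fill::zeros), vbh = mbh;
  arma::vec mWo(P.Wo.n_rows, arma::fill::zeros), vWo = mWo;
  double mbo = 0, vbo = 0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  arma::vec loss_log(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0; int n_batches = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      int B = end - start;
      arma::uvec rows(B);
      for (int i = 0; i < B; ++i) rows[i] = idx[start + i];
      arma::mat Xb = X.rows(rows);
      arma::vec yb = y.elem(rows);

      arma::mat Xin, H, A, maskH, maskX;
      arma::vec prob = forward(Xb, windows, P, p, dropout_site, 1,
                               true, &Xin, &H, &A, &maskH, &maskX);
      arma::vec pc = arma::clamp(prob, 1e-12, 1.0 - 1e-12);
      double loss = -arma::mean(yb % arma::log(pc) +
                                (1.0 - yb) % arma::log(1.0 - pc));
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d", ep + 1);
      ep_loss += loss; ++n_batches;

      // backprop (sigmoid + binary cross-entropy)
      arma::vec dz = (prob - yb) / B;
      arma::vec gWo = A.t() * dz;
      double gbo = arma::accu(dz);
      arma::mat dA = dz * P.Wo.t();
      if (p > 0 && dropout_site == 0) dA %= maskH;
      dA %= arma::conv_to<arma::mat>::from(A > 0);
      arma::mat gWh = H.t() * dA;
      arma::rowvec gbh = arma::sum(dA, 0);
      arma::mat dH = dA * P.Wh.t();
      dH %= arma::conv_to<arma::mat>::from(H > 0);

      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      auto adam = [&](arma::mat& W, const arma::mat& g,
                      arma::mat& m, arma::mat& v) {
        m = b1 * m + (1 - b1) * g;
        v = b2 * v + (1 - b2) * arma::square(g);
        W -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
      };
      for (int k = 0; k < K; ++k) {
        arma::mat dHk = dH.cols(k * u, (k + 1) * u - 1);
        arma::mat gW = Xin.cols(windows(k, 0), windows(k, 1)).t() * dHk;
        arma::rowvec gb = arma::sum(dHk, 0);
        adam(P.Wb[k], gW, mWb[k], vWb[k]);
        arma::mat mb = mbb[k], vb = vbb[k], bb = P.bb[k];
        adam(bb, gb, mb, vb);
        P.bb[k] = bb; mbb[k] = mb; vbb[k] = vb;
      }
      adam(P.Wh, gWh, mWh, vWh);
      { arma::mat bh = P.bh, mb = mbh, vb = vbh;
        adam(bh, gbh, mb, vb);
        P.bh = bh; mbh = mb; vbh = vb; }
      { arma::mat Wo = P.Wo, mo = mWo, vo = vWo;
        adam(Wo, gWo, mo, vo);
        P.Wo = Wo; mWo = mo; vWo = vo; }
      mbo = b1 * mbo + (1 - b1) * gbo;
      vbo = b2 * vbo + (1 - b2) * gbo * gbo;
      P.bo -= lr * (mbo / c1) / (std::sqrt(vbo / c2) + eps);
    }
    loss_log[ep] = ep_loss / n_batches;
  }
  return List::create(_["weights"] = pack(P), _["loss"] = loss_log);
}
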