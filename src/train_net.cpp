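// Minibatch Adam trainer for the pairwise knockoff-filter network.
//
// Architecture (p input features, each paired with its knockoff copy):
//   filter:  z_j = ri_j * x_j + rti_j * xt_j          (one unit per pair)
//   scale :  u_j = w0_j * z_j                          (element-wise)
//   dense :  h1  = relu(W1' u + b1)                    (p units)
//   dense :  h2  = relu(W2' h1 + b2)                   (p units)
//   output:  yhat = w3' h2 + b3                        (linear)
//
// W1[j,k] is the weight from u_j to h1_k, so the downstream path vector
// used for importances is w0 % (W1 * W2 * w3). L1 regularization applies
// to all weights (not biases) via its subgradient added to the minibatch
// gradient, matching the penalized-loss training described for the method.

#include <RcppArmadillo.h>
#include <random>

using namespace arma;

static inline mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }

struct AdamState {
  mat m, v;
  AdamState(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
};

static inline void adam_step(mat& w, const mat& g, AdamState& st, double lr,
                             double b1, double b2, double eps, double b1t,
                             double b2t) {
  st.m = b1 * st.m + (1.0 - b1) * g;
  st.v = b2 * st.v + (1.0 - b2) * square(g);
  w -= lr * (st.m / (1.0 - b1t)) / (sqrt(st.v / (1.0 - b2t)) + eps);
}

// [[Rcpp::export(name = ".train_pairwise_net")]]
Rcpp::List train_pairwise_net(const arma::mat& Xt,   // p x N originals
                              const arma::mat& Xkt,  // p x N knockoffs
                              const arma::vec& y,    // length N response
                              arma::vec ri, arma::vec rti, arma::vec w0,
                              arma::mat W1, arma::vec b1, arma::mat W2,
                              arma::vec b2, arma::vec w3, double b3,
                              double l1, double lr, int batch, int epochs,
                              unsigned int seed) {
  const uword p = Xt.n_rows, N = Xt.n_cols;
  if (Xkt.n_rows != p || Xkt.n_cols != N || y.n_elem != N)
    Rcpp::stop("shape mismatch between inputs, knockoffs and response");
  if (batch < 1) batch = 1;

  const double ab1 = 0.9, ab2 = 0.999, eps = 1e-8;
  AdamState s_ri(p, 1), s_rti(p, 1), s_w0(p, 1), s_W1(p, p), s_b1(p, 1),
      s_W2(p, p), s_b2(p, 1), s_w3(p, 1), s_b3(1, 1);
  mat mb3(1, 1);
  mb3(0, 0) = b3;

  std::mt19937 rng(seed);
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;

  vec loss_trace(epochs, fill::zeros);
  double b1t = 1.0, b2t = 1.0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    uword n_batches = 0;
    for (uword start = 0; start < N; start += (uword)batch) {
      uword stop = std::min(start + (uword)batch, N);
      uword B = stop - start;
      uvec take(B);
      for (uword i = 0; i < B; ++i) take[i] = idx[start + i];

      mat Xb = Xt.cols(take), Xkb = Xkt.cols(take);
      rowvec yb = y.elem(take).t();

      // forward
      mat Z = Xb.each_col() % ri + Xkb.each_col() % rti;  // p x B
      mat U = Z.each_col() % w0;
      mat A1 = W1.t() * U;
      A1.each_col() += b1;
      mat H1 = relu(A1);
      mat A2 = W2.t() * H1;
      A2.each_col() += b2;
      mat H2 = relu(A2);
      rowvec yhat = w3.t() * H2 + mb3(0, 0);

      rowvec err = yhat - yb;
      ep_loss += dot(err, err) / B;
      ++n_batches;

      // backward (MSE averaged over the minibatch)
      rowvec dy = 2.0 * err / (double)B;          // 1 x B
      vec g_w3 = H2 * dy.t();                     // p x 1
      double g_b3 = accu(dy);
      mat dH2 = w3 * dy;                          // p x B
      mat dA2 = dH2 % conv_to<mat>::from(A2 > 0.0);
      mat g_W2 = H1 * dA2.t();                    // p x p (from, to)
      vec g_b2 = sum(dA2, 1);
      mat dH1 = W2 * dA2;
      mat dA1 = dH1 % conv_to<mat>::from(A1 > 0.0);
      mat g_W1 = U * dA1.t();
      vec g_b1 = sum(dA1, 1);
      mat dU = W1 * dA1;                          // p x B
      vec g_w0 = sum(dU % Z, 1);
      mat dZ = dU.each_col() % w0;
      vec g_ri = sum(dZ % Xb, 1);
      vec g_rti = sum(dZ % Xkb, 1);

      if (l1 > 0.0) {
        g_ri += l1 * sign(ri);
        g_rti += l1 * sign(rti);
        g_w0 += l1 * sign(w0);
        g_W1 += l1 * sign(W1);
        g_W2 += l1 * sign(W2);
        g_w3 += l1 * sign(w3);
      }

      b1t *= ab1;
      b2t *= ab2;
      adam_step(ri, g_ri, s_ri, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(rti, g_rti, s_rti, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(w0, g_w0, s_w0, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(W1, g_W1, s_W1, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(b1, g_b1, s_b1, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(W2, g_W2, s_W2, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(b2, g_b2, s_b2, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(w3, g_w3, s_w3, lr, ab1, ab2, eps, b1t, b2t);
      adam_step(mb3, mat(1, 1, fill::value(g_b3)), s_b3, lr, ab1, ab2, eps, b1t, b2t);

      if (!std::isfinite(ep_loss))
        Rcpp::stop("non-finite training loss at epoch %d; reduce the learning rate",
                   ep + 1);
    }
    loss_trace[ep] = ep_loss / std::max<uword>(n_batches, 1);
  }

  return Rcpp::List::create(
      Rcpp::Named("ri") = ri, Rcpp::Named("rti") = rti,
      Rcpp::Named("w0") = w0, Rcpp::Named("W1") = W1,
      Rcpp::Named("b1") = b1, Rcpp::Named("W2") = W2,
      Rcpp::Named("b2") = b2, Rcpp::Named("w3") = w3,
      Rcpp::Named("b3") = mb3(0, 0), Rcpp::Named("loss_trace") = loss_trace);
}
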