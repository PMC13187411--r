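// Feed-forward MLP trainer: ReLU hidden layers, linear output, mean-squared
// error, adaptive-moment updates with decoupled L2 weight decay, and a step
// learning-rate schedule. Lives in C++ because the per-step optimizer update
// is memory-bound and dominates runtime in interpreted code. All randomness
// (weight init, batch shuffles) comes from R's RNG so set.seed() gives
// bit-reproducible training.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::rowvec;

static mat he_init(int nin, int nout) {
  mat W(nin, nout);
  const double s = std::sqrt(2.0 / nin);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    for (arma::uword i = 0; i < W.n_rows; ++i)
      W(i, j) = s * R::norm_rand();
  return W;
}

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                         const arma::ivec& hidden,
                         double lr, double weight_decay,
                         int sched_step, double sched_gamma,
                         int batch_size, int epochs) {
  const int n = X.n_rows, p = X.n_cols, q = Y.n_cols;
  const int L = hidden.n_elem + 1;          // weight layers
  std::vector<int> sizes(L + 1);
  sizes[0] = p;
  for (int l = 0; l < (int)hidden.n_elem; ++l) sizes[l + 1] = hidden[l];
  sizes[L] = q;

  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = he_init(sizes[l], sizes[l + 1]);
    b[l] = rowvec(sizes[l + 1], arma::fill::zeros);
    mW[l] = mat(sizes[l], sizes[l + 1], arma::fill::zeros);
    vW[l] = mW[l];
    mb[l] = rowvec(sizes[l + 1], arma::fill::zeros);
    vb[l] = mb[l];
  }

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double t = 0.0;
  arma::vec loss(epochs, arma::fill::zeros);
  int diverged_epoch = -1;

  std::vector<mat> A(L + 1), Z(L);
  arma::uvec perm(n);

  for (int ep = 0; ep < epochs && diverged_epoch < 0; ++ep) {
    const double cur_lr = lr * std::pow(sched_gamma, ep / sched_step);
    // Fisher-Yates with R's RNG
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double ep_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(s + batch_size, n) - 1;
      const arma::uvec idx = perm.subvec(s, e);
      const int m = e - s + 1;
      A[0] = X.rows(idx);
      for (int l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l < L - 1) ? arma::clamp(Z[l], 0.0, arma::datum::inf) : Z[l];
      }
      mat delta = A[L] - Y.rows(idx);
      const double batch_loss = arma::accu(arma::square(delta)) / (m * q);
      ep_loss += batch_loss;
      ++nb;
      if (!std::isfinite(batch_loss)) { diverged_epoch = ep + 1; break; }
      delta *= 2.0 / (m * q);
      t += 1.0;
      const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
      for (int l = L - 1; l >= 0; --l) {
        const mat gW = A[l].t() * delta;
        const rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<mat>::from(Z[l - 1] > 0.0);
        }
        mW[l] = b1 * mW[l] + (1.0 - b1) * gW;
        vW[l] = b2 * vW[l] + (1.0 - b2) * arma::square(gW);
        mb[l] = b1 * mb[l] + (1.0 - b1) * gb;
        vb[l] = b2 * vb[l] + (1.0 - b2) * arma::square(gb);
        W[l] -= cur_lr * ((mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps)
                          + weight_decay * W[l]);
        b[l] -= cur_lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    loss[ep] = ep_loss / std::max(nb, 1);
  }

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = Rcpp::wrap(W[l]);
    bout[l] = Rcpp::wrap(arma::conv_to<arma::vec>::from(b[l]));
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("diverged_epoch") = diverged_epoch);
}
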