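// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Full-batch Adam training of a fully connected network
//   inputs (n x p) -> relu(hidden) -> relu(hidden) -> sigmoid -> (n)
// on [0,1]-scaled features and targets. loss = "bce" gives binary cross
// entropy on the scaled target (gradient at the logit: (p - y)/n, the
// proper-scoring form); loss = "mse" gives mean squared error on the
// sigmoid output. Initial weights are supplied by the caller so that all
// randomness stays under R's RNG.
// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y, List init,
                   double lr, int epochs, std::string loss,
                   double beta1 = 0.9, double beta2 = 0.999,
                   double eps = 1e-8) {
  arma::mat W1 = as<arma::mat>(init["W1"]);
  arma::rowvec b1 = as<arma::rowvec>(init["b1"]);
  arma::mat W2 = as<arma::mat>(init["W2"]);
  arma::rowvec b2 = as<arma::rowvec>(init["b2"]);
  arma::vec W3 = as<arma::vec>(init["W3"]);
  double b3 = as<double>(init["b3"]);

  const int n = X.n_rows;
  const bool bce = (loss == "bce");

  // Adam moment buffers
  arma::mat mW1(arma::size(W1), arma::fill::zeros), vW1 = mW1;
  arma::rowvec mb1(arma::size(b1), arma::fill::zeros), vb1 = mb1;
  arma::mat mW2(arma::size(W2), arma::fill::zeros), vW2 = mW2;
  arma::rowvec mb2(arma::size(b2), arma::fill::zeros), vb2 = mb2;
  arma::vec mW3(arma::size(W3), arma::fill::zeros), vW3 = mW3;
  double mb3 = 0.0, vb3 = 0.0;

  arma::vec loss_hist(epochs, arma::fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    // forward
    arma::mat Z1 = X * W1;
    Z1.each_row() += b1;
    arma::mat A1 = arma::clamp(Z1, 0.0, arma::datum::inf);
    arma::mat Z2 = A1 * W2;
    Z2.each_row() += b2;
    arma::mat A2 = arma::clamp(Z2, 0.0, arma::datum::inf);
    arma::vec z3 = A2 * W3 + b3;
    arma::vec p = 1.0 / (1.0 + arma::exp(-z3));

    if (bce) {
      arma::vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
      loss_hist(ep) =
          arma::mean(-(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc)));
    } else {
      loss_hist(ep) = arma::mean(arma::square(p - y));
    }

    // backward (gradient at the pre-sigmoid logit)
    arma::vec dz3;
    if (bce) dz3 = (p - y) / (double)n;
    else dz3 = 2.0 * (p - y) % p % (1.0 - p) / (double)n;

    arma::vec gW3 = A2.t() * dz3;
    double gb3 = arma::accu(dz3);
    arma::mat dA2 = dz3 * W3.t();
    arma::mat dZ2 = dA2 % arma::conv_to<arma::mat>::from(Z2 > 0.0);
    arma::mat gW2 = A1.t() * dZ2;
    arma::rowvec gb2 = arma::sum(dZ2, 0);
    arma::mat dA1 = dZ2 * W2.t();
    arma::mat dZ1 = dA1 % arma::conv_to<arma::mat>::from(Z1 > 0.0);
    arma::mat gW1 = X.t() * dZ1;
    arma::rowvec gb1 = arma::sum(dZ1, 0);

    // Adam update
    const double t = (double)(ep + 1);
    const double bc1 = 1.0 - std::pow(beta1, t);
    const double bc2 = 1.0 - std::pow(beta2, t);
#define ADAM(param, m, v, g)                                   \
    m = beta1 * m + (1.0 - beta1) * (g);                       \
    v = beta2 * v + (1.0 - beta2) * arma::square(g);           \
    param -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
    ADAM(W1, mW1, vW1, gW1)
    ADAM(b1, mb1, vb1, gb1)
    ADAM(W2, mW2, vW2, gW2)
    ADAM(b2, mb2, vb2, gb2)
    ADAM(W3, mW3, vW3, gW3)
#undef ADAM
    mb3 = beta1 * mb3 + (1.0 - beta1) * gb3;
    vb3 = beta2 * vb3 + (1.0 - beta2) * gb3 * gb3;
    b3 -= lr * (mb3 / bc1) / (std::sqrt(vb3 / bc2) + eps);
  }

  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                      _["W3"] = W3, _["b3"] = b3,
                      _["loss_history"] = loss_hist);
}
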