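#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Online backpropagation with momentum for a 1-hidden-layer log-sigmoid
// network. `order` holds the 1-based row visiting order, one row per epoch.
// Loss is 0.5 * (y - t)^2 per sample; updates are
//   dw = -lr * grad + momentum * dw_prev
// applied after every sample, with the momentum buffer persisting across
// samples and epochs. The per-epoch MSE records the pre-update prediction
// error of each visited sample.
// [[Rcpp::export]]
List cpp_bpnn_train(NumericMatrix X, NumericVector y,
                    NumericMatrix W1, NumericVector b1,
                    NumericVector W2, double b2,
                    double lr, double momentum,
                    IntegerMatrix order) {
  const int n = X.nrow(), p = X.ncol(), h = W1.nrow();
  const int epochs = order.nrow();
  if (order.ncol() != n) stop("order must have one column per sample");

  NumericMatrix w1 = clone(W1);
  NumericVector v1 = clone(b1);
  NumericVector w2 = clone(W2);
  double v2 = b2;

  std::vector<double> dW1p(h * p, 0.0), db1p(h, 0.0), dW2p(h, 0.0);
  double db2p = 0.0;
  std::vector<double> hid(h), delta1(h);
  NumericVector mse(epochs);

  for (int e = 0; e < epochs; ++e) {
    double sse = 0.0;
    for (int s = 0; s < n; ++s) {
      const int i = order(e, s) - 1;
      // forward
      for (int j = 0; j < h; ++j) {
        double z = v1[j];
        for (int k = 0; k < p; ++k) z += w1(j, k) * X(i, k);
        hid[j] = sigmoid(z);
      }
      double z2 = v2;
      for (int j = 0; j < h; ++j) z2 += w2[j] * hid[j];
      const double yhat = sigmoid(z2);
      const double err = yhat - y[i];
      sse += err * err;
      // backward
      const double delta2 = err * yhat * (1.0 - yhat);
      for (int j = 0; j < h; ++j)
        delta1[j] = delta2 * w2[j] * hid[j] * (1.0 - hid[j]);
      // momentum updates
      for (int j = 0; j < h; ++j) {
        double d = -lr * delta2 * hid[j] + momentum * dW2p[j];
        dW2p[j] = d;
        w2[j] += d;
      }
      {
        double d = -lr * delta2 + momentum * db2p;
        db2p = d;
        v2 += d;
      }
      for (int j = 0; j < h; ++j) {
        for (int k = 0; k < p; ++k) {
          double d = -lr * delta1[j] * X(i, k) + momentum * dW1p[j * p + k];
          dW1p[j * p + k] = d;
          w1(j, k) += d;
        }
        double d = -lr * delta1[j] + momentum * db1p[j];
        db1p[j] = d;
        v1[j] += d;
      }
    }
    mse[e] = sse / n;
    if (!std::isfinite(mse[e]))
      stop("non-finite training error at epoch %d", e + 1);
  }
  return List::create(_["W1"] = w1, _["b1"] = v1, _["W2"] = w2,
                      _["b2"] = v2, _["mse"] = mse);
}
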