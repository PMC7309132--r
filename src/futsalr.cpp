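// Compiled kernels: brute-force k-NN search and the LSTM cell
// forward/backward (BPTT) used by the sequence classifier.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// k nearest training rows (Euclidean) for each query row, computed in
// query blocks via the expansion |x - q|^2 = |x|^2 - 2 x.q + |q|^2 so the
// cross terms go through BLAS. Distance ties are broken by training
// order: scanning ascends through training indices and a stored
// neighbour is only displaced on a strictly smaller distance.
// [[Rcpp::export]]
IntegerMatrix knn_neighbors_cpp(const arma::mat& X, const arma::mat& Q,
                                int k) {
  const int n = X.n_rows, m = Q.n_rows;
  if (k > n) k = n;
  IntegerMatrix out(m, k);
  arma::vec xn = arma::sum(arma::square(X), 1);
  const int block = 256;
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (int q0 = 0; q0 < m; q0 += block) {
    const int q1 = std::min(q0 + block, m) - 1;
    arma::mat cross = X * Q.rows(q0, q1).t();   // n x block
    for (int qi = q0; qi <= q1; ++qi) {
      const double* cr = cross.colptr(qi - q0);
      int filled = 0;
      for (int ti = 0; ti < n; ++ti) {
        const double dist = xn(ti) - 2.0 * cr[ti];
        if (filled < k || dist < bd[k - 1]) {
          int pos = (filled < k) ? filled++ : k - 1;
          while (pos > 0 && bd[pos - 1] > dist) {
            bd[pos] = bd[pos - 1]; bi[pos] = bi[pos - 1]; --pos;
          }
          bd[pos] = dist; bi[pos] = ti;
        }
      }
      for (int j = 0; j < k; ++j) out(qi, j) = bi[j] + 1;  // 1-based
    }
  }
  return out;
}

static inline arma::vec sigmoid(const arma::vec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// Forward pass over one sequence. Gate sections of W (4H x (H+I)) and b
// (4H), in row order: forget, input, candidate, output; the affine map
// acts on [h_{t-1}; x_t].
// [[Rcpp::export]]
List lstm_forward_cpp(const arma::mat& W, const arma::vec& b,
                      const arma::mat& Wy, const arma::vec& by,
                      const arma::mat& X, int readout = 0) {
  const int H = W.n_rows / 4, T = X.n_cols;
  arma::mat Fm(H, T), Im(H, T), Gm(H, T), Om(H, T), Cm(H, T), Hm(H, T);
  arma::vec h(H, arma::fill::zeros), C(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::vec hx = arma::join_cols(h, X.col(t));
    arma::vec a = W * hx + b;
    arma::vec f = sigmoid(a.subvec(0, H - 1));
    arma::vec i = sigmoid(a.subvec(H, 2 * H - 1));
    arma::vec g = arma::tanh(a.subvec(2 * H, 3 * H - 1));
    arma::vec o = sigmoid(a.subvec(3 * H, 4 * H - 1));
    C = f % C + i % g;
    h = o % arma::tanh(C);
    Fm.col(t) = f; Im.col(t) = i; Gm.col(t) = g; Om.col(t) = o;
    Cm.col(t) = C; Hm.col(t) = h;
  }
  arma::vec hread = (readout == 1) ? arma::vec(arma::mean(Hm, 1)) : h;
  arma::vec z = Wy * hread + by;
  z -= z.max();
  arma::vec p = arma::exp(z);
  p /= arma::accu(p);
  return List::create(_["h"] = Hm, _["C"] = Cm, _["prob"] = p,
                      _["f"] = Fm, _["i"] = Im, _["g"] = Gm, _["o"] = Om);
}

// Cross-entropy loss and analytic gradients for one sequence (BPTT).
// y0 is the 0-based true-class index.
// [[Rcpp::export]]
List lstm_grad_cpp(const arma::mat& W, const arma::vec& b,
                   const arma::mat& Wy, const arma::vec& by,
                   const arma::mat& X, int y0, int readout = 0) {
  const int H = W.n_rows / 4, T = X.n_cols, I = X.n_rows;
  arma::mat Fm(H, T), Im(H, T), Gm(H, T), Om(H, T), Cm(H, T), Hm(H, T);
  arma::vec h(H, arma::fill::zeros), C(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::vec hx = arma::join_cols(h, X.col(t));
    arma::vec a = W * hx + b;
    arma::vec f = sigmoid(a.subvec(0, H - 1));
    arma::vec i = sigmoid(a.subvec(H, 2 * H - 1));
    arma::vec g = arma::tanh(a.subvec(2 * H, 3 * H - 1));
    arma::vec o = sigmoid(a.subvec(3 * H, 4 * H - 1));
    C = f % C + i % g;
    h = o % arma::tanh(C);
    Fm.col(t) = f; Im.col(t) = i; Gm.col(t) = g; Om.col(t) = o;
    Cm.col(t) = C; Hm.col(t) = h;
  }
  arma::vec hread = (readout == 1) ? arma::vec(arma::mean(Hm, 1)) : arma::vec(Hm.col(T - 1));
  arma::vec z = Wy * hread + by;
  const double zmax = z.max();
  arma::vec ez = arma::exp(z - zmax);
  arma::vec p = ez / arma::accu(ez);
  const double loss = -(z(y0) - zmax - std::log(arma::accu(ez)));

  arma::vec dz = p; dz(y0) -= 1.0;
  arma::mat dWy = dz * hread.t();
  arma::vec dby = dz;
  arma::vec dh_read = Wy.t() * dz;

  arma::mat dW(arma::size(W), arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);
  arma::vec dh(H, arma::fill::zeros), dC(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::vec dh_t = dh;
    if (readout == 1) dh_t += dh_read / T;
    else if (t == T - 1) dh_t += dh_read;
    arma::vec f = Fm.col(t), i = Im.col(t), g = Gm.col(t), o = Om.col(t);
    arma::vec tC = arma::tanh(Cm.col(t));
    arma::vec do_ = dh_t % tC;
    arma::vec dCt = dC + dh_t % o % (1.0 - tC % tC);
    arma::vec Cprev = (t > 0) ? arma::vec(Cm.col(t - 1))
                              : arma::vec(H, arma::fill::zeros);
    arma::vec hprev = (t > 0) ? arma::vec(Hm.col(t - 1))
                              : arma::vec(H, arma::fill::zeros);
    arma::vec da(4 * H);
    da.subvec(0, H - 1)         = dCt % Cprev % f % (1.0 - f);
    da.subvec(H, 2 * H - 1)     = dCt % g % i % (1.0 - i);
    da.subvec(2 * H, 3 * H - 1) = dCt % i % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    arma::vec hx = arma::join_cols(hprev, X.col(t));
    dW += da * hx.t();
    db += da;
    arma::vec dhx = W.t() * da;
    dh = dhx.subvec(0, H - 1);
    dC = dCt % f;
  }
  (void)I;
  return List::create(_["loss"] = loss, _["prob"] = p,
                      _["dW"] = dW, _["db"] = db,
                      _["dWy"] = dWy, _["dby"] = dby);
}
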