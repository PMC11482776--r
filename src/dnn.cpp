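#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Minimal multilayer perceptron (ReLU hidden layers, linear or logistic
// output) trained with Adam and early stopping on a validation split.
// Inputs are expected to be standardized by the R wrapper. Uses R's RNG
// for weight initialization and epoch shuffling so fits are seedable.

static double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static double loss_of(const vec& pred, const vec& yy, bool binary) {
  if (!binary) return mean(square(pred - yy));
  double s = 0.0;
  for (uword i = 0; i < yy.n_elem; ++i) {
    double p = std::min(std::max(pred(i), 1e-12), 1.0 - 1e-12);
    s += -(yy(i) * std::log(p) + (1.0 - yy(i)) * std::log(1.0 - p));
  }
  return s / yy.n_elem;
}

static vec forward_all(const std::vector<mat>& W, const std::vector<rowvec>& b,
                       const mat& X, bool binary) {
  mat A = X;
  const size_t L = W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    A = A * W[l];
    A.each_row() += b[l];
    A.transform([](double v) { return v > 0 ? v : 0.0; });
  }
  vec out = A * W[L - 1] + b[L - 1](0);
  if (binary) out.transform([](double v) { return sigmoid(v); });
  return out;
}

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::ivec& hidden, bool binary,
                         const arma::uvec& train_idx, const arma::uvec& val_idx,
                         int max_epochs, int batch, double lr, int patience,
                         double l2) {
  const uword d = X.n_cols;
  const size_t L = hidden.n_elem + 1;

  std::vector<uword> dims;
  dims.push_back(d);
  for (uword l = 0; l < hidden.n_elem; ++l) dims.push_back(hidden(l));
  dims.push_back(1);

  std::vector<mat> W(L), mW(L), vW(L);
  std::vector<rowvec> b(L), mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    W[l].set_size(dims[l], dims[l + 1]);
    double sd = std::sqrt(2.0 / dims[l]);          // He initialization
    for (uword i = 0; i < W[l].n_elem; ++i) W[l](i) = norm_rand() * sd;
    b[l] = rowvec(dims[l + 1], fill::zeros);
    mW[l] = zeros(size(W[l])); vW[l] = zeros(size(W[l]));
    mb[l] = rowvec(dims[l + 1], fill::zeros); vb[l] = rowvec(dims[l + 1], fill::zeros);
  }

  const mat Xtr = X.rows(train_idx), Xval = X.rows(val_idx);
  const vec ytr = y.elem(train_idx), yval = y.elem(val_idx);
  const uword ntr = Xtr.n_rows;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::vector<mat> bestW = W;
  std::vector<rowvec> bestb = b;
  double best_val = datum::inf;
  int stall = 0;
  long step = 0;

  std::vector<uword> ord(ntr);
  for (uword i = 0; i < ntr; ++i) ord[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (uword i = ntr - 1; i > 0; --i) {        // Fisher-Yates via R RNG
      uword j = static_cast<uword>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }

    for (uword start = 0; start < ntr; start += batch) {
      const uword stop = std::min<uword>(start + batch, ntr);
      const uword m = stop - start;
      uvec rows(m);
      for (uword i = 0; i < m; ++i) rows(i) = ord[start + i];
      mat A = Xtr.rows(rows);
      vec yb = ytr.elem(rows);

      std::vector<mat> acts(L);                  // post-activation inputs per layer
      acts[0] = A;
      for (size_t l = 0; l + 1 < L; ++l) {
        A = A * W[l];
        A.each_row() += b[l];
        A.transform([](double v) { return v > 0 ? v : 0.0; });
        acts[l + 1] = A;
      }
      vec out = A * W[L - 1] + b[L - 1](0);
      vec delta;
      if (binary) {
        out.transform([](double v) { return sigmoid(v); });
        delta = (out - yb) / static_cast<double>(m);       // BCE w/ logistic
      } else {
        delta = 2.0 * (out - yb) / static_cast<double>(m); // MSE
      }

      ++step;
      mat D = delta;                              // m x 1
      for (size_t l = L; l-- > 0;) {
        mat gW = acts[l].t() * D + l2 * W[l];
        rowvec gb = sum(D, 0);
        if (l > 0) {
          mat Dprev = D * W[l].t();
          Dprev.elem(find(acts[l] <= 0)).zeros(); // ReLU gate
          D = Dprev;
        }
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * square(gW);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * square(gb);
        double corr = lr * std::sqrt(1 - std::pow(b2, step)) / (1 - std::pow(b1, step));
        W[l] -= corr * mW[l] / (sqrt(vW[l]) + eps);
        b[l] -= corr * mb[l] / (sqrt(vb[l]) + eps);
      }
    }

    double vl = loss_of(forward_all(W, b, Xval, binary), yval, binary);
    if (vl < best_val - 1e-9) {
      best_val = vl;
      bestW = W;
      bestb = b;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  Rcpp::List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = bestW[l];
    bl[l] = Rcpp::NumericVector(bestb[l].begin(), bestb[l].end());
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl,
                            Rcpp::Named("val_loss") = best_val);
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const Rcpp::List& fit, const arma::mat& X, bool binary) {
  Rcpp::List Wl = fit["W"], bl = fit["b"];
  const size_t L = Wl.size();
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(Wl[l]);
    Rcpp::NumericVector bv = bl[l];
    b[l] = rowvec(bv.begin(), bv.size());
  }
  return forward_all(W, b, X, binary);
}
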