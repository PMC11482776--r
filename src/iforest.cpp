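#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Average path length of an unsuccessful search in a binary search tree of
// m points; used both to terminate external nodes early and to normalize
// the final anomaly score. H(m) ~ ln(m) + Euler-Mascheroni.
static double c_factor(int m) {
  if (m <= 1) return 0.0;
  if (m == 2) return 1.0;
  const double em = 0.5772156649015329;
  return 2.0 * (std::log(static_cast<double>(m - 1)) + em) -
         2.0 * static_cast<double>(m - 1) / static_cast<double>(m);
}

struct IsoNode {
  int feat = -1;        // -1: external
  double split = 0.0;
  int left = -1, right = -1;
  double adj = 0.0;     // c(size) correction at external nodes
};

// Recursively grow one isolation tree over the rows in idx.
static int grow(std::vector<IsoNode>& nodes, const mat& P,
                std::vector<uword>& idx, int lo, int hi, int depth, int hlim) {
  const int m = hi - lo;
  nodes.push_back(IsoNode());
  const int me = static_cast<int>(nodes.size()) - 1;

  bool splittable = false;
  if (m > 1 && depth < hlim) {
    for (uword q = 0; q < P.n_cols && !splittable; ++q) {
      double mn = P(idx[lo], q), mx = mn;
      for (int i = lo + 1; i < hi; ++i) {
        double v = P(idx[i], q);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      if (mx > mn) splittable = true;
    }
  }
  if (!splittable) {
    nodes[me].adj = c_factor(m);
    return me;
  }

  // draw a feature with spread, then a uniform split point within its range
  int feat = -1;
  double mn = 0, mx = 0;
  while (feat < 0) {
    int q = static_cast<int>(unif_rand() * P.n_cols);
    if (q >= static_cast<int>(P.n_cols)) q = P.n_cols - 1;
    double a = P(idx[lo], q), b = a;
    for (int i = lo + 1; i < hi; ++i) {
      double v = P(idx[i], q);
      if (v < a) a = v;
      if (v > b) b = v;
    }
    if (b > a) { feat = q; mn = a; mx = b; }
  }
  double split = mn + unif_rand() * (mx - mn);

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (P(idx[i], feat) < split) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) mid = lo + m / 2;   // degenerate split guard

  nodes[me].feat = feat;
  nodes[me].split = split;
  int l = grow(nodes, P, idx, lo, mid, depth + 1, hlim);
  int r = grow(nodes, P, idx, mid, hi, depth + 1, hlim);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

// Isolation-forest anomaly scores s(point, psi) = 2^{-avg path / c(psi)}
// for every row of P. B trees, each on a subsample of size psi drawn
// without replacement. Uses R's RNG; seed from R.
// [[Rcpp::export]]
arma::vec iso_scores_cpp(const arma::mat& P, int B, int psi) {
  const uword p = P.n_rows;
  const int hlim = static_cast<int>(std::ceil(std::log2(static_cast<double>(psi))));
  vec path(p, fill::zeros);

  for (int b = 0; b < B; ++b) {
    // subsample without replacement (partial Fisher-Yates)
    std::vector<uword> pool(p);
    for (uword i = 0; i < p; ++i) pool[i] = i;
    std::vector<uword> idx(psi);
    for (int k = 0; k < psi; ++k) {
      int j = k + static_cast<int>(unif_rand() * (p - k));
      if (j >= static_cast<int>(p)) j = p - 1;
      std::swap(pool[k], pool[j]);
      idx[k] = pool[k];
    }

    std::vector<IsoNode> nodes;
    nodes.reserve(2 * psi);
    grow(nodes, P, idx, 0, psi, 0, hlim);

    for (uword i = 0; i < p; ++i) {
      int node = 0, depth = 0;
      while (nodes[node].feat >= 0) {
        node = (P(i, nodes[node].feat) < nodes[node].split) ? nodes[node].left
                                                            : nodes[node].right;
        ++depth;
      }
      path(i) += depth + nodes[node].adj;
    }
  }

  path /= static_cast<double>(B);
  return exp2(-path / c_factor(psi));
}

// Exposed for testing the score normalization: 2^{-h / c(psi)}.
// [[Rcpp::export]]
double iso_score_from_path(double h, int psi) {
  return std::pow(2.0, -h / c_factor(psi));
}
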