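// Compiled kernels: per-pixel NNLS, brute-force KNN majority vote,
// point-to-point-set distances, and collapsed-Gibbs LDA.
// All RNG goes through R's generator so set.seed() gives determinism.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Lawson-Hanson active-set NNLS for one right-hand side.
// A is m x n with full column rank on the passive set solves.
static arma::vec nnls_one(const arma::mat& A, const arma::vec& b,
                          int max_iter, double tol) {
  const int n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec w = A.t() * (b - A * x);
  int iter = 0;
  while (iter < max_iter) {
    int t = -1; double wmax = tol;
    for (int j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); t = j; }
    if (t < 0) break;
    passive[t] = true;
    while (true) {
      arma::uvec P(n); int np = 0;
      for (int j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
      P.resize(np);
      arma::vec z;
      bool ok = arma::solve(z, A.cols(P), b, arma::solve_opts::fast);
      if (!ok) z = arma::pinv(A.cols(P)) * b;
      if (z.min() > tol) {
        x.zeros();
        for (int i = 0; i < np; ++i) x(P(i)) = z(i);
        break;
      }
      double alpha = arma::datum::inf;
      for (int i = 0; i < np; ++i)
        if (z(i) <= tol) {
          double a = x(P(i)) / (x(P(i)) - z(i));
          if (a < alpha) alpha = a;
        }
      for (int i = 0; i < np; ++i) {
        x(P(i)) += alpha * (z(i) - x(P(i)));
        if (x(P(i)) <= tol) { passive[P(i)] = false; x(P(i)) = 0.0; }
      }
      if (++iter >= max_iter) break;
    }
    w = A.t() * (b - A * x);
    ++iter;
  }
  return x;
}

// Solve M x ~= y for every column of Y (pixels), x >= 0.
// [[Rcpp::export(name = ".nnls_cols")]]
arma::mat nnls_cols(const arma::mat& M, const arma::mat& Y) {
  arma::mat X(M.n_cols, Y.n_cols);
  const int max_iter = 10 * (int)M.n_cols + 30;
  for (arma::uword j = 0; j < Y.n_cols; ++j)
    X.col(j) = nnls_one(M, Y.col(j), max_iter, 1e-10);
  return X;
}

// Majority-of-k-nearest-neighbours vote over a logical label.
// Includes the cell itself in its neighbourhood (kernel of k cells).
// [[Rcpp::export(name = ".knn_majority")]]
LogicalVector knn_majority(NumericVector x, NumericVector y,
                           LogicalVector pos, int k) {
  const int n = x.size();
  if (k > n) stop("k exceeds number of cells");
  LogicalVector out(n);
  std::vector<std::pair<double,int> > d(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      d[j] = std::make_pair(dx * dx + dy * dy, j);
    }
    std::nth_element(d.begin(), d.begin() + k - 1, d.end());
    int npos = 0;
    for (int j = 0; j < k; ++j) npos += pos[d[j].second] ? 1 : 0;
    out[i] = 2 * npos > k;
  }
  return out;
}

// Min Euclidean distance from each query point to a point set.
// [[Rcpp::export(name = ".min_dist_to_points")]]
NumericVector min_dist_to_points(NumericVector qx, NumericVector qy,
                                 NumericVector px, NumericVector py) {
  const int n = qx.size(), m = px.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = qx[i] - px[j], dy = qy[i] - py[j];
      double dd = dx * dx + dy * dy;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Collapsed Gibbs sampler for LDA.
// docs: D x V count matrix. Returns posterior-mean phi (K x V) and
// theta (D x K), averaged over post-burn-in sweeps.
// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs(const arma::umat& docs, int K, double alpha, double beta,
               int n_iter, int burnin) {
  const int D = docs.n_rows, V = docs.n_cols;
  // expand tokens
  std::vector<int> tok_d, tok_w;
  for (int d = 0; d < D; ++d)
    for (int v = 0; v < V; ++v)
      for (arma::uword c = 0; c < docs(d, v); ++c) {
        tok_d.push_back(d); tok_w.push_back(v);
      }
  const int N = (int)tok_d.size();
  if (N == 0) stop("empty corpus");
  arma::mat nkw(K, V, arma::fill::zeros);
  arma::mat ndk(D, K, arma::fill::zeros);
  arma::vec nk(K, arma::fill::zeros);
  std::vector<int> z(N);
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K); if (k == K) k = K - 1;
    z[i] = k;
    nkw(k, tok_w[i]) += 1.0; ndk(tok_d[i], k) += 1.0; nk(k) += 1.0;
  }
  arma::mat phi_sum(K, V, arma::fill::zeros);
  arma::mat theta_sum(D, K, arma::fill::zeros);
  arma::vec p(K);
  int n_avg = 0;
  const double Vb = V * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = tok_d[i], w = tok_w[i], old = z[i];
      nkw(old, w) -= 1.0; ndk(d, old) -= 1.0; nk(old) -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p(k) = (ndk(d, k) + alpha) * (nkw(k, w) + beta) / (nk(k) + Vb);
        tot += p(k);
      }
      double u = unif_rand() * tot, cum = 0.0;
      int knew = K - 1;
      for (int k = 0; k < K; ++k) { cum += p(k); if (u <= cum) { knew = k; break; } }
      z[i] = knew;
      nkw(knew, w) += 1.0; ndk(d, knew) += 1.0; nk(knew) += 1.0;
    }
    if (it >= burnin) {
      for (int k = 0; k < K; ++k)
        for (int v = 0; v < V; ++v)
          phi_sum(k, v) += (nkw(k, v) + beta) / (nk(k) + Vb);
      for (int d = 0; d < D; ++d) {
        double nd = arma::accu(ndk.row(d)) + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (ndk(d, k) + alpha) / nd;
      }
      ++n_avg;
    }
  }
  if (n_avg == 0) n_avg = 1;
  return List::create(_["phi"] = phi_sum / n_avg,
                      _["theta"] = theta_sum / n_avg);
}

// Fold-in: estimate theta for new documents with phi held fixed.
// [[Rcpp::export(name = ".lda_fold_in")]]
arma::mat lda_fold_in(const arma::umat& docs, const arma::mat& phi,
                      double alpha, int n_iter, int burnin) {
  const int D = docs.n_rows, V = docs.n_cols, K = phi.n_rows;
  arma::mat theta_sum(D, K, arma::fill::zeros);
  arma::vec p(K);
  for (int d = 0; d < D; ++d) {
    std::vector<int> tw;
    for (int v = 0; v < V; ++v)
      for (arma::uword c = 0; c < docs(d, v); ++c) tw.push_back(v);
    const int N = (int)tw.size();
    arma::vec ndk(K, arma::fill::zeros);
    std::vector<int> z(N);
    for (int i = 0; i < N; ++i) {
      int k = (int)(unif_rand() * K); if (k == K) k = K - 1;
      z[i] = k; ndk(k) += 1.0;
    }
    int n_avg = 0;
    for (int it = 0; it < n_iter; ++it) {
      for (int i = 0; i < N; ++i) {
        const int w = tw[i], old = z[i];
        ndk(old) -= 1.0;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          p(k) = (ndk(k) + alpha) * phi(k, w);
          tot += p(k);
        }
        double u = unif_rand() * tot, cum = 0.0;
        int knew = K - 1;
        for (int k = 0; k < K; ++k) { cum += p(k); if (u <= cum) { knew = k; break; } }
        z[i] = knew; ndk(knew) += 1.0;
      }
      if (it >= burnin) {
        double nd = N + K * alpha;
        for (int k = 0; k < K; ++k) theta_sum(d, k) += (ndk(k) + alpha) / nd;
        ++n_avg;
      }
    }
    if (n_avg > 0) theta_sum.row(d) /= n_avg;
    else theta_sum.row(d).fill(1.0 / K);
  }
  return theta_sum;
}
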