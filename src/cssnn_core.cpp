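// Compiled SGD core for the cost-sensitive semi-supervised classifier.
//
// The R layer owns all randomness: it draws the per-epoch permutations and
// passes them in, so a run is fully determined by the R seed. This core
// executes the forward/backward passes and parameter updates for every
// epoch. Per batch, survivors are weighted Np/N and deaths Nn/N (computed
// here from the batch labels, once per batch); pseudo-label rows carry an
// extra factor alpha(t)/B2 in their gradient coefficient, and are skipped
// entirely while alpha(t) = 0 since their gradient is exactly zero then.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat relu(const mat& Z) {
  mat A = Z;
  A.elem(find(A < 0)).zeros();
  return A;
}

static mat softmax_rows_cpp(const mat& Z) {
  vec m = max(Z, 1);
  mat E = exp(Z.each_col() - m);
  vec s = sum(E, 1);
  return E.each_col() / s;
}

// batch class weights: w_i = Np/N for label 0, Nn/N for label 1
static vec batch_class_weights(const vec& lab) {
  const double N = lab.n_elem;
  const double Np = accu(lab);        // deaths
  const double Nn = N - Np;           // survivors
  const double zw = Np / N, ow = Nn / N;
  vec w(lab.n_elem);
  for (uword i = 0; i < lab.n_elem; ++i) w[i] = lab[i] > 0.5 ? ow : zw;
  return w;
}

// [[Rcpp::export]]
Rcpp::List cssnn_sgd_core(Rcpp::List W_in, Rcpp::List b_in,
                          const arma::mat& X1, const arma::mat& Y1,
                          const arma::vec& lab1,
                          const arma::mat& X2, const arma::mat& Y2,
                          const arma::vec& lab2,
                          const arma::umat& perm1, const arma::umat& perm2,
                          const arma::vec& alpha,
                          int batch_size, double lr, double momentum) {
  const int L = W_in.size();
  std::vector<mat> W(L), vW(L);
  std::vector<rowvec> b(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W_in[l]);
    b[l] = Rcpp::as<rowvec>(b_in[l]);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    vb[l].zeros(b[l].n_elem);
  }
  const int E = alpha.n_elem;
  const int n1 = X1.n_rows, n2 = X2.n_rows;
  const int nb1 = (n1 + batch_size - 1) / batch_size;
  const int nb2 = n2 > 0 ? (n2 + batch_size - 1) / batch_size : 0;
  vec hist_true(E, fill::zeros), hist_pseudo(E, fill::zeros);

  std::vector<mat> A(L + 1), Z(L);
  for (int e = 0; e < E; ++e) {
    const double a = alpha[e];
    const bool use_pseudo = (n2 > 0) && (a > 0);
    double lt_sum = 0.0, lp_sum = 0.0;
    for (int i = 0; i < nb1; ++i) {
      const int s1 = i * batch_size;
      const int e1 = std::min(s1 + batch_size, n1);
      const int B1 = e1 - s1;
      uvec idx1 = perm1(span(s1, e1 - 1), span(e)) - 1;
      vec w1 = batch_class_weights(lab1.elem(idx1));
      vec coef = w1 / (double) B1;

      mat Xb = X1.rows(idx1);
      mat Yb = Y1.rows(idx1);
      int B2 = 0;
      vec w2;
      if (use_pseudo) {
        const int j = nb2 > 0 ? (i % nb2) : 0;
        const int s2 = j * batch_size;
        const int e2 = std::min(s2 + batch_size, n2);
        B2 = e2 - s2;
        uvec idx2 = perm2(span(s2, e2 - 1), span(e)) - 1;
        w2 = batch_class_weights(lab2.elem(idx2));
        Xb = join_cols(Xb, X2.rows(idx2));
        Yb = join_cols(Yb, Y2.rows(idx2));
        coef = join_cols(coef, a * w2 / (double) B2);
      }

      // forward
      A[0] = Xb;
      for (int l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l < L - 1) ? relu(Z[l]) : softmax_rows_cpp(Z[l]);
      }
      const mat& P = A[L];

      // losses (pre-update outputs, per-batch normalization)
      mat R2 = square(Yb - P);
      vec rs = sum(R2, 1);
      lt_sum += dot(w1, rs.subvec(0, B1 - 1)) / (2.0 * B1);
      if (use_pseudo) {
        lp_sum += dot(w2, rs.subvec(B1, B1 + B2 - 1)) / (2.0 * B2);
      }

      // backward through softmax + MSE: dL/dP = coef * (P - Y)
      mat G = P - Yb;
      G.each_col() %= coef;
      vec gp = sum(G % P, 1);
      mat D = P % (G.each_col() - gp);
      for (int l = L - 1; l >= 0; --l) {
        mat gW = A[l].t() * D;
        rowvec gb = sum(D, 0);
        if (l > 0) {
          D = D * W[l].t();
          D.elem(find(Z[l - 1] <= 0)).zeros();
        }
        if (momentum > 0) {
          vW[l] = momentum * vW[l] - lr * gW;
          vb[l] = momentum * vb[l] - lr * gb;
          W[l] += vW[l];
          b[l] += vb[l];
        } else {
          W[l] -= lr * gW;
          b[l] -= lr * gb;
        }
      }
    }
    hist_true[e] = lt_sum / nb1;
    hist_pseudo[e] = lp_sum / nb1;
  }

  Rcpp::List W_out(L), b_out(L);
  for (int l = 0; l < L; ++l) {
    W_out[l] = W[l];
    b_out[l] = Rcpp::NumericVector(b[l].begin(), b[l].end());
  }
  return Rcpp::List::create(Rcpp::Named("W") = W_out,
                            Rcpp::Named("b") = b_out,
                            Rcpp::Named("hist_true") = hist_true,
                            Rcpp::Named("hist_pseudo") = hist_pseudo);
}
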