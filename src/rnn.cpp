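#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Forward pass of the leaky tanh RNN over a batch.
// U: cube (M x nb x T); returns states cube (J x nb x T) and outputs (T x nb).
// x_{t} = (1-alpha) x_{t-1} + alpha * tanh(W x_{t-1} + B u_t)
// y_t = sigmoid(C x_t)
// [[Rcpp::export]]
Rcpp::List cpp_forward(const arma::mat& W, const arma::mat& B, const arma::rowvec& C,
                       double alpha, const arma::cube& U, const arma::mat& x0) {
  const uword J = W.n_rows, nb = U.n_cols, T = U.n_slices;
  cube X(J, nb, T);
  mat Y(T, nb);
  mat x = x0;
  for (uword t = 0; t < T; ++t) {
    mat h = W * x + B * U.slice(t);
    x = (1.0 - alpha) * x + alpha * tanh(h);
    X.slice(t) = x;
    Y.row(t) = 1.0 / (1.0 + exp(-(C * x)));
  }
  return Rcpp::List::create(Rcpp::Named("states") = X,
                            Rcpp::Named("outputs") = Y);
}

// BPTT gradient of mean BCE over the final `win` timesteps.
// labels: nb-vector of 0/1.
// [[Rcpp::export]]
Rcpp::List cpp_bptt(const arma::mat& W, const arma::mat& B, const arma::rowvec& C,
                    double alpha, const arma::cube& U, const arma::vec& labels,
                    int win) {
  const uword J = W.n_rows, M = B.n_cols, nb = U.n_cols, T = U.n_slices;
  cube X(J, nb, T);      // post-update states
  cube TH(J, nb, T);     // tanh(h_t)
  mat x(J, nb, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat th = tanh(W * x + B * U.slice(t));
    x = (1.0 - alpha) * x + alpha * th;
    TH.slice(t) = th;
    X.slice(t) = x;
  }
  const uword t0 = T - (uword)win;
  double denom = (double)win * (double)nb;
  double loss = 0.0, acc = 0.0;
  // accumulate output-layer grads and dL/dx seeds
  mat gW(J, J, fill::zeros), gB(J, M, fill::zeros);
  rowvec gC(J, fill::zeros);
  // mean output over window for accuracy
  rowvec ymean(nb, fill::zeros);
  // backward
  mat delta(J, nb, fill::zeros);
  for (uword t = T; t-- > 0;) {
    if (t >= t0) {
      rowvec y = 1.0 / (1.0 + exp(-(C * X.slice(t))));
      ymean += y;
      for (uword b = 0; b < nb; ++b) {
        double yy = std::min(std::max(y(b), 1e-12), 1.0 - 1e-12);
        loss += -(labels(b) * std::log(yy) + (1.0 - labels(b)) * std::log(1.0 - yy));
      }
      rowvec e = (y - labels.t()) / denom;   // dL/d(Cx)
      gC += e * X.slice(t).t();
      delta += C.t() * e;                     // dL/dx_t
    }
    // x_t = (1-a) x_{t-1} + a tanh(W x_{t-1} + B u_t)
    mat d = alpha * (delta % (1.0 - square(TH.slice(t))));  // J x nb
    mat xprev = (t == 0) ? mat(J, nb, fill::zeros) : X.slice(t - 1);
    gW += d * xprev.t();
    gB += d * U.slice(t).t();
    delta = (1.0 - alpha) * delta + W.t() * d;
  }
  ymean /= (double)win;
  for (uword b = 0; b < nb; ++b)
    acc += ((ymean(b) > 0.5) ? 1.0 : 0.0) == labels(b) ? 1.0 : 0.0;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss / denom,
    Rcpp::Named("acc") = acc / (double)nb,
    Rcpp::Named("gW") = gW, Rcpp::Named("gB") = gB, Rcpp::Named("gC") = gC);
}

// Batched trial generation for the training loop. Uses R's RNG so the
// stream is governed by set.seed in the caller.
// dag_adj: cube (N x N x nDag) adjacency, row = cause; topo: nDag x N
// topological orders (1-based); design_*: rows (dag_id, cause, effect),
// 1-based, for balanced label-conditional sampling.
// Returns inputs cube (M x n x T) and labels.
// [[Rcpp::export]]
Rcpp::List cpp_generate_batch(int n, const arma::cube& dag_adj,
                              const arma::imat& topo,
                              const arma::imat& design_true,
                              const arma::imat& design_false,
                              double p_spont, double p_cause,
                              int K, int steps_per_obs, int gap_steps,
                              int settle_steps, double amp) {
  const int N = dag_adj.n_rows;
  const int M = 3 * N;
  const int T = K * (steps_per_obs + gap_steps) + settle_steps;
  cube U(M, n, T, fill::zeros);
  vec labels(n);
  imat dag_ids(n, 1);
  imat causes(n, 1), effects(n, 1);
  mat v(N, K);
  for (int b = 0; b < n; ++b) {
    bool lab = unif_rand() < 0.5;
    const arma::imat& des = lab ? design_true : design_false;
    int row = (int)std::floor(unif_rand() * des.n_rows);
    if (row >= (int)des.n_rows) row = des.n_rows - 1;
    int d = des(row, 0) - 1, cse = des(row, 1) - 1, eff = des(row, 2) - 1;
    // ancestral sampling, columns independent
    for (int k = 0; k < K; ++k) {
      for (int oi = 0; oi < N; ++oi) {
        int node = topo(d, oi) - 1;
        double a = 0;
        for (int par = 0; par < N; ++par)
          if (dag_adj(par, node, d) > 0.5) a += v(par, k);
        double p = 1.0 - (1.0 - p_spont) * std::pow(1.0 - p_cause, a);
        v(node, k) = (unif_rand() < p) ? 1.0 : 0.0;
      }
    }
    int block = steps_per_obs + gap_steps;
    for (int k = 0; k < K; ++k)
      for (int s = 0; s < steps_per_obs; ++s)
        for (int nn = 0; nn < N; ++nn)
          U(nn, b, k * block + s) = v(nn, k);
    for (int t = 0; t < T; ++t) {
      U(N + cse, b, t) = amp;
      U(2 * N + eff, b, t) = amp;
    }
    labels(b) = lab ? 1.0 : 0.0;
    dag_ids(b, 0) = d + 1;
    causes(b, 0) = cse + 1;
    effects(b, 0) = eff + 1;
  }
  return Rcpp::List::create(Rcpp::Named("inputs") = U,
                            Rcpp::Named("labels") = labels,
                            Rcpp::Named("dag_id") = dag_ids,
                            Rcpp::Named("cause") = causes,
                            Rcpp::Named("effect") = effects);
}
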