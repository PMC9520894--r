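// Masked multiplicative-update NMF under the mean Kullback-Leibler loss.
// Entries with mask == 0 contribute neither to the loss nor to the updates;
// callers must zero the data at masked positions so NA never propagates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12;

// mean KL over observed entries: d(a, ahat) = a*log(a/ahat) - a + ahat,
// with 0*log(0) = 0 and ahat floored at EPS.
static double mean_kl(const mat& A, const mat& Ahat, const mat& M,
                      const double n_obs) {
  double acc = 0.0;
  for (uword j = 0; j < A.n_cols; ++j) {
    for (uword i = 0; i < A.n_rows; ++i) {
      if (M(i, j) > 0.5) {
        const double a = A(i, j);
        const double ah = std::max(Ahat(i, j), EPS);
        acc += (a > 0.0 ? a * std::log(a / ah) - a : 0.0) + ah;
      }
    }
  }
  return acc / n_obs;
}

// [[Rcpp::export(name = ".cpp_nmf_kl")]]
Rcpp::List cpp_nmf_kl(const arma::mat& A, const arma::mat& M,
                      arma::mat W, arma::mat H,
                      const int max_iter, const double tol,
                      const double abs_tol, const int window,
                      const bool update_W,
                      const int conn_every, const int conn_stall) {
  const double n_obs = accu(M);
  std::vector<double> trace;
  trace.reserve(std::min(max_iter, 4096));

  mat Ahat = W * H;
  double prev_window_loss = datum::inf;
  int it = 0;

  // connectivity-stationarity stopping (classical consensus practice):
  // track the argmax sample assignment every `conn_every` iterations and
  // stop once it is unchanged `conn_stall` consecutive checks
  uvec assign_prev;
  int stable_checks = 0;

  for (it = 1; it <= max_iter; ++it) {
    if (update_W) {
      // W <- W o (R H^T) / (M H^T), R = M o (A / Ahat)
      Ahat = W * H;
      mat R = M % (A / clamp(Ahat, EPS, datum::inf));
      mat num = R * H.t();
      mat den = M * H.t();
      W %= num / clamp(den, EPS, datum::inf);
    }
    // H <- H o (W^T R) / (W^T M)
    Ahat = W * H;
    mat R = M % (A / clamp(Ahat, EPS, datum::inf));
    mat num = W.t() * R;
    mat den = W.t() * M;
    H %= num / clamp(den, EPS, datum::inf);

    Ahat = W * H;
    const double loss = mean_kl(A, Ahat, M, n_obs);
    trace.push_back(loss);

    if (loss < abs_tol) break;
    if (conn_every > 0 && it % conn_every == 0) {
      uvec assign = index_max(H, 0).t();
      if (assign_prev.n_elem == assign.n_elem &&
          all(assign == assign_prev)) {
        if (++stable_checks >= conn_stall) break;
      } else {
        stable_checks = 0;
      }
      assign_prev = assign;
    }
    if (it % window == 0) {
      const double rel = (prev_window_loss - loss) /
        std::max(prev_window_loss, EPS);
      if (std::isfinite(prev_window_loss) && rel < tol) break;
      prev_window_loss = loss;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("loss_trace") = trace,
    Rcpp::Named("n_iter") = static_cast<int>(trace.size()));
}

// [[Rcpp::export(name = ".cpp_mean_kl")]]
double cpp_mean_kl(const arma::mat& A, const arma::mat& Ahat,
                   const arma::mat& M) {
  return mean_kl(A, Ahat, M, accu(M));
}
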