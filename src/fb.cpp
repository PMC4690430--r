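#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for a set of individuals.
//
// pi:  n_ind x M matrix of initial state probabilities (row per individual)
// E:   n_rec x M matrix of emission likelihoods (records sorted by
//      individual, consecutive years)
// A:   M x M x n_rec array; slice r is the transition matrix from record
//      r-1 to record r (slice unused for the first record of an individual)
// starts: 1-based index of each individual's first record
// lens:   number of records per individual
//
// Returns smoothed state probabilities gamma (n_rec x M), pairwise joint
// probabilities xi (M x M x n_rec, zero slice for first records), and the
// log-likelihood per individual.
// [[Rcpp::export]]
List fb_all(NumericMatrix pi, NumericMatrix E, NumericVector A,
            IntegerVector starts, IntegerVector lens) {
  int M = E.ncol();
  int n_rec = E.nrow();
  int n_ind = starts.size();
  NumericMatrix gamma(n_rec, M);
  NumericVector xi(Dimension(M, M, n_rec));
  NumericVector loglik(n_ind);
  std::vector<double> alpha(n_rec * M), beta(n_rec * M), cscale(n_rec);

  const double *a = REAL(A);

  for (int i = 0; i < n_ind; ++i) {
    int s0 = starts[i] - 1;
    int T = lens[i];
    // forward
    double ll = 0.0;
    for (int t = 0; t < T; ++t) {
      int r = s0 + t;
      double c = 0.0;
      if (t == 0) {
        for (int m = 0; m < M; ++m) {
          alpha[r * M + m] = pi(i, m) * E(r, m);
          c += alpha[r * M + m];
        }
      } else {
        const double *At = a + (size_t)r * M * M;  // column-major M x M
        for (int m = 0; m < M; ++m) {
          double acc = 0.0;
          for (int l = 0; l < M; ++l)
            acc += alpha[(r - 1) * M + l] * At[l + m * M];
          alpha[r * M + m] = acc * E(r, m);
          c += alpha[r * M + m];
        }
      }
      if (c <= 0.0 || !R_finite(c))
        stop("zero or non-finite likelihood at individual %d, step %d",
             i + 1, t + 1);
      for (int m = 0; m < M; ++m) alpha[r * M + m] /= c;
      cscale[r] = c;
      ll += std::log(c);
    }
    loglik[i] = ll;
    // backward
    for (int m = 0; m < M; ++m) beta[(s0 + T - 1) * M + m] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      int r = s0 + t;
      const double *At1 = a + (size_t)(r + 1) * M * M;
      for (int l = 0; l < M; ++l) {
        double acc = 0.0;
        for (int m = 0; m < M; ++m)
          acc += At1[l + m * M] * E(r + 1, m) * beta[(r + 1) * M + m];
        beta[r * M + l] = acc / cscale[r + 1];
      }
    }
    // gamma and xi
    for (int t = 0; t < T; ++t) {
      int r = s0 + t;
      double tot = 0.0;
      for (int m = 0; m < M; ++m) {
        gamma(r, m) = alpha[r * M + m] * beta[r * M + m];
        tot += gamma(r, m);
      }
      for (int m = 0; m < M; ++m) gamma(r, m) /= tot;
      if (t > 0) {
        const double *At = a + (size_t)r * M * M;
        double *xr = REAL(xi) + (size_t)r * M * M;
        double xtot = 0.0;
        for (int l = 0; l < M; ++l)
          for (int m = 0; m < M; ++m) {
            double v = alpha[(r - 1) * M + l] * At[l + m * M] * E(r, m) *
                       beta[r * M + m] / cscale[r];
            xr[l + m * M] = v;
            xtot += v;
          }
        // renormalize against accumulated rounding
        for (int k = 0; k < M * M; ++k) xr[k] /= xtot;
      }
    }
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}
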