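// Integrator for the representative-metapopulation stochastic dynamics
//   dN_u/dt = N_u (N*_u - N_u + xi_u(t)) + sum_v D_uv (N_v - N_u)
// driven by pre-generated colored Gaussian noise paths xi sampled on a
// uniform grid of spacing dt (linearly interpolated between grid points).
// Heun (explicit trapezoid) stepping with `substeps` sub-steps per noise
// interval.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void rep_rhs(const arma::rowvec& Nstar, const arma::mat& D,
                           const arma::vec& drow, const arma::rowvec& xi,
                           const arma::rowvec& N, arma::rowvec& R) {
  R = N % (Nstar - N + xi);
  R += N * D.t() - N % drow.t();
}

// mode: 0 = plain recording (no cutoff)
//       1 = extinction rule: when all patches < N_c, zero out, keep going
//       2 = first passage: stop at absorption (all patches < N_c)
// [[Rcpp::export]]
List rep_integrate_cpp(const arma::mat& Nstar, const arma::cube& xi,
                       const arma::mat& D, const arma::mat& N0, double dt,
                       int substeps, double N_c, int mode, int record_every,
                       double rel_max) {
  const arma::uword n_real = Nstar.n_rows, M = Nstar.n_cols;
  const arma::uword n_t = xi.n_rows;  // noise grid points (steps = n_t - 1)
  arma::vec drow = arma::sum(D, 1);
  const double h = dt / substeps;

  const arma::uword n_rec = (n_t - 1) / record_every + 1;
  arma::cube Nrec;
  if (mode != 2) Nrec.set_size(n_rec, M, n_real);
  LogicalVector absorbed(n_real);
  NumericVector t_abs(n_real, NA_REAL);
  int status = 0;  // 1 = relative one-step change exceeded rel_max

  arma::rowvec N(M), k1(M), k2(M), y(M), xih(M), xi0(M), xi1(M);
  for (arma::uword r = 0; r < n_real; ++r) {
    N = N0.row(r);
    arma::rowvec ns = Nstar.row(r);
    bool dead = false;
    if (mode != 2) Nrec.slice(r).row(0) = N;
    arma::uword irec = 1;
    for (arma::uword k = 0; k + 1 < n_t && status == 0; ++k) {
      if (!dead) {
        xi0 = xi.slice(r).row(k);
        xi1 = xi.slice(r).row(k + 1);
        for (int s = 0; s < substeps; ++s) {
          double f0 = (double)s / substeps, f1 = (double)(s + 1) / substeps;
          arma::rowvec xa = (1 - f0) * xi0 + f0 * xi1;
          arma::rowvec xb = (1 - f1) * xi0 + f1 * xi1;
          rep_rhs(ns, D, drow, xa, N, k1);
          y = N + h * k1;
          y.transform([](double x) { return x < 0 ? 0.0 : x; });
          rep_rhs(ns, D, drow, xb, y, k2);
          arma::rowvec Nn = N + 0.5 * h * (k1 + k2);
          Nn.transform([](double x) { return x < 0 ? 0.0 : x; });
          double denom = std::max(N.max(), 1e-300);
          if (arma::abs(Nn - N).max() / denom > rel_max &&
              arma::abs(Nn - N).max() > 1e-8) {
            status = 1;
          }
          N = Nn;
        }
        if (N.max() < N_c && mode != 0) {
          if (mode == 2) {
            absorbed[r] = true;
            t_abs[r] = (k + 1) * dt;
            break;
          } else {
            N.zeros();
            dead = true;
            absorbed[r] = true;
            t_abs[r] = (k + 1) * dt;
          }
        }
      }
      if (mode != 2 && ((k + 1) % record_every == 0)) {
        Nrec.slice(r).row(irec) = N;
        ++irec;
      }
    }
  }

  List out = List::create(_["absorbed"] = absorbed, _["t_abs"] = t_abs,
                          _["status"] = status);
  if (mode != 2) out["N"] = Nrec;
  return out;
}

// First-passage times to a decreasing ladder of cutoffs: for each
// realization, the first time at which the abundance is below Nc_grid[j]
// in every patch, for each j (thresholds sorted decreasing). A single
// trajectory yields the passage time for every cutoff it reaches.
// [[Rcpp::export]]
NumericMatrix rep_first_passage_cpp(const arma::mat& Nstar,
                                    const arma::cube& xi,
                                    const arma::mat& D, const arma::mat& N0,
                                    double dt, int substeps,
                                    const arma::vec& Nc_grid) {
  const arma::uword n_real = Nstar.n_rows, M = Nstar.n_cols;
  const arma::uword n_t = xi.n_rows, n_c = Nc_grid.n_elem;
  arma::vec drow = arma::sum(D, 1);
  const double h = dt / substeps;
  NumericMatrix tfp(n_real, n_c);
  std::fill(tfp.begin(), tfp.end(), NA_REAL);

  arma::rowvec N(M), k1(M), k2(M), y(M), xi0(M), xi1(M);
  for (arma::uword r = 0; r < n_real; ++r) {
    N = N0.row(r);
    arma::rowvec ns = Nstar.row(r);
    arma::uword j = 0;
    for (arma::uword k = 0; k + 1 < n_t && j < n_c; ++k) {
      xi0 = xi.slice(r).row(k);
      xi1 = xi.slice(r).row(k + 1);
      for (int s = 0; s < substeps; ++s) {
        double f0 = (double)s / substeps, f1 = (double)(s + 1) / substeps;
        arma::rowvec xa = (1 - f0) * xi0 + f0 * xi1;
        arma::rowvec xb = (1 - f1) * xi0 + f1 * xi1;
        rep_rhs(ns, D, drow, xa, N, k1);
        y = N + h * k1;
        y.transform([](double x) { return x < 0 ? 0.0 : x; });
        rep_rhs(ns, D, drow, xb, y, k2);
        N += 0.5 * h * (k1 + k2);
        N.transform([](double x) { return x < 0 ? 0.0 : x; });
      }
      double nmax = N.max();
      while (j < n_c && nmax < Nc_grid(j)) {
        tfp(r, j) = (k + 1) * dt;
        ++j;
      }
    }
  }
  return tfp;
}
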