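// Adaptive Dormand-Prince RK45 integrator for the metacommunity
// Lotka-Volterra equations
//   dN_iu/dt = N_iu (B_iu - N_iu - sum_j A_ij,u N_ju)
//              + sum_v D_uv (N_iv - N_iu)
// with the all-patch extinction cutoff applied at checkpoints: a species
// whose abundance is below N_c in every patch is removed permanently.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void lv_rhs(const arma::cube& A, const arma::mat& B,
                          const arma::mat& D, const arma::vec& drow,
                          const arma::uvec& alive, const arma::mat& N,
                          arma::mat& R) {
  const arma::uword M = N.n_cols;
  for (arma::uword u = 0; u < M; ++u) {
    arma::vec g = B.col(u) - N.col(u) - A.slice(u) * N.col(u);
    R.col(u) = N.col(u) % g;
  }
  // migration: sum_v D_uv (N_iv - N_iu); drow(u) = sum_v D(u,v)
  R += N * D.t();
  R -= N.each_row() % drow.t();
  // extinct species are pinned at exactly zero
  for (arma::uword i = 0; i < N.n_rows; ++i)
    if (!alive(i)) R.row(i).zeros();
}

// Dormand-Prince coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// [[Rcpp::export]]
List lv_integrate_cpp(const arma::cube& A, const arma::mat& B,
                      const arma::mat& D, const arma::mat& N0,
                      const LogicalVector& alive0, double t0, double horizon,
                      double checkpoint_dt, double N_c, bool apply_cutoff,
                      double rtol, double atol, double neg_tol,
                      double max_steps, int record_every) {
  const arma::uword S = N0.n_rows, M = N0.n_cols;
  arma::vec drow = arma::sum(D, 1);
  arma::uvec alive(S);
  for (arma::uword i = 0; i < S; ++i) alive(i) = alive0[i] ? 1 : 0;

  arma::mat N = N0;
  for (arma::uword i = 0; i < S; ++i)
    if (!alive(i)) N.row(i).zeros();

  const int n_chk = (int)std::floor(horizon / checkpoint_dt + 1e-9);
  const int n_rec = n_chk / record_every + 1;
  arma::cube Nrec(S, M, n_rec);
  arma::vec times(n_rec);
  arma::umat alive_rec(S, n_rec);
  Nrec.slice(0) = N;
  times(0) = t0;
  alive_rec.col(0) = alive;

  std::vector<int> ext_species;
  std::vector<double> ext_times;

  arma::mat k1(S, M), k2(S, M), k3(S, M), k4(S, M), k5(S, M), k6(S, M),
      k7(S, M), y(S, M), ynew(S, M), err(S, M);
  double h = 1e-3;
  double t = t0;
  long nsteps = 0;
  int status = 0;  // 0 ok, 1 max steps, 2 step underflow, 3 negative blow-up
  int irec = 1;

  lv_rhs(A, B, D, drow, alive, N, k1);  // FSAL seed

  for (int chk = 1; chk <= n_chk && status == 0; ++chk) {
    double t_end = t0 + chk * checkpoint_dt;
    while (t < t_end - 1e-12 && status == 0) {
      if (h > t_end - t) h = t_end - t;
      // stages
      y = N + h * a21 * k1;
      lv_rhs(A, B, D, drow, alive, y, k2);
      y = N + h * (a31 * k1 + a32 * k2);
      lv_rhs(A, B, D, drow, alive, y, k3);
      y = N + h * (a41 * k1 + a42 * k2 + a43 * k3);
      lv_rhs(A, B, D, drow, alive, y, k4);
      y = N + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
      lv_rhs(A, B, D, drow, alive, y, k5);
      y = N + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
      lv_rhs(A, B, D, drow, alive, y, k6);
      ynew = N + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
      lv_rhs(A, B, D, drow, alive, ynew, k7);
      err = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);

      double emax = 0.0;
      for (arma::uword q = 0; q < S * M; ++q) {
        double sc = atol + rtol * std::max(std::fabs(N(q)), std::fabs(ynew(q)));
        double e = std::fabs(err(q)) / sc;
        if (e > emax) emax = e;
      }
      if (emax <= 1.0) {
        t += h;
        N = ynew;
        // clamp small negative excursions; large ones are a failure
        double nmin = N.min();
        if (nmin < 0) {
          if (nmin < -neg_tol) { status = 3; break; }
          N.transform([](double x) { return x < 0 ? 0.0 : x; });
          lv_rhs(A, B, D, drow, alive, N, k7);
        }
        k1 = k7;  // FSAL
      }
      double fac = emax > 0 ? 0.9 * std::pow(emax, -0.2) : 5.0;
      fac = std::min(5.0, std::max(0.2, fac));
      h *= fac;
      if (h < 1e-12) { status = 2; break; }
      if (++nsteps > max_steps) { status = 1; break; }
    }
    if (status != 0) break;
    // checkpoint: extinction rule
    if (apply_cutoff) {
      bool removed = false;
      for (arma::uword i = 0; i < S; ++i) {
        if (!alive(i)) continue;
        if (N.row(i).max() < N_c) {
          alive(i) = 0;
          N.row(i).zeros();
          ext_species.push_back((int)i + 1);
          ext_times.push_back(t);
          removed = true;
        }
      }
      if (removed) lv_rhs(A, B, D, drow, alive, N, k1);
    }
    if (chk % record_every == 0) {
      Nrec.slice(irec) = N;
      times(irec) = t0 + chk * checkpoint_dt;
      alive_rec.col(irec) = alive;
      ++irec;
    }
  }

  Nrec.resize(S, M, irec);
  return List::create(
      _["times"] = times.head(irec), _["N"] = Nrec,
      _["alive"] = alive_rec.cols(0, irec - 1),
      _["ext_species"] = ext_species, _["ext_times"] = ext_times,
      _["state"] = N, _["alive_final"] = alive, _["status"] = status,
      _["n_steps"] = (double)nsteps, _["t_final"] = t);
}

// [[Rcpp::export]]
arma::mat lv_rhs_cpp(const arma::cube& A, const arma::mat& B,
                     const arma::mat& D, const arma::mat& N,
                     const LogicalVector& alive0) {
  const arma::uword S = N.n_rows;
  arma::uvec alive(S);
  for (arma::uword i = 0; i < S; ++i) alive(i) = alive0[i] ? 1 : 0;
  arma::vec drow = arma::sum(D, 1);
  arma::mat R(arma::size(N));
  lv_rhs(A, B, D, drow, alive, N, R);
  return R;
}
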