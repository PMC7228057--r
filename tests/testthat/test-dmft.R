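test_that("colored noise generator reproduces prescribed kernels", {
  # zero kernel: identically zero paths
  k0 <- correlation_kernel(c(0, 1), c(0, 0))
  expect_true(all(generate_colored_noise(k0, T = 10, dt = 0.1,
                                         n_paths = 3) == 0))
  # short-ranged kernel: sample variance matches C(0)
  kd <- exponential_kernel(C0 = 3, tau0 = 0.1, lag_max = 1, dt = 0.05)
  xi <- generate_colored_noise(kd, T = 500, dt = 0.05, n_paths = 40,
                               seed = 2)
  expect_lt(abs(mean(apply(xi, 2, var)) - 3) / 3, 0.05)
  # exponential kernel: autocorrelation at lag tau0 is 1/e of C(0)
  ke <- exponential_kernel(C0 = 2, tau0 = 0.5)
  xe <- generate_colored_noise(ke, T = 2000, dt = 0.05, n_paths = 20,
                               seed = 3)
  ac <- sapply(seq_len(ncol(xe)), function(j) {
    a <- acf(xe[, j], lag.max = 10, plot = FALSE, demean = TRUE)
    a$acf[11]                          # lag 0.5 = tau0
  })
  expect_lt(abs(mean(ac) - exp(-1)), 0.03)
  # distinct paths are independent
  expect_lt(abs(cor(xe[, 1], xe[, 2])), 0.1)
})

test_that("representative dynamics has the expected noiseless limits", {
  k0 <- correlation_kernel(c(0, 1), c(0, 0))
  # positive N*: logistic relaxation to N*
  rp <- representative_params(N_star = 0.7, d = 0, kernel = k0)
  tr <- simulate_representative(rp, T = 60, dt = 0.05, n_real = 1,
                                N0 = 0.05)
  expect_equal(tail(tr$N[, 1, 1], 1), 0.7, tolerance = 1e-4)
  # negative N*: exponential decay to extinction
  rn <- representative_params(N_star = -0.4, d = 0, kernel = k0)
  trn <- simulate_representative(rn, T = 80, dt = 0.05, n_real = 1,
                                 N_c = 1e-8, N0 = 0.5)
  expect_true(trn$absorbed[1])
  expect_true(all(trn$N[nrow(trn$N), , 1] == 0))
})

test_that("a positive-N* patch acts as a source under weak noise", {
  ke <- exponential_kernel(C0 = 0.02, tau0 = 0.5)
  rp <- representative_params(N_star = c(0.5, -0.5), d = 0.02,
                              kernel = ke)
  tr <- simulate_representative(rp, T = 300, dt = 0.05, n_real = 20,
                                seed = 4, N0 = c(0.5, 0.05))
  win <- 150:dim(tr$N)[1]
  # migration contribution to patch 1: d * (N2 - N1) < 0 (exporter)
  m1 <- mean(tr$N[win, 1, ]); m2 <- mean(tr$N[win, 2, ])
  expect_lt(0.02 * (m2 - m1), 0)
  expect_gt(m1, 10 * m2)  # the sink population hangs far below the source
})

test_that("static cavity theory solves its closed-form limits", {
  # no heterogeneity: full survival at B / (1 + mu)
  et0 <- equilibrium_theory(list(mu_tot = 2, sigma = 0), B = 1, S = 50)
  expect_equal(et0$phi, 1)
  expect_equal(et0$mean_N, 1 / 3)
  expect_equal(et0$diversity_bound, 50)
  # mu = 0, small sigma: phi ~ pnorm(B / (sigma sqrt(q))) to leading order
  et <- equilibrium_theory(list(mu_tot = 0, sigma = 0.2), B = 1)
  expect_equal(et$phi, pnorm(1 / (0.2 * sqrt(et$q))), tolerance = 1e-6)
  expect_gt(et$phi, 0.99)
  # self-consistency identities of the returned solution
  mstar <- et$B - et$mu_tot * et$mean_N
  s <- et$sigma * sqrt(et$q)
  al <- mstar / s
  expect_equal(et$phi, pnorm(al), tolerance = 1e-8)
  expect_equal(et$mean_N, mstar * pnorm(al) + s * dnorm(al),
               tolerance = 1e-6)
})

test_that("the diversity bound decreases with interaction heterogeneity", {
  phis <- sapply(seq(0.3, 2.4, by = 0.3), function(s)
    equilibrium_theory(list(mu_tot = 4, sigma = s), B = 1)$phi)
  expect_true(all(diff(phis) < 0))
})

test_that("predicted N*_eff distribution integrates to the survival fraction", {
  sol <- structure(list(mean_Nstar = -0.3, var_Nstar = 1.2,
                        cov_Nstar = 0.6, M = 4, converged = TRUE),
                   class = "dmft_solution")
  grid <- seq(1e-9, -0.3 + 9 * sqrt(1.2), length.out = 3000)
  pd <- predicted_nstar_distribution(sol, x = grid)
  x <- pd$x
  quad <- sum(diff(x) * (head(pd$density, -1) + tail(pd$density, -1)) / 2)
  expect_equal(quad, pd$phi, tolerance = 1e-3)
  # multi-patch survival beats the single-patch marginal
  expect_gt(pd$phi, 1 - pnorm(0, -0.3, sqrt(1.2)))

  # M = 1 reduces to the plain Gaussian marginal
  sol1 <- structure(list(mean_Nstar = 0.4, var_Nstar = 0.5,
                         cov_Nstar = 0.2, M = 1, converged = TRUE),
                    class = "dmft_solution")
  pd1 <- predicted_nstar_distribution(sol1)
  expect_equal(pd1$density, dnorm(pd1$x, 0.4, sqrt(0.5)),
               tolerance = 1e-3)
  # unconverged solutions are refused
  sol_bad <- sol; sol_bad$converged <- FALSE
  expect_error(predicted_nstar_distribution(sol_bad), "unconverged")
})

test_that("the self-consistent solver reduces to the interaction-homogeneous limit", {
  sol <- self_consistent_solve(list(mu_tot = 1.5, sigma = 0), B = 1,
                               M = 1, d = 0,
                               controls = list(n_real = 100, T = 80,
                                               seed = 3))
  expect_true(sol$converged)
  expect_equal(sol$mean_N, 1 / 2.5, tolerance = 1e-3)
  expect_equal(sol$phi, 1)
  expect_true(all(sol$kernel$C_xi == 0))
  expect_equal(sol$kernel$W, 0)
})

test_that("below the instability the dynamical solver matches the static cavity", {
  scales <- list(mu_tot = 1, sigma = 0.5)
  sol <- self_consistent_solve(scales, B = 1, M = 1, d = 0,
                               controls = list(n_real = 2000, T = 250,
                                               n_avg = 4L, seed = 3))
  et <- equilibrium_theory(scales, B = 1)
  expect_true(sol$converged)
  # converged kernel is (numerically) zero: no endogenous noise
  expect_lt(sol$kernel$C_xi[1], 0.005 * 0.25 * et$q)
  expect_lt(abs(sol$mean_N - et$mean_N) / et$mean_N, 0.02)
  expect_lt(abs(sol$q - et$q) / et$q, 0.02)
  expect_lt(abs(sol$phi - et$phi) / et$phi, 0.02)
  # Jensen: second moment dominates squared mean
  expect_gte(sol$q, sol$mean_N^2)
})
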