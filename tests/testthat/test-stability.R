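test_that("Jacobian and leading eigenvalue match closed forms", {
  # logistic at carrying capacity: J = [-1]
  sysl <- logistic_system()
  J <- jacobian_at(matrix(1), sysl)
  expect_equal(as.numeric(J), -1)
  expect_equal(lambda_stab(matrix(1), sysl)$lambda_stab, -1)
  # two symmetric competitors at N = 2/3: eigenvalues -2/3 (1 +- 1/2)
  sys2 <- two_species_system(a = 0.5)
  ev <- sort(Re(lambda_stab(matrix(2 / 3, 2, 1), sys2)$spectrum))
  expect_equal(ev, c(-1, -1 / 3), tolerance = 1e-12)
})

test_that("analytic Jacobian agrees with finite differences", {
  sys <- small_random_system(S = 10, M = 2, seed = 71, c = 0.6)
  withr::local_seed(72)
  N <- matrix(runif(20, 0.2, 1), 10, 2)
  J <- suppressWarnings(jacobian_at(N, sys, warn_not_fixed = FALSE))
  h <- 1e-6
  Jfd <- matrix(0, 20, 20)
  for (v in 1:2) for (j in 1:10) {
    Np <- N; Nm <- N
    Np[j, v] <- Np[j, v] + h
    Nm[j, v] <- Nm[j, v] - h
    col_fd <- (lv_rhs(Np, sys) - lv_rhs(Nm, sys)) / (2 * h)
    Jfd[, (v - 1) * 10 + j] <- as.numeric(col_fd)
  }
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-5)
})

test_that("a state that is not a fixed point is flagged", {
  sys <- two_species_system()
  expect_warning(jacobian_at(matrix(c(0.2, 0.9), 2, 1), sys),
                 "not a fixed point")
})

test_that("decoupled patches give the max of patch-wise spectra", {
  p <- ensemble_params(S = 8, M = 2, c = 0.6, mu_A = 0.2, sd_A = 0.25,
                       rho = 0.8, d = 0, N_c = 1e-8, seed = 81)
  sys <- sample_interactions(p)
  tr <- simulate_metacommunity(sys, horizon = 400)
  lam_joint <- lambda_stab(tr$state, sys,
                           alive = tr$alive_final)$lambda_stab
  lams <- sapply(1:2, function(u) {
    sys_u <- sys
    sys_u$A <- sys$A[, , u, drop = FALSE]
    sys_u$B <- sys$B[, u, drop = FALSE]
    sys_u$D <- matrix(0, 1, 1)
    lambda_stab(tr$state[, u, drop = FALSE], sys_u,
                alive = tr$alive_final)$lambda_stab
  })
  expect_equal(lam_joint, max(lams), tolerance = 1e-8)
})

test_that("Newton finds the feasible equilibrium from a rough start", {
  sys <- two_species_system(a = 0.5)
  root <- newton_fixed_point(sys, matrix(c(0.3, 1.0), 2, 1))
  expect_true(root$converged)
  expect_equal(as.numeric(root$state), c(2 / 3, 2 / 3), tolerance = 1e-9)
  expect_lt(root$residual, 1e-9)
})

test_that("diversity sweep links vanishing noise to marginal stability", {
  p <- fluctuating_config(seed = 11)
  sys <- sample_interactions(p)
  tr <- simulate_metacommunity(sys, horizon = 3000)
  sw <- diversity_sweep(sys, tr$state, batch = 5)
  expect_true(any(!sw$fixed_point))    # starts fluctuating
  expect_true(any(sw$fixed_point))     # ends on the stable branch
  # fluctuation strength shrinks (within one batch of noise) along the
  # sweep and is exactly zero on the equilibrium branch
  expect_true(all(sw$std_xi[sw$fixed_point] == 0))
  cx <- sweep_crossings(sw)
  expect_false(is.na(cx$S_star_stable))
  expect_false(is.na(cx$S_star_noise_vanish))
  # putative fixed points above the crossing are unstable
  above <- sw$S_star > cx$S_star_stable & !is.na(sw$lambda_stab)
  if (any(above)) expect_true(all(sw$lambda_stab[above] > 0))
})
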