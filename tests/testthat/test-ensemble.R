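test_that("parameter validation rejects inadmissible values", {
  expect_error(ensemble_params(c = 1.2), "connectance")
  expect_error(ensemble_params(M = 8, rho = -0.5), "rho")
  expect_error(ensemble_params(gamma = 1.5), "gamma")
  expect_error(ensemble_params(N_c = 0))
  expect_error(ensemble_params(sd_A = -0.1))
  # the negative equicorrelation boundary is admissible
  expect_s3_class(ensemble_params(M = 5, rho = -1 / 4), "ensemble_params")
})

test_that("sampled disorder has the prescribed sparsity and moments", {
  p <- ensemble_params(S = 300, M = 4, c = 0.25, mu_A = 0.3, sd_A = 0.45,
                       rho = 0.95, seed = 7)
  sys <- sample_interactions(p)
  off <- row(sys$mask) != col(sys$mask)
  n_off <- sum(off)
  frac <- mean(sys$mask[off])
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n_off))
  vals <- sys$A[, , 1][sys$mask]
  expect_lt(abs(mean(vals) - 0.3), 4 * 0.45 / sqrt(length(vals)))
  expect_lt(abs(sd(vals) - 0.45), 0.02)
  expect_true(all(sys$A[cbind(1:300, 1:300, 1)] == 0))
})

test_that("inter-patch correlation matches rho", {
  p <- ensemble_params(S = 300, M = 4, c = 0.25, mu_A = 0.3, sd_A = 0.45,
                       rho = 0.95, seed = 7)
  sys <- sample_interactions(p)
  cors <- c(cor(sys$A[, , 1][sys$mask], sys$A[, , 2][sys$mask]),
            cor(sys$A[, , 1][sys$mask], sys$A[, , 3][sys$mask]),
            cor(sys$A[, , 2][sys$mask], sys$A[, , 4][sys$mask]))
  expect_lt(max(abs(cors - 0.95)), 0.005)

  p0 <- ensemble_params(S = 300, M = 2, c = 0.25, rho = 0, seed = 8)
  s0 <- sample_interactions(p0)
  expect_lt(abs(cor(s0$A[, , 1][s0$mask], s0$A[, , 2][s0$mask])), 0.02)
})

test_that("degenerate parameter limits hold exactly", {
  # sd_A = 0: every nonzero entry equals mu_A in every patch
  s <- sample_interactions(ensemble_params(S = 40, M = 3, c = 0.3,
                                           mu_A = 0.7, sd_A = 0,
                                           rho = 0.5, seed = 3))
  expect_true(all(s$A[, , 2][s$mask] == 0.7))
  # rho = 1: identical interaction values in all patches
  s1 <- sample_interactions(ensemble_params(S = 40, M = 3, c = 0.3,
                                            rho = 1, seed = 3))
  expect_identical(s1$A[, , 1], s1$A[, , 2])
  expect_identical(s1$A[, , 1], s1$A[, , 3])
})

test_that("sampling is reproducible and seed-sensitive", {
  p <- ensemble_params(S = 25, M = 2, seed = 123)
  expect_identical(sample_interactions(p), sample_interactions(p))
  p2 <- ensemble_params(S = 25, M = 2, seed = 124)
  expect_false(identical(sample_interactions(p)$A,
                         sample_interactions(p2)$A))
})

test_that("reciprocity correlation gamma is realised", {
  s1 <- sample_interactions(ensemble_params(S = 60, M = 2, c = 0.5,
                                            gamma = 1, rho = 0.9,
                                            seed = 5))
  expect_equal(s1$A[, , 1], t(s1$A[, , 1]))
  expect_equal(s1$A[, , 2], t(s1$A[, , 2]))

  s5 <- sample_interactions(ensemble_params(S = 200, M = 1, c = 0.5,
                                            mu_A = 0, sd_A = 1,
                                            gamma = 0.5, seed = 6))
  up <- upper.tri(s5$mask) & s5$mask
  a_ij <- s5$A[, , 1][up]
  a_ji <- t(s5$A[, , 1])[up]
  expect_lt(abs(cor(a_ij, a_ji) - 0.5), 0.03)
})

test_that("migration operator couples all patch pairs uniformly", {
  s <- small_random_system(S = 5, M = 4, d = 0.09)
  expect_equal(diag(s$D), rep(0, 4))
  expect_true(all(s$D[row(s$D) != col(s$D)] == 0.09 / 3))
})

test_that("disorder scales follow the full-entry-distribution convention", {
  # fully connected, zero mean: sigma = sd_A * sqrt(S)
  sc <- disorder_scales(ensemble_params(S = 100, c = 1, mu_A = 0,
                                        sd_A = 0.2))
  expect_equal(sc$sigma, 0.2 * sqrt(100))
  expect_equal(sc$mu_tot, 0)
  # no interactions
  sc0 <- disorder_scales(ensemble_params(S = 100, c = 0))
  expect_equal(sc0$sigma, 0)
  expect_equal(sc0$mu_tot, 0)
  # parameter formula agrees with the empirical full-entry variance
  p <- ensemble_params(S = 400, M = 1, c = 1 / 8, mu_A = 0.3,
                       sd_A = 0.45, seed = 9)
  sys <- sample_interactions(p)
  off <- row(sys$mask) != col(sys$mask)
  emp_sigma2 <- 400 * var(sys$A[, , 1][off])
  expect_lt(abs(emp_sigma2 - disorder_scales(p)$sigma^2) /
              disorder_scales(p)$sigma^2, 0.05)
})
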