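test_that("diversity series counts surviving species", {
  sys <- small_random_system(S = 15, M = 2, seed = 51, c = 0.2,
                             mu_A = 0.1, sd_A = 0.1)
  tr <- simulate_metacommunity(sys, horizon = 50)
  d <- diversity_series(tr)
  expect_equal(d$S_star[1], 15)
  expect_true(all(diff(d$S_star) <= 0))
  expect_equal(d$S_star[nrow(d)],
               15 - nrow(tr$extinction_log))
})

test_that("kernel estimator recovers an injected exponential kernel", {
  # 200 independent OU series with C(tau) = C0 exp(-|tau|/tau0):
  # W = 2 C0 tau0, tau_c = tau0 (sigma = 1 so C_xi = C_N)
  C0 <- 2; tau0 <- 4; n <- 4000
  arr <- array(0, dim = c(40, 5, n))
  for (i in 1:40) for (u in 1:5)
    arr[i, u, ] <- 1.5 + ou_series(n, dt = 1, tau0 = tau0, C0 = C0,
                                   seed = 1000 + i * 5 + u)
  tr <- fake_trajectory(arr)
  k <- stationary_kernel(tr, sigma = 1, window = seq_len(n),
                         max_lag = 40)
  expect_lt(abs(k$C_xi[1] - C0) / C0, 0.05)
  expect_lt(abs(k$W - 2 * C0 * tau0) / (2 * C0 * tau0), 0.05)
  expect_lt(abs(k$tau_c - tau0) / tau0, 0.15)
  # doubling the window moves W by less than 10%
  k_half <- stationary_kernel(tr, sigma = 1, window = seq_len(n %/% 2),
                              max_lag = 40)
  expect_lt(abs(k$W - k_half$W) / k$W, 0.10)
})

test_that("constant and equilibrium trajectories carry zero noise", {
  arr <- array(0.8, dim = c(6, 2, 300))
  tr <- fake_trajectory(arr)
  k <- stationary_kernel(tr, sigma = 2, window = 1:300, max_lag = 20)
  expect_true(all(abs(k$C_N) < 1e-12))
  expect_equal(k$W, 0)
  expect_equal(noise_strength(tr, sigma = 2, window = 1:300), 0)
  # a dynamically reached fixed point likewise
  sys <- two_species_system(a = 0.5)
  tr2 <- simulate_metacommunity(sys, N0 = matrix(c(0.3, 0.9), 2, 1),
                                horizon = 400)
  k2 <- stationary_kernel(tr2, sigma = 2, window = 201:401, max_lag = 30)
  expect_lt(k2$C_xi[1], 1e-8)
  expect_lt(abs(k2$W), 1e-6)
})

test_that("noise strength squared equals the lag-0 noise kernel exactly", {
  arr <- array(abs(rnorm(8 * 2 * 500, 1, 0.3)), dim = c(8, 2, 500))
  tr <- fake_trajectory(arr)
  k <- stationary_kernel(tr, sigma = 1.7, window = 1:500, max_lag = 10)
  expect_equal(noise_strength(tr, sigma = 1.7, window = 1:500)^2,
               k$C_xi[1])
})

test_that("diffusion contribution matches the migration term", {
  sys1 <- logistic_system(M = 1)
  tr1 <- simulate_metacommunity(sys1, N0 = matrix(0.5), horizon = 10)
  expect_true(all(diffusion_contribution(tr1)$diff == 0))

  # M = 2, N = (2, 1), d = 0.1: source patch loses 0.1, sink gains 0.1
  sys2 <- logistic_system(M = 2, d = 0.1)
  arr <- array(c(2, 1), dim = c(1, 2, 3))
  tr2 <- fake_trajectory(arr, system = sys2)
  dd <- diffusion_contribution(tr2, system = sys2)
  expect_equal(dd$diff[1, 1, 1], -0.1)
  expect_equal(dd$diff[1, 2, 1], 0.1)

  # symmetric migration conserves individuals: patch sum is zero
  sys <- small_random_system(S = 10, M = 3, seed = 61)
  tr <- simulate_metacommunity(sys, horizon = 30)
  dd2 <- diffusion_contribution(tr)
  sums <- apply(dd2$diff, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-12)
})

test_that("source/sink persistence separates signal from noise", {
  # deterministic nonzero mean: every pair persistent
  arr <- array(0, dim = c(4, 2, 100))
  arr[, 1, ] <- 2; arr[, 2, ] <- 1
  sys <- logistic_system(M = 2, d = 0.1)
  # give species distinct values so some pairs are sources, some sinks
  arr[3:4, 1, ] <- 0.5; arr[3:4, 2, ] <- 1.5
  tr <- fake_trajectory(arr, system = sys)
  ss <- source_sink_stats(diffusion_contribution(tr, system = sys))
  expect_true(all(ss$table$persistent))
  expect_equal(ss$frac_all_persistent, 1)
  expect_setequal(unique(ss$table$label), c("source", "sink"))
  # sources are the pairs with negative mean migration contribution
  expect_true(all(ss$table$mean_diff[ss$table$label == "source"] < 0))

  # zero-mean white noise: persistent fraction collapses
  withr::local_seed(77)
  arrn <- array(rnorm(10 * 2 * 400), dim = c(10, 2, 400))
  din <- structure(list(diff = arrn, times = 1:400,
                        surviving = rep(TRUE, 10)),
                   class = "diffusion_series")
  ssn <- source_sink_stats(din)
  expect_lt(ssn$frac_all_persistent, 0.05)
})

test_that("interpatch synchrony separates coupled from independent patches", {
  base <- t(sapply(1:6, function(i)
    1 + 0.3 * sin(seq(0, 20, length.out = 400) + i)))
  arr <- array(0, dim = c(6, 2, 400))
  arr[, 1, ] <- base; arr[, 2, ] <- base      # duplicated patches
  expect_equal(interpatch_synchrony(fake_trajectory(arr), window = 1:400),
               1)
  withr::local_seed(88)
  arr[, 2, ] <- base[, sample(400)]           # scrambled: independent
  expect_lt(abs(interpatch_synchrony(fake_trajectory(arr),
                                     window = 1:400)), 0.15)
})

test_that("stationary window detection rejects drifting transients", {
  # strongly drifting synthetic abundances: no admissible window
  arr <- array(rep(seq(0.1, 2, length.out = 200), each = 8),
               dim = c(4, 2, 200))
  expect_error(stationary_window(fake_trajectory(arr)), "stationary")
  # a settled system passes
  flat <- array(abs(rnorm(4 * 2 * 200, 1, 0.05)), dim = c(4, 2, 200))
  expect_true(length(stationary_window(fake_trajectory(flat),
                                       min_length = 20)) >= 20)
})
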