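test_that("rhs matches hand-evaluated rates", {
  # logistic: N(1 - N) at N = 0.5
  expect_equal(lv_rhs(matrix(0.5), logistic_system())[1, 1], 0.25)
  # pure migration: patch 2 receives d * (N1 - N2)
  sys2 <- logistic_system(M = 2, d = 0.1)
  r <- lv_rhs(matrix(c(1, 0), 1, 2), sys2)
  expect_equal(r[1, 2], 0.1)
  # scalar-loop oracle on a random 3-species community
  sys3 <- small_random_system(S = 3, M = 1, seed = 2, c = 1)
  N <- matrix(c(0.4, 1.2, 0.7), 3, 1)
  oracle <- numeric(3)
  for (i in 1:3) {
    inter <- 0
    for (j in 1:3) inter <- inter + sys3$A[i, j, 1] * N[j, 1]
    oracle[i] <- N[i, 1] * (sys3$B[i, 1] - N[i, 1] - inter)
  }
  expect_equal(as.numeric(lv_rhs(N, sys3)), oracle)
})

test_that("two symmetric competitors converge to B/(1+a)", {
  sys <- two_species_system(a = 0.5)
  tr <- simulate_metacommunity(sys, N0 = matrix(c(0.3, 0.9), 2, 1),
                               horizon = 200)
  expect_equal(as.numeric(tr$state), c(2 / 3, 2 / 3), tolerance = 1e-6)
})

test_that("extinction rule removes species only when below cutoff everywhere", {
  N_c <- 1e-3
  st <- rbind(c(0.5 * N_c, 2 * N_c),    # survives in patch 2
              c(0.5 * N_c, 0.9 * N_c),  # below everywhere: removed
              c(N_c, N_c))              # exactly at cutoff: kept (strict)
  out <- apply_extinction_rule(st, N_c)
  expect_equal(out$removed, 2L)
  expect_true(all(out$N[2, ] == 0))
  expect_equal(out$N[1, ], st[1, ])
  expect_equal(out$N[3, ], st[3, ])
  expect_equal(out$alive, c(TRUE, FALSE, TRUE))
})

test_that("extinct species stay extinct along trajectories", {
  sys <- small_random_system(S = 20, M = 2, seed = 10, c = 0.6,
                             mu_A = 0.6, sd_A = 0.5, N_c = 1e-4)
  tr <- simulate_metacommunity(sys, horizon = 300, N_c = 1e-4)
  if (nrow(tr$extinction_log) > 0) {
    for (k in seq_len(nrow(tr$extinction_log))) {
      i <- tr$extinction_log$species[k]
      after <- tr$times > tr$extinction_log$time[k]
      expect_true(all(tr$N[i, , after] == 0))
    }
  }
  expect_true(all(diff(colSums(tr$alive)) <= 0))
  expect_true(all(tr$N >= 0))
})

test_that("d = 0 decouples patches", {
  p <- ensemble_params(S = 12, M = 2, c = 0.5, mu_A = 0.2, sd_A = 0.3,
                       rho = 0.8, d = 0, N_c = 1e-8, seed = 21)
  sys <- sample_interactions(p)
  N0 <- initial_state(sys)
  tr_joint <- simulate_metacommunity(sys, N0 = N0, horizon = 100)
  for (u in 1:2) {
    sys_u <- sys
    sys_u$A <- sys$A[, , u, drop = FALSE]
    sys_u$B <- sys$B[, u, drop = FALSE]
    sys_u$D <- matrix(0, 1, 1)
    sys_u$params$M <- 1L
    tr_u <- simulate_metacommunity(sys_u, N0 = N0[, u, drop = FALSE],
                                   horizon = 100)
    expect_lt(max(abs(tr_joint$N[, u, ] - tr_u$N[, 1, ])), 1e-5)
  }
})

test_that("integration is equivariant under species relabeling", {
  sys <- small_random_system(S = 8, M = 2, seed = 31, c = 0.6)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  sys_p <- sys
  sys_p$A <- sys$A[perm, perm, , drop = FALSE]
  sys_p$B <- sys$B[perm, , drop = FALSE]
  sys_p$mask <- sys$mask[perm, perm]
  N0 <- initial_state(sys)
  tr <- simulate_metacommunity(sys, N0 = N0, horizon = 50)
  tr_p <- simulate_metacommunity(sys_p, N0 = N0[perm, ], horizon = 50)
  expect_lt(max(abs(tr$N[perm, , ] - tr_p$N)), 1e-8)
})

test_that("halving tolerances leaves checkpoints nearly unchanged", {
  sys <- small_random_system(S = 10, M = 2, seed = 41, c = 0.5)
  N0 <- initial_state(sys)
  tr1 <- simulate_metacommunity(sys, N0 = N0, horizon = 50, rtol = 1e-6,
                                atol = 1e-10)
  tr2 <- simulate_metacommunity(sys, N0 = N0, horizon = 50, rtol = 5e-7,
                                atol = 5e-11)
  expect_lt(max(abs(tr1$N - tr2$N)), 1e-4)
})

test_that("fixed points are detected by the residual criterion", {
  sys <- two_species_system(a = 0.5)
  # all-extinct state is trivially stationary
  expect_true(detect_fixed_point(matrix(0, 2, 1), sys)$is_fixed_point)
  # the closed-form equilibrium
  expect_true(detect_fixed_point(matrix(2 / 3, 2, 1), sys,
                                 tol = 1e-8)$is_fixed_point)
  # a transient state is not
  expect_false(detect_fixed_point(matrix(c(0.1, 0.9), 2, 1),
                                  sys)$is_fixed_point)
})

test_that("annealing returns an equilibrated system unchanged and prunes a marginal species", {
  sys <- two_species_system(a = 0.5)
  ann <- anneal_to_fixed_point(sys, matrix(2 / 3, 2, 1),
                               N_c_start = 1e-8, stage_horizon = 50)
  expect_true(ann$success)
  expect_equal(sum(ann$alive), 2L)
  expect_equal(ann$N_c_final, 1e-8)

  # a fluctuating community: the rising cutoff prunes the most
  # extinction-prone (lowest-abundance) species until the survivors
  # admit a stable equilibrium
  p <- fluctuating_config(seed = 12)
  sysf <- sample_interactions(p)
  trf <- simulate_metacommunity(sysf, horizon = 2000)
  annf <- anneal_to_fixed_point(sysf, trf$state)
  expect_true(annf$success)
  expect_lt(sum(annf$alive), sum(trf$alive_final))
  expect_lt(lambda_stab(annf$state, sysf,
                        alive = annf$alive)$lambda_stab, 0)
  # the pruned species were typically the rarer ones in the
  # fluctuating state
  Nbar <- apply(trf$N[, , dim(trf$N)[3] %/% 2 + seq_len(500),
                      drop = FALSE], 1, mean)
  removed <- trf$alive_final & !annf$alive
  expect_lt(median(Nbar[removed]), median(Nbar[annf$alive]))
})
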