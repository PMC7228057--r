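# Builders for small deterministic systems used across tests.

# Two competing species with symmetric interaction a in one patch:
# closed-form equilibrium N1 = N2 = B / (1 + a).
two_species_system <- function(a = 0.5, B = 1, N_c = 1e-10) {
  p <- ensemble_params(S = 2, M = 1, c = 1, mu_A = a, sd_A = 0,
                       B = B, d = 0, N_c = N_c, seed = 1)
  sample_interactions(p)
}

# A single logistic species (no interactions).
logistic_system <- function(M = 1, B = 1, d = 0) {
  p <- ensemble_params(S = 1, M = M, c = 0, mu_A = 0, sd_A = 0,
                       B = B, d = d, N_c = 1e-10, seed = 1)
  sample_interactions(p)
}

small_random_system <- function(S = 10, M = 2, seed = 42, c = 0.5,
                                mu_A = 0.2, sd_A = 0.3, rho = 0.8,
                                d = 0.05, N_c = 1e-8) {
  sample_interactions(ensemble_params(S = S, M = M, c = c, mu_A = mu_A,
                                      sd_A = sd_A, rho = rho, d = d,
                                      N_c = N_c, seed = seed))
}

# Exact discretisation of an Ornstein-Uhlenbeck process: stationary
# autocovariance C0 * exp(-|tau| / tau0) on a grid of spacing dt.
# Independent of the package's FFT-based noise generator.
ou_series <- function(n, dt, tau0, C0, seed) {
  withr::local_seed(seed)
  a <- exp(-dt / tau0)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sqrt(C0))
  innov <- rnorm(n - 1, 0, sqrt(C0 * (1 - a^2)))
  for (t in 2:n) x[t] <- a * x[t - 1] + innov[t - 1]
  x
}

# Wrap a plain abundance array (species x patch x time) as a trajectory
# object so observable estimators can be exercised on synthetic data.
fake_trajectory <- function(N_arr, times = seq_len(dim(N_arr)[3]) - 1,
                            system = NULL) {
  S <- dim(N_arr)[1]
  structure(list(times = times, N = N_arr,
                 alive = matrix(TRUE, S, dim(N_arr)[3]),
                 extinction_log = data.frame(species = integer(),
                                             time = numeric()),
                 state = N_arr[, , dim(N_arr)[3], drop = TRUE],
                 alive_final = rep(TRUE, S),
                 system = system, N_c = 1e-8, checkpoint_dt = 1),
            class = "lv_trajectory")
}

# The Experiment-B style configuration at reduced size, in a regime with
# persistent fluctuations (denser network, moderate patch heterogeneity).
fluctuating_config <- function(seed = 11) {
  ensemble_params(S = 100, M = 4, c = 0.5, mu_A = 0.1, sd_A = 0.32,
                  rho = 0.7, d = 0.05, N_c = 1e-8, seed = seed)
}
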