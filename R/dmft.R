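#' Generate stationary colored Gaussian noise paths
#'
#' Samples stationary zero-mean Gaussian paths whose autocovariance on a
#' uniform time grid matches a prescribed kernel, by circulant embedding
#' (FFT). The kernel is linearly interpolated onto the grid and treated
#' as zero beyond its tabulated range. If the circulant embedding is not
#' positive semidefinite on the grid, negative eigenvalues are clipped
#' to zero with a warning (nearest-PSD projection).
#'
#' @param kernel a [correlation_kernel()].
#' @param T total duration (the paths have `round(T/dt) + 1` samples).
#' @param dt grid spacing; should be at most `tau_c / 10` for a faithful
#'   discretisation of the kernel.
#' @param n_paths number of independent paths.
#' @param seed integer seed.
#' @return A matrix with `round(T/dt) + 1` rows and `n_paths` columns.
#' @export
#' @examples
#' k <- exponential_kernel(C0 = 1, tau0 = 0.5)
#' xi <- generate_colored_noise(k, T = 20, dt = 0.05, n_paths = 4, seed = 1)
generate_colored_noise <- function(kernel, T, dt, n_paths, seed = 1L) {
  stopifnot(inherits(kernel, "correlation_kernel"), T > 0, dt > 0,
            n_paths >= 1)
  n <- round(T / dt) + 1L
  Cg <- approx(kernel$lags, kernel$C_xi, xout = (0:(n - 1L)) * dt,
               rule = 2, yright = 0)$y
  Cg[(0:(n - 1L)) * dt > max(kernel$lags)] <- 0
  if (all(Cg == 0)) return(matrix(0, n, n_paths))
  L <- 2L * (n - 1L)
  cvec <- c(Cg, Cg[(n - 1L):2L])
  ev <- Re(fft(cvec))
  if (min(ev) < -0.01 * max(ev)) {
    warning("kernel substantially non-positive-semidefinite on the grid; ",
            "clipping negative eigenvalues")
  }
  ev[ev < 0] <- 0
  amp <- sqrt(ev / L)
  withr::local_seed(seed)
  out <- matrix(0, n, n_paths)
  n_cplx <- ceiling(n_paths / 2)
  chunk <- max(1L, min(n_cplx, floor(2e7 / L)))
  j <- 1L
  while (j <= n_cplx) {
    jn <- min(n_cplx, j + chunk - 1L)
    k <- jn - j + 1L
    Z <- matrix(complex(real = rnorm(L * k), imaginary = rnorm(L * k)),
                L, k)
    Y <- mvfft(Z * amp)
    cr <- seq(2L * j - 1L, by = 2L, length.out = k)
    keep_r <- cr <= n_paths
    out[, cr[keep_r]] <- Re(Y[1:n, which(keep_r), drop = FALSE])
    ci <- seq(2L * j, by = 2L, length.out = k)
    keep_i <- ci <= n_paths
    if (any(keep_i))
      out[, ci[keep_i]] <- Im(Y[1:n, which(keep_i), drop = FALSE])
    j <- jn + 1L
  }
  out
}

#' Parameters of the representative metapopulation
#'
#' The single-species stochastic process produced by the mean-field
#' mapping: in each patch the abundance relaxes towards a characteristic
#' level `N_star[u]` under multiplicative colored noise, coupled to the
#' other patches by migration,
#' `dN_u/dt = N_u (N*_u - N_u + xi_u) + sum_v D_uv (N_v - N_u)`.
#'
#' @param N_star characteristic abundances, length-`M` vector (or an
#'   `n x M` matrix of per-realisation draws passed straight to
#'   [simulate_representative()]).
#' @param d total migration rate (pairwise rate `d/(M-1)`).
#' @param kernel the noise autocovariance, a [correlation_kernel()].
#' @param M number of patches (default from `N_star`).
#' @param interpatch_noise_corr correlation of the noise between patches
#'   (default 0: independent noise, the asynchronous regime).
#' @return An object of class `"representative_params"`.
#' @export
representative_params <- function(N_star, d = 0, kernel,
                                  M = if (is.matrix(N_star)) ncol(N_star)
                                      else length(N_star),
                                  interpatch_noise_corr = 0) {
  stopifnot(inherits(kernel, "correlation_kernel"), M >= 1, d >= 0,
            interpatch_noise_corr >= 0, interpatch_noise_corr <= 1)
  D <- matrix(if (M > 1) d / (M - 1) else 0, M, M)
  diag(D) <- 0
  structure(list(N_star = N_star, d = d, D = D, M = M, kernel = kernel,
                 interpatch_noise_corr = interpatch_noise_corr),
            class = "representative_params")
}

# noise cube (n_t, M, n_real), optionally correlated between patches
rep_noise_cube <- function(rep, T, dt, n_real, seed) {
  n <- round(T / dt) + 1L
  M <- rep$M
  r <- rep$interpatch_noise_corr
  xi <- generate_colored_noise(rep$kernel, T, dt, n_real * M, seed = seed)
  cube <- array(xi, dim = c(n, M, n_real))
  if (r > 0 && M > 1) {
    shared <- generate_colored_noise(rep$kernel, T, dt, n_real,
                                     seed = seed + 7L)
    for (k in seq_len(n_real))
      cube[, , k] <- sqrt(1 - r) * cube[, , k] + sqrt(r) * shared[, k]
  }
  cube
}

#' Simulate the representative metapopulation
#'
#' Integrates the representative stochastic dynamics for `n_real`
#' independent realisations with fresh noise, applying the all-patch
#' extinction cutoff (a realisation whose abundance drops below `N_c`
#' in every patch is zeroed permanently and counted as extinct).
#'
#' @param rep a [representative_params()] object.
#' @param T duration.
#' @param dt noise grid spacing (integration uses sub-steps of at most
#'   `max_step`).
#' @param n_real number of realisations.
#' @param N_c extinction cutoff (0 disables extinctions).
#' @param seed integer seed.
#' @param N0 initial abundances: scalar, length-`M`, or `n_real x M`
#'   matrix; default `pmax(N_star, 0.1)`.
#' @param record_dt recording interval (default `5 * dt`).
#' @param max_step upper bound on the integration sub-step.
#' @return An object of class `"rep_trajectory"`: list with `times`,
#'   abundance array `N` (`n_rec x M x n_real`), logical `absorbed`,
#'   absorption times `t_abs`, and the `rep` parameters.
#' @export
simulate_representative <- function(rep, T, dt = NULL, n_real = 1L,
                                    N_c = 0, seed = 1L, N0 = NULL,
                                    record_dt = NULL, max_step = 0.01) {
  stopifnot(inherits(rep, "representative_params"))
  if (is.null(dt)) {
    tc <- rep$kernel$tau_c
    dt <- if (is.finite(tc) && tc > 0) min(tc / 10, 0.05) else 0.05
  }
  M <- rep$M
  Nstar <- rep$N_star
  if (!is.matrix(Nstar)) Nstar <- matrix(Nstar, n_real, M, byrow = TRUE)
  stopifnot(nrow(Nstar) == n_real, ncol(Nstar) == M)
  if (is.null(N0)) N0 <- pmax(Nstar, 0.1)
  if (!is.matrix(N0)) N0 <- matrix(N0, n_real, M)
  substeps <- max(1L, ceiling(dt / max_step))
  xi <- rep_noise_cube(rep, T, dt, n_real, seed)
  record_every <- if (is.null(record_dt)) 5L else
    max(1L, round(record_dt / dt))
  res <- rep_integrate_cpp(Nstar, xi, rep$D, N0, dt, substeps,
                           N_c, if (N_c > 0) 1L else 0L, record_every, 0.5)
  if (res$status != 0)
    stop("representative integration unstable: one-step relative change ",
         "exceeded bound; reduce dt")
  n_rec <- dim(res$N)[1]
  structure(list(times = (0:(n_rec - 1L)) * dt * record_every,
                 N = res$N, absorbed = as.logical(res$absorbed),
                 t_abs = as.numeric(res$t_abs), rep = rep, dt = dt),
            class = "rep_trajectory")
}

#' Static (equilibrium) cavity theory
#'
#' Solves the self-consistent equations for the equilibrium assemblage
#' of a high-diversity random Lotka-Volterra community with uncorrelated
#' interaction directions: each species experiences an effective
#' carrying capacity `N* ~ Normal(B - mu_tot * mean_N, sigma^2 q)` and
#' survives at abundance `max(N*, 0)`. The three unknowns (survival
#' fraction `phi`, mean abundance `mean_N` and second moment `q`, both
#' over the full pool with extinct species counted as zero) close on
#' truncated-Gaussian identities; the solution reduces to a single root
#' find for the rescaled threshold `alpha = (B - mu_tot mean_N)/(sigma
#' sqrt(q))` through `(1 + alpha^2) pnorm(alpha) + alpha dnorm(alpha) =
#' 1 / sigma^2`.
#'
#' The implied maximal diversity of a pool of `S` species is `S * phi`.
#'
#' @param scales disorder scales, a list with `mu_tot` and `sigma` (see
#'   [disorder_scales()]).
#' @param B carrying capacity (scalar).
#' @param S optional pool size for the diversity bound.
#' @return A list with `phi`, `mean_N`, `q`, and (if `S` given)
#'   `diversity_bound = S * phi`.
#' @export
#' @examples
#' equilibrium_theory(list(mu_tot = 9.375, sigma = 2.96), B = 1, S = 250)
equilibrium_theory <- function(scales, B = 1, S = NULL) {
  mu <- scales$mu_tot; sigma <- scales$sigma
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0, B > 0)
  if (sigma == 0) {
    if (1 + mu <= 0) stop("no bounded equilibrium: 1 + mu_tot <= 0")
    m <- B / (1 + mu)
    out <- list(phi = 1, mean_N = m, q = m^2, alpha = Inf,
                mu_tot = mu, sigma = sigma, B = B)
  } else {
    f2 <- function(a) (1 + a^2) * pnorm(a) + a * dnorm(a)
    target <- 1 / sigma^2
    lo <- -20; hi <- 20
    while (f2(hi) < target) hi <- hi * 2
    alpha <- uniroot(function(a) f2(a) - target, c(lo, hi),
                     tol = 1e-12)$root
    f1 <- alpha * pnorm(alpha) + dnorm(alpha)
    denom <- alpha + mu * f1
    if (denom <= 0)
      stop("no physical branch: effective threshold diverges ",
           "(alpha + mu_tot * f1 <= 0)")
    s <- B / denom
    m <- s * f1
    q <- s^2 / sigma^2
    out <- list(phi = pnorm(alpha), mean_N = m, q = q, alpha = alpha,
                mu_tot = mu, sigma = sigma, B = B)
  }
  if (!is.null(S)) out$diversity_bound <- S * out$phi
  out
}

#' Self-consistent dynamical mean-field solution
#'
#' Iterates the mean-field closure for the representative
#' metapopulation. Each iteration (with its own fixed seed):
#' \enumerate{
#'   \item draws per-realisation characteristic abundances `N*_u` from
#'     the current equicorrelated Gaussian (mean `mean_Nstar`, variance
#'     `var_Nstar`, cross-patch covariance `cov_Nstar`);
#'   \item simulates the representative dynamics under the current noise
#'     kernel with the all-patch cutoff;
#'   \item measures, over a late-time window, the mean abundance `m`
#'     and second moment `q` over the full ensemble (extinct
#'     realisations count as zero), the connected within-patch
#'     autocorrelation `C_N`, and the persistent (time-mean) products
#'     within and between patches;
#'   \item updates `C_xi <- sigma^2 C_N`, `mean_Nstar <- B - mu_tot m`,
#'     `var_Nstar <- sigma^2 <Nbar_u^2>`, `cov_Nstar <- sigma^2 rho
#'     <Nbar_u Nbar_v>`, with damping.
#' }
#' Convergence is declared when the relative closure residual (maximum
#' over kernel lags and the `N*` statistics) stays below `tol`.
#'
#' By default the same quenched sample of `N*` draws and noise seeds is
#' reused at every iteration, which turns the closure into a
#' deterministic fixed-point problem that converges to the full
#' tolerance (with secant acceleration along the dominant slow mode);
#' the sampling error of the reported moments is then estimated from
#' fresh measurement-only passes. Near strongly-interacting scales the
#' closure map can have coexisting weak- and strong-noise fixed points;
#' `controls$init` selects the starting point, and `phi_target`
#' restricts the theory to a prescribed surviving fraction (removing
#' the most extinction-prone `N*` draws first), the matched-diversity
#' comparison used when relating theory to a pruned community.
#'
#' @param scales disorder scales (`mu_tot`, `sigma`).
#' @param B carrying capacity.
#' @param M number of patches.
#' @param rho inter-patch interaction correlation.
#' @param d total migration rate.
#' @param phi_target optional surviving fraction to impose (see above).
#' @param controls list overriding any of: `n_real` (realisations per
#'   iteration), `T` (duration), `dt` (noise grid), `record_dt`,
#'   `lag_max` (kernel support), `burn_frac`, `damping`, `max_iter`,
#'   `tol`, `N_c`, `surv_floor` (window-mean abundance below which a
#'   non-absorbed realisation still counts as lost), `n_avg`
#'   (measurement-only passes), `resample` (fresh randomness per
#'   iteration instead of the quenched sample), `init` (`"static"`:
#'   full-pool static cavity; `"weak"`: interaction-homogeneous start),
#'   `seed`.
#' @return An object of class `"dmft_solution"`: `mean_Nstar`,
#'   `var_Nstar`, `cov_Nstar`, `phi`, `mean_N`, `q`, the converged
#'   `kernel`, `converged`, `iterations`, `residual_history`,
#'   `closure_residual`, and a pooled sample `N_sample` of stationary
#'   surviving abundances from the final iteration.
#' @export
self_consistent_solve <- function(scales, B = 1, M = 1, rho = 0.95,
                                  d = 0.01, phi_target = NULL,
                                  controls = list()) {
  ctl <- modifyList(list(n_real = 200L, T = 200, dt = 0.05,
                         record_dt = 0.1, lag_max = 10, burn_frac = 0.4,
                         damping = if (isTRUE(controls$resample)) 0.3 else 0.6,
                         max_iter = 60L, tol = 5e-3,
                         N_c = 1e-8, surv_floor = 1e-3, n_avg = 3L,
                         resample = FALSE, init = "static", seed = 1L),
                    controls)
  mu <- scales$mu_tot; sigma <- scales$sigma
  stopifnot(M >= 1, sigma >= 0)

  # initialisation: the closure map can have coexisting fixed points
  # (a weak-noise state and a strong-noise maximal-heterogeneity one).
  # "static" starts from the full-pool static cavity; "weak" starts from
  # the interaction-homogeneous solution and grows towards the
  # weak-noise branch -- the state the pruned dynamics actually reaches.
  eq <- if (identical(ctl$init, "weak")) {
    m0 <- B / (1 + mu)
    list(phi = 1, mean_N = m0, q = m0^2)
  } else if (is.null(phi_target)) {
    equilibrium_theory(scales, B = B)
  } else {
    static_matched(scales, B = B, phi_target = phi_target)
  }
  mstar <- B - mu * eq$mean_N
  v <- sigma^2 * eq$q
  vx <- rho * v
  lag_grid <- seq(0, ctl$lag_max, by = ctl$record_dt)
  C_xi <- 0.5 * sigma^2 * eq$q * exp(-lag_grid / 2)
  if (sigma == 0) C_xi[] <- 0

  measure <- function(seed) {
    raw <- dmft_iteration(mstar, v, vx, lag_grid, C_xi, M, d, ctl, seed,
                          phi_target = phi_target)
    list(C_xi = sigma^2 * raw$C_conn, mstar = B - mu * raw$m,
         m = raw$m, q = raw$q, v = sigma^2 * raw$q0_within,
         vx = sigma^2 * rho * raw$q0_cross, phi = raw$phi,
         se_m = raw$se_m, se_v = sigma^2 * raw$se_q0,
         se_C0 = sigma^2 * raw$se_C0, N_sample = raw$N_sample)
  }

  # With resample = FALSE (default) the same quenched sample of N* draws
  # and noise seeds is reused at every iteration: the closure becomes a
  # deterministic fixed-point problem that can be converged to the full
  # tolerance. Sampling error of the reported moments is then estimated
  # from fresh measurement-only passes. resample = TRUE draws fresh
  # randomness each iteration (stochastic approximation), with
  # convergence bands widened by 3 Monte-Carlo standard errors.
  resid_hist <- numeric(0)
  converged <- FALSE
  ok_streak <- 0L
  it_done <- 0L
  dev_prev <- NULL
  ratios <- numeric(0)
  cool <- 0L          # iterations since the last accelerated step
  for (it in seq_len(ctl$max_iter)) {
    it_done <- it
    meas <- measure(if (ctl$resample) ctl$seed + 101L * it else ctl$seed)
    # kernels below half a percent of the natural scale sigma^2 q count
    # as zero: the equilibrium phase has no dynamical noise to resolve
    zero_kernel <- max(C_xi[1], meas$C_xi[1]) < 0.005 * sigma^2 * eq$q
    band_k <- if (zero_kernel) Inf else
      max(ctl$tol * max(C_xi[1], meas$C_xi[1]),
          if (ctl$resample) 3 * meas$se_C0 else 0, 1e-12)
    band_m <- max(ctl$tol * max(abs(mstar), 0.1),
                  if (ctl$resample) 3 * mu * meas$se_m else 0)
    band_v <- max(ctl$tol * max(v, 1e-12),
                  if (ctl$resample) 3 * meas$se_v else 0)
    dev <- c(meas$C_xi - C_xi, meas$mstar - mstar, meas$v - v,
             meas$vx - vx)
    nk <- length(C_xi)
    resid <- max(max(abs(dev[1:nk])) / band_k,
                 abs(dev[nk + 1]) / band_m, abs(dev[nk + 2]) / band_v)
    resid_hist <- c(resid_hist, resid)
    ok_streak <- if (resid < 1) ok_streak + 1L else 0L
    # damped update, plus a secant extrapolation along the dominant
    # slow mode when the deterministic iteration contracts geometrically
    th <- ctl$damping
    boost <- 0
    if (!ctl$resample && !is.null(dev_prev)) {
      n1 <- sqrt(sum(dev^2)); n0 <- sqrt(sum(dev_prev^2))
      cosang <- if (n1 > 0 && n0 > 0)
        sum(dev * dev_prev) / (n1 * n0) else 0
      ratios <- c(ratios, if (n0 > 0) n1 / n0 else 0)
      cool <- cool + 1L
      if (cool >= 5L && length(ratios) >= 3 &&
          all(tail(ratios, 3) > 0.5 & tail(ratios, 3) < 0.99) &&
          cosang > 0.8) {
        r <- exp(mean(log(tail(ratios, 3))))
        boost <- min(r / (1 - r), 12)
        cool <- 0L
      }
    }
    dev_prev <- dev
    step <- (th + boost) * dev
    C_xi <- C_xi + step[1:nk]
    mstar <- mstar + step[nk + 1]
    v <- max(v + step[nk + 2], 0)
    vx <- min(max(vx + step[nk + 3], 0), v)
    if (ok_streak >= 2L) {
      converged <- TRUE
      break
    }
  }

  # closure residual of the converged state against its own quenched
  # measurement (the quantity the iteration drives to zero)
  chk <- measure(if (ctl$resample) ctl$seed + 101L * (it_done + 1L)
                 else ctl$seed)
  closure_res <- max(abs(chk$C_xi - C_xi)) /
    max(C_xi[1], 0.005 * sigma^2 * eq$q, 1e-12)

  # fresh measurement-only passes at the final parameters: averaged
  # moments and pooled abundance sample with sampling error
  fin <- lapply(seq_len(ctl$n_avg), function(k)
    measure(ctl$seed + 7777L + 101L * k))
  avg <- function(f) Reduce(`+`, lapply(fin, `[[`, f)) / length(fin)
  kern <- correlation_kernel(lag_grid, C_xi,
                             C_N = if (sigma > 0) C_xi / sigma^2 else C_xi,
                             sigma = sigma)
  structure(list(
    mean_Nstar = mstar, var_Nstar = v, cov_Nstar = vx,
    phi = avg("phi"), mean_N = avg("m"), q = avg("q"),
    se_mean_N = fin[[1]]$se_m / sqrt(ctl$n_avg),
    kernel = kern, converged = converged, iterations = it_done,
    residual_history = resid_hist,
    closure_residual = closure_res,
    C_xi_measured = chk$C_xi,
    N_sample = unlist(lapply(fin, `[[`, "N_sample")),
    M = M, rho = rho, d = d, B = B,
    scales = scales, controls = ctl), class = "dmft_solution")
}

# Static cavity restricted to the surviving fraction phi_target: only
# the top phi_target of the N* distribution contributes abundance, the
# remainder being extinct. Used to initialise diversity-matched solves.
static_matched <- function(scales, B, phi_target, damping = 0.2,
                           max_iter = 2000, tol = 1e-10) {
  mu <- scales$mu_tot; sigma <- scales$sigma
  m <- B / (1 + max(mu, 0))
  q <- m^2
  for (k in seq_len(max_iter)) {
    mstar <- B - mu * m
    s <- max(sigma * sqrt(q), 1e-12)
    zcut <- mstar + s * qnorm(1 - phi_target)
    a <- max(zcut, 0)
    al <- (a - mstar) / s
    m_new <- mstar * pnorm(al, lower.tail = FALSE) + s * dnorm(al)
    q_new <- (mstar^2 + s^2) * pnorm(al, lower.tail = FALSE) +
      (mstar + a) * s * dnorm(al)
    if (abs(m_new - m) < tol && abs(q_new - q) < tol) {
      m <- m_new; q <- q_new
      break
    }
    m <- (1 - damping) * m + damping * m_new
    q <- (1 - damping) * q + damping * q_new
  }
  list(phi = phi_target, mean_N = m, q = q, mu_tot = mu, sigma = sigma,
       B = B)
}

# One forward pass of the mean-field closure: draw N*, simulate, measure.
# With phi_target set, only the top phi_target fraction of realisations
# by max-over-patches N* (the extinction-risk ranking) participates; the
# rest are extinct from the outset and contribute zeros, emulating a
# community whose most extinction-prone species have already been lost.
dmft_iteration <- function(mstar, v, vx, lag_grid, C_xi, M, d, ctl, seed,
                           phi_target = NULL) {
  withr::local_seed(seed)
  n_real <- ctl$n_real
  vx <- min(max(vx, 0), v)
  z0 <- rnorm(n_real)
  Zu <- matrix(rnorm(n_real * M), n_real, M)
  Nstar <- mstar + sqrt(vx) * z0 + sqrt(max(v - vx, 0)) * Zu
  dead0 <- rep(FALSE, n_real)
  if (!is.null(phi_target)) {
    risk <- apply(Nstar, 1, max)
    dead0 <- rank(risk, ties.method = "first") <=
      round((1 - phi_target) * n_real)
  }

  kern <- correlation_kernel(lag_grid, C_xi)
  rp <- representative_params(Nstar, d = d, kernel = kern, M = M)
  # start at the characteristic abundance: survivors are equilibrated
  # from the outset, doomed realisations carry negligible weight.
  # Strong transient kernels can make the default sub-step too coarse;
  # halve it until the integration passes its stability guard.
  N0 <- pmax(Nstar, 0.01)
  N0[dead0, ] <- 0
  tr <- NULL
  h <- 0.01
  for (try in 1:4) {
    tr <- tryCatch(suppressWarnings(
      simulate_representative(rp, T = ctl$T, dt = ctl$dt,
                              n_real = n_real, N_c = ctl$N_c,
                              seed = seed + 1L, N0 = N0,
                              record_dt = ctl$record_dt, max_step = h)),
      error = function(e) NULL)
    if (!is.null(tr)) break
    h <- h / 2
  }
  if (is.null(tr))
    stop("representative integration unstable even at max_step = ", h * 2)
  n_rec <- dim(tr$N)[1]
  win <- seq(floor(ctl$burn_frac * n_rec) + 1L, n_rec)
  Nw <- tr$N[win, , , drop = FALSE]                 # time x patch x real

  m <- mean(Nw)
  q <- mean(Nw^2)
  Nbar <- apply(Nw, c(2, 3), mean)                  # patch x real
  q0_within <- mean(Nbar^2)
  q0_cross <- if (M > 1) {
    # Nbar is M x n_real; average of Nbar_u * Nbar_v over patch pairs
    tot <- colSums(Nbar)^2
    diag2 <- colSums(Nbar^2)
    mean((tot - diag2) / (M * (M - 1)))
  } else q0_within

  n_lag <- length(lag_grid) - 1L
  X <- matrix(Nw, nrow = length(win))               # columns: patch x real
  keep <- colSums(X^2) > 0
  C_conn <- if (any(keep)) {
    ac <- acov_columns(X[, keep, drop = FALSE], n_lag, demean = TRUE)
    rowSums(ac) / ncol(X)                           # extinct contribute 0
  } else rep(0, n_lag + 1L)

  # Monte-Carlo standard errors across realisations
  rmean <- apply(Nw, 3, mean)
  se_m <- sd(rmean) / sqrt(n_real)
  nb2 <- colMeans(Nbar^2)                           # per-realisation
  se_q0 <- sd(nb2) / sqrt(n_real)
  vs <- colMeans(X^2) - colMeans(X)^2
  vr <- colMeans(matrix(vs, nrow = M))              # per-realisation
  se_C0 <- sd(vr) / sqrt(n_real)

  # survivors: not absorbed and not decaying towards extinction
  surv <- !tr$absorbed & apply(Nbar, 2, max) > ctl$surv_floor
  N_sample <- as.numeric(Nw[, , surv, drop = FALSE])
  N_sample <- N_sample[N_sample > 0]
  if (length(N_sample) > 20000)
    N_sample <- N_sample[round(seq(1, length(N_sample), length.out = 20000))]

  list(C_conn = C_conn, m = m, q = q, q0_within = q0_within,
       q0_cross = q0_cross, phi = mean(surv),
       se_m = se_m, se_q0 = se_q0, se_C0 = se_C0, N_sample = N_sample)
}

#' @export
print.dmft_solution <- function(x, ...) {
  cat(sprintf(
    "dmft_solution (M = %d): phi = %.3f, mean_N = %.4g, q = %.4g\n",
    x$M, x$phi, x$mean_N, x$q))
  cat(sprintf(
    "  N*: mean %.4g, var %.4g, cross-cov %.4g; std(xi) = %.4g\n",
    x$mean_Nstar, x$var_Nstar, x$cov_Nstar, sqrt(max(x$kernel$C_xi[1], 0))))
  cat(sprintf("  %s after %d iterations (last residual %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, tail(x$residual_history, 1)))
  invisible(x)
}

#' Predicted distribution of the effective characteristic abundance
#'
#' From a converged mean-field solution, the characteristic abundances
#' `N*_u` of a species across the `M` patches are equicorrelated
#' Gaussian; the effective cross-patch value governing extinction risk
#' is their maximum (one source patch is enough to rescue the species).
#' This returns the density of `N*_eff = max_u N*_u` restricted to the
#' positive (survival) region; its integral over the positive support is
#' the predicted surviving fraction.
#'
#' @param solution a converged `"dmft_solution"`.
#' @param M number of patches (default from the solution).
#' @param x evaluation grid (default: automatic).
#' @return A list with `x`, `density` (unnormalised on `x > 0`), and
#'   `phi` (`P(N*_eff > 0)`).
#' @export
predicted_nstar_distribution <- function(solution, M = solution$M,
                                         x = NULL) {
  stopifnot(inherits(solution, "dmft_solution"))
  if (!solution$converged)
    stop("refusing to evaluate an unconverged solution")
  mu <- solution$mean_Nstar
  v <- solution$var_Nstar
  vx <- min(max(solution$cov_Nstar, 0), v)
  vi <- max(v - vx, 0)
  sdt <- sqrt(v)
  if (is.null(x)) x <- seq(mu - 4 * sdt, mu + 5 * sdt, length.out = 400)
  zg <- seq(-7, 7, by = 0.02)
  wz <- dnorm(zg) * 0.02
  if (vi < 1e-14) {
    dens <- dnorm(x, mean = mu, sd = sqrt(vx))
    phi <- 1 - pnorm(0, mean = mu, sd = sqrt(vx))
  } else {
    si <- sqrt(vi)
    dens <- vapply(x, function(xx) {
      u <- (xx - mu - sqrt(vx) * zg) / si
      sum(wz * M * pnorm(u)^(M - 1) * dnorm(u) / si)
    }, numeric(1))
    u0 <- (0 - mu - sqrt(vx) * zg) / si
    phi <- 1 - sum(wz * pnorm(u0)^M)
  }
  keep <- x > 0
  list(x = x[keep], density = dens[keep], phi = phi, M = M)
}
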