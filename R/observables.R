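#' Diversity time series
#'
#' Counts the species not yet removed by the extinction rule at each
#' recorded checkpoint.
#'
#' @param trajectory an [simulate_metacommunity()] trajectory.
#' @return A data.frame with columns `time` and `S_star` (non-increasing).
#' @export
diversity_series <- function(trajectory) {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  data.frame(time = trajectory$times,
             S_star = colSums(trajectory$alive))
}

#' Detect a stationary late-time window
#'
#' Scans suffixes of the trajectory for the longest window that passes
#' two split-half drift tests: the community mean abundance (over
#' species surviving to the end) and the diversity `S*(t)` must each
#' change by less than `drift_tol` (relative) between the two halves.
#'
#' @param trajectory an `lv_trajectory`.
#' @param drift_tol relative drift tolerance (default 0.05).
#' @param min_length minimum window length in checkpoints.
#' @return Integer vector of checkpoint indices forming the window.
#' @export
stationary_window <- function(trajectory, drift_tol = 0.05,
                              min_length = 50L) {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  Tn <- length(trajectory$times)
  surv <- trajectory$alive_final
  if (!any(surv)) stop("no surviving species")
  m_t <- apply(trajectory$N[surv, , , drop = FALSE], 3, mean)
  S_t <- colSums(trajectory$alive)
  ok <- function(idx) {
    h <- length(idx) %/% 2
    m1 <- mean(m_t[idx[1:h]]); m2 <- mean(m_t[idx[(h + 1):length(idx)]])
    s1 <- mean(S_t[idx[1:h]]); s2 <- mean(S_t[idx[(h + 1):length(idx)]])
    abs(m2 - m1) / ((m1 + m2) / 2) < drift_tol &&
      abs(s2 - s1) / ((s1 + s2) / 2) < drift_tol
  }
  for (start in unique(pmax(1L, floor(Tn * seq(0.5, 0.9, by = 0.1))))) {
    idx <- start:Tn
    if (length(idx) >= min_length && ok(idx)) return(idx)
  }
  stop("no stationary window found (mean abundance or diversity still drifting)")
}

#' Correlation kernel container
#'
#' Holds a stationary lag kernel on a uniform grid of non-negative lags,
#' together with its integrated power `W` (full-line integral, exploiting
#' lag symmetry) and correlation time `tau_c` (lag of decay to `1/e` of
#' the lag-0 value).
#'
#' @param lags non-negative lags, uniformly spaced from 0.
#' @param C_xi noise kernel values at those lags.
#' @param C_N abundance autocorrelation (optional; `C_xi / sigma^2`).
#' @param sigma interaction heterogeneity used in the closure.
#' @param truncate_at index beyond which the kernel is treated as zero
#'   for the `W` integral (default: full range).
#' @return An object of class `"correlation_kernel"`.
#' @export
correlation_kernel <- function(lags, C_xi, C_N = NULL, sigma = NA_real_,
                               truncate_at = length(lags)) {
  stopifnot(length(lags) == length(C_xi), !is.unsorted(lags), lags[1] == 0)
  keep <- seq_len(truncate_at)
  W <- full_line_integral(lags[keep], C_xi[keep])
  tau_c <- NA_real_
  if (length(lags) > 1 && C_xi[1] > 0) {
    target <- C_xi[1] / exp(1)
    below <- which(C_xi <= target)
    if (length(below) > 0) {
      k <- below[1]
      tau_c <- if (k == 1) 0 else
        approx(C_xi[(k - 1):k], lags[(k - 1):k], xout = target)$y
    }
  }
  structure(list(lags = lags, C_xi = C_xi, C_N = C_N, sigma = sigma,
                 W = W, tau_c = tau_c, truncate_at = truncate_at),
            class = "correlation_kernel")
}

#' @export
print.correlation_kernel <- function(x, ...) {
  cat(sprintf(
    "correlation_kernel: %d lags up to %.3g; C_xi(0) = %.4g, W = %.4g, tau_c = %.3g\n",
    length(x$lags), max(x$lags), x$C_xi[1], x$W, x$tau_c))
  invisible(x)
}

#' An exponential correlation kernel
#'
#' `C(tau) = C0 * exp(-|tau| / tau0)`, for which the full-line integrated
#' power is `W = 2 C0 tau0` and the correlation time is `tau0`.
#'
#' @param C0 lag-0 value (noise variance).
#' @param tau0 decay time.
#' @param lag_max largest tabulated lag (default `10 tau0`).
#' @param dt lag grid spacing (default `tau0 / 20`).
#' @return A [correlation_kernel()].
#' @export
exponential_kernel <- function(C0, tau0, lag_max = 10 * tau0,
                               dt = tau0 / 20) {
  lags <- seq(0, lag_max, by = dt)
  correlation_kernel(lags, C0 * exp(-lags / tau0))
}

#' Stationary autocorrelation kernel of a trajectory
#'
#' Estimates the species/patch-averaged connected autocorrelation
#' `C_N(tau)` of the abundances over a stationary window (each surviving
#' species-patch series has its own time mean removed), and forms the
#' ecological-noise kernel through the closure `C_xi = sigma^2 C_N`.
#' The `W` integral is truncated at the first lag beyond which `|C_xi|`
#' stays below a noise floor of twice the standard deviation of the
#' large-lag kernel values.
#'
#' @param trajectory an `lv_trajectory`.
#' @param sigma interaction heterogeneity (see [disorder_scales()]).
#' @param window checkpoint indices (default [stationary_window()]).
#' @param max_lag largest lag in model time units (default 50
#'   checkpoints' worth).
#' @return A [correlation_kernel()] with `C_N` (connected), `C_xi`, `W`
#'   and `tau_c`.
#' @export
stationary_kernel <- function(trajectory, sigma,
                              window = stationary_window(trajectory),
                              max_lag = NULL) {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  dt <- diff(trajectory$times[window[1:2]])
  if (is.null(max_lag)) max_lag <- 50 * dt
  n_lag <- min(length(window) %/% 3L, round(max_lag / dt))
  surv <- trajectory$alive_final
  X <- matrix(aperm(trajectory$N[surv, , window, drop = FALSE], c(3, 1, 2)),
              nrow = length(window))
  ac <- acov_columns(X, n_lag, demean = TRUE)
  C_N <- rowMeans(ac)
  lags <- (0:n_lag) * dt
  C_xi <- sigma^2 * C_N
  # noise floor from the large-lag tail
  tail_idx <- seq(max(2L, floor(0.75 * n_lag)), n_lag + 1L)
  floor_level <- 2 * sd(C_xi[tail_idx])
  trunc <- n_lag + 1L
  if (is.finite(floor_level) && floor_level > 0) {
    above <- which(abs(C_xi) >= floor_level)
    if (length(above) > 0 && max(above) < n_lag + 1L)
      trunc <- max(above) + 1L
  }
  k <- correlation_kernel(lags, C_xi, C_N = C_N, sigma = sigma,
                          truncate_at = trunc)
  if (is.finite(k$tau_c) && k$tau_c > 0 &&
      length(window) * dt < 50 * k$tau_c)
    warning("stationary window shorter than 50 correlation times; ",
            "kernel estimate may be unreliable")
  k$n_series <- ncol(X)
  k
}

#' Strength of the endogenous fluctuations
#'
#' `std(xi) = sigma * sqrt(mean temporal variance of N)` over surviving
#' species-patch pairs; identical to `sqrt(C_xi(0))` of
#' [stationary_kernel()] computed on the same window.
#'
#' @inheritParams stationary_kernel
#' @return Scalar `std(xi)`; zero at an equilibrium.
#' @export
noise_strength <- function(trajectory, sigma,
                           window = stationary_window(trajectory)) {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  surv <- trajectory$alive_final
  X <- matrix(aperm(trajectory$N[surv, , window, drop = FALSE], c(3, 1, 2)),
              nrow = length(window))
  v <- pmax(colMeans(X^2) - colMeans(X)^2, 0)  # divisor-n variance
  sigma * sqrt(mean(v))
}

#' Migration (diffusion) contribution to the growth of each population
#'
#' Evaluates `sum_v D_uv (N_iv - N_iu)` along the trajectory: the net
#' rate at which individuals of species `i` flow into patch `u`.
#' Negative time-average marks a source patch (net exporter), positive a
#' sink.
#'
#' @param trajectory an `lv_trajectory`.
#' @param system interaction set (defaults to the trajectory's).
#' @param window checkpoint indices (default: all).
#' @return An object of class `"diffusion_series"`: list with the
#'   `S x M x T` array `diff`, `times`, and the surviving-species mask.
#' @export
diffusion_contribution <- function(trajectory, system = trajectory$system,
                                   window = seq_along(trajectory$times)) {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  D <- system$D
  drow <- rowSums(D)
  N <- trajectory$N[, , window, drop = FALSE]
  S <- dim(N)[1]; M <- dim(N)[2]; Tn <- dim(N)[3]
  dif <- array(0, dim = dim(N))
  for (t in seq_len(Tn)) {
    Nt <- matrix(N[, , t], S, M)
    dif[, , t] <- Nt %*% t(D) - sweep(Nt, 2, drow, `*`)
  }
  structure(list(diff = dif, times = trajectory$times[window],
                 surviving = trajectory$alive_final),
            class = "diffusion_series")
}

#' Source/sink persistence statistics
#'
#' For every surviving species-patch pair, the time average `mean_diff`
#' and temporal standard deviation `sd_diff` of the migration
#' contribution to growth. A pair is a `source` when `mean_diff < 0`
#' (net exporter) and `persistent` when the average is at least one
#' standard deviation away from zero, i.e. the pair retains its
#' source/sink identity most of the time.
#'
#' @param diff_series a [diffusion_contribution()] object.
#' @return A list with the per-pair `table` (data.frame) and the summary
#'   fractions `frac_sources_persistent` (among sources) and
#'   `frac_all_persistent` (among all surviving pairs).
#' @export
source_sink_stats <- function(diff_series) {
  stopifnot(inherits(diff_series, "diffusion_series"))
  d <- diff_series$diff
  surv <- which(diff_series$surviving)
  S <- dim(d)[1]; M <- dim(d)[2]
  rows <- expand.grid(species = surv, patch = seq_len(M))
  mean_diff <- sd_diff <- numeric(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    x <- d[rows$species[r], rows$patch[r], ]
    mean_diff[r] <- mean(x)
    sd_diff[r] <- sd(x)
  }
  tab <- data.frame(rows, mean_diff = mean_diff, sd_diff = sd_diff)
  tab$label <- ifelse(tab$mean_diff < 0, "source", "sink")
  tab$persistent <- abs(tab$mean_diff) >= tab$sd_diff
  src <- tab$label == "source"
  list(table = tab,
       frac_sources_persistent = if (any(src)) mean(tab$persistent[src]) else NA_real_,
       frac_all_persistent = mean(tab$persistent),
       n_sources = sum(src), n_pairs = nrow(tab))
}

#' Mean inter-patch synchrony of abundance fluctuations
#'
#' Averages, over surviving species and over patch pairs, the Pearson
#' correlation between the abundance time series of the same species in
#' two patches (each series centred on its own mean).
#'
#' @inheritParams stationary_kernel
#' @return Scalar mean cross-patch correlation.
#' @export
interpatch_synchrony <- function(trajectory,
                                 window = stationary_window(trajectory)) {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  M <- dim(trajectory$N)[2]
  if (M < 2) stop("interpatch synchrony requires M >= 2")
  surv <- which(trajectory$alive_final)
  vals <- c()
  for (i in surv) {
    X <- t(trajectory$N[i, , window, drop = TRUE])   # time x patch
    if (any(apply(X, 2, sd) == 0)) next
    cc <- cor(X)
    vals <- c(vals, cc[upper.tri(cc)])
  }
  mean(vals)
}
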