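# Internal numerical helpers shared across modules.

# Autocovariance of each column of X up to max_lag, via FFT.
# divisor n (biased estimator) so that lag-0 equals the per-series
# variance with divisor n; demean removes each series' own mean.
acov_columns <- function(X, max_lag, demean = TRUE, chunk = 400L) {
  X <- as.matrix(X)
  n <- nrow(X); K <- ncol(X)
  if (demean) X <- sweep(X, 2, colMeans(X))
  nfft <- stats::nextn(2L * n, 2)
  out <- matrix(0, max_lag + 1L, K)
  for (j0 in seq(1L, K, by = chunk)) {
    j1 <- min(K, j0 + chunk - 1L)
    Xp <- rbind(X[, j0:j1, drop = FALSE],
                matrix(0, nfft - n, j1 - j0 + 1L))
    F <- mvfft(Xp)
    ac <- Re(mvfft(F * Conj(F), inverse = TRUE)) / nfft
    out[, j0:j1] <- ac[seq_len(max_lag + 1L), , drop = FALSE] / n
  }
  out
}

# Trapezoidal full-line integral of a symmetric kernel given on lags >= 0.
full_line_integral <- function(lags, C) {
  if (length(lags) < 2) return(0)
  2 * pracma::trapz(lags, C)
}

# Simple deterministic hex hash of an R object (provenance stamps).
object_hash <- function(x) {
  b <- serialize(x, NULL, version = 2)
  b <- as.integer(b)
  h1 <- 0; h2 <- 0
  for (i in seq_along(b)) {
    h1 <- (h1 * 31 + b[i]) %% 2147483647
    h2 <- (h2 * 131 + b[i]) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

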