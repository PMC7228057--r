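#' Parameters of the random-metacommunity ensemble
#'
#' Bundles and validates the parameters defining the quenched-disorder
#' ensemble of a Lotka-Volterra metacommunity: a pool of `S` species on
#' `M` patches, a directed interaction network of connectance `c`, and
#' Gaussian nonzero interaction coefficients whose values differ slightly
#' between patches with equicorrelation `rho`.
#'
#' @param S species-pool size.
#' @param M number of patches.
#' @param c connectance: probability that a directed pair `(i, j)`
#'   interacts, in `[0, 1]`. The Bernoulli draw is shared by all patches,
#'   so a pair interacts everywhere or nowhere.
#' @param mu_A mean of the nonzero interaction coefficients.
#' @param sd_A standard deviation of the nonzero coefficients.
#' @param rho inter-patch correlation of a given coefficient's values
#'   across patches; must lie in `[-1/(M-1), 1]` (the positive-definite
#'   range of an equicorrelation matrix). `rho = 1` makes all patches
#'   share identical interaction values.
#' @param gamma correlation between `A[i,j,u]` and `A[j,i,u]` within a
#'   patch (reciprocity); default 0 (fully independent directions).
#' @param B carrying capacity, either a scalar (used for every
#'   species-patch) or an `S x M` matrix.
#' @param d total migration rate out of a patch; each pair of patches is
#'   coupled at rate `d/(M-1)`.
#' @param N_c extinction cutoff: a species whose abundance is below `N_c`
#'   in every patch simultaneously is removed permanently. `1/N_c` sets
#'   the absolute population-size scale.
#' @param seed integer seed; the sampled disorder is a deterministic
#'   function of the parameters and the seed.
#'
#' @return An object of class `"ensemble_params"` (a validated list).
#' @seealso [sample_interactions()], [disorder_scales()]
#' @export
#' @examples
#' ensemble_params(S = 250, M = 8, c = 1 / 8, mu_A = 0.3, sd_A = 0.45,
#'                 rho = 0.95)
ensemble_params <- function(S = 250, M = 8, c = 1 / 8, mu_A = 0.3,
                            sd_A = 0.45, rho = 0.95, gamma = 0, B = 1,
                            d = 0.01, N_c = 1e-8, seed = 1L) {
  stopifnot(S >= 1, M >= 1, sd_A >= 0, N_c > 0, d >= 0)
  if (c < 0 || c > 1) stop("connectance `c` must lie in [0, 1]")
  rho_min <- if (M > 1) -1 / (M - 1) else -1
  if (rho < rho_min - 1e-12 || rho > 1)
    stop(sprintf("`rho` outside the positive-definite range [%.4f, 1]",
                 rho_min))
  if (gamma < -1 || gamma > 1) stop("`gamma` must lie in [-1, 1]")
  if (is.matrix(B)) {
    if (!all(dim(B) == c(S, M))) stop("matrix `B` must be S x M")
  } else {
    stopifnot(length(B) == 1, is.finite(B))
  }
  structure(list(S = as.integer(S), M = as.integer(M), c = c, mu_A = mu_A,
                 sd_A = sd_A, rho = rho, gamma = gamma, B = B, d = d,
                 N_c = N_c, seed = as.integer(seed)),
            class = "ensemble_params")
}

#' @export
print.ensemble_params <- function(x, ...) {
  cat(sprintf(
    "ensemble_params: S = %d, M = %d, c = %.4g, A ~ N(%.3g, %.3g^2)\n",
    x$S, x$M, x$c, x$mu_A, x$sd_A))
  cat(sprintf("  rho = %.3g, gamma = %.3g, d = %.3g, N_c = %.3g, seed = %d\n",
              x$rho, x$gamma, x$d, x$N_c, x$seed))
  sc <- disorder_scales(x)
  cat(sprintf("  rescaled disorder: mu_tot = %.4g, sigma = %.4g\n",
              sc$mu_tot, sc$sigma))
  invisible(x)
}

#' Sample a quenched metacommunity interaction set
#'
#' Draws one realisation of the disorder: a sparsity mask shared across
#' patches (each directed off-diagonal pair is nonzero with probability
#' `c`), and for each nonzero pair `M` jointly Gaussian values, each
#' marginally `N(mu_A, sd_A^2)`, with equicorrelation `rho` between
#' patches. The patch values are built from a shared and an idiosyncratic
#' standard-normal component,
#' `A[i,j,u] = mu_A + sd_A * (alpha * zbar + beta * (z_u - zbar))`
#' with `beta = sqrt(1 - rho)` and `alpha = sqrt(1 + (M-1) rho)`, which
#' realises the equicorrelation exactly for any admissible `rho`
#' (including negative values down to `-1/(M-1)`).
#'
#' When `gamma != 0`, the mask is drawn on unordered pairs (both
#' directions present or absent together) and the standard-normal
#' components of `(i,j)` and `(j,i)` are correlated with coefficient
#' `gamma`, so that `cor(A[i,j,u], A[j,i,u]) = gamma`; `gamma = 1` gives
#' exactly symmetric interactions.
#'
#' @param params an [ensemble_params()] object.
#' @return An object of class `"interaction_set"`: list with the `S x S x M`
#'   interaction array `A` (zero diagonal), `S x M` carrying capacities
#'   `B`, `M x M` migration matrix `D` with off-diagonal `d/(M-1)`, the
#'   logical sparsity `mask`, and `params`.
#' @export
#' @examples
#' sys <- sample_interactions(ensemble_params(S = 20, M = 2, seed = 4))
#' dim(sys$A)
sample_interactions <- function(params) {
  stopifnot(inherits(params, "ensemble_params"))
  S <- params$S; M <- params$M
  withr::local_seed(params$seed)

  # sparsity mask, one Bernoulli draw per directed (gamma == 0) or
  # unordered (gamma != 0) off-diagonal pair, shared across patches
  mask <- matrix(FALSE, S, S)
  if (params$gamma == 0) {
    mask[] <- runif(S * S) < params$c
  } else {
    up <- upper.tri(mask)
    draw <- matrix(FALSE, S, S)
    draw[up] <- runif(sum(up)) < params$c
    mask <- draw | t(draw)
  }
  diag(mask) <- FALSE

  A <- array(0, dim = c(S, S, M))
  idx <- which(mask)                      # linear indices in an S x S slice
  n_nz <- length(idx)
  if (n_nz > 0 && M >= 1) {
    alpha <- sqrt(max(0, 1 + (M - 1) * params$rho))
    beta <- sqrt(max(0, 1 - params$rho))
    # standard-normal components: shared across patches (via zbar) and
    # idiosyncratic; reciprocity correlation gamma applied to both.
    Z <- matrix(rnorm(n_nz * M), n_nz, M)
    if (params$gamma != 0) {
      # pair up (i,j) and (j,i): both are in idx because mask is symmetric
      ii <- ((idx - 1) %% S) + 1
      jj <- ((idx - 1) %/% S) + 1
      tidx <- (ii - 1) * S + jj            # linear index of the transpose
      pos <- match(tidx, idx)
      first <- which(ii < jj)              # handle each unordered pair once
      g <- params$gamma
      Z2 <- matrix(rnorm(n_nz * M), n_nz, M)
      Z[pos[first], ] <- g * Z[first, ] + sqrt(1 - g^2) * Z2[first, ]
    }
    zbar <- rowMeans(Z)
    vals <- params$mu_A + params$sd_A *
      (alpha * zbar + beta * (Z - zbar))
    for (u in seq_len(M)) {
      slice <- matrix(0, S, S)
      slice[idx] <- vals[, u]
      A[, , u] <- slice
    }
  }

  B <- if (is.matrix(params$B)) params$B else matrix(params$B, S, M)
  D <- matrix(if (M > 1) params$d / (M - 1) else 0, M, M)
  diag(D) <- 0

  structure(list(A = A, B = B, D = D, mask = mask, params = params),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  p <- x$params
  cat(sprintf("interaction_set: S = %d, M = %d, %d nonzero pairs (%.3f of off-diagonal)\n",
              p$S, p$M, sum(x$mask), mean(x$mask[row(x$mask) != col(x$mask)])))
  invisible(x)
}

#' Rescaled disorder parameters
#'
#' Computes the two parameters through which the disorder enters the
#' large-`S` theory: the total mean interaction load
#' `mu_tot = c S mu_A` and the rescaled interaction heterogeneity
#' `sigma = sqrt(S var(A))` where `var(A)` is the variance of the full
#' entry distribution including the zero mass,
#' `var(A) = c (sd_A^2 + (1 - c) mu_A^2)`, so
#' `sigma^2 = c S (sd_A^2 + (1 - c) mu_A^2)`. This convention reduces to
#' `sigma = sd_A sqrt(S)` for a fully connected network.
#'
#' @param params an [ensemble_params()] object.
#' @return A list with elements `mu_tot` and `sigma`.
#' @export
#' @examples
#' disorder_scales(ensemble_params(S = 250, c = 1 / 8, mu_A = 0.3,
#'                                 sd_A = 0.45))
disorder_scales <- function(params) {
  stopifnot(inherits(params, "ensemble_params"))
  mu_tot <- params$c * params$S * params$mu_A
  sigma2 <- params$c * params$S *
    (params$sd_A^2 + (1 - params$c) * params$mu_A^2)
  list(mu_tot = mu_tot, sigma = sqrt(sigma2))
}
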