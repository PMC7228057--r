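#' Community Jacobian at a state
#'
#' Analytic linearisation of the metacommunity dynamics around a state,
#' restricted to the live species. With growth factor
#' `G_iu = B_iu - N_iu - sum_j A_ij,u N_ju`, the Jacobian entries are
#' `d(dN_iu/dt)/dN_jv = delta_uv [delta_ij G_iu - N_iu (delta_ij +
#' A_ij,u)] + delta_ij [(1 - delta_uv) D_uv - delta_uv sum_w D_uw]`.
#' Coordinates are ordered species-within-patch blocks.
#'
#' @param state an `S x M` abundance matrix.
#' @param system an [sample_interactions()] object.
#' @param alive logical length-`S` mask of live species; default: any
#'   patch abundance positive.
#' @param warn_not_fixed warn when the state is not a fixed point
#'   (spectrum is still returned, flagged via the attribute
#'   `"residual"`).
#' @return A dense `(S_live * M) x (S_live * M)` matrix with attributes
#'   `"species"` (live indices), `"M"`, and `"residual"`.
#' @export
jacobian_at <- function(state, system, alive = NULL,
                        warn_not_fixed = TRUE) {
  stopifnot(inherits(system, "interaction_set"))
  S <- nrow(system$B); M <- ncol(system$B)
  N <- as.matrix(state)
  stopifnot(all(dim(N) == c(S, M)))
  if (is.null(alive)) alive <- apply(N, 1, max) > 0
  live <- which(alive)
  nL <- length(live)
  if (nL == 0) stop("no live species")
  res <- detect_fixed_point(N, system, tol = 1e-6)
  if (warn_not_fixed && !res$is_fixed_point)
    warning(sprintf("state is not a fixed point (residual %.3g); ",
                    res$residual), "spectrum describes the tangent flow")
  D <- system$D
  drow <- rowSums(D)
  J <- matrix(0, nL * M, nL * M)
  for (u in seq_len(M)) {
    Au <- system$A[live, live, u, drop = FALSE][, , 1]
    if (nL == 1) Au <- matrix(Au, 1, 1)
    Nu <- N[live, u]
    G <- system$B[live, u] - Nu - system$A[live, , u] %*% N[, u]
    blk <- -Nu * (diag(nL) + Au)
    diag(blk) <- diag(blk) + as.numeric(G)
    iu <- (u - 1) * nL + seq_len(nL)
    J[iu, iu] <- blk - diag(drow[u], nL)
    for (v in seq_len(M)) {
      if (v == u) next
      iv <- (v - 1) * nL + seq_len(nL)
      J[cbind(iu, iv)] <- D[u, v]
    }
  }
  attr(J, "species") <- live
  attr(J, "M") <- M
  attr(J, "residual") <- res$residual
  J
}

#' Linear stability of a fixed point
#'
#' The leading eigenvalue (maximal real part) of the community Jacobian
#' at a fixed point, over the live species-patch coordinates. Negative
#' at stable equilibria; positive at putative fixed points above the
#' critical diversity, where abundances fluctuate instead.
#'
#' @param state an `S x M` abundance matrix, or a precomputed
#'   [jacobian_at()] matrix.
#' @param system interaction set (ignored when `state` is a Jacobian).
#' @param alive live-species mask, passed to [jacobian_at()].
#' @param zero_tol eigenvalues with `|Re| < zero_tol` are treated as
#'   exact-zero modes and excluded.
#' @return An object of class `"stability_report"`: `lambda_stab`, the
#'   full `spectrum`, `diversity` (live species count) and `residual`
#'   of the state.
#' @export
#' @examples
#' sys <- sample_interactions(ensemble_params(S = 1, M = 1, c = 0, seed = 1))
#' lambda_stab(matrix(1, 1, 1), sys)$lambda_stab   # logistic: -1
lambda_stab <- function(state, system = NULL, alive = NULL,
                        zero_tol = 1e-10) {
  J <- if (is.matrix(state) && !is.null(attr(state, "species"))) state
       else jacobian_at(state, system, alive, warn_not_fixed = FALSE)
  ev <- eigen(J, only.values = TRUE)$values
  keep <- abs(Re(ev)) >= zero_tol | abs(Im(ev)) >= zero_tol
  lam <- if (any(keep)) max(Re(ev[keep])) else 0
  structure(list(lambda_stab = lam, spectrum = ev,
                 diversity = length(attr(J, "species")),
                 residual = attr(J, "residual")),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: lambda_stab = %.5g at diversity %d\n",
              x$lambda_stab, x$diversity))
  invisible(x)
}

#' Newton solve for a (putative) fixed point
#'
#' Root-finds the metacommunity rate equations over a live-species set
#' using the analytic Jacobian with a backtracking line search. Species
#' whose solved abundance falls below `prune_below` (or negative) are
#' removed and the solve restarts on the reduced community, so the
#' returned equilibrium is feasible (all live abundances positive).
#' Above the critical diversity such equilibria exist but are unstable;
#' they are exactly the "putative fixed points" whose spectrum is
#' probed by [lambda_stab()].
#'
#' @param system interaction set.
#' @param start starting `S x M` abundance matrix (e.g. a time-averaged
#'   fluctuating state).
#' @param alive initial live mask.
#' @param tol residual (max abs rate) tolerance.
#' @param max_iter Newton iterations per prune round.
#' @param prune_below abundance below which a species is dropped.
#' @return A list with `state`, `alive`, `converged`, `residual`,
#'   `prunes`.
#' @export
newton_fixed_point <- function(system, start, alive = NULL, tol = 1e-10,
                               max_iter = 60L, prune_below = 1e-8) {
  stopifnot(inherits(system, "interaction_set"))
  S <- nrow(system$B); M <- ncol(system$B)
  N <- as.matrix(start)
  if (is.null(alive)) alive <- apply(N, 1, max) > 0
  prunes <- 0L
  repeat {
    live <- which(alive)
    nL <- length(live)
    if (nL == 0) return(list(state = matrix(0, S, M), alive = alive,
                             converged = TRUE, residual = 0,
                             prunes = prunes))
    x <- N[live, , drop = FALSE]
    x[x <= 0] <- prune_below * 10
    conv <- FALSE
    for (k in seq_len(max_iter)) {
      Nfull <- matrix(0, S, M); Nfull[live, ] <- x
      FF <- lv_rhs(Nfull, system, alive = alive)[live, , drop = FALSE]
      r0 <- max(abs(FF))
      if (r0 < tol) { conv <- TRUE; break }
      # J coordinates are species-within-patch: column-major vec layout
      J <- jacobian_at(Nfull, system, alive = alive,
                       warn_not_fixed = FALSE)
      step <- tryCatch(solve(J, -as.numeric(FF)), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        # keep iterates positive: a coordinate may shrink by at most a
        # factor 20 per step, so genuine boundary roots are approached
        # gradually and handled by pruning rather than jumped onto
        xn <- pmax(x + matrix(lam * step, nL, M), 0.05 * x)
        Nfull[live, ] <- xn
        r1 <- max(abs(lv_rhs(Nfull, system,
                             alive = alive)[live, , drop = FALSE]))
        if (r1 < r0 || lam < 1e-4) break
        lam <- lam / 2
      }
      x <- xn
    }
    drop <- apply(x, 1, max) < prune_below
    if (!any(drop)) {
      N <- matrix(0, S, M); N[live, ] <- pmax(x, 0)
      Nr <- lv_rhs(N, system, alive = alive)[live, , drop = FALSE]
      return(list(state = N, alive = alive, converged = conv,
                  residual = max(abs(Nr)), prunes = prunes))
    }
    alive[live[drop]] <- FALSE
    N[live[drop], ] <- 0
    prunes <- prunes + 1L
    if (prunes > S) stop("pruning failed to terminate")
  }
}

#' Diversity sweep: fluctuation strength and stability versus diversity
#'
#' Probes the same metacommunity at a ladder of diversities by removing
#' species in batches, starting with the most extinction-prone ones
#' (ranked by ascending time-averaged maximum-over-patches abundance, a
#' monotone proxy for the effective characteristic abundance governing
#' extinction risk). At each diversity the community is re-equilibrated
#' and measured: the rescaled fluctuation strength `std(xi)/sigma`, and
#' the linear stability `lambda_stab` of the (putative) fixed point
#' found by Newton from the time-averaged state. Fluctuations shrink as
#' diversity decreases and vanish at the diversity where the fixed
#' point first becomes stable (`lambda_stab < 0`): equilibria and
#' fluctuating states form a single continuum.
#'
#' @param system interaction set.
#' @param state starting `S x M` abundances (a late-time fluctuating
#'   state).
#' @param batch number of species removed per step.
#' @param reequil_horizon relaxation time after each removal.
#' @param measure_horizon measurement window per step.
#' @param fp_tol residual below which the dynamics count as having
#'   reached a fixed point (then `std(xi)` is recorded as 0).
#' @param min_diversity stop once the community is this small.
#' @param n_equilibrium_steps stop after this many consecutive
#'   equilibrium steps (the curve has flattened onto the stable branch).
#' @return An object of class `"diversity_sweep"`: data.frame with
#'   columns `S_star`, `std_xi`, `std_xi_over_sigma`, `lambda_stab`,
#'   `putative` (TRUE when the spectrum comes from a Newton root rather
#'   than a dynamically reached equilibrium), `fixed_point`.
#' @export
diversity_sweep <- function(system, state, batch = 5L,
                            reequil_horizon = 150, measure_horizon = 250,
                            fp_tol = 1e-6, min_diversity = 8L,
                            n_equilibrium_steps = 3L) {
  stopifnot(inherits(system, "interaction_set"))
  sigma <- disorder_scales(system$params)$sigma
  N <- as.matrix(state)
  alive <- apply(N, 1, max) > 0
  rows <- list()
  eq_run <- 0L
  repeat {
    S_star <- sum(alive)
    if (S_star < min_diversity) break
    tr0 <- simulate_metacommunity(system, N0 = N, alive0 = alive,
                                  horizon = reequil_horizon,
                                  record_every = max(1L, reequil_horizon %/% 10L))
    trm <- simulate_metacommunity(system, N0 = tr0$state,
                                  alive0 = tr0$alive_final,
                                  horizon = measure_horizon)
    N <- trm$state; alive <- trm$alive_final
    S_star <- sum(alive)
    win <- seq_along(trm$times)[-1]
    surv <- trm$alive_final
    X <- matrix(aperm(trm$N[surv, , win, drop = FALSE], c(3, 1, 2)),
                nrow = length(win))
    v <- pmax(colMeans(X^2) - colMeans(X)^2, 0)
    std_xi <- sigma * sqrt(mean(v))
    fp <- detect_fixed_point(N, system, tol = fp_tol)
    if (fp$is_fixed_point) {
      lam <- lambda_stab(N, system, alive = alive)$lambda_stab
      putative <- FALSE
      std_xi <- 0
    } else {
      Nbar <- apply(trm$N[, , win, drop = FALSE], c(1, 2), mean)
      root <- tryCatch(newton_fixed_point(system, Nbar, alive = alive),
                       error = function(e) NULL)
      if (!is.null(root) && root$converged) {
        lam <- lambda_stab(root$state, system,
                           alive = root$alive)$lambda_stab
        putative <- TRUE
      } else {
        lam <- NA_real_
        putative <- NA
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(S_star = S_star, std_xi = std_xi,
                 std_xi_over_sigma = std_xi / sigma,
                 lambda_stab = lam, putative = putative,
                 fixed_point = fp$is_fixed_point)
    eq_run <- if (fp$is_fixed_point) eq_run + 1L else 0L
    if (eq_run >= n_equilibrium_steps) break
    # remove the most extinction-prone batch: lowest time-averaged
    # max-over-patches abundance
    Nbar_max <- apply(apply(trm$N[, , win, drop = FALSE], c(1, 2), mean),
                      1, max)
    Nbar_max[!alive] <- Inf
    drop <- order(Nbar_max)[seq_len(min(batch, sum(alive)))]
    alive[drop] <- FALSE
    N[drop, ] <- 0
    if (sum(alive) < min_diversity) break
  }
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_sweep", "data.frame")
  out
}

#' Diversity at which fluctuations vanish and stability is regained
#'
#' Convenience summary of a [diversity_sweep()] curve: the largest
#' diversity at which the dynamics reach a fixed point
#' (`S_star_equilibrium`), the smallest diversity still fluctuating
#' (`S_star_fluctuating`), and the largest diversity with
#' `lambda_stab < 0` (`S_star_stable`).
#'
#' @param curve a `diversity_sweep` data.frame.
#' @param noise_tol rescaled fluctuation strength below which the
#'   endogenous noise counts as vanished (default 0.01; near the
#'   transition critical slowing leaves residual drift in any finite
#'   measurement window).
#' @return A list with the four diversities (NA when absent).
#' @export
sweep_crossings <- function(curve, noise_tol = 0.01) {
  eq <- curve$S_star[curve$fixed_point]
  fl <- curve$S_star[!curve$fixed_point]
  st <- curve$S_star[!is.na(curve$lambda_stab) & curve$lambda_stab < 0]
  nv <- curve$S_star[curve$std_xi_over_sigma < noise_tol]
  list(S_star_equilibrium = if (length(eq)) max(eq) else NA,
       S_star_fluctuating = if (length(fl)) min(fl) else NA,
       S_star_stable = if (length(st)) max(st) else NA,
       S_star_noise_vanish = if (length(nv)) max(nv) else NA)
}
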