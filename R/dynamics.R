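#' Right-hand side of the metacommunity dynamics
#'
#' Evaluates the instantaneous growth rates
#' `dN_iu/dt = N_iu (B_iu - N_iu - sum_j A_ij,u N_ju)
#'             + sum_v D_uv (N_iv - N_iu)`
#' for an abundance matrix `N` (species in rows, patches in columns).
#' Rows of species marked extinct are identically zero.
#'
#' @param N an `S x M` abundance matrix (non-negative).
#' @param system an [sample_interactions()] object.
#' @param alive logical vector of length `S`; defaults to all alive.
#' @return An `S x M` matrix of rates.
#' @export
lv_rhs <- function(N, system, alive = NULL) {
  stopifnot(inherits(system, "interaction_set"))
  S <- nrow(system$B); M <- ncol(system$B)
  if (is.null(dim(N))) N <- matrix(N, S, M)
  if (!all(dim(N) == c(S, M))) stop("`N` must be S x M")
  if (anyNA(N)) stop("NaN/NA in abundance state")
  if (is.null(alive)) alive <- rep(TRUE, S)
  lv_rhs_cpp(system$A, system$B, system$D, N, alive)
}

#' Default initial abundances
#'
#' I.i.d. uniform on `[0.1, 1]` per species-patch; any order-one positive
#' start relaxes to the same statistical steady state.
#'
#' @param system an interaction set.
#' @param seed integer seed.
#' @return An `S x M` matrix.
#' @export
initial_state <- function(system, seed = system$params$seed + 1000L) {
  withr::local_seed(seed)
  S <- nrow(system$B); M <- ncol(system$B)
  matrix(runif(S * M, 0.1, 1), S, M)
}

#' Integrate the metacommunity dynamics
#'
#' Adaptive (Dormand-Prince 4/5) integration of the deterministic
#' Lotka-Volterra metacommunity equations between checkpoints spaced
#' `checkpoint_dt` apart. At every checkpoint the extinction rule is
#' applied: a species whose abundance is strictly below `N_c` in all
#' patches is removed (zeroed in every patch) and cannot return.
#' Values pushed slightly negative by the integrator (within `neg_tol`)
#' are clamped to zero; a larger negative excursion aborts.
#'
#' @param system an [sample_interactions()] object.
#' @param N0 initial `S x M` abundance matrix (default [initial_state()]).
#' @param horizon integration time (model time units).
#' @param checkpoint_dt spacing of checkpoints at which the state is
#'   recorded and the extinction rule tested (default 1).
#' @param N_c extinction cutoff; default taken from the system's params.
#'   Use `apply_cutoff = FALSE` to integrate without extinctions.
#' @param apply_cutoff logical; apply the all-patch extinction rule.
#' @param alive0 initial alive mask (for continuing reduced communities).
#' @param t0 starting time label.
#' @param rtol,atol relative/absolute local error tolerances.
#' @param neg_tol clamping tolerance for negative excursions.
#' @param record_every record every k-th checkpoint (extinction testing
#'   still happens at every checkpoint).
#' @param max_steps abort threshold on accepted+rejected steps.
#' @return An object of class `"lv_trajectory"`: list with `times`
#'   (checkpoints), `N` (`S x M x T` array), `alive` (`S x T`),
#'   `extinction_log` (data.frame species/time), `state` and
#'   `alive_final` (final state), `system`, and integrator diagnostics.
#' @export
#' @examples
#' sys <- sample_interactions(ensemble_params(S = 10, M = 2, seed = 2))
#' tr <- simulate_metacommunity(sys, horizon = 50)
#' diversity_series(tr)[["S_star"]][1:5]
simulate_metacommunity <- function(system, N0 = initial_state(system),
                                   horizon = 1000, checkpoint_dt = 1,
                                   N_c = system$params$N_c,
                                   apply_cutoff = TRUE, alive0 = NULL,
                                   t0 = 0, rtol = 1e-6, atol = 1e-10,
                                   neg_tol = 1e-7, record_every = 1L,
                                   max_steps = 5e8) {
  stopifnot(inherits(system, "interaction_set"), horizon > 0)
  S <- nrow(system$B)
  if (is.null(alive0)) alive0 <- apply(N0 > 0, 1, any)
  res <- lv_integrate_cpp(system$A, system$B, system$D, N0, alive0,
                          t0, horizon, checkpoint_dt, N_c, apply_cutoff,
                          rtol, atol, neg_tol, max_steps,
                          as.integer(record_every))
  if (res$status == 2) stop("integrator step underflow at t = ", res$t_final)
  if (res$status == 3) stop("negative abundance beyond clamp tolerance at t = ",
                            res$t_final)
  if (res$status == 1) stop("max_steps exceeded at t = ", res$t_final)
  structure(list(
    times = as.numeric(res$times),
    N = res$N,
    alive = res$alive > 0,
    extinction_log = data.frame(species = as.integer(res$ext_species),
                                time = as.numeric(res$ext_times)),
    state = res$state,
    alive_final = as.logical(res$alive_final),
    system = system, N_c = N_c, checkpoint_dt = checkpoint_dt,
    n_steps = res$n_steps), class = "lv_trajectory")
}

#' @export
print.lv_trajectory <- function(x, ...) {
  cat(sprintf("lv_trajectory: t in [%g, %g], %d checkpoints, S* = %d / %d\n",
              x$times[1], x$times[length(x$times)], length(x$times),
              sum(x$alive_final), nrow(x$state)))
  invisible(x)
}

#' Apply the all-patch extinction rule to a state
#'
#' Species `i` is zeroed in all patches iff `N[i, u] < N_c` for every
#' patch `u` (strict inequality: a species sitting exactly at the cutoff
#' is kept). Already-extinct (all-zero) rows stay zero.
#'
#' @param N an `S x M` abundance matrix.
#' @param N_c extinction cutoff.
#' @return A list with the updated matrix `N`, integer vector `removed`
#'   of newly zeroed species, and logical `alive` per species.
#' @export
apply_extinction_rule <- function(N, N_c) {
  stopifnot(all(N >= 0), N_c > 0)
  N <- as.matrix(N)
  below <- apply(N, 1, function(r) max(r) < N_c)
  was_dead <- apply(N, 1, function(r) all(r == 0))
  removed <- which(below & !was_dead)
  N[below, ] <- 0
  list(N = N, removed = removed, alive = !below & !was_dead)
}

#' Test whether a state is a fixed point of the dynamics
#'
#' A state qualifies when the maximum over live species-patch
#' coordinates of the relative rate `|dN/dt| / max(N, N_c)` is below
#' `tol`. The all-extinct state is trivially a fixed point.
#'
#' @param state an `S x M` abundance matrix, or an `lv_trajectory` (its
#'   final state is used).
#' @param system interaction set (defaults to the trajectory's).
#' @param tol residual tolerance (per unit time).
#' @param N_c floor used in the relative normalisation.
#' @return A list (`fixed_point_report`) with `is_fixed_point`,
#'   `residual`, and the `state`.
#' @export
detect_fixed_point <- function(state, system = NULL, tol = 1e-6,
                               N_c = 1e-8) {
  if (inherits(state, "lv_trajectory")) {
    if (is.null(system)) system <- state$system
    N_c <- state$N_c
    state <- state$state
  }
  stopifnot(inherits(system, "interaction_set"))
  R <- lv_rhs(state, system)
  denom <- pmax(state, N_c)
  residual <- max(abs(R) / denom)
  structure(list(is_fixed_point = residual < tol, residual = residual,
                 tol = tol, state = state), class = "fixed_point_report")
}

#' Anneal a fluctuating community to a fixed point
#'
#' Starting from a late-time state, raises the working extinction cutoff
#' by a geometric schedule (factor `10^(1/4)` per stage), re-integrating
#' for `stage_horizon` at each stage, until the dynamics of the
#' surviving community satisfy the fixed-point criterion. The increased
#' cutoff removes the most extinction-prone species first, shrinking the
#' community until its equilibrium is reachable and stable.
#'
#' @param system interaction set.
#' @param state starting `S x M` abundance matrix (a late-time state).
#' @param N_c_start initial cutoff (defaults to the system's `N_c`).
#' @param N_c_max schedule ceiling; failing to equilibrate before the
#'   cutoff reaches this order-one value is reported as failure.
#' @param stage_horizon integration window per stage.
#' @param factor multiplicative cutoff increment per stage.
#' @param fp_tol fixed-point residual tolerance.
#' @param settle_horizon extra relaxation (at the original cutoff)
#'   applied when a stage's final state is nearly at equilibrium.
#' @param settle_gate residual below which a stage is considered calm
#'   enough to attempt settling and Newton refinement.
#' @return A list with the reduced `state`, `alive`, the final working
#'   cutoff `N_c_final`, the `fixed_point_report`, number of `stages`,
#'   and `success`.
#' @export
anneal_to_fixed_point <- function(system, state,
                                  N_c_start = system$params$N_c,
                                  N_c_max = 2, stage_horizon = 200,
                                  factor = 10^(1 / 4), fp_tol = 1e-6,
                                  settle_horizon = 2000,
                                  settle_gate = 0.1) {
  stopifnot(inherits(system, "interaction_set"))
  N_c <- N_c_start
  N <- as.matrix(state)
  alive <- apply(N, 1, max) > 0
  stages <- 0L
  repeat {
    tr <- simulate_metacommunity(system, N0 = N, horizon = stage_horizon,
                                 N_c = N_c, alive0 = alive,
                                 record_every = max(1L, stage_horizon %/% 50L))
    N <- tr$state; alive <- tr$alive_final
    rep0 <- detect_fixed_point(N, system, tol = fp_tol, N_c = N_c)
    if (rep0$is_fixed_point) {
      return(list(state = N, alive = alive, N_c_final = N_c,
                  fixed_point = rep0, stages = stages, success = TRUE))
    }
    if (rep0$residual < settle_gate) {
      # fluctuations have died down: let the surviving community settle
      # at the ORIGINAL cutoff (the raised cutoff is a removal protocol,
      # not part of the system), then refine the root by Newton and
      # accept it if it is feasible and linearly stable (slow stable
      # modes otherwise take arbitrarily long to decay dynamically)
      tr2 <- simulate_metacommunity(system, N0 = N, horizon = settle_horizon,
                                    N_c = N_c_start, alive0 = alive,
                                    record_every = settle_horizon)
      N <- tr2$state; alive <- tr2$alive_final
      rep0 <- detect_fixed_point(N, system, tol = fp_tol, N_c = N_c_start)
      root <- tryCatch(newton_fixed_point(system, N, alive = alive),
                       error = function(e) NULL)
      if (!is.null(root) && root$converged &&
          lambda_stab(root$state, system,
                      alive = root$alive)$lambda_stab < 0) {
        rep1 <- detect_fixed_point(root$state, system, tol = fp_tol,
                                   N_c = N_c)
        return(list(state = root$state, alive = root$alive,
                    N_c_final = N_c, fixed_point = rep1,
                    stages = stages, success = TRUE))
      }
    }
    stages <- stages + 1L
    N_c <- N_c * factor
    if (N_c > N_c_max) {
      return(list(state = N, alive = alive, N_c_final = N_c,
                  fixed_point = rep0, stages = stages, success = FALSE))
    }
  }
}
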