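#' Experiment configuration
#'
#' A config fully determines every output: the disorder ensemble, the
#' integration horizons, and the analysis settings. Two presets are
#' provided: `"desk"` (transient plus measurement window of order
#' 1e4 time units, suitable for interactive work) and `"full"` (order
#' 1e5, at which the surviving diversity has fully plateaued).
#'
#' @param ensemble an [ensemble_params()] object.
#' @param preset `"desk"` or `"full"`; sets `horizon` unless given.
#' @param horizon total integration time.
#' @param checkpoint_dt checkpoint spacing (extinction testing and
#'   recording).
#' @param n_replicates number of replicate runs (disorder and initial
#'   conditions resampled with shifted seeds).
#' @param anneal logical: also locate the fixed-point state of the very
#'   same system by cutoff annealing (Experiment B reporting).
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(ensemble = ensemble_params(),
                              preset = c("desk", "full"),
                              horizon = NULL, checkpoint_dt = 1,
                              n_replicates = 1L, anneal = TRUE) {
  preset <- match.arg(preset)
  if (is.null(horizon)) horizon <- if (preset == "desk") 1e4 else 1e5
  stopifnot(inherits(ensemble, "ensemble_params"), horizon > 0)
  structure(list(ensemble = ensemble, preset = preset, horizon = horizon,
                 checkpoint_dt = checkpoint_dt,
                 n_replicates = as.integer(n_replicates), anneal = anneal),
            class = "experiment_config")
}

#' Read / write experiment configurations as YAML
#'
#' Flat YAML with exactly the ensemble field names plus the run
#' settings; `read_config(write_config(cfg, f))` round-trips.
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `read_config` returns an `experiment_config`;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  e <- config$ensemble
  lst <- list(S = e$S, M = e$M, c = e$c, mu_A = e$mu_A, sd_A = e$sd_A,
              rho = e$rho, gamma = e$gamma, B = e$B, d = e$d, N_c = e$N_c,
              seed = e$seed, preset = config$preset,
              horizon = config$horizon,
              checkpoint_dt = config$checkpoint_dt,
              n_replicates = config$n_replicates, anneal = config$anneal)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ens <- ensemble_params(S = lst$S, M = lst$M, c = lst$c, mu_A = lst$mu_A,
                         sd_A = lst$sd_A, rho = lst$rho,
                         gamma = lst$gamma %||% 0, B = lst$B %||% 1,
                         d = lst$d, N_c = lst$N_c, seed = lst$seed)
  experiment_config(ens, preset = lst$preset %||% "desk",
                    horizon = lst$horizon,
                    checkpoint_dt = lst$checkpoint_dt %||% 1,
                    n_replicates = lst$n_replicates %||% 1L,
                    anneal = lst$anneal %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment A: a single well-mixed community relaxes to equilibrium
#'
#' Integrates a single-patch (`M = 1`) community until the fixed-point
#' criterion holds (checked every `chunk` time units) or the horizon is
#' exhausted. Species go extinct until the surviving community reaches
#' a stable equilibrium.
#'
#' @param config an [experiment_config()] with `M = 1`.
#' @param chunk integration chunk between fixed-point checks.
#' @param fp_tol fixed-point residual tolerance.
#' @return An `"experiment_report"`: `S_star`, `lambda_stab`, the
#'   equilibrium `state`, `fixed_point` report, `diversity` series,
#'   provenance (`config_hash`, `seed`, package version).
#' @export
run_experiment_A <- function(config, chunk = 500, fp_tol = 1e-8) {
  stopifnot(inherits(config, "experiment_config"),
            config$ensemble$M == 1L)
  system <- sample_interactions(config$ensemble)
  N <- initial_state(system)
  alive <- rep(TRUE, config$ensemble$S)
  t_done <- 0
  div <- NULL
  fp <- NULL
  while (t_done < config$horizon) {
    tr <- simulate_metacommunity(system, N0 = N, alive0 = alive,
                                 horizon = chunk, t0 = t_done,
                                 checkpoint_dt = config$checkpoint_dt)
    N <- tr$state; alive <- tr$alive_final
    div <- rbind(div, diversity_series(tr))
    t_done <- t_done + chunk
    fp <- detect_fixed_point(N, system, tol = fp_tol,
                             N_c = config$ensemble$N_c)
    if (fp$is_fixed_point) break
  }
  lam <- if (fp$is_fixed_point)
    lambda_stab(N, system, alive = alive)$lambda_stab else NA_real_
  structure(list(experiment = "A", S_star = sum(alive),
                 lambda_stab = lam, state = N, alive = alive,
                 fixed_point = fp, reached_fixed_point = fp$is_fixed_point,
                 time = t_done, diversity = div, system = system,
                 config_hash = object_hash(config),
                 seed = config$ensemble$seed,
                 version = as.character(utils::packageVersion("metaLV"))),
            class = "experiment_report")
}

#' Experiment B: a heterogeneous metacommunity sustains fluctuations
#'
#' Integrates an `M`-patch metacommunity (`rho < 1`) over the preset
#' horizon, then characterises the late-time state over its detected
#' stationary window: diversity series, fluctuation strength
#' `std(xi)`, the stationary noise kernel, source/sink persistence,
#' inter-patch synchrony, and (optionally) the fixed-point state of
#' the very same system located by cutoff annealing, with the relative
#' diversity excess of the fluctuating state.
#'
#' @param config an [experiment_config()] with `M >= 2` and `rho < 1`.
#' @return An `"experiment_report"` with the fields above; when
#'   `config$n_replicates > 1`, replicate summaries (final diversity,
#'   `std(xi)`) are attached as `replicates`.
#' @export
run_experiment_B <- function(config) {
  stopifnot(inherits(config, "experiment_config"),
            config$ensemble$M >= 2L, config$ensemble$rho < 1)
  run_one <- function(seed_shift) {
    ens <- config$ensemble
    ens$seed <- ens$seed + seed_shift
    system <- sample_interactions(ens)
    sc <- disorder_scales(ens)
    tr <- simulate_metacommunity(system, horizon = config$horizon,
                                 checkpoint_dt = config$checkpoint_dt)
    win <- stationary_window(tr)
    kern <- stationary_kernel(tr, sc$sigma, window = win)
    stdxi <- noise_strength(tr, sc$sigma, window = win)
    ss <- source_sink_stats(diffusion_contribution(tr, window = win))
    syn <- interpatch_synchrony(tr, window = win)
    fp <- detect_fixed_point(tr)
    list(system = system, trajectory = tr, window = win, kernel = kern,
         std_xi = stdxi, source_sink = ss, synchrony = syn,
         S_star = sum(tr$alive_final), is_fixed_point = fp$is_fixed_point,
         sigma = sc$sigma)
  }
  main <- run_one(0L)
  out <- list(experiment = "B", S_star = main$S_star,
              std_xi = main$std_xi, sigma = main$sigma,
              kernel = main$kernel, source_sink = main$source_sink,
              synchrony = main$synchrony,
              diversity = diversity_series(main$trajectory),
              is_fixed_point = main$is_fixed_point,
              trajectory = main$trajectory, window = main$window,
              system = main$system,
              config_hash = object_hash(config),
              seed = config$ensemble$seed,
              version = as.character(utils::packageVersion("metaLV")))
  if (config$anneal) {
    ann <- anneal_to_fixed_point(main$system, main$trajectory$state)
    out$anneal <- ann
    out$S_star_fixed_point <- sum(ann$alive)
    out$diversity_excess <- (out$S_star - out$S_star_fixed_point) /
      out$S_star_fixed_point
  }
  if (config$n_replicates > 1L) {
    reps <- lapply(seq_len(config$n_replicates - 1L), function(k) {
      r <- run_one(1000L * k)
      data.frame(replicate = k + 1L, S_star = r$S_star,
                 std_xi = r$std_xi, is_fixed_point = r$is_fixed_point)
    })
    out$replicates <- rbind(
      data.frame(replicate = 1L, S_star = main$S_star,
                 std_xi = main$std_xi,
                 is_fixed_point = main$is_fixed_point),
      do.call(rbind, reps))
  }
  structure(out, class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report (%s): S* = %d\n", x$experiment, x$S_star))
  if (x$experiment == "A")
    cat(sprintf("  fixed point: %s (lambda_stab = %.4g) at t = %g\n",
                x$reached_fixed_point, x$lambda_stab, x$time))
  if (x$experiment == "B") {
    cat(sprintf("  std(xi) = %.4g (sigma = %.3g), synchrony = %.3f\n",
                x$std_xi, x$sigma, x$synchrony))
    cat(sprintf("  source persistence: %.1f%% of sources, %.1f%% of all pairs\n",
                100 * x$source_sink$frac_sources_persistent,
                100 * x$source_sink$frac_all_persistent))
    if (!is.null(x$S_star_fixed_point))
      cat(sprintf("  fixed-point diversity %d -> excess %.0f%%\n",
                  x$S_star_fixed_point, 100 * x$diversity_excess))
  }
  invisible(x)
}

#' Export an experiment report
#'
#' Writes the flat summary as JSON plus the tabular pieces (diversity
#' series, kernel, source/sink table) as CSV into a directory.
#'
#' @param report an `"experiment_report"`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(experiment = report$experiment, S_star = report$S_star,
               config_hash = report$config_hash, seed = report$seed,
               version = report$version)
  if (report$experiment == "B") {
    summ$std_xi <- report$std_xi
    summ$sigma <- report$sigma
    summ$synchrony <- report$synchrony
    summ$frac_sources_persistent <-
      report$source_sink$frac_sources_persistent
    summ$frac_all_persistent <- report$source_sink$frac_all_persistent
    summ$W <- report$kernel$W
    summ$tau_c <- report$kernel$tau_c
    if (!is.null(report$S_star_fixed_point)) {
      summ$S_star_fixed_point <- report$S_star_fixed_point
      summ$diversity_excess <- report$diversity_excess
    }
    write.csv(report$source_sink$table,
              file.path(dir, "source_sink.csv"), row.names = FALSE)
    write.csv(data.frame(lag = report$kernel$lags,
                         C_xi = report$kernel$C_xi,
                         C_N = report$kernel$C_N),
              file.path(dir, "kernel.csv"), row.names = FALSE)
  } else {
    summ$lambda_stab <- report$lambda_stab
    summ$reached_fixed_point <- report$reached_fixed_point
  }
  write.csv(report$diversity, file.path(dir, "diversity.csv"),
            row.names = FALSE)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Save / load a trajectory
#'
#' Trajectories are stored as RDS (self-describing R serialisation);
#' small trajectories can additionally be exported as tidy CSV
#' (`time`, `species`, `patch`, `N`).
#'
#' @param trajectory an `lv_trajectory`.
#' @param path output file (`.rds`).
#' @param csv optional path for a tidy CSV export.
#' @return `path`, invisibly.
#' @export
save_trajectory <- function(trajectory, path, csv = NULL) {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  saveRDS(trajectory, path)
  if (!is.null(csv)) {
    d <- dim(trajectory$N)
    df <- data.frame(
      time = rep(trajectory$times, each = d[1] * d[2]),
      species = rep(seq_len(d[1]), times = d[2] * d[3]),
      patch = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      N = as.numeric(trajectory$N))
    write.csv(df, csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) readRDS(path)
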