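#' Exact stochastic simulation of a CTMC
#'
#' Gillespie's direct method for a [ctmc_model()], with stopping rules for
#' absorption, extinction of the branching-relevant coordinates, and first
#' threshold crossing. The compiled kernel uses R's random number stream, so
#' runs are reproducible under a seed.
#'
#' @param ctmc a [ctmc_model()].
#' @param t_max time horizon.
#' @param rng_seed optional integer seed.
#' @param stop_rule optional list: `list(coord = j, level = L)` stops when
#'   state coordinate `j` first reaches count `L`.
#' @param record_times optional increasing times at which the state is
#'   recorded (state just before the first jump past each time).
#' @return object of class `simulation_result`: `t_end`, final `state`,
#'   `crossed`, `t_cross`, `extinct`, `n_events`, and `grid_states` when
#'   `record_times` is given.
#' @export
gillespie <- function(ctmc, t_max, rng_seed = NULL, stop_rule = NULL,
                      record_times = NULL) {
  stopifnot(inherits(ctmc, "ctmc_model"), t_max > 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  parts <- ssa_parts(ctmc)
  res <- ssa_run_cpp(ctmc$x0, parts$deltas, parts$coef, parts$idx1,
                     parts$idx2, ctmc$scale, t_max,
                     if (is.null(stop_rule)) 0L else as.integer(stop_rule$coord),
                     if (is.null(stop_rule)) 0 else stop_rule$level,
                     as.integer(ctmc$bp_coords),
                     as.numeric(record_times %||% numeric(0)),
                     1e9)
  res$record_times <- record_times
  class(res) <- "simulation_result"
  res
}

ssa_parts <- function(ctmc) {
  E <- length(ctmc$events)
  d <- ctmc$state_dim
  deltas <- matrix(0L, E, d)
  coef <- numeric(E)
  idx1 <- integer(E)
  idx2 <- integer(E)
  for (e in seq_len(E)) {
    ev <- ctmc$events[[e]]
    deltas[e, ] <- as.integer(ev$delta)
    coef[e] <- ev$coef
    idx1[e] <- ev$idx[1]
    idx2[e] <- if (length(ev$idx) == 2L) ev$idx[2] else 0L
  }
  list(deltas = deltas, coef = coef, idx1 = idx1, idx2 = idx2)
}

#' Empirical time-shift samples from stochastic simulation
#'
#' For each surviving replicate, the empirical time-shift is
#' `tau_hat = t_det - t_sim`, the difference between the times at which the
#' deterministic trajectory and the stochastic path first push the designated
#' coordinate to the threshold (default `0.05 * scale` counts). Extinct
#' replicates are discarded and resampled, matching conditioning on
#' non-extinction.
#'
#' @param ctmc a [ctmc_model()].
#' @param det_traj deterministic [deterministic_solution()] of the same model.
#' @param coord state coordinate monitored (e.g. infectives, virions).
#' @param reps number of surviving replicates wanted.
#' @param threshold_frac threshold as a fraction of `scale`.
#' @param threshold absolute count threshold (overrides `threshold_frac`).
#' @param rng_seed optional integer seed.
#' @param t_max simulation horizon.
#' @return tibble with columns `tau_hat` and `t_sim`.
#' @export
empirical_timeshift <- function(ctmc, det_traj, coord, reps,
                                threshold_frac = 0.05, threshold = NULL,
                                rng_seed = NULL, t_max = 1e4) {
  stopifnot(inherits(ctmc, "ctmc_model"), inherits(det_traj, "trajectory"))
  level <- threshold %||% (threshold_frac * ctmc$scale)
  t_det <- threshold_time(det_traj, coord, level)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  t_sim <- numeric(reps)
  got <- 0L
  attempts <- 0L
  while (got < reps) {
    attempts <- attempts + 1L
    if (attempts > 1000 * reps) stop("survival too rare: giving up resampling")
    res <- gillespie(ctmc, t_max, stop_rule = list(coord = coord, level = level))
    if (res$crossed) {
      got <- got + 1L
      t_sim[got] <- res$t_cross
    }
  }
  tibble::tibble(tau_hat = t_det - t_sim, t_sim = t_sim)
}

#' Empirical samples of the martingale limit from branching-process paths
#'
#' Simulates the branching process (as a CTMC) to `t_end` and extracts
#' `W_hat = mean_i(e^{-lam t_end} Z_i(t_end) / v_i)` over coordinates with
#' `v_i > 0`; every coordinate estimates the same scalar limit almost surely.
#' Only surviving runs are returned.
#'
#' @param bp a continuous supercritical [branching_model()].
#' @param z0 initial count vector.
#' @param t_end simulation horizon (long enough for `W(t)` to settle).
#' @param reps number of surviving samples wanted.
#' @param rng_seed optional integer seed.
#' @return tibble with columns `w_hat` and the per-coordinate estimates.
#' @export
empirical_w <- function(bp, z0, t_end, reps, rng_seed = NULL) {
  stopifnot(inherits(bp, "branching_model"), !bp$discrete)
  eig <- eigen_quantities(bp)
  ctmc <- bp_to_ctmc(bp, z0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  out <- matrix(NA_real_, reps, bp$m)
  got <- 0L
  attempts <- 0L
  while (got < reps) {
    attempts <- attempts + 1L
    if (attempts > 1000 * reps) stop("survival too rare: giving up resampling")
    res <- gillespie(ctmc, t_end)
    if (!res$extinct && sum(res$state) > 0) {
      got <- got + 1L
      out[got, ] <- exp(-eig$lam * t_end) * res$state / eig$v
    }
  }
  colnames(out) <- paste0("w_", bp$type_names)
  tibble::tibble(w_hat = rowMeans(out),
                 !!!as.data.frame(out))
}
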