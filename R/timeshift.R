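#' Transform the martingale limit into a time-shift
#'
#' A surviving stochastic path that converges to limit `w` runs ahead of (or
#' behind) the deterministic mean curve by `tau = (log w - log mu_W) / lam`,
#' where `mu_W = z0 . u` is the mean of W. Positive `tau` means the
#' stochastic path is ahead.
#'
#' @param w positive value(s) of the martingale limit.
#' @param lam growth rate.
#' @param mu_W mean of W.
#' @return time-shift value(s).
#' @export
w_to_tau <- function(w, lam, mu_W) {
  stopifnot(all(w > 0), lam > 0, mu_W > 0)
  (log(w) - log(mu_W)) / lam
}

#' Time-shift distribution
#'
#' Wraps either a PE-route [w_distribution()] or an MM-route [fit_gg()]
#' surrogate as the distribution of the time-shift
#' `tau = (log W* - log mu_W)/lam`, conditional on non-extinction.
#'
#' @param backend a `w_distribution` (PE) or `gg_fit` (MM).
#' @param lam growth rate; taken from the backend when available.
#' @param mu_W mean of W; required for a `gg_fit` backend.
#' @return object of class `timeshift_distribution`.
#' @export
timeshift_distribution <- function(backend, lam = NULL, mu_W = NULL) {
  if (inherits(backend, "w_distribution")) {
    lam <- lam %||% backend$lam
    mu_W <- mu_W %||% backend$mu_W
    method <- "pe"
  } else if (inherits(backend, "gg_fit") || (is.list(backend) &&
                                             !is.null(backend$gg_scale))) {
    if (is.null(lam) || is.null(mu_W)) {
      stop("lam and mu_W must be supplied for an MM backend")
    }
    method <- "mm"
  } else {
    stop("backend must be a w_distribution or gg_fit")
  }
  stopifnot(lam > 0, mu_W > 0)
  structure(list(backend = backend, lam = lam, mu_W = mu_W, method = method),
            class = "timeshift_distribution")
}

#' @export
print.timeshift_distribution <- function(x, ...) {
  cat(sprintf("timeshift_distribution (%s backend): lambda = %.6g, E[W] = %.6g\n",
              toupper(x$method), x$lam, x$mu_W))
  invisible(x)
}

#' Density, CDF and sampling of the time-shift
#'
#' Change of variables `w = mu_W exp(lam tau)` applied to the conditional law
#' of `W*`: `g(tau) = g_{W*}(mu_W e^{lam tau}) mu_W lam e^{lam tau}` for the
#' PE backend, and the closed form [timeshift_pdf_mm()] for the MM backend.
#'
#' @param dist a [timeshift_distribution()].
#' @param tau real evaluation points.
#' @return numeric densities / probabilities / samples.
#' @export
tau_pdf <- function(dist, tau) {
  stopifnot(inherits(dist, "timeshift_distribution"))
  w <- dist$mu_W * exp(dist$lam * tau)
  if (dist$method == "mm") {
    timeshift_pdf_mm(dist$backend, dist$lam, dist$mu_W, tau)
  } else {
    pdf_wstar(dist$backend, w) * dist$mu_W * dist$lam * exp(dist$lam * tau)
  }
}

#' @rdname tau_pdf
#' @export
tau_cdf <- function(dist, tau) {
  stopifnot(inherits(dist, "timeshift_distribution"))
  w <- dist$mu_W * exp(dist$lam * tau)
  if (dist$method == "mm") {
    stats::pgamma(
      (w / dist$backend$gg_scale)^dist$backend$gg_shape2,
      shape = dist$backend$gg_shape1 / dist$backend$gg_shape2, scale = 1)
  } else {
    wd <- dist$backend
    (cdf_w(wd, w) - wd$q_star) / (1 - wd$q_star)
  }
}

#' @rdname tau_pdf
#' @param n number of draws.
#' @param rng_seed optional integer seed.
#' @export
sample_tau <- function(dist, n, rng_seed = NULL) {
  stopifnot(inherits(dist, "timeshift_distribution"))
  w <- if (dist$method == "mm") {
    sample_gg(dist$backend, n, rng_seed)
  } else {
    sample_wstar_pe(dist$backend, n, rng_seed)
  }
  w_to_tau(w, dist$lam, dist$mu_W)
}

# ---- deterministic trajectories -------------------------------------------

.ode_solve_counter <- new.env(parent = emptyenv())
.ode_solve_counter$n <- 0L

#' Number of deterministic ODE solves performed so far
#'
#' Exposed so callers can assert that hybrid ensemble generation costs a
#' single deterministic solve regardless of the number of replicates.
#'
#' @param reset reset the counter to zero.
#' @return integer count (before any reset).
#' @export
ode_solve_count <- function(reset = FALSE) {
  n <- .ode_solve_counter$n
  if (reset) .ode_solve_counter$n <- 0L
  n
}

#' Deterministic (fluid-limit) trajectory of a density-dependent CTMC
#'
#' Integrates the density ODE `x' = sum_events delta * coef * prod(x[idx])`
#' from `x0 / scale` over `t_span`, returning a densely interpolable
#' trajectory. The flow near the unstable initial equilibrium is well defined
#' backwards in time, so the trajectory can be extended to negative times for
#' use with positive time-shifts.
#'
#' @param ctmc a [ctmc_model()].
#' @param t_span length-2 time interval (may start negative).
#' @param n_grid number of grid points for the dense interpolant.
#' @param rtol,atol ODE tolerances.
#' @return object of class `trajectory` with `time`, `state` (density
#'   matrix), `scale` and spline interpolants per coordinate.
#' @export
deterministic_solution <- function(ctmc, t_span, n_grid = 2001,
                                   rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(ctmc, "ctmc_model"), length(t_span) == 2)
  x0 <- ctmc$x0 / ctmc$scale
  rhs <- function(t, y, parms) list(ctmc_drift(ctmc, y))
  times_fwd <- seq(0, max(t_span[2], 0), length.out = max(2, n_grid))
  sol <- deSolve::ode(y = x0, times = times_fwd, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  .ode_solve_counter$n <- .ode_solve_counter$n + 1L
  tt <- sol[, 1]
  st <- sol[, -1, drop = FALSE]
  if (t_span[1] < 0) {
    times_bwd <- seq(0, t_span[1], length.out = max(2, ceiling(n_grid / 4)))
    solb <- deSolve::ode(y = x0, times = times_bwd, func = rhs, parms = NULL,
                         method = "lsoda", rtol = rtol, atol = atol)
    tt <- c(rev(solb[-1, 1]), tt)
    st <- rbind(solb[rev(seq_len(nrow(solb))[-1]), -1, drop = FALSE], st)
  }
  interp <- lapply(seq_len(ncol(st)), function(j) {
    stats::splinefun(tt, st[, j], method = "fmm")
  })
  structure(list(time = tt, state = st, scale = ctmc$scale,
                 state_names = ctmc$state_names, interp = interp,
                 ctmc = ctmc),
            class = "trajectory")
}

#' Evaluate a trajectory
#'
#' @param traj a `trajectory`.
#' @param t times inside the integrated domain.
#' @param coord optional coordinate index; default returns all coordinates.
#' @param counts return counts (`density * scale`) instead of densities.
#' @return matrix (times x coordinates) or vector.
#' @export
traj_eval <- function(traj, t, coord = NULL, counts = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  rng <- range(traj$time)
  if (any(t < rng[1] - 1e-9) || any(t > rng[2] + 1e-9)) {
    stop(sprintf("evaluation outside integrated domain [%g, %g]; extend t_span",
                 rng[1], rng[2]))
  }
  cols <- coord %||% seq_along(traj$interp)
  out <- vapply(cols, function(j) traj$interp[[j]](t), numeric(length(t)))
  out <- matrix(out, nrow = length(t))
  if (counts) out <- out * traj$scale
  if (!is.null(coord) && length(coord) == 1L) drop(out) else out
}

#' Shift a trajectory in time
#'
#' Returns the trajectory `t -> traj(t + tau)`: the time-shifted
#' deterministic solution that approximates a stochastic path with martingale
#' limit `w = mu_W exp(lam tau)`.
#'
#' @param traj a `trajectory`.
#' @param tau time-shift.
#' @return object of class `shifted_trajectory` (evaluable via
#'   [traj_eval()]).
#' @export
shifted_trajectory <- function(traj, tau) {
  stopifnot(inherits(traj, "trajectory"))
  out <- traj
  out$tau <- tau
  out$time <- traj$time - tau
  out$interp <- lapply(traj$interp, function(f) function(t) f(t + tau))
  class(out) <- c("shifted_trajectory", "trajectory")
  out
}

#' Hybrid ensemble of macroscopic sample paths
#'
#' Generates `length(tau_samples)` approximate sample paths by shifting a
#' single deterministic solution: the cost is one ODE solve plus draws from
#' the univariate time-shift distribution.
#'
#' @param traj a `trajectory`.
#' @param tau_samples vector of time-shifts (e.g. from [sample_tau()]).
#' @return list of `shifted_trajectory` objects.
#' @export
hybrid_ensemble <- function(traj, tau_samples) {
  lapply(tau_samples, function(tau) shifted_trajectory(traj, tau))
}

#' Peak time of a trajectory coordinate
#'
#' Golden-section refinement of the dense interpolant's maximum.
#'
#' @param traj a `trajectory`.
#' @param coord coordinate index.
#' @return time of the maximum.
#' @export
peak_time <- function(traj, coord) {
  f <- traj$interp[[coord]]
  grid_val <- traj$state[, coord]
  i0 <- which.max(grid_val)
  lo <- traj$time[max(1, i0 - 2)]
  hi <- traj$time[min(length(traj$time), i0 + 2)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' First threshold-crossing time of a trajectory coordinate
#'
#' @param traj a `trajectory`.
#' @param coord coordinate index.
#' @param level threshold on the count scale.
#' @return first time the coordinate (in counts) reaches `level`.
#' @export
threshold_time <- function(traj, coord, level) {
  f <- function(t) traj_eval(traj, t, coord, counts = TRUE) - level
  tt <- traj$time
  vals <- traj$state[, coord] * traj$scale - level
  idx <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (!length(idx)) {
    if (vals[1] >= 0) return(tt[1])
    stop("deterministic trajectory never reaches the threshold; extend t_span")
  }
  i <- idx[1]
  stats::uniroot(f, c(tt[i], tt[i + 1]), tol = 1e-10)$root
}

#' Export a trajectory to delimited text
#'
#' @param traj a `trajectory`.
#' @param path output path (tab-separated `time` plus state columns).
#' @param counts write counts instead of densities.
#' @export
export_trajectory <- function(traj, path, counts = FALSE) {
  st <- if (counts) traj$state * traj$scale else traj$state
  df <- data.frame(time = traj$time, st)
  names(df) <- c("time", traj$state_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
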