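#' Run configuration
#'
#' Collects the hyper-parameters of a full analysis run. Defaults are the
#' settings used throughout the worked examples: `n = 30` Taylor moments,
#' embedded step `h = 0.1`, LST tolerance `eps = 1e-6`, 21 inversion terms.
#'
#' @param method `"both"`, `"pe"` or `"mm"`.
#' @param n,h,eps see [lst_config()].
#' @param inversion_order Abate-Whitt terms.
#' @param nodes `"cme"` or `"euler"`.
#' @param rng_seed optional integer seed recorded in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(method = c("both", "pe", "mm"), n = 30, h = 0.1,
                       eps = 1e-6, inversion_order = 21, nodes = "cme",
                       rng_seed = NULL) {
  structure(list(method = match.arg(method),
                 lst = lst_config(n = n, h = h, eps = eps),
                 inversion_order = inversion_order, nodes = nodes,
                 rng_seed = rng_seed),
            class = "run_config")
}

#' Full analysis: distribution of W and of the time-shift
#'
#' End-to-end pipeline: eigen-quantities, extinction probabilities,
#' conditional moments, then the PE route (LST evaluator plus inversion) and
#' the MM route (generalised-gamma moment matching), each with its
#' time-shift distribution. An MM-only run performs no LST inversion work
#' beyond the shared moment recursion.
#'
#' @param model a supercritical [branching_model()].
#' @param z0 initial count vector.
#' @param config a [run_config()].
#' @return object of class `w_analysis` with elements `eig`, `q`, `q_star`,
#'   `mu_W`, `moments` (a `moment_table`), `w_moments`, `wstar_moments`,
#'   `wdist` and `tau_pe` (PE route, if requested), `ggfit` and `tau_mm`
#'   (MM route, if requested).
#' @export
compute_w <- function(model, z0, config = run_config()) {
  stopifnot(inherits(model, "branching_model"), inherits(config, "run_config"))
  ev <- lst_evaluator(model, config$lst)
  z0 <- check_z0(z0, model$m)
  ext <- extinction_probs(model)
  q_star <- ext$q_star(z0)
  w_mom <- w_moments_from_initial(ev$table, z0, k_max = min(ev$table$n_max, 5))
  wstar_mom <- conditional_moments(w_mom, q_star)
  out <- list(model = model, z0 = z0, config = config, ev = ev,
              eig = ev$eig, moments = ev$table, q = ext$q, q_star = q_star,
              mu_W = sum(z0 * ev$eig$u), w_moments = w_mom,
              wstar_moments = wstar_mom)
  if (config$method %in% c("both", "pe")) {
    out$wdist <- w_distribution(ev, z0, config$inversion_order, config$nodes)
    out$tau_pe <- timeshift_distribution(out$wdist)
  }
  if (config$method %in% c("both", "mm")) {
    out$ggfit <- fit_gg(wstar_mom)
    out$tau_mm <- timeshift_distribution(out$ggfit, lam = ev$eig$lam,
                                         mu_W = out$mu_W)
  }
  structure(out, class = "w_analysis")
}

#' @export
print.w_analysis <- function(x, ...) {
  cat(sprintf(
    "w_analysis: m = %d, z0 = (%s)\n  lambda = %.6g, E[W] = %.6g, q* = %.6g\n",
    x$model$m, paste(x$z0, collapse = ", "), x$eig$lam, x$mu_W, x$q_star))
  if (!is.null(x$ggfit)) {
    cat(sprintf("  MM fit: scale = %.5g, shape1 = %.5g, shape2 = %.5g\n",
                x$ggfit$gg_scale, x$ggfit$gg_shape1, x$ggfit$gg_shape2))
  }
  invisible(x)
}

#' @export
glance.w_analysis <- function(x, ...) {
  tibble::tibble(lambda = x$eig$lam, mu_W = x$mu_W, q_star = x$q_star,
                 n_moments = x$config$lst$n, h = x$config$lst$h,
                 eps = x$config$lst$eps, method = x$config$method)
}

#' @export
tidy.w_analysis <- function(x, ...) {
  tibble::tibble(
    quantity = c("lambda", "mu_W", "q_star",
                 paste0("E[W^", seq_along(x$w_moments), "]")),
    value = c(x$eig$lam, x$mu_W, x$q_star, x$w_moments))
}

#' Validation report for a fixture model
#'
#' Runs the simulation-based checks for a model bundle (as produced by the
#' fixture constructors): extinction fraction against `q*` (99% binomial
#' CI), and the Kolmogorov-Smirnov distance between empirical time-shifts
#' and the PE time-shift CDF. For the SIR fixture the Table-style CDF error
#' metrics against the analytic law are included (both L1 conventions).
#'
#' @param fixture list with `bp`, `ctmc`, `z0` (from [fixture_sir()] etc.).
#' @param analysis optional [compute_w()] result (computed if missing).
#' @param reps surviving replicates for the time-shift comparison.
#' @param coord monitored CTMC coordinate (defaults to
#'   `fixture$infected_coord`).
#' @param rng_seed integer seed.
#' @param t_span deterministic integration window.
#' @return tibble with columns `check`, `statistic`, `value`, `pass`.
#' @export
validate_model <- function(fixture, analysis = NULL, reps = 500,
                           coord = NULL, rng_seed = 1,
                           t_span = c(-50, 200)) {
  coord <- coord %||% fixture$infected_coord
  analysis <- analysis %||% compute_w(fixture$bp, fixture$z0)
  rows <- list()

  # extinction fraction vs q*
  set.seed(rng_seed)
  n_ext <- 0L
  n_runs <- max(2 * reps, 500)
  level <- 0.05 * fixture$ctmc$scale
  for (i in seq_len(n_runs)) {
    res <- gillespie(fixture$ctmc, t_max = 1e4,
                     stop_rule = list(coord = coord, level = level))
    if (!res$crossed) n_ext <- n_ext + 1L
  }
  phat <- n_ext / n_runs
  ci <- stats::binom.test(n_ext, n_runs,
                          conf.level = 0.99)$conf.int
  rows$extinction <- tibble::tibble(
    check = "extinction fraction vs q*", statistic = "q*",
    value = phat,
    pass = analysis$q_star >= ci[1] && analysis$q_star <= ci[2])

  # KS distance, empirical time-shift vs PE tau CDF
  det <- deterministic_solution(fixture$ctmc, t_span)
  emp <- empirical_timeshift(fixture$ctmc, det, coord, reps,
                             rng_seed = rng_seed + 1)
  ks <- ks_distance(emp$tau_hat, tau_cdf_interp(analysis$tau_pe, emp$tau_hat))
  # 0.05 method tolerance plus the 99% KS sampling band for `reps` draws
  ks_bound <- 0.05 + 1.63 / sqrt(reps)
  rows$ks <- tibble::tibble(
    check = "KS(empirical tau, PE tau CDF)", statistic = "KS",
    value = ks, pass = ks < ks_bound)

  # SIR only: analytic CDF error metrics
  if (fixture$bp$m == 1L) {
    grid <- seq(0, 10, by = 0.1)
    pars <- fixture$params
    exact <- sir_analytic_cdf(pars[["beta"]], pars[["gamma"]], grid)
    pe <- cdf_w(analysis$wdist, grid, clip = FALSE)
    met <- cdf_error_metrics(pe, exact, grid)
    rows$l1 <- tibble::tibble(
      check = c("SIR CDF error (L1 sum)", "SIR CDF error (L1 mean)",
                "SIR CDF error (max)"),
      statistic = c("l1_sum", "l1_mean", "max_err"),
      value = c(met$l1_sum, met$l1_mean, met$max_err),
      pass = c(met$l1_sum < 0.1, met$l1_mean < 1e-3, met$max_err < 1e-3))
  }
  do.call(rbind, rows)
}

#' Interpolated time-shift CDF
#'
#' Evaluates the time-shift CDF on a fixed grid covering `span` and returns a
#' monotone interpolator; inversion wiggle at the 1e-4 level is removed by a
#' running maximum. Useful when the CDF is needed at many points (e.g.
#' Kolmogorov-Smirnov comparisons against thousands of simulated shifts).
#'
#' @param dist a [timeshift_distribution()].
#' @param span numeric vector whose range sets the grid (padded by 1).
#' @param n_grid grid resolution.
#' @return a function evaluating the CDF.
#' @export
tau_cdf_interp <- function(dist, span, n_grid = 301) {
  rng <- range(span) + c(-1, 1)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  F <- cummax(pmin(pmax(tau_cdf(dist, grid), 0), 1))
  stats::approxfun(grid, F, rule = 2)
}

# sup |ecdf - F| over the sample (both one-sided parts)
ks_distance <- function(x, cdf_fun) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf_fun(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

#' Write a run manifest
#'
#' Records the configuration, seeds and package version of a run as JSON so
#' deterministic outputs can be reproduced bit-for-bit.
#'
#' @param path output path.
#' @param config a [run_config()].
#' @param extra optional named list merged into the manifest.
#' @export
write_run_manifest <- function(path, config, extra = list()) {
  manifest <- c(list(
    package = "timeshiftr",
    version = as.character(utils::packageVersion("timeshiftr")),
    method = config$method, n = config$lst$n, h = config$lst$h,
    eps = config$lst$eps, inversion_order = config$inversion_order,
    nodes = config$nodes, rng_seed = config$rng_seed), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
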