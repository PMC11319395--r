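#' Distribution of the martingale limit W by transform inversion
#'
#' Bundles everything the probability-estimation (PE) route needs to expose
#' the law of `W` for a given initial condition: the LST
#' `phi(theta) = prod_i phi_i(theta)^{z0_i}`, the extinction atom `q_star` at
#' zero, the mean `mu_W = z0 . u`, and an Abate-Whitt inversion rule. The
#' distribution is the mixture `G_W(w) = q_star` at `w = 0` plus an
#' absolutely continuous part recovered by inverting `phi(theta)/theta`.
#'
#' @param ev an [lst_evaluator()].
#' @param z0 initial count vector.
#' @param inversion_order number of Abate-Whitt terms (default 21).
#' @param nodes node family: `"cme"` (default) or `"euler"`, or a node list.
#' @return object of class `w_distribution`.
#' @export
w_distribution <- function(ev, z0, inversion_order = 21, nodes = "cme") {
  stopifnot(inherits(ev, "lst_evaluator"))
  z0 <- check_z0(z0, ev$model$m)
  ext <- extinction_probs(ev$model)
  if (is.character(nodes)) {
    nodes <- switch(nodes,
                    cme = cme_nodes(inversion_order),
                    euler = euler_nodes(inversion_order),
                    stop("unknown node family"))
  }
  lst <- function(theta) {
    lst_for_initial(lst_eval_batch(ev, theta), z0)
  }
  structure(list(ev = ev, z0 = z0, lst = lst,
                 q = ext$q, q_star = ext$q_star(z0),
                 mu_W = sum(z0 * ev$eig$u), lam = ev$eig$lam,
                 inversion_order = nodes$order, nodes = nodes),
            class = "w_distribution")
}

#' @export
print.w_distribution <- function(x, ...) {
  cat(sprintf(
    "w_distribution: m = %d, z0 = (%s), q* = %.6g, E[W] = %.6g, lambda = %.6g\n",
    x$ev$model$m, paste(x$z0, collapse = ", "), x$q_star, x$mu_W, x$lam))
  invisible(x)
}

#' CDF of W on the positive half-line by inversion
#'
#' Evaluates `L^{-1}{phi(theta)/theta}(w)` with the distribution's node
#' family. Raw (unclipped) values are used when reproducing error tables;
#' by default values are clipped to `[0, 1]`.
#'
#' @param wdist a [w_distribution()].
#' @param w strictly positive evaluation points.
#' @param clip clip the result to `[0, 1]`.
#' @return numeric vector of CDF values.
#' @export
invert_cdf <- function(wdist, w, clip = TRUE) {
  stopifnot(inherits(wdist, "w_distribution"), all(w > 0))
  H <- function(theta) wdist$lst(theta) / theta
  val <- invert_lt(H, w, wdist$nodes)
  if (clip) val <- pmin(pmax(val, 0), 1)
  val
}

#' CDF of W including the extinction atom
#'
#' @inheritParams invert_cdf
#' @param w nonnegative evaluation points; `w = 0` returns the atom `q_star`.
#' @return numeric vector of probabilities.
#' @export
cdf_w <- function(wdist, w, clip = TRUE) {
  stopifnot(all(w >= 0))
  out <- numeric(length(w))
  pos <- w > 0
  out[!pos] <- wdist$q_star
  if (any(pos)) out[pos] <- invert_cdf(wdist, w[pos], clip = clip)
  out
}

#' PDF of W conditional on non-extinction
#'
#' `g_{W*}(w) = G_W'(w) / (1 - q_star)` for `w > 0`. Two computation modes
#' are exposed: `"inversion"` inverts `phi(theta) - q_star` directly (the
#' transform of the continuous part's density; the extinction atom must be
#' removed or its point mass smears across small `w`), `"derivative"`
#' differentiates the Abate-Whitt CDF sum in `w` analytically, using the
#' analyticity of `phi` to obtain `phi'` by complex central differencing.
#'
#' @inheritParams invert_cdf
#' @param mode `"inversion"` (default) or `"derivative"`.
#' @return numeric vector of density values.
#' @export
pdf_wstar <- function(wdist, w, mode = c("inversion", "derivative")) {
  stopifnot(inherits(wdist, "w_distribution"), all(w > 0))
  mode <- match.arg(mode)
  if (mode == "inversion") {
    dens <- invert_lt(function(theta) wdist$lst(theta) - wdist$q_star, w,
                      wdist$nodes)
  } else {
    # G(w) = sum_k Re[(eta_k/beta_k) phi(beta_k/w)]  =>
    # G'(w) = -(1/w^2) sum_k Re[eta_k phi'(beta_k/w)]
    nodes <- wdist$nodes
    K <- length(nodes$beta)
    thetas <- as.vector(outer(nodes$beta, 1 / w))
    delta <- 1e-5 * pmax(1, abs(thetas))
    vp <- wdist$lst(c(thetas + delta, thetas - delta))
    nth <- length(thetas)
    dphi <- (vp[seq_len(nth)] - vp[nth + seq_len(nth)]) / (2 * delta)
    dmat <- matrix(dphi, K, length(w))
    dens <- -as.numeric(colSums(Re(nodes$eta * dmat))) / w^2
  }
  pmax(dens, 0) / (1 - wdist$q_star)
}

#' Sample W* by inverse-CDF on an adaptive grid
#'
#' Builds a monotone interpolant of the conditional CDF
#' `(G_W(w) - q_star)/(1 - q_star)` on an adaptive grid covering quantiles
#' `1e-4` to `1 - 1e-4`, then samples by inversion. Reproducible under a
#' fixed seed.
#'
#' @param wdist a [w_distribution()].
#' @param n_samples number of draws.
#' @param rng_seed optional integer seed.
#' @param grid_size number of grid points for the CDF interpolant.
#' @return numeric vector of samples of `W* = W | W > 0`.
#' @export
sample_wstar_pe <- function(wdist, n_samples, rng_seed = NULL,
                            grid_size = 400) {
  stopifnot(n_samples >= 1)
  grid <- wstar_cdf_grid(wdist, grid_size)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  u <- stats::runif(n_samples, min = 1e-4, max = 1 - 1e-4)
  stats::approx(grid$u, grid$w, xout = u, rule = 2)$y
}

# Monotone conditional-CDF grid used for sampling and tau CDFs.
wstar_cdf_grid <- function(wdist, grid_size = 400) {
  mu_star <- wdist$mu_W / (1 - wdist$q_star)
  w_hi <- 10 * mu_star
  repeat {
    u_hi <- (cdf_w(wdist, w_hi) - wdist$q_star) / (1 - wdist$q_star)
    if (u_hi >= 1 - 1e-4 || w_hi > 1e6 * mu_star) break
    w_hi <- 2 * w_hi
  }
  w <- seq(w_hi / grid_size * 1e-3, w_hi, length.out = grid_size)
  G <- cdf_w(wdist, w)
  u <- (G - wdist$q_star) / (1 - wdist$q_star)
  u <- cummax(pmin(pmax(u, 0), 1))       # isotonic correction
  keep <- !duplicated(u)
  if (sum(keep) < 10) stop("CDF grid construction failed: non-monotone inversion")
  list(w = c(0, w[keep]), u = c(0, u[keep]))
}

#' Analytic SIR reference: LST and CDF of W
#'
#' For the single-type linear birth-death approximation of the SIR model the
#' law of W is known in closed form: with `q = gamma/beta`,
#' `phi(theta) = q + (1 - q) / (1 + beta theta / (beta - gamma))` and
#' `G_W(w) = q + (1 - q)(1 - exp(-(1 - q) w))`; conditional on survival, W is
#' exponential with rate `1 - q`. These are the reference oracles for the PE
#' and MM routes.
#'
#' @param beta transmission rate; must exceed `gamma`.
#' @param gamma recovery rate.
#' @param theta complex evaluation point(s).
#' @return `sir_analytic_lst`: complex LST values; `sir_analytic_cdf`:
#'   CDF values.
#' @export
sir_analytic_lst <- function(beta, gamma, theta) {
  if (beta <= gamma) stop(subcritical_error("requires beta > gamma"))
  q <- gamma / beta
  q + (1 - q) / (1 + beta * theta / (beta - gamma))
}

#' @rdname sir_analytic_lst
#' @param w nonnegative point(s).
#' @export
sir_analytic_cdf <- function(beta, gamma, w) {
  if (beta <= gamma) stop(subcritical_error("requires beta > gamma"))
  stopifnot(all(w >= 0))
  q <- gamma / beta
  q + (1 - q) * (1 - exp(-(1 - q) * w))
}

#' CDF error metrics on a grid
#'
#' Summarises the discrepancy between a method CDF and a reference CDF over a
#' grid (default `0, 0.1, ..., 10`): the L1-norm in both conventions (sum and
#' mean over grid points) and the maximal absolute error.
#'
#' @param method_cdf,exact_cdf numeric vectors of CDF values on `grid`.
#' @param grid evaluation grid (only its length is used).
#' @return tibble with columns `l1_sum`, `l1_mean`, `max_err`.
#' @export
cdf_error_metrics <- function(method_cdf, exact_cdf,
                              grid = seq(0, 10, by = 0.1)) {
  stopifnot(length(method_cdf) == length(exact_cdf),
            length(method_cdf) == length(grid))
  err <- abs(method_cdf - exact_cdf)
  tibble::tibble(l1_sum = sum(err), l1_mean = mean(err), max_err = max(err))
}

#' Export a CDF/PDF table
#'
#' @param wdist a [w_distribution()].
#' @param w positive grid.
#' @param path output path (tab-separated columns `w`, `cdf`, `pdf_wstar`).
#' @export
export_cdf_table <- function(wdist, w, path) {
  utils::write.table(
    data.frame(w = w, cdf = cdf_w(wdist, w), pdf_wstar = pdf_wstar(wdist, w)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
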