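#' Generalised gamma density and moments
#'
#' The moment-matching (MM) surrogate for `W*` is the generalised gamma
#' distribution `GG(gg_scale, gg_shape1, gg_shape2)` with density
#' `g(w) = (a2 / (b^{a1} Gamma(a1/a2))) w^{a1-1} exp(-(w/b)^{a2})` and
#' `k`-th moment `M_k = b^k Gamma((a1 + k)/a2) / Gamma(a1/a2)`
#' (writing `b, a1, a2` for scale and shapes). The scale parameter is named
#' `gg_scale` to avoid a clash with transmission rates. All evaluation is in
#' log space for stability.
#'
#' @param p list or `gg_fit` with elements `gg_scale`, `gg_shape1`,
#'   `gg_shape2` (all positive).
#' @param w positive evaluation points.
#' @return density values.
#' @export
gg_pdf <- function(p, w) {
  stopifnot(all(w > 0))
  check_gg(p)
  b <- p$gg_scale; a1 <- p$gg_shape1; a2 <- p$gg_shape2
  exp(log(a2) - a1 * log(b) - lgamma(a1 / a2) +
        (a1 - 1) * log(w) - (w / b)^a2)
}

#' @rdname gg_pdf
#' @param k positive moment order.
#' @export
gg_moment <- function(p, k) {
  stopifnot(all(k > 0))
  check_gg(p)
  b <- p$gg_scale; a1 <- p$gg_shape1; a2 <- p$gg_shape2
  exp(k * log(b) + lgamma((a1 + k) / a2) - lgamma(a1 / a2))
}

check_gg <- function(p) {
  stopifnot(is.numeric(p$gg_scale), p$gg_scale > 0,
            is.numeric(p$gg_shape1), p$gg_shape1 > 0,
            is.numeric(p$gg_shape2), p$gg_shape2 > 0)
  invisible(p)
}

#' Standardise moments to scientific mantissa form
#'
#' Expresses each moment as `m_k = c_k 10^{eta_k}` with `c_k` in `[1, 10)`,
#' so all orders carry comparable weight in the moment-matching loss.
#'
#' @param moments positive numeric vector.
#' @return list with `c` (mantissas) and `eta` (integer exponents).
#' @export
standardize_moments <- function(moments) {
  stopifnot(all(moments > 0), all(is.finite(moments)))
  eta <- floor(log10(moments))
  list(c = moments / 10^eta, eta = as.integer(eta))
}

#' Fit a generalised gamma to the first five moments of W*
#'
#' Minimises the sum of squared standardised-moment residuals
#' `sum_k (c_k - M_k(p) / 10^{eta_k})^2` over the three positive parameters,
#' by bounded quasi-Newton optimisation on the log scale with a fixed set of
#' starts (the gamma method-of-moments point and the exponential point).
#'
#' @param moments_wstar numeric vector of the first five moments `E[W*^k]`.
#' @return object of class `gg_fit` with the fitted parameters, the attained
#'   `loss`, the fitted `moments`, and a `converged` flag (`FALSE` triggers a
#'   warning and returns the best candidate found).
#' @export
fit_gg <- function(moments_wstar) {
  stopifnot(length(moments_wstar) >= 5)
  mom <- moments_wstar[1:5]
  stopifnot(all(is.finite(mom)), all(mom > 0))
  std <- standardize_moments(mom)
  loss_of <- function(lp) {
    p <- list(gg_scale = exp(lp[1]), gg_shape1 = exp(lp[2]),
              gg_shape2 = exp(lp[3]))
    Mk <- gg_moment(p, 1:5)
    if (any(!is.finite(Mk))) return(1e10)
    sum((std$c - Mk / 10^std$eta)^2)
  }
  m1 <- mom[1]; m2 <- mom[2]
  varx <- max(m2 - m1^2, 1e-12 * m1^2)
  starts <- list(
    log(c(varx / m1, m1^2 / varx, 1)),     # gamma method-of-moments
    log(c(m1, 1, 1)),                      # exponential
    log(c(m1, 1.5, 0.8))
  )
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, loss_of, method = "L-BFGS-B",
                   lower = rep(-15, 3), upper = rep(15, 3),
                   control = list(maxit = 2000, factr = 10)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("generalised-gamma moment matching failed")
  o2 <- stats::optim(best$par, loss_of, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-15))
  if (o2$value < best$value) best <- o2
  p <- list(gg_scale = exp(best$par[1]), gg_shape1 = exp(best$par[2]),
            gg_shape2 = exp(best$par[3]))
  converged <- best$value < 1e-4
  if (!converged) {
    warning(sprintf("moment-matching loss %.3g above target; returning best fit",
                    best$value))
  }
  structure(c(p, list(loss = best$value, target_moments = mom,
                      moments = gg_moment(p, 1:5), converged = converged)),
            class = "gg_fit")
}

#' @export
print.gg_fit <- function(x, ...) {
  cat(sprintf(
    "gg_fit: scale = %.6g, shape1 = %.6g, shape2 = %.6g (loss %.3g)\n",
    x$gg_scale, x$gg_shape1, x$gg_shape2, x$loss))
  invisible(x)
}

#' @export
tidy.gg_fit <- function(x, ...) {
  tibble::tibble(term = c("gg_scale", "gg_shape1", "gg_shape2"),
                 estimate = c(x$gg_scale, x$gg_shape1, x$gg_shape2))
}

#' @export
glance.gg_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, converged = x$converged,
                 mean = x$moments[1])
}

#' Sample from a fitted generalised gamma
#'
#' Uses the exact change of variables `W* = gg_scale * X^(1/a2)` with
#' `X ~ Gamma(a1/a2, 1)`, equivalent to the inverse-CDF method on the stated
#' density.
#'
#' @param p a `gg_fit` or parameter list.
#' @param n number of draws.
#' @param rng_seed optional integer seed.
#' @return numeric samples.
#' @export
sample_gg <- function(p, n, rng_seed = NULL) {
  check_gg(p)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  x <- stats::rgamma(n, shape = p$gg_shape1 / p$gg_shape2, scale = 1)
  p$gg_scale * x^(1 / p$gg_shape2)
}

#' Time-shift density under the moment-matching surrogate
#'
#' Pushes the fitted `GG` law of `W*` through
#' `tau = (log w - log mu_W) / lam`:
#' `g(tau) = (a2 lam mu_W^{a1} / (b^{a1} Gamma(a1/a2)))
#'   exp(-(mu_W e^{lam tau} / b)^{a2} + a1 lam tau)`, supported on the whole
#' real line.
#'
#' @param p generalised-gamma parameters.
#' @param lam growth rate (positive).
#' @param mu_W mean of W (positive).
#' @param tau real evaluation points.
#' @return density values.
#' @export
timeshift_pdf_mm <- function(p, lam, mu_W, tau) {
  check_gg(p)
  stopifnot(lam > 0, mu_W > 0)
  b <- p$gg_scale; a1 <- p$gg_shape1; a2 <- p$gg_shape2
  exp(log(a2) + log(lam) + a1 * (log(mu_W) - log(b)) - lgamma(a1 / a2) -
        (mu_W * exp(lam * tau) / b)^a2 + a1 * lam * tau)
}
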