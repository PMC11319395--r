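#' LST engine configuration
#'
#' Hyper-parameters of the Laplace-Stieltjes transform evaluator: the number
#' of Taylor moments `n`, the embedded-process time step `h`, the LST error
#' tolerance `eps` controlling the radius of the trusted Taylor disc, and the
#' tolerances of the embedded-pgf ODE integration.
#'
#' @param n number of moments in the Taylor expansion (default 30).
#' @param h embedded time step (default 0.1).
#' @param eps LST error tolerance (default 1e-6).
#' @param ode_rtol,ode_atol relative/absolute ODE tolerances.
#' @return object of class `lst_config`.
#' @export
lst_config <- function(n = 30, h = 0.1, eps = 1e-6,
                       ode_rtol = 1e-10, ode_atol = 1e-12) {
  stopifnot(n >= 1, h > 0, eps > 0)
  structure(list(n = n, h = h, eps = eps,
                 ode_rtol = ode_rtol, ode_atol = ode_atol),
            class = "lst_config")
}

#' Truncated-Taylor LST approximation
#'
#' Evaluates `sum_{k=0}^{n} (-theta)^k E[W_i^k] / k!`. The absolute error is
#' at most `|theta|^{n+1} E[W_i^{n+1}] / (n+1)!`, which is what
#' [error_radius()] inverts to find the trusted disc.
#'
#' @param table a `moment_table` holding moments at least to order `n`.
#' @param i type index.
#' @param theta complex scalar or vector.
#' @param n truncation order (default: all available moments).
#' @return complex value(s) of the truncated series.
#' @export
taylor_lst <- function(table, i, theta, n = table$n_max) {
  stopifnot(inherits(table, "moment_table"), i >= 1, i <= table$m,
            n <= table$n_max)
  coef <- c(1, table$xi[seq_len(n), i] / factorial(seq_len(n)))
  # Horner in (-theta)
  val <- rep(coef[n + 1] + 0i, length(theta))
  for (k in n:1) val <- coef[k] + val * (-theta)
  val
}

#' Radius of the error-controlled Taylor disc
#'
#' `L(n, eps) = ((n+1)! eps / gamma)^(1/(n+1))` with
#' `gamma = max_i E[W_i^{n+1}]`; the truncated LST has absolute error at most
#' `eps` for every type whenever `|theta| <= L`.
#'
#' @param table a `moment_table` holding order `n + 1`.
#' @param n Taylor order.
#' @param eps error tolerance.
#' @return positive radius `L`.
#' @export
error_radius <- function(table, n, eps) {
  stopifnot(inherits(table, "moment_table"), table$n_max >= n + 1)
  gam <- max(table$xi[n + 1, ])
  exp((lgamma(n + 2) + log(eps) - log(gam)) / (n + 1))
}

#' Progeny generating function of the embedded process
#'
#' Integrates the backward equations `dF_i/dt = a_i (f_i(F) - F_i)` with
#' `F(s, 0) = s` over `[0, h]` and returns `F(s, h)`, the progeny generating
#' function of the discrete-time chain obtained by observing the CT-MBP every
#' `h` time units. Complex arguments are supported by integrating real and
#' imaginary parts jointly; many evaluation points can be batched as matrix
#' columns and share one ODE solve.
#'
#' @param model a continuous [branching_model()].
#' @param s complex vector of length `m`, or `m x p` matrix of points.
#' @param h time step.
#' @param rtol,atol ODE tolerances.
#' @return object of the same shape as `s`.
#' @export
embedded_pgf <- function(model, s, h, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "branching_model"), !model$discrete, h > 0)
  m <- model$m
  was_matrix <- is.matrix(s)
  smat <- if (was_matrix) s else matrix(as.complex(s), nrow = m)
  stopifnot(nrow(smat) == m)
  p <- ncol(smat)
  a <- model$a
  rhs <- function(t, y, parms) {
    F <- matrix(complex(real = y[seq_len(m * p)],
                        imaginary = y[m * p + seq_len(m * p)]), m, p)
    dF <- a * (pgf_eval(model, F) - F)
    if (p == 1L) dF <- matrix(dF, m, 1)
    list(c(Re(dF), Im(dF)))
  }
  y0 <- c(Re(smat), Im(smat))
  sol <- deSolve::ode(y = y0, times = c(0, h), func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("embedded-pgf ODE integration failed at s = ",
         paste(format(smat[, 1]), collapse = ", "))
  }
  yh <- sol[nrow(sol), -1]
  out <- matrix(complex(real = yh[seq_len(m * p)],
                        imaginary = yh[m * p + seq_len(m * p)]), m, p)
  if (was_matrix) out else drop(out)
}

#' Build an LST evaluator
#'
#' Precomputes everything [lst_eval()] needs: the eigen-system, conditional
#' moments to order `n + 1` (the extra order feeds the error bound), the
#' moment bound `gamma`, and the trusted radius `L`. Works for continuous
#' models (embedded pgf obtained by ODE solves) and discrete models (progeny
#' generating functions used directly, shrink factor `1/rho`).
#'
#' @param model a supercritical [branching_model()].
#' @param config an [lst_config()].
#' @return object of class `lst_evaluator` with fields `model`, `eig`,
#'   `table`, `gamma_bound`, `L`, `config` and a composition counter.
#' @export
lst_evaluator <- function(model, config = lst_config()) {
  stopifnot(inherits(model, "branching_model"), inherits(config, "lst_config"))
  eig <- eigen_quantities(model)
  table <- if (model$discrete) {
    moment_recursion_discrete(model, eig, config$n + 1)
  } else {
    moment_recursion(model, eig, config$n + 1)
  }
  h <- if (model$discrete) 1 else config$h
  structure(list(model = model, eig = eig, table = table, config = config,
                 h = h,
                 gamma_bound = max(table$xi[config$n + 1, ]),
                 L = error_radius(table, config$n, config$eps),
                 counter = new.env(parent = emptyenv())),
            class = "lst_evaluator")
}

#' @export
print.lst_evaluator <- function(x, ...) {
  cat(sprintf(
    "lst_evaluator: m = %d, n = %d moments, h = %g, eps = %g, L = %.6g\n",
    x$model$m, x$config$n, x$h, x$config$eps, x$L))
  invisible(x)
}

kappa_for <- function(ev, theta) {
  amag <- abs(theta)
  lamh <- ev$eig$lam * ev$h
  kap <- ifelse(amag <= ev$L, 0, ceiling(log(amag / ev$L) / lamh))
  if (any(kap > 1e6)) stop("theta too large: composition count overflow")
  as.integer(kap)
}

#' Evaluate the LST of the martingale limit
#'
#' Computes `phi_i(theta) = E[exp(-theta W_i)]` for all types. Inside the
#' trusted disc (`|theta| <= L`) the truncated Taylor series is used; outside
#' it, `theta` is shrunk by `exp(-lam h kappa)` with
#' `kappa = ceil(log(|theta|/L) / (lam h))`, evaluated by Taylor, and the
#' embedded-process progeny generating function applied exactly `kappa`
#' times, exploiting the functional equation
#' `phi(theta) = f~(phi(theta e^{-lam h}))`.
#'
#' `lst_eval_batch()` evaluates many points in one pass; all points share a
#' single composition chain of length `max(kappa)` so each chain step is one
#' batched ODE solve.
#'
#' @param ev an [lst_evaluator()].
#' @param theta complex scalar (`lst_eval`) or vector (`lst_eval_batch`).
#' @return `lst_eval`: complex vector `phi(theta)` of length `m`;
#'   `lst_eval_batch`: an `m x length(theta)` complex matrix.
#' @export
lst_eval <- function(ev, theta) {
  stopifnot(inherits(ev, "lst_evaluator"), length(theta) == 1L)
  drop(lst_eval_batch(ev, theta))
}

#' @rdname lst_eval
#' @export
lst_eval_batch <- function(ev, theta) {
  theta <- as.complex(theta)
  m <- ev$model$m
  p <- length(theta)
  kap_each <- kappa_for(ev, theta)
  kap <- max(kap_each)
  lamh <- ev$eig$lam * ev$h
  th0 <- theta * exp(-lamh * kap_each)
  base <- matrix(0 + 0i, m, p)
  for (i in seq_len(m)) {
    base[i, ] <- taylor_lst(ev$table, i, th0, n = ev$config$n)
  }
  cnt <- ev$counter
  cnt$compositions <- 0L
  out <- base
  if (kap > 0) {
    # merged chain: each point joins when `remaining` steps equal its kappa,
    # so every point receives exactly its own number of compositions.
    joiners <- split(seq_len(p), kap_each)
    active <- joiners[[as.character(kap)]]
    phi <- base[, active, drop = FALSE]
    for (remaining in kap:1) {
      if (ev$model$discrete) {
        phi <- pgf_eval(ev$model, phi)
        phi <- matrix(phi, m, length(active))
      } else {
        phi <- embedded_pgf(ev$model, phi, ev$h,
                            rtol = ev$config$ode_rtol,
                            atol = ev$config$ode_atol)
      }
      cnt$compositions <- cnt$compositions + 1L
      joining <- joiners[[as.character(remaining - 1L)]]
      if (!is.null(joining)) {
        active <- c(active, joining)
        phi <- cbind(phi, base[, joining, drop = FALSE])
      }
    }
    out[, active] <- phi
  }
  out
}

#' @rdname lst_eval
#' @export
lst_discrete <- function(ev, theta) {
  stopifnot(ev$model$discrete)
  lst_eval(ev, theta)
}

#' LST for an arbitrary initial condition
#'
#' By founder independence, `phi(theta) = prod_i phi_i(theta)^{z0_i}`.
#'
#' @param phis complex vector `phi_i(theta)` (length `m`) or `m x p` matrix.
#' @param z0 initial count vector.
#' @return complex scalar (or length-`p` vector).
#' @export
lst_for_initial <- function(phis, z0) {
  if (is.matrix(phis)) {
    z0 <- check_z0(z0, nrow(phis))
    out <- rep(1 + 0i, ncol(phis))
    for (i in seq_len(nrow(phis))) {
      if (z0[i] > 0) out <- out * phis[i, ]^z0[i]
    }
    out
  } else {
    z0 <- check_z0(z0, length(phis))
    prod(phis^z0)
  }
}
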