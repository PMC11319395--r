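#' Define a multitype Markov branching process
#'
#' Constructs a continuous- or discrete-time multitype Markov branching
#' process (CT-/DT-MBP) from death/linear/quadratic reproduction rates. Each
#' type-`i` individual lives an exponential time with rate
#' `a_i = nu_i + sum_j alpha_ij + sum_{k<=l} beta_ikl` and on death leaves no
#' offspring (rate `nu_i`), one individual of type `j` (rate `alpha_ij`), or
#' one of type `k` plus one of type `l` (rate `beta_ikl`). For a discrete-time
#' model the same quantities are offspring probabilities (summing to one per
#' type) and lifetimes are unit.
#'
#' @param nu numeric vector of death-without-offspring rates (length `m`).
#' @param alpha `m x m` matrix of linear rates; the diagonal must be zero
#'   (a type turning into itself is not a branching event).
#' @param beta quadratic rates, either an `m x m x m` array with
#'   `beta[i, k, l]` the rate of type `i` splitting into `k` and `l`, or a
#'   data frame with columns `i`, `k`, `l`, `rate`. Entries given with
#'   `k > l` are folded onto the canonical ordering `l >= k` by summation.
#' @param discrete logical; `TRUE` for a DT-MBP (entries are probabilities).
#' @param type_names optional character vector of type labels.
#'
#' @return An object of class `branching_model` with elements `m`, `nu`,
#'   `alpha`, `beta` (canonical `l >= k` storage), `discrete` and, for
#'   continuous models, the lifetime rates `a`.
#' @export
#' @examples
#' # linear birth-death process: I -> 0 at rate gamma, I -> 2I at rate beta
#' m <- branching_model(nu = 0.5, beta = data.frame(i = 1, k = 1, l = 1, rate = 0.95))
#' lifetime_rates(m)
branching_model <- function(nu, alpha = NULL, beta = NULL, discrete = FALSE,
                            type_names = NULL) {
  m <- length(nu)
  stopifnot(m >= 1, all(is.finite(nu)), all(nu >= 0))
  if (is.null(alpha)) alpha <- matrix(0, m, m)
  alpha <- as.matrix(alpha)
  stopifnot(identical(dim(alpha), c(m, m)), all(alpha >= 0))
  if (any(diag(alpha) != 0)) {
    stop("alpha must have a zero diagonal (alpha[i, i] is not a branching event)")
  }
  beta_arr <- array(0, dim = c(m, m, m))
  if (!is.null(beta)) {
    if (is.data.frame(beta)) {
      stopifnot(all(c("i", "k", "l", "rate") %in% names(beta)))
      for (r in seq_len(nrow(beta))) {
        i <- beta$i[r]; k <- beta$k[r]; l <- beta$l[r]; rate <- beta$rate[r]
        stopifnot(rate >= 0, i >= 1, i <= m, k >= 1, k <= m, l >= 1, l <= m)
        if (k > l) { tmp <- k; k <- l; l <- tmp }
        beta_arr[i, k, l] <- beta_arr[i, k, l] + rate
      }
    } else {
      beta <- as.array(beta)
      stopifnot(identical(dim(beta), c(m, m, m)), all(beta >= 0))
      # fold any k > l entries onto the canonical l >= k storage
      for (i in seq_len(m)) for (k in seq_len(m)) for (l in seq_len(m)) {
        if (k > l && beta[i, k, l] > 0) {
          beta_arr[i, l, k] <- beta_arr[i, l, k] + beta[i, k, l]
        } else if (k <= l) {
          beta_arr[i, k, l] <- beta_arr[i, k, l] + beta[i, k, l]
        }
      }
    }
  }
  a <- nu + rowSums(alpha) + apply(beta_arr, 1, sum)
  if (discrete) {
    if (any(abs(a - 1) > 1e-10)) {
      stop("discrete model: offspring probabilities must sum to 1 for every type")
    }
  } else if (any(a <= 0)) {
    stop("invalid model: lifetime rate a_i = 0 for type(s) ",
         paste(which(a <= 0), collapse = ", "), " (type never dies)")
  }
  model <- structure(
    list(m = m, nu = as.numeric(nu), alpha = unname(alpha), beta = beta_arr,
         discrete = discrete,
         a = if (discrete) rep(1, m) else as.numeric(a),
         type_names = type_names %||% paste0("type", seq_len(m))),
    class = "branching_model")
  if (!is_irreducible(model)) {
    warning("mean matrix is reducible; the theory assumes irreducibility")
  }
  model
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.branching_model <- function(x, ...) {
  cat(sprintf("%s multitype Markov branching process, m = %d type(s)\n",
              if (x$discrete) "Discrete-time" else "Continuous-time", x$m))
  if (!x$discrete) {
    cat("lifetime rates a:", paste(signif(x$a, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Lifetime rates of a continuous-time branching model
#'
#' Returns `a_i = nu_i + sum_{j != i} alpha_ij + sum_{k<=l} beta_ikl`, the
#' exponential rate parameter of type-`i` lifetimes.
#'
#' @param model a [branching_model()].
#' @return numeric vector of length `m`.
#' @export
lifetime_rates <- function(model) {
  stopifnot(inherits(model, "branching_model"))
  if (model$discrete) stop("lifetime rates are defined for continuous models only")
  model$a
}

#' Evaluate progeny generating functions
#'
#' Evaluates `f_i(s) = (nu_i + sum_j alpha_ij s_j + sum_{k<=l} beta_ikl s_k s_l) / a_i`
#' (without the `a_i` divisor for discrete models, where entries are already
#' probabilities). Accepts complex arguments: the LST engine composes these
#' functions off the unit cube.
#'
#' @param model a [branching_model()].
#' @param s complex (or numeric) vector of length `m`, or an `m x p` matrix of
#'   `p` evaluation points.
#' @param i optional type index; if `NULL` all types are evaluated.
#' @return If `i` is given, a complex scalar (or length-`p` vector); otherwise
#'   a length-`m` vector (or `m x p` matrix) of values for every type.
#' @export
pgf_eval <- function(model, s, i = NULL) {
  stopifnot(inherits(model, "branching_model"))
  m <- model$m
  smat <- if (is.matrix(s)) s else matrix(s, nrow = m)
  stopifnot(nrow(smat) == m)
  p <- ncol(smat)
  idx <- if (is.null(i)) seq_len(m) else i
  if (!all(idx >= 1 & idx <= m)) stop("type index out of range")
  out <- matrix(0 + 0i, length(idx), p)
  for (r in seq_along(idx)) {
    ii <- idx[r]
    val <- rep(model$nu[ii] + 0i, p)
    for (j in seq_len(m)) {
      if (model$alpha[ii, j] != 0) val <- val + model$alpha[ii, j] * smat[j, ]
    }
    for (k in seq_len(m)) for (l in k:m) {
      b <- model$beta[ii, k, l]
      if (b != 0) val <- val + b * smat[k, ] * smat[l, ]
    }
    out[r, ] <- if (model$discrete) val else val / model$a[ii]
  }
  if (!is.null(i) && length(i) == 1L) {
    if (is.matrix(s)) out[1, ] else drop(out[1, 1])
  } else if (is.matrix(s)) out else drop(out)
}

#' Growth matrix of a branching model
#'
#' For a continuous model returns `Omega` with
#' `Omega_ij = a_i (df_i/ds_j(1) - delta_ij)`; its dominant eigenvalue is the
#' Malthusian parameter. For a discrete model returns the mean offspring
#' matrix `M_ij = df_i/ds_j(1)`.
#'
#' @param model a [branching_model()].
#' @return an `m x m` real matrix.
#' @export
build_growth_matrix <- function(model) {
  stopifnot(inherits(model, "branching_model"))
  m <- model$m
  # mean offspring matrix M_ij = alpha_ij + sum_{k<=l} beta_ikl (d_jk + d_jl), / a_i if CT
  M <- model$alpha
  for (i in seq_len(m)) for (k in seq_len(m)) for (l in k:m) {
    b <- model$beta[i, k, l]
    if (b != 0) {
      M[i, k] <- M[i, k] + b
      M[i, l] <- M[i, l] + b
    }
  }
  if (model$discrete) return(M)
  M - diag(model$a, m)
}

is_irreducible <- function(model) {
  m <- model$m
  if (m == 1L) return(TRUE)
  G <- build_growth_matrix(model)
  adj <- (G > 0) & !diag(TRUE, m)
  reach <- adj | diag(TRUE, m)
  for (k in seq_len(m)) reach <- reach | (reach %*% reach > 0)  # transitive closure
  all(reach)
}

#' Dominant eigen-system of a growth matrix
#'
#' Extracts the Perron root and its left/right eigenvectors with the
#' normalisation `u . 1 = 1`, `u . v = 1`. The right eigenvector `u` carries
#' the conditional means `E[W_i] = u_i`; `v` is the direction onto which the
#' rescaled process collapses.
#'
#' @param growth_matrix an `m x m` matrix (`Omega` for continuous models, the
#'   mean offspring matrix for discrete ones), or a [branching_model()] from
#'   which it is built.
#' @param discrete logical; if `TRUE` the matrix is a mean offspring matrix
#'   and the growth rate is `lam = log(rho)` with `rho` its Perron root.
#' @return An object of class `eigen_system` with `growth_matrix`, `lam`,
#'   `rho` (discrete only), `u`, `v`.
#' @export
eigen_quantities <- function(growth_matrix, discrete = FALSE) {
  if (inherits(growth_matrix, "branching_model")) {
    discrete <- growth_matrix$discrete
    growth_matrix <- build_growth_matrix(growth_matrix)
  }
  A <- as.matrix(growth_matrix)
  m <- nrow(A)
  er <- eigen(A)
  el <- eigen(t(A))
  dom <- which.max(Re(er$values))
  lam0 <- er$values[dom]
  # Perron root must be real and simple for an irreducible nonnegative pattern
  if (abs(Im(lam0)) > 1e-9 * max(1, abs(lam0))) {
    stop("dominant eigenvalue is not real; model violates Perron assumptions")
  }
  gap <- sort(abs(Re(er$values) - Re(lam0)))
  if (m > 1 && gap[2] < 1e-12 * max(1, abs(Re(lam0)))) {
    stop("dominant eigenvalue is not simple")
  }
  u <- Re(er$vectors[, dom])
  doml <- which.max(Re(el$values))
  v <- Re(el$vectors[, doml])
  if (all(u <= 0)) u <- -u
  if (all(v <= 0)) v <- -v
  if (any(u <= 0) || any(v <= 0)) {
    stop("Perron eigenvectors cannot be scaled strictly positive")
  }
  u <- u / sum(u)
  v <- v / sum(u * v)
  rho <- if (discrete) Re(lam0) else NA_real_
  lam <- if (discrete) log(Re(lam0)) else Re(lam0)
  if (!discrete && lam <= 0) {
    stop(subcritical_error(sprintf("Malthusian parameter lambda = %.6g <= 0", lam)))
  }
  if (discrete && rho <= 1) {
    stop(subcritical_error(sprintf("mean offspring Perron root rho = %.6g <= 1", rho)))
  }
  structure(list(growth_matrix = A, lam = lam, rho = rho,
                 u = as.numeric(u), v = as.numeric(v), discrete = discrete),
            class = "eigen_system")
}

subcritical_error <- function(msg) {
  structure(class = c("subcritical_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' @export
print.eigen_system <- function(x, ...) {
  cat(sprintf("eigen_system: lambda = %.6g%s\n", x$lam,
              if (x$discrete) sprintf(" (rho = %.6g)", x$rho) else ""))
  cat("u:", paste(signif(x$u, 6), collapse = ", "), "\n")
  cat("v:", paste(signif(x$v, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Extinction probabilities
#'
#' Solves `f_i(q) = q_i` for the minimal non-negative fixed point by monotone
#' fixed-point iteration started at 0, and returns the product-form extinction
#' probability for arbitrary initial conditions,
#' `q_star(z0) = prod_i q_i^{z0_i}`.
#'
#' @param model a supercritical [branching_model()].
#' @param tol sup-norm stopping tolerance for the iteration.
#' @param max_iter iteration cap.
#' @param start starting vector (default 0; starting at 1 returns the trivial
#'   fixed point, which distinguishes minimality).
#' @return list with `q` (per-type extinction probabilities) and `q_star`, a
#'   function of the initial count vector `z0`.
#' @export
extinction_probs <- function(model, tol = 1e-14, max_iter = 1e6, start = NULL) {
  stopifnot(inherits(model, "branching_model"))
  q <- start %||% rep(0, model$m)
  for (it in seq_len(max_iter)) {
    qn <- Re(pgf_eval(model, q))
    if (max(abs(qn - q)) < tol) {
      q <- qn
      return(list(
        q = q,
        q_star = function(z0) {
          z0 <- check_z0(z0, model$m)
          prod(q ^ z0)
        },
        iterations = it))
    }
    q <- qn
  }
  stop("extinction fixed-point iteration failed to converge within ", max_iter,
       " iterations")
}

check_z0 <- function(z0, m) {
  stopifnot(length(z0) == m, all(z0 >= 0), all(z0 == round(z0)))
  if (sum(z0) == 0) stop("initial condition must contain at least one individual")
  as.numeric(z0)
}
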