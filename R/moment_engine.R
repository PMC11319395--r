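#' Conditional moments of the martingale limit by linear recursion
#'
#' Computes `E[W_i^n]` for `n = 1, ..., n_max`, where `W_i` is the martingale
#' limit of the process started from a single type-`i` individual. Order 1 is
#' the right Perron eigenvector `u`; each higher order solves the linear
#' system `C^(n) Xi^(n) = d^(n)` obtained by differentiating the functional
#' equation of the moment generating function `n` times: with
#' `at_ij = alpha_ij / (a_i + n lam)` and `bt_ikl = beta_ikl / (a_i + n lam)`,
#' row `i` of `C^(n)` is `e_i - sum_{j != i} at_ij e_j - sum_{k<=l} bt_ikl
#' (e_k + e_l)` and `d_i = sum_{k<=l} bt_ikl sum_{r=1}^{n-1} C(n,r)
#' E[W_k^r] E[W_l^{n-r}]`.
#'
#' @param model a continuous supercritical [branching_model()].
#' @param eig its [eigen_quantities()].
#' @param n_max highest moment order.
#' @return object of class `moment_table`: an `n_max x m` matrix `xi` with
#'   `xi[n, i] = E[W_i^n]`, plus `m`, `n_max`.
#' @export
moment_recursion <- function(model, eig, n_max) {
  stopifnot(inherits(model, "branching_model"), !model$discrete,
            inherits(eig, "eigen_system"), n_max >= 1)
  m <- model$m
  lam <- eig$lam
  xi <- matrix(NA_real_, n_max, m)
  xi[1, ] <- eig$u
  for (n in seq_len(n_max)[-1]) {
    C <- diag(1, m)
    d <- numeric(m)
    for (i in seq_len(m)) {
      denom <- model$a[i] + n * lam
      for (j in seq_len(m)) {
        if (j != i && model$alpha[i, j] != 0) {
          C[i, j] <- C[i, j] - model$alpha[i, j] / denom
        }
      }
      for (k in seq_len(m)) for (l in k:m) {
        b <- model$beta[i, k, l]
        if (b != 0) {
          bt <- b / denom
          C[i, k] <- C[i, k] - bt
          C[i, l] <- C[i, l] - bt
          r <- seq_len(n - 1)
          d[i] <- d[i] + bt * sum(choose(n, r) * xi[r, k] * xi[n - r, l])
        }
      }
    }
    xi[n, ] <- solve(C, d)
  }
  new_moment_table(xi, model)
}

#' Conditional moments for discrete-time models
#'
#' Differentiates the discrete-time functional equation
#' `Xi(theta) = f(Xi(theta / rho))` `n` times at zero. The resulting linear
#' system per order has row `i` equal to
#' `e_i - rho^{-n} (sum_j alpha_ij e_j + sum_{k<=l} beta_ikl (e_k + e_l))`
#' with right-hand side `rho^{-n} sum_{k<=l} beta_ikl sum_{r=1}^{n-1}
#' C(n,r) E[W_k^r] E[W_l^{n-r}]`.
#'
#' @inheritParams moment_recursion
#' @return a `moment_table`.
#' @export
moment_recursion_discrete <- function(model, eig, n_max) {
  stopifnot(inherits(model, "branching_model"), model$discrete,
            inherits(eig, "eigen_system"), n_max >= 1)
  m <- model$m
  rho <- eig$rho
  xi <- matrix(NA_real_, n_max, m)
  xi[1, ] <- eig$u
  for (n in seq_len(n_max)[-1]) {
    shrink <- rho^(-n)
    C <- diag(1, m)
    d <- numeric(m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (model$alpha[i, j] != 0) {
          C[i, j] <- C[i, j] - shrink * model$alpha[i, j]
        }
      }
      for (k in seq_len(m)) for (l in k:m) {
        b <- model$beta[i, k, l]
        if (b != 0) {
          C[i, k] <- C[i, k] - shrink * b
          C[i, l] <- C[i, l] - shrink * b
          r <- seq_len(n - 1)
          d[i] <- d[i] + shrink * b * sum(choose(n, r) * xi[r, k] * xi[n - r, l])
        }
      }
    }
    xi[n, ] <- solve(C, d)
  }
  new_moment_table(xi, model)
}

new_moment_table <- function(xi, model) {
  colnames(xi) <- model$type_names
  if (any(!is.finite(xi)) || any(xi <= 0)) {
    stop("moment recursion produced non-finite or non-positive moments")
  }
  structure(list(xi = xi, m = ncol(xi), n_max = nrow(xi)),
            class = "moment_table")
}

#' @export
print.moment_table <- function(x, ...) {
  cat(sprintf("moment_table: E[W_i^n], n = 1..%d, m = %d type(s)\n",
              x$n_max, x$m))
  print(utils::head(x$xi, 5))
  if (x$n_max > 5) cat("...\n")
  invisible(x)
}

#' Tidy a moment table
#'
#' @param x a `moment_table`.
#' @param ... unused.
#' @return tibble with columns `order`, `type`, `moment`.
#' @export
tidy.moment_table <- function(x, ...) {
  tibble::tibble(
    order = rep(seq_len(x$n_max), x$m),
    type = rep(colnames(x$xi), each = x$n_max),
    moment = as.vector(x$xi))
}

#' Export a moment table to delimited text
#'
#' @param table a `moment_table`.
#' @param path output path (tab-separated, orders in rows, types in columns).
#' @export
export_moment_table <- function(table, path) {
  utils::write.table(cbind(order = seq_len(table$n_max), table$xi), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Moments of W for an arbitrary initial condition
#'
#' With `z0` independent founders, `W` is the sum of the founders' independent
#' limits, so its moments follow from the multinomial theorem. Implemented as
#' iterated convolution of exponential moment sequences
#' (`E[W^k]/k!`), which is equivalent to enumerating integer partitions.
#'
#' @param table a `moment_table`.
#' @param z0 nonnegative integer initial count vector (length `m`).
#' @param k_max number of moments to return (`<= table$n_max`).
#' @return numeric vector `E[W^k]`, `k = 1..k_max`.
#' @export
w_moments_from_initial <- function(table, z0, k_max = table$n_max) {
  stopifnot(inherits(table, "moment_table"), k_max <= table$n_max, k_max >= 1)
  z0 <- check_z0(z0, table$m)
  # exponential moment sequences a_k = E[U^k]/k!, a_0 = 1
  acc <- c(1, numeric(k_max))
  kfact <- factorial(0:k_max)
  for (i in seq_len(table$m)) {
    if (z0[i] == 0) next
    seq_i <- c(1, table$xi[seq_len(k_max), i] / kfact[-1])
    for (rep in seq_len(z0[i])) {
      acc <- convolve_trunc(acc, seq_i, k_max)
    }
  }
  acc[-1] * kfact[-1]
}

convolve_trunc <- function(a, b, k_max) {
  out <- numeric(k_max + 1)
  for (k in 0:k_max) {
    out[k + 1] <- sum(a[seq_len(k + 1)] * b[(k + 1):1])
  }
  out
}

#' Moments conditional on non-extinction
#'
#' `W` has an atom of mass `q_star` at zero; conditioning on survival scales
#' every positive-order moment by `1 / (1 - q_star)`.
#'
#' @param w_moments numeric vector `E[W^k]`, `k >= 1`.
#' @param q_star extinction probability for the initial condition, in `[0, 1)`.
#' @return numeric vector `E[W*^k]`.
#' @export
conditional_moments <- function(w_moments, q_star) {
  stopifnot(q_star >= 0, q_star < 1)
  w_moments / (1 - q_star)
}
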