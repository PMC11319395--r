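#' Define a density-dependent CTMC population model
#'
#' Specifies a continuous-time Markov chain by a list of events, each with a
#' stoichiometry vector and a mass-action rate of the form
#' `coef * x[a]` (first order) or `coef * x[a] * x[b] / scale` (second order),
#' the density-dependent forms under which a deterministic (fluid) limit
#' exists. This structured form is what the exact simulator and the
#' deterministic solver consume.
#'
#' @param state_names character vector of state labels (length `d`).
#' @param events list of events, each a list with `delta` (integer change
#'   vector of length `d`), `coef` (positive rate constant) and `idx`
#'   (integer vector of 1 or 2 state indices entering the rate product).
#' @param scale system size (`N` or `K`); second-order rates are divided by it.
#' @param x0 initial count vector.
#' @param bp_coords indices of the coordinates approximated by the branching
#'   process; their joint absorption at zero is "extinction".
#' @return object of class `ctmc_model`.
#' @export
ctmc_model <- function(state_names, events, scale, x0, bp_coords = NULL) {
  d <- length(state_names)
  stopifnot(length(x0) == d, all(x0 >= 0), scale > 0)
  for (ev in events) {
    stopifnot(length(ev$delta) == d, is.numeric(ev$coef), ev$coef >= 0,
              length(ev$idx) %in% c(1L, 2L),
              all(ev$idx >= 1), all(ev$idx <= d))
  }
  structure(list(state_dim = d, state_names = state_names, events = events,
                 scale = scale, x0 = as.numeric(x0),
                 bp_coords = bp_coords %||% seq_len(d)),
            class = "ctmc_model")
}

#' @export
print.ctmc_model <- function(x, ...) {
  cat(sprintf("ctmc_model: %d states (%s), %d events, scale = %g\n",
              x$state_dim, paste(x$state_names, collapse = ", "),
              length(x$events), x$scale))
  invisible(x)
}

# Event rates at a given count state (used by tests and the pure-R fallback).
ctmc_rates <- function(ctmc, x) {
  vapply(ctmc$events, function(ev) {
    r <- ev$coef * prod(x[ev$idx])
    if (length(ev$idx) == 2L) r <- r / ctmc$scale
    r
  }, numeric(1))
}

# Density drift x' = sum_e delta_e coef_e prod(x[idx_e]) for the fluid limit.
ctmc_drift <- function(ctmc, x) {
  dx <- numeric(ctmc$state_dim)
  for (ev in ctmc$events) {
    dx <- dx + ev$delta * (ev$coef * prod(x[ev$idx]))
  }
  dx
}

#' Represent a branching process as a CTMC
#'
#' Expands the death/linear/quadratic rates of a continuous-time
#' [branching_model()] into explicit CTMC events (all first order in the
#' counts), so the exact simulator can generate branching-process paths.
#'
#' @param model a continuous [branching_model()].
#' @param z0 initial count vector.
#' @return a [ctmc_model()] whose states are the branching-process types.
#' @export
bp_to_ctmc <- function(model, z0) {
  stopifnot(inherits(model, "branching_model"), !model$discrete)
  m <- model$m
  z0 <- check_z0(z0, m)
  ev <- list()
  for (i in seq_len(m)) {
    e_i <- function(j) { v <- numeric(m); v[j] <- 1; v }
    if (model$nu[i] > 0) {
      ev[[length(ev) + 1]] <- list(delta = -e_i(i), coef = model$nu[i], idx = i)
    }
    for (j in seq_len(m)) {
      if (model$alpha[i, j] > 0) {
        ev[[length(ev) + 1]] <- list(delta = -e_i(i) + e_i(j),
                                     coef = model$alpha[i, j], idx = i)
      }
    }
    for (k in seq_len(m)) for (l in k:m) {
      b <- model$beta[i, k, l]
      if (b > 0) {
        ev[[length(ev) + 1]] <- list(delta = -e_i(i) + e_i(k) + e_i(l),
                                     coef = b, idx = i)
      }
    }
  }
  ctmc_model(model$type_names, ev, scale = 1, x0 = z0,
             bp_coords = seq_len(m))
}
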