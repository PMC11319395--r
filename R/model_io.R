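#' Read or write a model specification file
#'
#' Models are stored as YAML with keys `m`, `nu`, `alpha` (sparse triplets
#' `i, j, rate`), `beta` (triplets `i, k, l, rate`), `discrete` and an
#' optional `ctmc` block (stoichiometries, structured mass-action rates,
#' `scale`, `x0`). The representation round-trips exactly.
#'
#' @param path file path.
#' @return `read_model_spec()` returns a list with `bp` (a
#'   [branching_model()]) and, if present, `ctmc` (a [ctmc_model()]) and
#'   `z0`; `write_model_spec()` returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  m <- spec$m
  nu <- as.numeric(spec$nu)
  alpha <- matrix(0, m, m)
  for (tr in spec$alpha %||% list()) {
    alpha[tr$i, tr$j] <- tr$rate
  }
  beta <- NULL
  if (length(spec$beta %||% list())) {
    beta <- do.call(rbind, lapply(spec$beta, function(tr) {
      data.frame(i = tr$i, k = tr$k, l = tr$l, rate = tr$rate)
    }))
  }
  bp <- branching_model(nu = nu, alpha = alpha, beta = beta,
                        discrete = isTRUE(spec$discrete),
                        type_names = spec$type_names)
  out <- list(bp = bp, z0 = spec$z0)
  if (!is.null(spec$ctmc)) {
    cb <- spec$ctmc
    events <- lapply(cb$events, function(ev) {
      list(delta = as.numeric(ev$delta), coef = ev$coef,
           idx = as.integer(ev$idx))
    })
    out$ctmc <- ctmc_model(cb$state_names, events, cb$scale,
                           as.numeric(cb$x0),
                           bp_coords = as.integer(cb$bp_coords %||%
                                                    seq_along(cb$state_names)))
  }
  if (!is.null(spec$gg_fit)) out$gg_fit <- spec$gg_fit
  out
}

#' @rdname read_model_spec
#' @param model a [branching_model()].
#' @param ctmc optional [ctmc_model()] written under the `ctmc` block.
#' @param z0 optional initial condition vector.
#' @param gg_fit optional fitted generalised-gamma parameters (see
#'   [fit_gg()]) serialised under a `gg_fit` block.
#' @export
write_model_spec <- function(model, path, ctmc = NULL, z0 = NULL,
                             gg_fit = NULL) {
  stopifnot(inherits(model, "branching_model"))
  m <- model$m
  alpha_tr <- list()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (model$alpha[i, j] != 0) {
      alpha_tr[[length(alpha_tr) + 1]] <- list(i = i, j = j,
                                               rate = model$alpha[i, j])
    }
  }
  beta_tr <- list()
  for (i in seq_len(m)) for (k in seq_len(m)) for (l in k:m) {
    if (model$beta[i, k, l] != 0) {
      beta_tr[[length(beta_tr) + 1]] <- list(i = i, k = k, l = l,
                                             rate = model$beta[i, k, l])
    }
  }
  spec <- list(m = m, nu = model$nu, alpha = alpha_tr, beta = beta_tr,
               discrete = model$discrete, type_names = model$type_names)
  if (!is.null(z0)) spec$z0 <- z0
  if (!is.null(ctmc)) {
    spec$ctmc <- list(
      state_names = ctmc$state_names,
      events = lapply(ctmc$events, function(ev) {
        list(delta = ev$delta, coef = ev$coef, idx = ev$idx)
      }),
      scale = ctmc$scale, x0 = ctmc$x0, bp_coords = ctmc$bp_coords)
  }
  if (!is.null(gg_fit)) {
    spec$gg_fit <- list(gg_scale = gg_fit$gg_scale,
                        gg_shape1 = gg_fit$gg_shape1,
                        gg_shape2 = gg_fit$gg_shape2)
  }
  yaml::write_yaml(spec, path, precision = 17L)
  invisible(path)
}
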