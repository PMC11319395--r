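#' Plot the CDF of W
#'
#' @param object a [w_distribution()].
#' @param w_max upper plotting limit (default five conditional means).
#' @param n_grid grid resolution.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.w_distribution <- function(object, w_max = NULL, n_grid = 200, ...) {
  w_max <- w_max %||% (5 * object$mu_W / (1 - object$q_star))
  w <- seq(0, w_max, length.out = n_grid)
  df <- tibble::tibble(w = w, cdf = cdf_w(object, w))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$cdf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[1, ], size = 2) +
    ggplot2::labs(x = "w", y = expression(G[W](w)),
                  title = "CDF of the martingale limit W",
                  subtitle = sprintf("atom q* = %.4f at w = 0", object$q_star))
}

#' Plot a time-shift density
#'
#' @param object a [timeshift_distribution()].
#' @param tau_range plotting range (default chosen from the quantiles).
#' @param n_grid grid resolution.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.timeshift_distribution <- function(object, tau_range = NULL,
                                            n_grid = 200, ...) {
  if (is.null(tau_range)) {
    s <- sort(sample_tau(object, 2000, rng_seed = 1))
    tau_range <- c(s[20], s[1980]) + c(-1, 1)
  }
  tau <- seq(tau_range[1], tau_range[2], length.out = n_grid)
  df <- tibble::tibble(tau = tau, density = tau_pdf(object, tau))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tau), y = "density",
                  title = sprintf("Time-shift density (%s method)",
                                  toupper(object$method)))
}

#' Plot a deterministic or shifted trajectory
#'
#' @param object a `trajectory`.
#' @param coords coordinates to draw (default all).
#' @param counts plot counts instead of densities.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trajectory <- function(object, coords = NULL, counts = FALSE, ...) {
  coords <- coords %||% seq_along(object$state_names)
  st <- if (counts) object$state * object$scale else object$state
  df <- do.call(rbind, lapply(coords, function(j) {
    tibble::tibble(time = object$time, value = st[, j],
                   coordinate = object$state_names[j])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$coordinate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = if (counts) "count" else "density")
}
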