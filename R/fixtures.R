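#' SIR epidemic fixture
#'
#' The Markovian SIR epidemic in a closed population of size `N`, together
#' with its early-time branching-process approximation: a single-type linear
#' birth-death process in which an infectious individual recovers at rate
#' `gamma` and transmits (splits into two infectives) at rate `beta`. This is
#' the one model family where the law of W is known in closed form (see
#' [sir_analytic_cdf()]), making it the package's analytic reference.
#'
#' @param beta transmission rate (per infective, per unit time).
#' @param gamma recovery rate.
#' @param N population size for the CTMC.
#' @param I0 initial number of infectives.
#' @return list with `bp` (the [branching_model()]), `ctmc`
#'   (the [ctmc_model()] with states S, I), `z0` (branching-process initial
#'   condition) and the parameters.
#' @export
fixture_sir <- function(beta = 0.95, gamma = 0.5, N = 1e6, I0 = 1) {
  bp <- branching_model(nu = gamma,
                        beta = data.frame(i = 1, k = 1, l = 1, rate = beta),
                        type_names = "I")
  ctmc <- ctmc_model(
    state_names = c("S", "I"),
    events = list(
      list(delta = c(-1, 1), coef = beta, idx = c(1L, 2L)),  # infection b S I / N
      list(delta = c(0, -1), coef = gamma, idx = 2L)         # recovery g I
    ),
    scale = N, x0 = c(N - I0, I0), bp_coords = 2L)
  list(bp = bp, ctmc = ctmc, z0 = I0, params = c(beta = beta, gamma = gamma),
       infected_coord = 2L)
}

#' SEIR epidemic fixture
#'
#' SEIR epidemic CTMC and its two-type branching-process approximation with
#' types (E, I): an exposed individual activates (`E -> I`) at rate `sigma`;
#' an infectious individual recovers at rate `gamma` or transmits at rate
#' `beta`, producing one new E while remaining infectious (quadratic term
#' `s1 s2` for type 2).
#'
#' @param beta transmission rate.
#' @param sigma activation (incubation) rate.
#' @param gamma recovery rate.
#' @param N population size.
#' @param E0,I0 initial exposed/infectious counts.
#' @return list as in [fixture_sir()]; `z0 = c(E0, I0)`.
#' @export
fixture_seir <- function(beta = 0.56, sigma = 0.5, gamma = 0.33, N = 1e6,
                         E0 = 1, I0 = 0) {
  bp <- branching_model(
    nu = c(0, gamma),
    alpha = matrix(c(0, sigma, 0, 0), 2, 2, byrow = TRUE),
    beta = data.frame(i = 2, k = 1, l = 2, rate = beta),
    type_names = c("E", "I"))
  ctmc <- ctmc_model(
    state_names = c("S", "E", "I"),
    events = list(
      list(delta = c(-1, 1, 0), coef = beta, idx = c(1L, 3L)),  # infection
      list(delta = c(0, -1, 1), coef = sigma, idx = 2L),        # activation
      list(delta = c(0, 0, -1), coef = gamma, idx = 3L)         # recovery
    ),
    scale = N, x0 = c(N - E0 - I0, E0, I0), bp_coords = c(2L, 3L))
  list(bp = bp, ctmc = ctmc, z0 = c(E0, I0),
       params = c(beta = beta, sigma = sigma, gamma = gamma),
       infected_coord = 3L)
}

#' Within-host innate-response fixture
#'
#' Six-state within-host viral dynamics CTMC (target cells U, refractory
#' cells R, eclipse-phase cells E, infectious cells I, virions V, interferons
#' A) with two infection routes (cell-free at rate `beta1`, cell-to-cell at
#' rate `beta2`) and an innate interferon response, plus its three-type
#' branching-process approximation on (E, I, V). With `bb_i = beta_i U0 / K`
#' the branching process has lifetime rates
#' `a = (sigma + eta, gamma + p_V + bb2, bb1 + c_V)` and progeny generating
#' functions `f1 = (eta + sigma s2)/a1`,
#' `f2 = (gamma + p_V s2 s3 + bb2 s2 s1)/a2`, `f3 = (c_V + bb1 s1)/a3`.
#'
#' @param beta1,beta2 infection rates (virus-to-cell, cell-to-cell).
#' @param sigma eclipse progression rate; `eta` eclipse death rate.
#' @param eta death rate of eclipse-phase cells.
#' @param gamma removal rate of infectious cells.
#' @param p_V,c_V virion production/clearance rates.
#' @param p_A,c_A interferon production/clearance rates.
#' @param rho_R rate of target cells becoming refractory; `delta` return rate.
#' @param delta rate of refractory cells returning to target.
#' @param U0 initial number of target cells.
#' @param K carrying capacity (defaults to `U0`).
#' @param E0 initial eclipse-phase cells.
#' @return list as in [fixture_sir()]; `z0 = c(E0, 0, 0)` on types (E, I, V).
#' @export
fixture_innate <- function(beta1 = 2.0, beta2 = 1.6, sigma = 4.0, eta = 1.0,
                           gamma = 1.7, p_V = 45.3, c_V = 10.0,
                           p_A = 6.0, c_A = 3.0, rho_R = 104.0,
                           delta = 4.4e-3, U0 = 8e7, K = U0, E0 = 1) {
  bb1 <- beta1 * U0 / K
  bb2 <- beta2 * U0 / K
  bp <- branching_model(
    nu = c(eta, gamma, c_V),
    alpha = matrix(c(0, sigma, 0,
                     0, 0, 0,
                     bb1, 0, 0), 3, 3, byrow = TRUE),
    beta = data.frame(i = c(2, 2), k = c(2, 1), l = c(3, 2),
                      rate = c(p_V, bb2)),
    type_names = c("E", "I", "V"))
  # CTMC states: (U, R, E, I, V, A)
  ctmc <- ctmc_model(
    state_names = c("U", "R", "E", "I", "V", "A"),
    events = list(
      list(delta = c(-1, 0, 1, 0, -1, 0), coef = beta1, idx = c(1L, 5L)),  # cell-free infection
      list(delta = c(-1, 0, 1, 0, 0, 0), coef = beta2, idx = c(1L, 4L)),   # cell-to-cell infection
      list(delta = c(-1, 1, 0, 0, 0, 0), coef = rho_R, idx = c(1L, 6L)),   # U -> R via interferon
      list(delta = c(1, -1, 0, 0, 0, 0), coef = delta, idx = 2L),          # R -> U
      list(delta = c(0, 0, -1, 1, 0, 0), coef = sigma, idx = 3L),          # eclipse -> infectious
      list(delta = c(0, 0, -1, 0, 0, 0), coef = eta, idx = 3L),            # eclipse death
      list(delta = c(0, 0, 0, -1, 0, 0), coef = gamma, idx = 4L),          # removal
      list(delta = c(0, 0, 0, 0, 1, 0), coef = p_V, idx = 4L),             # virion production
      list(delta = c(0, 0, 0, 0, -1, 0), coef = c_V, idx = 5L),            # virion clearance
      list(delta = c(0, 0, 0, 0, 0, 1), coef = p_A, idx = 4L),             # interferon production
      list(delta = c(0, 0, 0, 0, 0, -1), coef = c_A, idx = 6L)             # interferon clearance
    ),
    scale = K, x0 = c(U0 - E0, 0, E0, 0, 0, 0), bp_coords = c(3L, 4L, 5L))
  list(bp = bp, ctmc = ctmc, z0 = c(E0, 0, 0),
       params = c(beta1 = beta1, beta2 = beta2, sigma = sigma, eta = eta,
                  gamma = gamma, p_V = p_V, c_V = c_V, p_A = p_A, c_A = c_A,
                  rho_R = rho_R, delta = delta, U0 = U0, K = K),
       infected_coord = 5L)
}
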