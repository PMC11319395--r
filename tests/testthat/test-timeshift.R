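test_that("w_to_tau is the exact log transform", {
  expect_equal(w_to_tau(2, 0.45, 2), 0)
  expect_equal(w_to_tau(exp(0.45) * 2, 0.45, 2), 1)
  w <- c(0.1, 1, 7)
  expect_equal(2 * exp(0.45 * w_to_tau(w, 0.45, 2)), w, tolerance = 1e-12)
  expect_error(w_to_tau(0, 0.45, 2))
})

test_that("pushing exponential W samples through the transform matches the
           closed-form time-shift density", {
  q <- 0.5 / 0.95
  lam <- 0.45; mu <- 1
  set.seed(21)
  w <- stats::rexp(1e5, rate = 1 - q)
  tau <- w_to_tau(w, lam, mu)
  # Gumbel-type closed form from composing the exponential law with the map
  Ftau <- function(x) 1 - exp(-(1 - q) * mu * exp(lam * x))
  expect_lt(ks_dist(tau, Ftau), 0.01)
  # identical to the MM density with exponential parameters
  p_exp <- list(gg_scale = 1 / (1 - q), gg_shape1 = 1, gg_shape2 = 1)
  x <- seq(-10, 4, by = 0.1)
  g_closed <- (1 - q) * mu * lam * exp(lam * x) * exp(-(1 - q) * mu * exp(lam * x))
  expect_equal(timeshift_pdf_mm(p_exp, lam, mu, x), g_closed,
               tolerance = 1e-12)
})

test_that("PE and MM time-shift distributions agree on the fixtures", {
  an_sir <- compute_w(sir_fix$bp, 1)
  x <- seq(-10, 8, by = 0.25)
  pe <- tau_pdf(an_sir$tau_pe, x)
  mm <- tau_pdf(an_sir$tau_mm, x)
  expect_lt(max(abs(pe - mm)), 0.02)
  # SIR analytic density against the PE route (inversion-bias tolerance)
  q <- 0.5 / 0.95
  g_exact <- (1 - q) * exp(0.45 * x) * exp(-(1 - q) * exp(0.45 * x)) * 0.45
  expect_lt(max(abs(pe - g_exact)), 5e-3)
  expect_lt(max(abs(mm - g_exact)), 1e-6)
  # normalisation by trapezoid
  expect_equal(sum((pe[-1] + pe[-length(pe)]) / 2 * diff(x)), 1,
               tolerance = 1e-2)
})

test_that("time-shift sampling is seeded and quantile-consistent", {
  an <- compute_w(sir_fix$bp, 1)
  s1 <- sample_tau(an$tau_mm, 500, rng_seed = 31)
  expect_identical(s1, sample_tau(an$tau_mm, 500, rng_seed = 31))
  # monotone transform preserves quantiles
  w <- sample_gg(an$ggfit, 2000, rng_seed = 32)
  tau <- sample_tau(an$tau_mm, 2000, rng_seed = 32)
  expect_equal(sort(tau), w_to_tau(sort(w), an$eig$lam, an$mu_W),
               tolerance = 1e-12)
  # sample mean matches the density integral within Monte Carlo error
  s <- sample_tau(an$tau_mm, 2e4, rng_seed = 33)
  mean_int <- stats::integrate(function(x) x * tau_pdf(an$tau_mm, x),
                               -Inf, Inf)$value
  expect_lt(abs(mean(s) - mean_int), 3 * stats::sd(s) / sqrt(length(s)))
})

test_that("deterministic solutions obey the fluid-limit structure", {
  # SIR early growth from a small seed is exponential at rate beta - gamma
  sirN <- fixture_sir(N = 1e6)
  det <- deterministic_solution(sirN$ctmc, c(0, 30))
  i0 <- 1e-6
  i1 <- traj_eval(det, 1, coord = 2)
  expect_lt(abs(i1 - i0 * exp(0.45)) / (i0 * exp(0.45)), 0.01)
  # SEIR: Jacobian of the infected subsystem at (1, 0, 0) is Omega^T
  drift <- function(x) timeshiftr:::ctmc_drift(seir_fix$ctmc, x)
  x_star <- c(1, 0, 0)
  d <- 1e-7
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, (j == 1) * d, (j == 2) * d)
    J[, j] <- ((drift(x_star + e) - drift(x_star - e)) / (2 * d))[2:3]
  }
  expect_equal(J, t(build_growth_matrix(seir_fix$bp)), tolerance = 1e-6)
})

test_that("innate-response fluid limit conserves cells and matches rates", {
  det <- deterministic_solution(innate_fix$ctmc, c(0, 8), n_grid = 801)
  st <- det$state
  # U + R + E + I cells only change through eclipse death and removal
  cells <- st[, 1] + st[, 2] + st[, 3] + st[, 4]
  expect_true(all(diff(cells) <= 1e-10))
  expect_true(all(st > -1e-9))
  # virions peak then decline in the depletion phase
  expect_gt(max(st[, 5]), st[1, 5])
})

test_that("shifting a trajectory translates it exactly", {
  det <- deterministic_solution(fixture_sir(N = 1e6)$ctmc, c(-20, 60))
  sh <- shifted_trajectory(det, 0)
  tt <- c(0, 5, 20)
  expect_equal(traj_eval(sh, tt), traj_eval(det, tt), tolerance = 1e-12)
  sh2 <- shifted_trajectory(det, 3.5)
  expect_equal(traj_eval(sh2, tt - 3.5), traj_eval(det, tt),
               tolerance = 1e-10)
  back <- shifted_trajectory(sh2, -3.5)
  expect_equal(traj_eval(back, tt), traj_eval(det, tt), tolerance = 1e-10)
  # peak time translates: argmax_t i(t + tau) = t_p - tau
  tp <- peak_time(det, 2)
  expect_equal(peak_time(sh2, 2), tp - 3.5, tolerance = 1e-6)
  expect_error(traj_eval(det, -100), "domain")
})

test_that("hybrid ensembles reuse a single ODE solve", {
  ode_solve_count(reset = TRUE)
  det <- deterministic_solution(fixture_sir(N = 1e6)$ctmc, c(-20, 60))
  n0 <- ode_solve_count()
  ens <- hybrid_ensemble(det, c(-1, 0, 0.5, 2))
  expect_length(ens, 4)
  expect_identical(ode_solve_count(), n0)  # no further solves
  peaks <- vapply(ens, peak_time, numeric(1), coord = 2)
  expect_equal(peaks, peak_time(det, 2) - c(-1, 0, 0.5, 2), tolerance = 1e-5)
})
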