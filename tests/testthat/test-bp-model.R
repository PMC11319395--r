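test_that("lifetime rates match the fixture parameterisations", {
  expect_equal(lifetime_rates(sir_fix$bp), 1.45)
  expect_equal(lifetime_rates(seir_fix$bp), c(0.5, 0.89))
  expect_equal(lifetime_rates(innate_fix$bp), c(5.0, 48.6, 12.0))
})

test_that("invalid rate structures are rejected", {
  expect_error(branching_model(nu = c(0, 0.5),
                               alpha = matrix(c(0.3, 1, 1, 0), 2, 2)),
               "diagonal")
  # a type that never dies makes the lifetime distribution ill-defined
  expect_error(branching_model(nu = c(1, 0),
                               alpha = matrix(c(0, 1, 0, 0), 2, 2,
                                              byrow = TRUE)),
               "never dies")
  expect_error(branching_model(nu = 0.9, discrete = TRUE), "sum to 1")
})

test_that("quadratic rates fold onto the canonical l >= k ordering", {
  m1 <- branching_model(nu = c(0, 0.5),
                        beta = data.frame(i = c(2, 2), k = c(2, 1),
                                          l = c(1, 2), rate = c(0.3, 0.2)),
                        alpha = matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(m1$beta[2, 1, 2], 0.5)
  expect_equal(m1$beta[2, 2, 1], 0)
})

test_that("progeny generating functions normalise and evaluate correctly", {
  for (fx in list(sir_fix, seir_fix, innate_fix)) {
    ones <- rep(1 + 0i, fx$bp$m)
    expect_equal(pgf_eval(fx$bp, ones), ones, tolerance = 1e-12)
  }
  # SEIR f1 is linear pass-through to type 2 (sigma / a1 = 1)
  expect_equal(Re(pgf_eval(seir_fix$bp, c(0.3, 0.4), i = 1)), 0.4)
  # SIR f(0) = gamma / (beta + gamma)
  expect_equal(Re(pgf_eval(sir_fix$bp, 0, i = 1)), 0.5 / 1.45,
               tolerance = 1e-12)
  expect_error(pgf_eval(sir_fix$bp, 1, i = 2), "out of range")
})

test_that("growth matrices take the printed forms", {
  expect_equal(build_growth_matrix(sir_fix$bp), matrix(0.45), tolerance = 1e-12)
  expect_equal(build_growth_matrix(seir_fix$bp),
               matrix(c(-0.5, 0.5, 0.56, -0.33), 2, 2, byrow = TRUE))
  pure_death <- suppressWarnings(branching_model(nu = 1))
  expect_equal(build_growth_matrix(pure_death), matrix(-1))
})

test_that("eigen quantities use the u.1 = 1, u.v = 1 normalisation", {
  e1 <- eigen_quantities(sir_fix$bp)
  expect_equal(e1$lam, 0.45)
  expect_equal(e1$u, 1)
  expect_equal(e1$v, 1)

  e2 <- eigen_quantities(seir_fix$bp)
  lam_closed <- (-(0.5 + 0.33) + sqrt((0.5 - 0.33)^2 + 4 * 0.5 * 0.56)) / 2
  expect_equal(e2$lam, lam_closed, tolerance = 1e-12)
  expect_equal(sum(e2$u), 1)
  expect_equal(sum(e2$u * e2$v), 1)
  expect_true(all(e2$u > 0) && all(e2$v > 0))
  Om <- build_growth_matrix(seir_fix$bp)
  expect_equal(as.numeric(Om %*% e2$u), e2$lam * e2$u, tolerance = 1e-10)
  expect_equal(as.numeric(e2$v %*% Om), e2$lam * e2$v, tolerance = 1e-10)
})

test_that("subcritical models are refused before any W computation", {
  sub <- fixture_sir(beta = 0.4, gamma = 0.5)$bp
  expect_error(eigen_quantities(sub), class = "subcritical_error")
  dt_sub <- branching_model(nu = 0.6,
                            beta = data.frame(i = 1, k = 1, l = 1, rate = 0.4),
                            discrete = TRUE)
  expect_error(eigen_quantities(dt_sub), class = "subcritical_error")
})

test_that("reducible mean structure warns", {
  expect_warning(
    branching_model(nu = c(0.2, 0.5),
                    alpha = matrix(c(0, 0.4, 0, 0), 2, 2, byrow = TRUE),
                    beta = data.frame(i = 2, k = 2, l = 2, rate = 0.4)),
    "reducible")
})

test_that("extinction probabilities solve the minimal fixed point", {
  ext <- extinction_probs(sir_fix$bp)
  expect_equal(ext$q, 0.5 / 0.95, tolerance = 1e-12)
  # fixed-point residual
  expect_lt(abs(Re(pgf_eval(sir_fix$bp, ext$q, i = 1)) - ext$q), 1e-12)
  # starting at 1 finds the non-minimal root, distinguishing minimality
  at_one <- extinction_probs(sir_fix$bp, start = rep(1, 1))
  expect_equal(at_one$q, 1)
  ext2 <- extinction_probs(seir_fix$bp)
  resid <- Re(pgf_eval(seir_fix$bp, ext2$q)) - ext2$q
  expect_lt(max(abs(resid)), 1e-12)
  expect_true(all(ext2$q >= 0 & ext2$q < 1))
  # product form over founders
  expect_equal(ext2$q_star(c(1, 0)), ext2$q[1])
  expect_equal(ext2$q_star(c(2, 3)), ext2$q[1]^2 * ext2$q[2]^3)
  expect_error(ext2$q_star(c(0, 0)), "at least one")
})

test_that("embedded discrete chain has Perron root exp(lam h)", {
  for (fx in list(sir_fix, seir_fix, innate_fix)) {
    eig <- eigen_quantities(fx$bp)
    h <- 0.25
    M <- expm_eigen(build_growth_matrix(fx$bp), h)
    rho <- max(Re(eigen(M)$values))
    expect_equal(rho, exp(eig$lam * h), tolerance = 1e-10)
  }
})

test_that("model specification files round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(seir_fix$bp, path, ctmc = seir_fix$ctmc, z0 = seir_fix$z0)
  back <- read_model_spec(path)
  expect_equal(back$bp$nu, seir_fix$bp$nu)
  expect_equal(back$bp$alpha, seir_fix$bp$alpha)
  expect_equal(back$bp$beta, seir_fix$bp$beta)
  expect_equal(back$z0, seir_fix$z0)
  expect_equal(back$ctmc$x0, seir_fix$ctmc$x0)
  expect_equal(length(back$ctmc$events), length(seir_fix$ctmc$events))
  expect_equal(back$ctmc$scale, seir_fix$ctmc$scale)
})
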