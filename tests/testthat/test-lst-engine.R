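ev_sir <- lst_evaluator(sir_fix$bp)
ev_seir <- lst_evaluator(seir_fix$bp)

test_that("truncated Taylor series behaves like an LST near zero", {
  tab <- ev_sir$table
  expect_equal(taylor_lst(tab, 1, 0 + 0i), 1 + 0i)
  # slope at zero is -E[W_i]
  d <- 1e-7
  slope <- Re(taylor_lst(tab, 1, d) - taylor_lst(tab, 1, -d)) / (2 * d)
  expect_equal(slope, -ev_sir$eig$u[1], tolerance = 1e-6)
  # within the disc the truncation meets the printed closed form
  expect_lt(abs(taylor_lst(tab, 1, 0.05 + 0i, n = 30) -
                  sir_analytic_lst(0.95, 0.5, 0.05)), 1e-6)
})

test_that("error radius inverts the Lagrange remainder bound", {
  tab <- ev_sir$table
  n <- 30
  for (eps in c(1e-6, 1e-8)) {
    L <- error_radius(tab, n, eps)
    # defining identity: L^{n+1} gamma / (n+1)! = eps
    expect_equal(exp((n + 1) * log(L) + log(max(tab$xi[n + 1, ])) -
                       lgamma(n + 2)), eps, tolerance = 1e-10)
  }
  expect_gt(error_radius(tab, 30, 1e-5), error_radius(tab, 30, 1e-6))
})

test_that("embedded pgf solves the backward equations", {
  # fixed point at 1
  expect_equal(embedded_pgf(seir_fix$bp, c(1 + 0i, 1 + 0i), 0.1),
               c(1 + 0i, 1 + 0i), tolerance = 1e-10)
  # small-h slope: F(s, h) = s + h a (f(s) - s) + O(h^2)
  s <- c(0.3 + 0.1i, 0.7 - 0.2i)
  h <- 1e-4
  a <- lifetime_rates(seir_fix$bp)
  lin <- s + h * a * (pgf_eval(seir_fix$bp, s) - s)
  expect_lt(max(abs(embedded_pgf(seir_fix$bp, s, h) - lin)), 1e-6)
  # closed-form linear birth-death transient pgf
  for (s1 in c(0.2 + 0i, 0.8 + 0.3i, -0.5 + 1i)) {
    expect_lt(abs(embedded_pgf(sir_fix$bp, s1, 0.1) -
                    bd_transient_pgf(s1, 0.1, 0.95, 0.5)), 1e-8)
  }
})

test_that("lst_eval matches the SIR closed form on a complex grid", {
  expect_equal(lst_eval(ev_sir, 0 + 0i), 1 + 0i)
  expect_identical(ev_sir$counter$compositions, 0L)
  thetas <- c(0.05, 1, 10, 50, 100, 2 + 3i, 30i, 70 + 70i, 0.3 - 0.2i)
  for (th in thetas) {
    err <- abs(lst_eval(ev_sir, th) - sir_analytic_lst(0.95, 0.5, th))
    expect_lt(err, 1e-5)  # 10 * eps
  }
})

test_that("composition count equals the ceiling rule", {
  th <- 50 + 0i
  lam <- ev_sir$eig$lam
  h <- ev_sir$config$h
  kappa <- ceiling(log(abs(th) / ev_sir$L) / (lam * h))
  lst_eval(ev_sir, th)
  expect_identical(ev_sir$counter$compositions, as.integer(kappa))
})

test_that("LST satisfies analytic structure constraints", {
  set.seed(3)
  thetas <- complex(real = runif(12, 0, 40), imaginary = runif(12, -40, 40))
  phis <- lst_eval_batch(ev_seir, thetas)
  # |phi| <= 1 on Re theta >= 0
  expect_true(all(abs(phis) <= 1 + 1e-10))
  # conjugate symmetry
  phis_conj <- lst_eval_batch(ev_seir, Conj(thetas))
  expect_equal(phis_conj, Conj(phis), tolerance = 1e-9)
  # theta -> +Inf picks up the extinction probabilities
  q <- extinction_probs(seir_fix$bp)$q
  expect_lt(max(abs(lst_eval(ev_seir, 1e6 + 0i) - q)), 1e-4)
  # -phi'(0+) recovers the mean for a composite initial condition
  d <- 1e-6
  z0 <- c(2, 1)
  slope <- Re(lst_for_initial(lst_eval(ev_seir, d + 0i), z0) -
                lst_for_initial(lst_eval(ev_seir, -d + 0i), z0)) / (2 * d)
  expect_equal(-slope, sum(z0 * ev_seir$eig$u), tolerance = 1e-5)
})

test_that("functional equation residual is small across the disc boundary", {
  # theta inside the disc with theta e^{-lam h} also inside: both sides are
  # independent Taylor evaluations, so this genuinely probes consistency.
  th <- 0.9 * ev_seir$L + 0i
  lhs <- lst_eval(ev_seir, th)
  inner <- lst_eval(ev_seir, th * exp(-ev_seir$eig$lam * 0.1))
  rhs <- embedded_pgf(seir_fix$bp, inner, 0.1)
  expect_lt(max(abs(lhs - rhs)), 1e-5)
  # and at the stated exterior test points
  for (th in c(1 + 0i, 10i, 20 + 20i, 50 + 0i)) {
    lhs <- lst_eval(ev_seir, th)
    rhs <- embedded_pgf(seir_fix$bp,
                        lst_eval(ev_seir, th * exp(-ev_seir$eig$lam * 0.1)),
                        0.1)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("discrete-time LST satisfies its functional equation", {
  dt <- branching_model(nu = 0.3,
                        beta = data.frame(i = 1, k = 1, l = 1, rate = 0.7),
                        discrete = TRUE)
  ev <- lst_evaluator(dt)
  expect_equal(lst_discrete(ev, 0 + 0i), 1 + 0i)
  rho <- ev$eig$rho
  # interior point: two independent Taylor evaluations, residual at the
  # truncation-tolerance scale
  th0 <- 0.9 * ev$L + 0i
  expect_lt(abs(lst_discrete(ev, th0) -
                  pgf_eval(dt, matrix(lst_discrete(ev, th0 / rho), 1, 1))),
            1e-5)
  for (th in c(2 + 1i, 10 + 0i, 5i)) {
    lhs <- lst_discrete(ev, th)
    rhs <- pgf_eval(dt, matrix(lst_discrete(ev, th / rho), 1, 1))
    expect_lt(abs(lhs - rhs), 1e-8)
  }
  # extinction atom in the far-field limit
  expect_lt(abs(lst_discrete(ev, 1e6 + 0i) - 3 / 7), 1e-4)
})

test_that("initial-condition LST is the product over founders", {
  phis <- c(0.3 + 0.1i, 0.5 - 0.2i)
  expect_equal(lst_for_initial(phis, c(1, 0)), phis[1])
  expect_equal(lst_for_initial(phis, c(2, 0)), phis[1]^2)
  expect_equal(lst_for_initial(phis, c(2, 3)), phis[1]^2 * phis[2]^3)
  # large composite initial condition stays a valid LST on Re theta >= 0
  thetas <- complex(real = runif(8, 0, 20), imaginary = runif(8, -20, 20))
  vals <- lst_for_initial(lst_eval_batch(ev_seir, thetas), c(15, 10))
  expect_true(all(abs(vals) <= 1 + 1e-10))
})
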