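test_that("generalised gamma specialises to the exponential and gamma", {
  p_exp <- list(gg_scale = 2, gg_shape1 = 1, gg_shape2 = 1)
  k <- 1:5
  expect_equal(gg_moment(p_exp, k), 2^k * factorial(k), tolerance = 1e-12)
  w <- c(0.5, 1, 3)
  expect_equal(gg_pdf(p_exp, w), stats::dexp(w, rate = 1 / 2),
               tolerance = 1e-12)
  p_g <- list(gg_scale = 1, gg_shape1 = 3, gg_shape2 = 1)
  expect_equal(gg_moment(p_g, 1), 3, tolerance = 1e-12)   # Gamma(4)/Gamma(3)
  total <- stats::integrate(function(x)
    gg_pdf(list(gg_scale = 2, gg_shape1 = 1.5, gg_shape2 = 0.8), x),
    0, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  expect_error(gg_pdf(list(gg_scale = -1, gg_shape1 = 1, gg_shape2 = 1), 1))
})

test_that("moment standardisation produces mantissas in [1, 10)", {
  expect_equal(standardize_moments(1), list(c = 1, eta = 0L))
  expect_equal(standardize_moments(4.2222)$c, 4.2222)
  s <- standardize_moments(8913.58)
  expect_equal(s$c, 8.91358)
  expect_equal(s$eta, 3L)
  m <- c(0.03, 2, 8913.58)
  s <- standardize_moments(m)
  expect_true(all(s$c >= 1 & s$c < 10))
  expect_equal(s$c * 10^s$eta, m)
  expect_error(standardize_moments(c(1, -2)))
})

test_that("moment matching recovers the exponential special case", {
  q <- 0.5 / 0.95
  mom <- factorial(1:5) / (1 - q)^(1:5)
  fit <- fit_gg(mom)
  expect_lt(abs(fit$gg_shape1 - 1), 1e-3)
  expect_lt(abs(fit$gg_shape2 - 1), 1e-3)
  expect_lt(abs(fit$gg_scale - 1 / (1 - q)), 1e-3)
  expect_lt(fit$loss, 1e-10)
  expect_true(fit$converged)
})

test_that("moment matching round-trips a generic generalised gamma", {
  truth <- list(gg_scale = 2.0, gg_shape1 = 1.5, gg_shape2 = 0.8)
  fit <- fit_gg(gg_moment(truth, 1:5))
  expect_lt(abs(fit$gg_scale - 2.0), 1e-4)
  expect_lt(abs(fit$gg_shape1 - 1.5), 1e-4)
  expect_lt(abs(fit$gg_shape2 - 0.8), 1e-4)
  # fitted moments reproduce the targets
  expect_lt(max(abs(fit$moments - fit$target_moments) / fit$target_moments),
            1e-6)
})

test_that("fitted moments reproduce the SEIR targets", {
  an <- compute_w(seir_fix$bp, seir_fix$z0, run_config(method = "mm"))
  fit <- an$ggfit
  expect_lt(max(abs(fit$moments - an$wstar_moments) / an$wstar_moments), 1e-3)
  expect_lt(fit$loss, 1e-6)
})

test_that("moment matching is scale-equivariant", {
  truth <- list(gg_scale = 1.3, gg_shape1 = 2.1, gg_shape2 = 1.1)
  mom <- gg_moment(truth, 1:5)
  s <- 3.7
  f1 <- fit_gg(mom)
  f2 <- fit_gg(mom * s^(1:5))
  expect_equal(f2$gg_scale, s * f1$gg_scale, tolerance = 1e-3)
  expect_equal(f2$gg_shape1, f1$gg_shape1, tolerance = 1e-3)
  expect_equal(f2$gg_shape2, f1$gg_shape2, tolerance = 1e-3)
})

test_that("generalised gamma sampling matches its own moments", {
  p <- list(gg_scale = 2, gg_shape1 = 1, gg_shape2 = 1)
  s1 <- sample_gg(p, 1000, rng_seed = 5)
  expect_identical(s1, sample_gg(p, 1000, rng_seed = 5))
  n <- 1e5
  s <- sample_gg(p, n, rng_seed = 6)
  expect_lt(abs(mean(s) - 2), 3 * stats::sd(s) / sqrt(n))
  p2 <- list(gg_scale = 1.5, gg_shape1 = 2, gg_shape2 = 0.9)
  s2 <- sample_gg(p2, n, rng_seed = 7)
  for (k in 1:3) {
    se <- stats::sd(s2^k) / sqrt(n)
    expect_lt(abs(mean(s2^k) - gg_moment(p2, k)), 3.5 * se)
  }
})

test_that("MM time-shift density is the exact pushforward of the GG law", {
  p <- list(gg_scale = 2.1, gg_shape1 = 1.4, gg_shape2 = 0.9)
  lam <- 0.45; mu <- 1
  tau <- seq(-8, 4, by = 0.25)
  w <- mu * exp(lam * tau)
  expect_equal(timeshift_pdf_mm(p, lam, mu, tau),
               gg_pdf(p, w) * mu * lam * exp(lam * tau), tolerance = 1e-12)
  # doubling mu_W translates the density left by log(2)/lam exactly
  shift <- log(2) / lam
  expect_equal(timeshift_pdf_mm(p, lam, 2 * mu, tau),
               timeshift_pdf_mm(p, lam, mu, tau + shift), tolerance = 1e-12)
  total <- stats::integrate(function(x) timeshift_pdf_mm(p, lam, mu, x),
                            -Inf, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("tidy and glance summarise a fit", {
  fit <- fit_gg(factorial(1:5))
  td <- tidy(fit)
  expect_equal(td$term, c("gg_scale", "gg_shape1", "gg_shape2"))
  expect_true(all(td$estimate > 0))
  gl <- glance(fit)
  expect_true(gl$converged)
})

test_that("fitted parameters serialise into the model-spec format", {
  fit <- fit_gg(factorial(1:5))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(sir_fix$bp, path, gg_fit = fit)
  back <- read_model_spec(path)
  expect_equal(back$gg_fit$gg_scale, fit$gg_scale, tolerance = 1e-12)
})
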