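test_that("intercept-only fit returns the sample mean", {
  d <- fixture_data(n = 30)
  f <- gamma_glm(mass_kg ~ 1, d)
  expect_equal(unname(exp(coef(f)[1])), mean(d$mass_kg), tolerance = 1e-9)
})

test_that("categorical fit returns the group sample means", {
  d <- fixture_data(n = 40)
  d$g <- factor(rep(c("early", "late"), each = 20))
  f <- gamma_glm(mass_kg ~ g, d)
  fitted_means <- tapply(fitted(f), d$g, unique)
  expect_equal(unname(fitted_means),
               unname(tapply(d$mass_kg, d$g, mean)), tolerance = 1e-9)
})

test_that("IRLS agrees with brute-force likelihood maximization", {
  for (seed in c(42, 7)) {
    d <- fixture_data(n = 10, seed = seed)
    f <- gamma_glm(mass_kg ~ timing_day, d)
    X <- cbind(1, d$timing_day)
    bf <- brute_force_gamma_fit(d$mass_kg, X)
    expect_equal(unname(coef(f)), unname(bf$coefficients), tolerance = 1e-6)
    expect_equal(f$loglik, bf$loglik, tolerance = 1e-8)
  }
})

test_that("IRLS agrees with stats::glm on the same likelihood", {
  d <- fixture_data(n = 60, seed = 11)
  f <- gamma_glm(mass_kg ~ timing_day, d)
  g <- glm(mass_kg ~ timing_day, data = d, family = Gamma(link = "log"),
           control = glm.control(epsilon = 1e-12))
  expect_equal(coef(f), coef(g), tolerance = 1e-7)
  expect_equal(f$deviance, deviance(g), tolerance = 1e-8)
})

test_that("gamma_loglik matches its closed forms", {
  y <- c(1.5, 2, 3.2); mu <- c(1, 2.5, 3)
  expect_equal(gamma_loglik(y, mu, 1), sum(-log(mu) - y / mu))
  expect_equal(gamma_loglik(2, 2, 2), log(2) - 2)
  expect_error(gamma_loglik(y, mu[1:2], 1), "equal length")
  expect_error(gamma_loglik(-y, mu, 1), "positive")
  # y == mu: likelihood increases monotonically in the shape
  ll <- vapply(c(1, 10, 100, 1000), function(s)
    gamma_loglik(mu, mu, s), 1)
  expect_true(all(diff(ll) > 0))
})

test_that("shape MLE recovers the truth and is scale invariant", {
  set.seed(1)
  mu <- exp(rnorm(4000, 3, 0.3))
  y <- rgamma(4000, shape = 120, scale = mu / 120)
  sh <- gamma_shape_mle(y, mu)
  expect_lt(abs(sh / 120 - 1), 0.05)
  expect_equal(gamma_shape_mle(2 * y, 2 * mu), sh, tolerance = 1e-6)
  expect_warning(cap <- gamma_shape_mle(mu, mu, max_shape = 1e6),
                 "upper bound")
  expect_equal(cap, 1e6)
})

test_that("AIC counts the shape and respects likelihood identities", {
  d <- fixture_data(n = 50, seed = 9)
  f0 <- gamma_glm(mass_kg ~ 1, d)
  f1 <- gamma_glm(mass_kg ~ timing_day, d)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * (f1$p + 1))
  expect_equal(f1$aic - f0$aic,
               -2 * (f1$loglik - f0$loglik) + 2 * (f1$p - f0$p))
  expect_equal(AIC(f1), f1$aic)          # stats::AIC via logLik method
  # nested model never has higher likelihood
  expect_gte(f1$loglik, f0$loglik)
  # likelihood additivity: duplicating every observation doubles it
  mu <- fitted(f1)
  expect_equal(gamma_loglik(rep(d$mass_kg, 2), rep(mu, 2), f1$shape),
               2 * gamma_loglik(d$mass_kg, mu, f1$shape))
})

test_that("degenerate designs and responses are rejected with clear errors", {
  d <- fixture_data(n = 20)
  d$dup <- d$timing_day
  expect_error(gamma_glm(mass_kg ~ timing_day + dup, d), "aliased.*dup")
  d2 <- d; d2$mass_kg[1] <- -1
  expect_error(gamma_glm(mass_kg ~ timing_day, d2), "positive")
})

test_that("large-sample slope estimate is consistent", {
  d <- simulate_dataset(sim_config(n = 20000, seed = 13))
  f <- gamma_glm(mass_kg ~ timing_day, d)
  expect_lt(abs(exp(coef(f)[2]) - 0.985), 0.001)
  expect_true(f$converged)
  # covariance is symmetric positive definite
  expect_equal(f$vcov, t(f$vcov))
  expect_true(all(eigen(f$vcov, only.values = TRUE)$values > 0))
})

test_that("prediction and simulation are coherent with the fit", {
  d <- fixture_data(n = 80, seed = 21)
  f <- gamma_glm(mass_kg ~ timing_day, d)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, type = "link"), log(fitted(f)))
  nd <- data.frame(timing_day = c(55, 65))
  expect_equal(predict(f, nd, type = "link"),
               unname(coef(f)[1] + coef(f)[2] * c(55, 65)))
  sims <- simulate(f, nsim = 3, seed = 2)
  expect_equal(dim(sims), c(80, 3))
  expect_true(all(sims > 0))
  expect_identical(sims, simulate(f, nsim = 3, seed = 2))
  r <- residuals(f, "response")
  expect_equal(r, d$mass_kg - fitted(f))
})
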