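test_that("spline bases are a partition of unity", {
  x <- seq(50, 80, length.out = 200)
  b1 <- build_basis(x, smooth_spec(n_knots = 6))
  expect_equal(rowSums(b1$B), rep(1, 200), tolerance = 1e-12)
  xc <- seq(0, 364.9, length.out = 300)
  b2 <- build_basis(xc, smooth_spec(n_knots = 6, cyclic = TRUE))
  expect_equal(rowSums(b2$B), rep(1, 300), tolerance = 1e-12)
  expect_error(build_basis(c(1, 1, 2, 2), smooth_spec()), "4 distinct")
})

test_that("cyclic basis wraps: rows at 0 and at the period coincide", {
  spec <- smooth_spec(n_knots = 6, cyclic = TRUE, period = 365)
  b0 <- build_basis(c(0, 50, 100, 200, 364.999999), spec)
  expect_equal(b0$B[1, ], b0$B[5, ], tolerance = 1e-5)
})

test_that("an unpenalized minimal basis reproduces a cubic exactly", {
  x <- seq(1, 10, length.out = 40)
  curve <- 0.02 * (x - 5)^3 / 10 + 3          # cubic on the log scale
  d <- data.frame(timing_day = x, mass_kg = exp(curve))
  suppressWarnings(
    f <- gamma_smooth(mass_kg ~ timing_day, d,
                      smooth_spec(n_knots = 0, lambda = 0)))
  expect_equal(f$linear.predictors, curve, tolerance = 1e-6)
})

test_that("huge penalty collapses the smooth onto the straight-line fit", {
  d <- simulate_dataset(sim_config(n = 120, seed = 14,
                                   nonlinear_curve = default_nonlinear_curve))
  f_lin <- gamma_glm(mass_kg ~ timing_day, d)
  f_smo <- gamma_smooth(mass_kg ~ timing_day, d,
                        smooth_spec(n_knots = 6, lambda = 1e9))
  expect_equal(f_smo$linear.predictors, f_lin$linear.predictors,
               tolerance = 1e-4)
  # coefficient second divided differences vanish against Greville sites
  xi <- f_smo$basis$greville
  beta <- f_smo$coefficients
  dd <- diff(diff(beta) / diff(xi)) / diff(xi, lag = 2)
  expect_lt(max(abs(dd)), 1e-6)
  expect_equal(f_smo$edf, 2, tolerance = 1e-3)
})

test_that("noise-free data from the default curve is interpolated", {
  set.seed(20)
  x <- sort(runif(100, 52, 75))
  d <- data.frame(timing_day = x,
                  mass_kg = exp(default_nonlinear_curve(x)))
  suppressWarnings(
    f <- gamma_smooth(mass_kg ~ timing_day, d,
                      smooth_spec(n_knots = 10, lambda = 1e-8)))
  expect_lt(max(abs(f$linear.predictors - default_nonlinear_curve(x))), 1e-3)
})

test_that("effective degrees of freedom decrease in the penalty", {
  d <- simulate_dataset(sim_config(n = 120, seed = 15,
                                   nonlinear_curve = default_nonlinear_curve))
  lams <- 10^seq(-3, 7, by = 2)
  edfs <- vapply(lams, function(l)
    gamma_smooth(mass_kg ~ timing_day, d,
                 smooth_spec(n_knots = 6, lambda = l))$edf, 1)
  expect_true(all(diff(edfs) < 0))
  expect_gt(edfs[1], 5)                      # near the basis dimension
  expect_lt(edfs[length(edfs)], 2.2)         # near the linear limit
})

test_that("gcv selection picks from the grid and stores the profile", {
  d <- simulate_dataset(sim_config(n = 120, seed = 16,
                                   nonlinear_curve = default_nonlinear_curve))
  f <- gamma_smooth(mass_kg ~ timing_day, d, smooth_spec(n_knots = 6))
  expect_equal(nrow(f$gcv), 30)
  expect_true(f$lambda %in% f$gcv$lambda)
  expect_equal(f$gcv$gcv[f$gcv$lambda == f$lambda], min(f$gcv$gcv))
  cur <- smooth_curve(f)
  expect_equal(nrow(cur), 100)
  expect_true(all(cur$lower < cur$mean & cur$mean < cur$upper))
})

test_that("cyclic fits of periodic data have no boundary discontinuity", {
  period_curve <- function(day) log(40) + 0.1 * sin(2 * pi * day / 365)
  set.seed(30)
  day <- runif(300, 0, 365)
  cfg <- sim_config(n = 300, mass_shape = 2000,
                    nonlinear_curve = period_curve)
  mu <- exp(period_curve(day))
  d <- data.frame(timing_day = day,
                  mass_kg = rgamma(300, 2000, scale = mu / 2000))
  f <- gamma_smooth(mass_kg ~ timing_day, d,
                    smooth_spec(n_knots = 7, cyclic = TRUE, lambda = 1,
                                period = 365))
  ends <- predict(f, c(0.0001, 364.9999), type = "link")
  interior <- predict(f, seq(0, 365, length.out = 200), type = "link")
  expect_lt(abs(diff(ends)), max(abs(diff(interior))))
})

test_that("the smooth beats interval categorization on nonlinear data", {
  cfg <- sim_config(n = 120, nonlinear_curve = default_nonlinear_curve)
  wins <- 0L
  reps <- 20L
  set.seed(55)
  rep_seeds <- sample.int(1e6, reps)
  for (r in seq_len(reps)) {
    cfg$seed <- rep_seeds[r]
    d <- simulate_dataset(cfg)
    f_smo <- gamma_smooth(mass_kg ~ timing_day, d, smooth_spec(n_knots = 6))
    d$timing_cat <- categorize(d$timing_day,
                               break_scheme("interval", 5))$assignment
    d$timing_cat <- droplevels(d$timing_cat)
    f_cat <- gamma_glm(mass_kg ~ timing_cat, d)
    wins <- wins + (f_smo$aic < f_cat$aic)
  }
  expect_gt(wins / reps, 0.5)
})
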