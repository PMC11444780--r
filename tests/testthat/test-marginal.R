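make_cat_fit <- function(n = 90, seed = 5, scheme = break_scheme("uneven")) {
  d <- simulate_dataset(sim_config(n = n, seed = seed))
  d$timing_cat <- categorize(d$timing_day, scheme)$assignment
  list(data = d, fit = gamma_glm(mass_kg ~ timing_cat, d))
}

test_that("marginal means back-transform the group means with log-symmetric CIs", {
  mc <- make_cat_fit()
  mm <- marginal_means(mc$fit)
  expect_equal(mm$mean, as.vector(tapply(mc$data$mass_kg, mc$data$timing_cat,
                                         mean)), tolerance = 1e-8)
  expect_true(all(mm$lower < mm$mean & mm$mean < mm$upper))
  expect_equal(mm$mean / mm$lower, mm$upper / mm$mean, tolerance = 1e-9)
})

test_that("marginal means are invariant to the factor coding", {
  mc <- make_cat_fit()
  d2 <- mc$data
  d2$timing_cat <- relevel(d2$timing_cat, "late")
  f2 <- gamma_glm(mass_kg ~ timing_cat, d2)
  mm1 <- marginal_means(mc$fit)
  mm2 <- marginal_means(f2)
  mm2 <- mm2[match(mm1$at, mm2$at), ]
  expect_equal(mm1$mean, mm2$mean, tolerance = 1e-8)
  expect_equal(mm1$lower, mm2$lower, tolerance = 1e-6)
})

test_that("continuous fits give marginal means at chosen predictor values", {
  d <- simulate_dataset(sim_config(n = 120, seed = 5))
  f <- gamma_glm(mass_kg ~ timing_day, d)
  mm <- marginal_means(f)                 # default: at the mean timing
  expect_equal(mm$at, mean(d$timing_day))
  pr <- predict(f, data.frame(timing_day = mm$at), type = "link",
                se.fit = TRUE)
  expect_equal(mm$mean, exp(pr$fit))
  expect_equal(mm$upper, exp(pr$fit + 1.96 * pr$se.fit))
  expect_error(marginal_means(make_cat_fit()$fit, at = "nonsense"),
               "unknown category")
})

test_that("pairwise comparisons enumerate all level pairs", {
  mc <- make_cat_fit()                    # 3 levels
  pw <- pairwise_comparisons(mc$fit)
  expect_equal(nrow(pw$table), 3)         # C(3,2)
  expect_true(all(pw$table$p_adj >= pw$table$p))
  expect_true(all(pw$table$p_adj <= 1))
  d <- simulate_dataset(sim_config(n = 50, seed = 2))
  expect_error(pairwise_comparisons(gamma_glm(mass_kg ~ timing_day, d)),
               "categorical")
})

test_that("pairwise p-values reflect the effect size", {
  set.seed(10)
  g <- factor(rep(c("a", "b"), each = 50))
  # identical groups (same draws replayed): adjusted p about 1
  y_same <- rep(rgamma(50, 400, scale = 20 / 400), 2)
  f_same <- gamma_glm(y ~ g, data.frame(y = y_same, g = g))
  expect_gt(pairwise_comparisons(f_same)$table$p_adj, 0.99)
  # 10 vs 40 with tiny variance: overwhelming significance
  y_far <- c(rgamma(50, 10000, scale = 10 / 10000),
             rgamma(50, 10000, scale = 40 / 10000))
  f_far <- gamma_glm(y ~ g, data.frame(y = y_far, g = g))
  expect_lt(pairwise_comparisons(f_far)$table$p_adj, 1e-6)
})

test_that("bonferroni letters are never less conservative than unadjusted", {
  shares <- function(letters) {
    s <- strsplit(unname(letters), "")
    k <- length(s)
    out <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
      length(intersect(s[[i]], s[[j]])) > 0))
    out[upper.tri(out)]
  }
  for (seed in 1:5) {
    mc <- make_cat_fit(n = 45, seed = seed,
                       scheme = break_scheme("quartiles"))
    b <- pairwise_comparisons(mc$fit, adjust = "bonferroni")$letters
    u <- pairwise_comparisons(mc$fit, adjust = "none")$letters
    # every pair sharing under 'none' also shares under bonferroni
    expect_true(all(shares(b) | !shares(u)))
  }
})

test_that("compact letter displays satisfy their defining property", {
  p_all_sig <- matrix(0.001, 3, 3); diag(p_all_sig) <- 1
  expect_equal(unname(cld_letters(c("A", "B", "C"), p_all_sig)),
               c("a", "b", "c"))
  p_none <- matrix(0.9, 3, 3)
  expect_equal(unname(cld_letters(c("A", "B", "C"), p_none)),
               rep("a", 3))
  chain <- matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3)
  expect_equal(unname(cld_letters(c("A", "B", "C"), chain)),
               c("a", "ab", "b"))
  expect_error(cld_letters(c("A", "B"), matrix(c(1, .2, .8, 1), 2)),
               "symmetric")
})

test_that("letters match the exhaustive minimal oracle on 3 and 4 levels", {
  for (k in 3:4) {
    for (p in all_p_matrices(k)) {
      got <- cld_letters(letters[1:k], p, alpha = 0.05)
      expect_true(cld_valid(got, p, 0.05))
      expect_equal(length(unique(unlist(strsplit(got, "")))),
                   min_cld_letters(p, 0.05))
    }
  }
})

test_that("letter partitions are invariant to level permutation", {
  set.seed(3)
  for (rep in 1:10) {
    p <- all_p_matrices(4)[[sample(2^6, 1)]]
    perm <- sample(4)
    a <- cld_letters(letters[1:4], p)
    b <- cld_letters(letters[1:4][perm], p[perm, perm])
    shares <- function(s, i, j)
      length(intersect(strsplit(s[i], "")[[1]], strsplit(s[j], "")[[1]])) > 0
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(shares(unname(a), perm[i], perm[j]),
                   shares(unname(b), i, j))
  }
})

test_that("mcfadden is zero for the null fit and guards mismatched data", {
  d <- simulate_dataset(sim_config(n = 60, seed = 6))
  f0 <- gamma_glm(mass_kg ~ 1, d)
  f1 <- gamma_glm(mass_kg ~ timing_day, d)
  expect_equal(mcfadden(f0, f0), 0)
  expect_gt(mcfadden(f1, f0), 0)
  expect_lte(mcfadden(f1, f0), 1)
  expect_equal(mcfadden(f1), mcfadden(f1, f0))
  d2 <- simulate_dataset(sim_config(n = 60, seed = 99))
  expect_error(mcfadden(f1, gamma_glm(mass_kg ~ 1, d2)), "same data|same response")
})
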