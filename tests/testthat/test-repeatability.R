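test_that("AICc matches the hand formula on a fixed dataset", {
  set.seed(71)
  d <- gaussian_rpt_data(0.5, n_ind = 10, n_trip = 4)
  fit <- lme4::lmer(y ~ 1 + (1 | individual_id), data = d, REML = FALSE)
  ll <- logLik(fit)
  k <- attr(ll, "df"); n <- nrow(d)
  expect_equal(aicc(fit),
               -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-12)
  # and for lm
  lf <- lm(y ~ 1, data = d)
  kl <- attr(logLik(lf), "df")
  expect_equal(aicc(lf), stats::AIC(lf) + 2 * kl * (kl + 1) / (n - kl - 1),
               tolerance = 1e-12)
})

test_that("collinearity screen drops one of each offending pair by priority", {
  set.seed(73)
  z <- rnorm(100)
  d <- data.frame(
    mass_kg = 0.9 * z + sqrt(1 - 0.81) * rnorm(100),
    axillary_girth_cm = 0.95 * z + sqrt(1 - 0.9) * rnorm(100),
    flipper_length_cm = rnorm(100)
  )
  stopifnot(abs(cor(d$mass_kg, d$axillary_girth_cm)) > 0.7)
  keep <- screen_collinearity(d)
  expect_false("mass_kg" %in% keep)
  expect_true(all(c("axillary_girth_cm", "flipper_length_cm") %in% keep))
  # orthogonal columns all retained
  d2 <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_setequal(screen_collinearity(d2), c("a", "b", "c"))
  # perfectly correlated pair: exactly one removed
  d3 <- data.frame(a = z, b = z, c = rnorm(100))
  expect_length(screen_collinearity(d3), 2)
  expect_error(screen_collinearity(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("Cholesky-constructed mass/girth correlation fires the removal rule", {
  set.seed(75)
  L <- chol(matrix(c(1, 0.85, 0.85, 1), 2))
  m <- matrix(rnorm(400), ncol = 2) %*% L
  d <- data.frame(mass_kg = m[, 1], axillary_girth_cm = m[, 2],
                  axis_length_cm = rnorm(200))
  keep <- screen_collinearity(d)
  expect_false("mass_kg" %in% keep)
  expect_true("axillary_girth_cm" %in% keep)
})

test_that("intercept-only models are selected under the null", {
  set.seed(77)
  hits <- replicate(30, {
    ni <- 50; nt <- 4
    d <- data.frame(
      individual_id = gl(ni, nt),
      y = rep(rnorm(ni, 0, 0.7), each = nt) + rnorm(ni * nt),
      girth = rep(rnorm(ni), each = nt),
      axis = rep(rnorm(ni), each = nt),
      flipper = rep(rnorm(ni), each = nt)
    )
    length(select_fixed_effects(d, "y", c("girth", "axis", "flipper"))$covariates) == 0
  })
  expect_gte(mean(hits), 0.8)
})

test_that("a strong girth effect is retained", {
  set.seed(79)
  hits <- replicate(30, {
    ni <- 50; nt <- 4
    girth <- rep(rnorm(ni), each = nt)
    d <- data.frame(
      individual_id = gl(ni, nt),
      y = 0.8 * girth + rep(rnorm(ni, 0, 0.7), each = nt) + rnorm(ni * nt),
      girth = girth,
      axis = rep(rnorm(ni), each = nt),
      flipper = rep(rnorm(ni), each = nt)
    )
    "girth" %in% select_fixed_effects(d, "y", c("girth", "axis", "flipper"))$covariates
  })
  expect_gte(mean(hits), 0.9)
})

test_that("repeatability is the variance-component ratio and complements to 1", {
  set.seed(81)
  d <- gaussian_rpt_data(0.5, n_ind = 40, n_trip = 6)
  r <- repeatability_gaussian(d, "y", n_perm = 0, n_boot = 0)
  expect_equal(r$r, r$sigma_alpha2 / (r$sigma_alpha2 + r$sigma_eps2),
               tolerance = 1e-12)
  expect_equal(r$r + r$r_individual, 1, tolerance = 1e-12)
  # equal components give r = 0.5 by construction of the formula
  expect_equal(0.5 / (0.5 + 0.5), 0.5)
})

test_that("repeatability is invariant to shifting the response", {
  set.seed(83)
  d <- gaussian_rpt_data(0.4, n_ind = 25, n_trip = 5)
  r1 <- repeatability_gaussian(d, "y", n_perm = 0, n_boot = 0)
  d$y <- d$y + 100
  r2 <- repeatability_gaussian(d, "y", n_perm = 0, n_boot = 0)
  expect_equal(r1$r, r2$r, tolerance = 1e-6)
  # adjusted repeatability invariant to recentering covariates
  d$cov <- rep(rnorm(25), each = 5)
  a1 <- repeatability_gaussian(d, "y", "cov", n_perm = 0, n_boot = 0)
  d$cov <- d$cov - 7
  a2 <- repeatability_gaussian(d, "y", "cov", n_perm = 0, n_boot = 0)
  expect_equal(a1$r, a2$r, tolerance = 1e-6)
  expect_true(a1$adjusted); expect_false(r1$adjusted)
})

test_that("zero individual effect gives near-zero r and non-significant permutation test", {
  set.seed(85)
  res <- replicate(40, {
    d <- gaussian_rpt_data(0, n_ind = 20, n_trip = 5)
    r <- repeatability_gaussian(d, "y", n_perm = 99, n_boot = 0)
    c(r$r, r$p_perm)
  })
  expect_lt(mean(res[1, ]), 0.1)
  expect_gte(mean(res[2, ] > 0.05), 0.9)
})

test_that("gaussian repeatability recovers the simulation truth", {
  set.seed(87)
  est <- replicate(25, {
    d <- gaussian_rpt_data(0.6, n_ind = 50, n_trip = 8)
    repeatability_gaussian(d, "y", n_perm = 0, n_boot = 0)$r
  })
  expect_lt(abs(mean(est) - 0.6), 0.05)
})

test_that("bootstrap CI brackets the estimate and permutation detects real effects", {
  set.seed(89)
  d <- gaussian_rpt_data(0.6, n_ind = 30, n_trip = 6)
  r <- repeatability_gaussian(d, "y", n_perm = 99, n_boot = 99)
  expect_lte(r$ci_low, r$r)
  expect_gte(r$ci_high, r$r)
  expect_lt(r$p_perm, 0.05)
})

test_that("proportion repeatability uses the logit distribution variance", {
  set.seed(91)
  ni <- 30; nt <- 6; nd <- 80
  a <- rep(rnorm(ni, 0, sqrt(4.29)), each = nt)
  e <- rnorm(ni * nt, 0, 1)
  k <- rbinom(ni * nt, nd, plogis(qlogis(0.75) + a + e))
  d <- data.frame(individual_id = gl(ni, nt), k = k, n = nd)
  r <- repeatability_proportion(d, "k", "n")
  expect_equal(r$distribution_variance, pi^2 / 3, tolerance = 1e-12)
  expect_equal(pi^2 / 3, 3.28987, tolerance = 1e-5)
  expect_equal(r$r, r$sigma_alpha2 /
                 (r$sigma_alpha2 + r$sigma_olre2 + pi^2 / 3),
               tolerance = 1e-12)
  expect_true(is.na(r$ci_low) && is.na(r$p_perm))
  expect_equal(r$r + r$r_individual, 1, tolerance = 1e-12)
  # zero between-individual variance -> r near 0
  k0 <- rbinom(ni * nt, nd, plogis(qlogis(0.75) + rnorm(ni * nt, 0, 1)))
  d0 <- data.frame(individual_id = gl(ni, nt), k = k0, n = nd)
  expect_lt(repeatability_proportion(d0, "k", "n")$r, 0.1)
  expect_error(repeatability_proportion(
    data.frame(individual_id = gl(4, 2), k = 0, n = 10), "k", "n"),
    "0 or 1")
})

test_that("repeatability bands follow the 0.25/0.5/0.75 cuts", {
  expect_equal(classify_band(0.1), "low")
  expect_equal(classify_band(0.25), "low")
  expect_equal(classify_band(0.3), "considerable")
  expect_equal(classify_band(0.5), "considerable")
  expect_equal(classify_band(0.6), "moderate")
  expect_equal(classify_band(0.75), "moderate")
  expect_equal(classify_band(0.9), "high")
  expect_error(classify_band(1.2))
})
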