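test_that("ROPE Bayes factors match their definition and a closed-form oracle", {
  set.seed(2)
  pr <- rnorm(2e5)
  rope <- c(-0.2, 0.2)
  # posterior identical to prior: BF = 1
  bf1 <- rope_bayes_factor(pr, rnorm(2e5), rope)
  expect_equal(bf1$bf_rope, 1, tolerance = 0.05)
  # posterior entirely inside the ROPE: BF -> 0
  expect_equal(rope_bayes_factor(pr, runif(1e4, -0.1, 0.1), rope)$bf_rope, 0)
  # posterior entirely outside: BF -> Inf
  expect_identical(rope_bayes_factor(pr, runif(1e4, 0.5, 0.6), rope)$bf_rope,
                   Inf)

  # analytic normal prior/posterior case
  post <- rnorm(2e5, 0.3, 0.1)
  got <- rope_bayes_factor(pr, post, rope)$bf_rope
  p_pr <- pnorm(0.2) - pnorm(-0.2)
  p_po <- pnorm(0.2, 0.3, 0.1) - pnorm(-0.2, 0.3, 0.1)
  oracle <- (p_pr / (1 - p_pr)) / (p_po / (1 - p_po))
  expect_equal(got, oracle, tolerance = 0.05)

  expect_error(rope_bayes_factor(numeric(0), post, rope), "non-empty")
  expect_error(rope_bayes_factor(runif(100, -0.1, 0.1), post, rope),
               "strictly between")
  expect_identical(classify_bf(5), "supports_H1")
  expect_identical(classify_bf(0.2), "supports_H0")
  expect_identical(classify_bf(1.5), "anecdotal")
})

test_that("the shortest-interval HDI behaves on known distributions", {
  set.seed(5)
  x <- rnorm(5e4)
  h <- hdi(x)
  expect_equal(h, c(-1.96, 1.96), tolerance = 0.08)
  expect_true(h[1] < median(x) && h[2] > median(x))
  # skewed distribution: HDI is tighter than the equal-tailed interval
  y <- rexp(5e4)
  expect_lt(diff(hdi(y)), diff(quantile(y, c(0.025, 0.975))))
})

test_that("robust correlations recover known associations and reject bad input", {
  set.seed(31)
  x <- rnorm(400)
  est <- robust_correlation(x, x + rnorm(400, 0, 1e-3), seed = 1)
  expect_gt(est$posterior_median, 0.99)
  expect_error(robust_correlation(x, rep(1, 400)), "constant")

  # independent draws: HDI covers zero
  est0 <- robust_correlation(rnorm(1000), rnorm(1000), seed = 2)
  expect_true(est0$hdi_95[1] < 0 && est0$hdi_95[2] > 0)

  # recovery at the study's sample size
  set.seed(7)
  z1 <- rnorm(743); z2 <- 0.48 * z1 + sqrt(1 - 0.48^2) * rnorm(743)
  est48 <- robust_correlation(z1, z2, seed = 3)
  expect_true(est48$posterior_median > 0.42 && est48$posterior_median < 0.53)
  expect_true(est48$hdi_95[1] < est48$posterior_median &&
                est48$posterior_median < est48$hdi_95[2])

  # polyserial flavour against the latent generating correlation
  yo <- cut(z2, c(-Inf, -0.6, 0.3, 1, Inf), labels = FALSE)
  ps <- robust_correlation(z1, yo, kind = "polyserial", seed = 4)
  expect_true(abs(ps$posterior_median - 0.48) < 0.08)
})

test_that("partial correlations residualise on the control", {
  set.seed(12)
  th <- rnorm(2000)
  # control independent of both: partial ~ zero-order
  x <- 0.5 * th + sqrt(0.75) * rnorm(2000)
  ctrl <- rnorm(2000)
  pz <- robust_partial_correlation(th, x, ctrl, seed = 5)
  z0 <- robust_correlation(th, x, seed = 6)
  expect_lt(abs(pz$posterior_median - z0$posterior_median), 0.03)
  expect_identical(pz$kind, "partial_r")
  expect_equal(pz$rope, c(-0.1, 0.1))

  expect_error(robust_partial_correlation(th, ctrl, ctrl), "collinear")

  # fully mediated association: posterior concentrates in the ROPE
  cov <- simulate_covariates(th, targets = c(v = 0.4), confounder_share = 1,
                             seed = 8)
  pm <- robust_partial_correlation(th, cov$v, cov$confounder, seed = 9)
  expect_gt(pm$p_rope, 0.9)
  expect_identical(pm$evidence, "supports_H0")
})

test_that("the robust t model recovers standardized group differences", {
  set.seed(17)
  # identical groups
  g <- rnorm(300)
  same <- robust_ttest(g, g + 0, seed = 10)
  expect_lt(abs(same$posterior_median), 0.1)
  expect_gt(same$p_rope, 0.5)
  expect_error(robust_ttest(rep(1, 10), rep(1, 10)), "zero variance")

  # group moments of the clinical/normative design
  a <- rnorm(743, 1.01, 1.17); b <- rnorm(721, 0.01, 0.93)
  tt <- robust_ttest(a, b, seed = 11)
  expect_true(tt$posterior_median > 0.85 && tt$posterior_median < 1.15)
  expect_identical(tt$evidence, "supports_H1")

  # 1% gross outliers barely move the heavy-tailed estimate
  set.seed(23)
  a2 <- rnorm(1000, 0.5); b2 <- rnorm(1000)
  clean <- robust_ttest(a2, b2, seed = 12)$posterior_median
  a2[1:10] <- 50
  dirty <- robust_ttest(a2, b2, seed = 12)$posterior_median
  expect_lt(abs(clean - dirty), 0.05)
})
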