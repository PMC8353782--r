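test_that("PUC boundary cases and enumeration identity hold", {
  J <- 6
  all_one <- bifactor_structure(1:J, specific = "S")
  expect_equal(puc(all_one), 0)
  all_alone <- bifactor_structure(1:J, specific = NA)
  expect_equal(puc(all_alone), 1)
  expect_error(puc(bifactor_structure("x")), "2 items")

  # random membership structures vs an independent combn-based count
  set.seed(14)
  for (r in 1:5) {
    J <- sample(5:12, 1)
    spec <- sample(c("A", "B", NA), J, replace = TRUE)
    meth <- sample(c("M", NA), J, replace = TRUE)
    s <- bifactor_structure(1:J, specific = spec, method = meth)
    pairs <- combn(J, 2)
    shared <- apply(pairs, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      isTRUE(spec[i] == spec[j]) || isTRUE(meth[i] == meth[j])
    })
    expect_equal(puc(s), 1 - mean(shared))
  }
})

test_that("ECV reduces correctly and matches a brute-force oracle", {
  s0 <- bifactor_structure(1:5, lambda_general = 0.6, specific = "S",
                           lambda_specific = 0)
  expect_equal(ecv(s0)$ECV, 1)
  s5 <- bifactor_structure(1:4, lambda_general = 0.5, specific = "S",
                           lambda_specific = 0.5)
  expect_equal(ecv(s5)$ECV, 0.5)
  expect_error(ecv(bifactor_structure(1:3, lambda_general = 0)), "zero")

  set.seed(3)
  lg <- runif(8, 0.3, 0.8)
  ls <- runif(8, 0.1, 0.5)
  spec <- rep(c("A", "B"), each = 4)
  s <- bifactor_structure(1:8, lambda_general = lg, specific = spec,
                          lambda_specific = ls)
  e <- ecv(s)
  expect_equal(e$ECV, sum(lg^2) / (sum(lg^2) + sum(ls^2)), tolerance = 1e-12)
  expect_equal(unname(e$item_ECV), lg^2 / (lg^2 + ls^2), tolerance = 1e-12)
  expect_equal(unname(e$S_ECV["A"]),
               sum(lg[1:4]^2) / sum(lg[1:4]^2 + ls[1:4]^2), tolerance = 1e-12)
  # ECV is the common-variance-weighted aggregate of item ECVs
  wts <- lg^2 + ls^2
  expect_equal(e$ECV, sum(wts * e$item_ECV) / sum(wts), tolerance = 1e-12)
})

test_that("bivariate normal CDF matches the closed form for median orthants", {
  # Phi2(0, 0, rho) = 1/4 + asin(rho) / (2 pi)
  for (r in c(-0.9, -0.4, 0, 0.3, 0.75, 0.95)) {
    expect_equal(bvnorm_cdf(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-10)
  }
  expect_equal(bvnorm_cdf(Inf, 0.3, 0.5), pnorm(0.3))
  expect_equal(bvnorm_cdf(-Inf, 0.3, 0.5), 0)
  expect_equal(bvnorm_cdf(1, 2, 0), pnorm(1) * pnorm(2))
  expect_equal(bvnorm_cdf(0.5, -0.2, 1), pnorm(-0.2))
})

test_that("categorical omegas behave like reliabilities", {
  tau <- matrix(rep(c(-1.2, -0.2, 0.6, 1.4), each = 6), 6)
  s <- bifactor_structure(1:6, lambda_general = 0.7,
                          specific = rep(c("A", "B"), each = 3),
                          lambda_specific = 0.4, thresholds = tau)
  wT <- omega_categorical(s, "total")
  wH <- omega_categorical(s, "hierarchical")
  expect_true(wT > 0 && wT < 1)
  expect_lte(wH, wT)
  wS <- omega_categorical(s, "subscale")
  wHS <- omega_categorical(s, "hier_subscale")
  expect_true(all(wHS < wS))

  # zero loadings give zero omega
  s0 <- bifactor_structure(1:4, lambda_general = 0, thresholds = tau[1:4, ])
  expect_equal(omega_categorical(s0, "total"), 0)

  # raising general loadings (specifics fixed) raises general saturation
  sweep_wH <- vapply(c(0.5, 0.6, 0.7, 0.8), function(l) {
    omega_categorical(bifactor_structure(
      1:6, lambda_general = l, specific = rep(c("A", "B"), each = 3),
      lambda_specific = 0.4, thresholds = tau), "hierarchical")
  }, numeric(1))
  expect_true(all(diff(sweep_wH) > 0))

  # omega_H <= omega_T across random admissible structures
  set.seed(8)
  for (r in 1:4) {
    lg <- runif(5, 0.3, 0.7); ls <- runif(5, 0.1, 0.5)
    sr <- bifactor_structure(1:5, lg, specific = "S", lambda_specific = ls,
                             thresholds = tau[1:5, ])
    expect_lte(omega_categorical(sr, "hierarchical"),
               omega_categorical(sr, "total") + 1e-12)
  }
})

test_that("omega total agrees with an empirical parallel-forms reliability", {
  tau <- matrix(rep(c(-1, 0, 1), each = 6), 6)
  lg <- 0.7; ls <- 0.4
  s <- bifactor_structure(1:6, lambda_general = lg,
                          specific = rep(c("A", "B"), each = 3),
                          lambda_specific = ls, thresholds = tau)
  wT <- omega_categorical(s, "total")

  # simulate two parallel forms sharing the same factor draws
  set.seed(11)
  n <- 60000
  G <- rnorm(n); FA <- rnorm(n); FB <- rnorm(n)
  make_form <- function() {
    vapply(1:6, function(j) {
      f <- if (j <= 3) FA else FB
      z <- lg * G + ls * f + sqrt(1 - lg^2 - ls^2) * rnorm(n)
      1 + rowSums(outer(z, tau[j, ], `>`))
    }, numeric(n))
  }
  emp <- cor(rowSums(make_form()), rowSums(make_form()))
  expect_equal(wT, emp, tolerance = 0.02)
})

test_that("polychoric correlations recover latent association", {
  set.seed(21)
  n <- 5000
  z1 <- rnorm(n); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(n)
  cuts1 <- c(-Inf, -1, 0, 1, Inf); cuts2 <- c(-Inf, -0.5, 0.5, Inf)
  x <- cut(z1, cuts1, labels = FALSE)
  y <- cut(z2, cuts2, labels = FALSE)
  r <- polychoric(x, y)
  expect_true(r > 0.55 && r < 0.65)

  # independence
  y0 <- cut(rnorm(n), cuts2, labels = FALSE)
  expect_lt(abs(polychoric(x, y0)), 0.05)

  # identical ordinal vectors push against the upper bound
  expect_gt(polychoric(x, x), 0.99)

  expect_error(polychoric(rep(1, 100), x[1:100]), "degenerate")
})
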