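test_that("MAP scoring respects the prior, monotonicity and the score bounds", {
  # flat likelihood: posterior mode is the prior mean
  z <- zero_slope_bank()
  expect_equal(score_map(c(1, 2, 3, 4), bank = z)$theta_hat, 0,
               tolerance = 1e-5)
  expect_equal(score_map(c(1, 2, 3, 4), bank = z,
                         prior = latent_dist(0.7, 1))$theta_hat, 0.7,
               tolerance = 1e-5)

  # raising any single response never decreases the score
  set.seed(41)
  for (rep in 1:10) {
    resp <- sample(1:4, 8, replace = TRUE)
    j <- sample(8, 1)
    up <- resp; up[j] <- resp[j] + 1L
    expect_gte(score_map(up)$theta_hat, score_map(resp)$theta_hat - 1e-7)
  }

  # complete patterns stay inside the all-extreme bounds
  lo <- score_map(rep(1, 8))$theta_hat
  hi <- score_map(rep(5, 8))$theta_hat
  for (rep in 1:10) {
    th <- score_map(sample(1:5, 8, replace = TRUE))$theta_hat
    expect_true(th >= lo - 1e-8 && th <= hi + 1e-8)
  }

  # T-score affine identity, exactly
  s <- score_map(c(2, 3, 1, 4, 5, 2, 3, 1))
  expect_identical(s$t_score, 50 + 10 * s$theta_hat)

  # missing items are dropped and counted
  r <- rep(3, 8); r[c(2, 5)] <- NA
  expect_identical(score_map(r)$n_items_used, 6L)
  expect_error(score_map(rep(NA, 8)), "missing")
  expect_error(score_map(c(7, rep(3, 7))), "range")
})

test_that("EAP matches a dense-grid posterior oracle and symmetry arguments", {
  z <- zero_slope_bank()
  expect_equal(score_eap(c(2, 2, 3, 3), bank = z)$theta_hat, 0,
               tolerance = 1e-8)

  # brute-force quadrature oracle at 1e5 grid points
  bank <- gafs8_bank()
  for (resp in list(rep(2, 8), c(1, 5, 2, 4, 3, 2, 1, 5))) {
    grid <- seq(-8, 8, length.out = 1e5)
    lw <- dnorm(grid, log = TRUE)
    for (j in seq_along(bank)) {
      lw <- lw + log(category_probabilities(bank[[j]], grid)[, resp[j]])
    }
    w <- exp(lw - max(lw)); w <- w / sum(w)
    oracle <- sum(grid * w)
    expect_equal(score_eap(resp, bank = bank)$theta_hat, oracle,
                 tolerance = 1e-4)
  }

  # mirrored bank, mirrored responses: EAPs symmetric about the prior mean
  mb <- mirror_bank()
  e1 <- score_eap(c(1, 2), bank = mb)$theta_hat
  e2 <- score_eap(c(5, 4), bank = mb)$theta_hat
  expect_equal(e1, -e2, tolerance = 1e-6)

  # EAP and MAP agree closely for informative patterns
  expect_equal(score_eap(rep(4, 8))$theta_hat, score_map(rep(4, 8))$theta_hat,
               tolerance = 0.05)
})

test_that("conditional reliability is information over information plus prior precision", {
  expect_equal(conditional_reliability(0, bank = zero_slope_bank()), 0)
  r <- conditional_reliability(seq(-4, 4, 0.5))
  expect_true(all(r >= 0 & r <= 1))
  # definitional identity
  th <- 0.8
  info <- test_information(gafs8_bank(), th)
  expect_equal(conditional_reliability(th), info / (info + 1))
  # wider prior raises reliability at fixed information
  expect_gt(conditional_reliability(0, prior_sd = 2),
            conditional_reliability(0, prior_sd = 1))
})

test_that("classical TAS-20 composites apply reversal, proration and the cutoff", {
  allthree <- classical_scores(rep(3, 20))
  expect_equal(allthree$prorated_total, 60)
  expect_equal(allthree$tas20_total, 60)
  expect_false(allthree$high_alexithymia)

  # all responses 1: 15 forward stay 1, 5 reversed become 5
  expect_equal(classical_scores(rep(1, 20))$tas20_total, 15 + 25)

  # cutoff is >= 61: push one item up from the all-3 pattern
  r <- rep(3, 20); r[1] <- 4
  expect_true(classical_scores(r)$high_alexithymia)

  # 16-item prorated form (named), total unavailable
  nm <- paste0("tas", sprintf("%02d", 1:16))
  p <- classical_scores(setNames(rep(4, 16), nm))
  expect_true(is.na(p$tas20_total))
  # reversed items among 1..16 are 4,5,10: 13 * 4 + 3 * 2 = 58 -> mean * 20
  expect_equal(p$prorated_total, (13 * 4 + 3 * 2) / 16 * 20)

  expect_error(classical_scores(setNames(rep(3, 15), nm[1:15])), "16")
  expect_error(classical_scores(rep(6, 20)), "1..5")
})

test_that("zero-based response coding is recognised and normalised", {
  s1 <- score_map(c(0, 4, 2, 3, 1, 0, 2, 4))   # 0..4 coding
  s2 <- score_map(c(1, 5, 3, 4, 2, 1, 3, 5))   # same pattern, 1..5
  expect_equal(s1$theta_hat, s2$theta_hat)
})

test_that("score_respondents appends scores and classical composites", {
  df <- data.frame(matrix(3L, nrow = 3, ncol = 20,
                          dimnames = list(NULL, paste0("tas", sprintf("%02d", 1:20)))))
  df[2, "tas01"] <- 5L
  out <- score_respondents(df)
  expect_true(all(c("theta_hat", "se", "t_score", "tas20_total",
                    "high_alexithymia") %in% names(out)))
  expect_gt(out$theta_hat[2], out$theta_hat[1])
  expect_equal(out$tas20_total[1], 60)
  expect_error(score_respondents(df[, 1:5]), "missing item columns")
})

test_that("simulated respondents are scored with high trait recovery", {
  sim <- sim_one_group(gafs8_bank(), 2000, seed = 99)
  th_hat <- gafs8:::.batch_map(gafs8_bank(), sim$data, latent_dist(0, 1))
  expect_gt(cor(sim$theta, th_hat), 0.9)
  # the batch grid scorer agrees with the optimiser-based MAP
  for (i in sample(2000, 25)) {
    expect_lt(abs(th_hat[i] - score_map(sim$data[i, ])$theta_hat), 0.01)
  }
})
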