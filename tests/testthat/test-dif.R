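test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.03), 0.03)

  step_up_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.20)),
               step_up_oracle(c(0.01, 0.02, 0.03, 0.20)))
  set.seed(9)
  for (i in 1:5) {
    p <- runif(sample(3:12, 1))
    expect_equal(bh_fdr(p), step_up_oracle(p))
    expect_true(all(bh_fdr(p) >= p))
  }
  expect_error(bh_fdr(c(0.1, NaN)), "missing")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1|\\[0, 1\\]")
})

test_that("wABC is zero without DIF, monotone in shifts, and symmetric", {
  it <- gafs8_bank()[["6"]]
  foc <- latent_dist(1.01, 1.17)
  expect_equal(wabc(it, it, foc), 0)

  shifted <- function(delta) grm_item(it$a, it$d + delta, label = "s")
  w <- vapply(c(0.2, 0.5, 1.0), function(d) wabc(it, shifted(d), foc),
              numeric(1))
  expect_true(all(diff(w) > 0))

  # relabelling reference and focal leaves the area unchanged
  expect_equal(wabc(it, shifted(0.5), foc), wabc(shifted(0.5), it, foc))

  # independent numeric oracle: trapezoid integration on a finer, offset grid
  grid <- seq(foc$mu - 8 * foc$sigma, foc$mu + 8 * foc$sigma,
              length.out = 4001)
  f <- abs(expected_item_score(it, grid) -
             expected_item_score(shifted(0.5), grid)) *
    dnorm(grid, foc$mu, foc$sigma)
  oracle <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
  expect_equal(wabc(it, shifted(0.5), foc), oracle, tolerance = 1e-3)

  expect_error(wabc(it, grm_item(1, c(1, -1)), foc), "categories")
})

test_that("ESSD carries the focal-higher sign convention and matches Monte Carlo", {
  it <- gafs8_bank()[["12"]]
  foc <- latent_dist(1.01, 1.17)
  expect_equal(essd(it, it, foc), 0)
  easier <- grm_item(it$a, it$d + 0.6, label = "e")
  expect_gt(essd(it, easier, foc), 0)   # focal intercepts easier -> positive

  # Monte-Carlo oracle on a two-item bank
  set.seed(123)
  n <- 1e6
  th <- rnorm(n, foc$mu, foc$sigma)
  draw_scores <- function(item) {
    pk <- category_probabilities(item, th)
    cum <- pk %*% upper.tri(diag(item$K), diag = TRUE)
    1L + rowSums(runif(n) > cum[, -item$K, drop = FALSE])
  }
  x_ref <- draw_scores(it); x_foc <- draw_scores(easier)
  mc <- (mean(expected_item_score(easier, th)) -
           mean(expected_item_score(it, th))) /
    sqrt((var(x_ref) + var(x_foc)) / 2)
  expect_equal(essd(it, easier, foc), mc, tolerance = 5e-3)
})

test_that("test-level DTF indices vanish without DIF and are location invariant", {
  bank <- sub_bank(c(1, 6, 14))
  foc <- latent_dist(1.01, 1.17)
  expect_equal(etssd(bank, bank, foc), 0)
  expect_equal(uetsds(bank, bank, rnorm(50)), 0)
  expect_error(uetsds(bank, bank, numeric(0)), "non-empty")

  # shifting both parameter sets and the focal density by a constant leaves
  # the effect sizes unchanged (location identification)
  shift_bank <- function(b, c) {
    grm_bank(lapply(b, function(i) grm_item(i$a, i$d - i$a * c, i$label)))
  }
  foc_bank <- grm_bank(lapply(bank, function(i) {
    grm_item(i$a, i$d + 0.4, i$label)
  }))
  e0 <- etssd(bank, foc_bank, foc)
  e1 <- etssd(shift_bank(bank, 0.8), shift_bank(foc_bank, 0.8),
              latent_dist(foc$mu + 0.8, foc$sigma))
  expect_equal(e0, e1, tolerance = 1e-8)
  w0 <- wabc(bank[[1]], foc_bank[[1]], foc)
  w1 <- wabc(shift_bank(bank, 0.8)[[1]], shift_bank(foc_bank, 0.8)[[1]],
             latent_dist(foc$mu + 0.8, foc$sigma))
  expect_equal(w0, w1, tolerance = 1e-8)
})

test_that("the iterative Wald procedure reports coherent flags on matched groups", {
  bank <- sub_bank(c(1, 6, 13, 14))
  sim <- sim_two_groups(bank, 400, seed = 55, foc = latent_dist(0.5, 1))
  dif <- iterative_wald_dif(sim$data, sim$group, quadrature = 21, tol = 5e-4)
  expect_lte(dif$n_iterations, 10L)
  # recorded p_FDR is consistent with the flag decision
  expect_true(all(dif$items$p_FDR[dif$items$flagged] < 0.05))
  expect_true(all(dif$items$p_FDR[!dif$items$flagged] >= 0.05))
  # anchors are exactly the unflagged items
  expect_setequal(dif$anchors, dif$items$item[!dif$items$flagged])
  # constrained (anchor) items carry exactly zero effect size
  expect_true(all(dif$items$wABC[!dif$items$flagged] == 0))
  expect_true(all(dif$items$wABC >= 0))
  expect_true(dif$UETSDS >= 0)
})

test_that("subgroup scans validate partitions and reproduce the two-group result", {
  bank <- sub_bank(c(1, 6, 12, 14))
  sim <- sim_two_groups(bank, 300, seed = 70,
                        dif = list(`6` = list(group = "foc", d_shift = 1.5)))
  expect_error(subgroup_dif_scan(sim$data, list(all_same = rep("a", 600))),
               "degenerate")
  expect_error(subgroup_dif_scan(sim$data, list(rep(c("a", "b"), 300))),
               "named")

  scan <- suppressWarnings(subgroup_dif_scan(
    sim$data,
    list(diagnosis = sim$group,
         random = rep(c("u", "v"), length.out = 600)),
    quadrature = 15))
  direct <- suppressWarnings(
    iterative_wald_dif(sim$data, sim$group, quadrature = 15))
  expect_equal(scan$summary$max_wABC[1], max(direct$items$wABC),
               tolerance = 1e-6)
  expect_true(scan$summary$practical[1])    # planted large DIF
  expect_false(scan$summary$practical[2])   # random split of the same sample
})
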