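test_that("cumulative and category probabilities follow the logistic graded model", {
  it1 <- gafs8_bank()[["1"]]

  # frozen values: direct logistic evaluation of the published item 1 at theta = 0
  expect_equal(cumulative_probabilities(it1, 0),
               c(0.9565, 0.3343, 0.0607, 0.0018), tolerance = 1e-2)
  expect_equal(category_probabilities(it1, 0),
               c(0.0435, 0.6222, 0.2736, 0.0589, 0.0018), tolerance = 1e-2)
  # and at full precision against plogis computed here
  expect_equal(cumulative_probabilities(it1, 0.73),
               plogis(it1$a * 0.73 + it1$d), tolerance = 1e-12)

  # logistic midpoint: a*theta + d_k = 0 gives P* = 0.5
  it <- grm_item(a = 2, d = c(1, -1))
  expect_equal(cumulative_probabilities(it, -0.5)[1L], 0.5)
  expect_equal(cumulative_probabilities(it, 0.5)[2L], 0.5)

  # limits
  expect_true(all(cumulative_probabilities(it1, -30) < 1e-10))
  expect_equal(category_probabilities(it1, 30)[it1$K], 1, tolerance = 1e-10)

  expect_error(cumulative_probabilities(it1, NA), "finite")
  expect_error(cumulative_probabilities(it1, Inf), "finite")
})

test_that("probability invariants hold across the published bank and trait range", {
  grid <- seq(-8, 8, length.out = 161)
  for (item in gafs8_bank()) {
    pk <- category_probabilities(item, grid)
    expect_true(all(abs(rowSums(pk) - 1) < 1e-12))
    expect_true(all(pk >= 0))
    ps <- cumulative_probabilities(item, grid)
    # non-increasing in category, non-decreasing in theta (a > 0)
    expect_true(all(ps[, -1L] <= ps[, -ncol(ps)] + 1e-12))
    expect_true(all(diff(ps) >= -1e-12))
  }
})

test_that("expected scores sum, saturate and respect zero discrimination", {
  bank <- gafs8_bank()
  expect_equal(expected_test_score(bank, 30), 40, tolerance = 1e-6)
  expect_equal(expected_test_score(bank, -30), 8, tolerance = 1e-6)

  z <- grm_item(a = 0, d = c(1.5, 0.5, -0.5, -1.5))
  expect_equal(expected_item_score(z, -3), expected_item_score(z, 3))

  # independent oracle: brute-force summation over categories at several thetas
  for (th in c(-1.3, 0, 0.8)) {
    es <- 0
    for (item in bank) {
      ps <- c(1, plogis(item$a * th + item$d), 0)
      es <- es + sum(seq_len(item$K) * (ps[-length(ps)] - ps[-1L]))
    }
    expect_equal(expected_test_score(bank, th), es, tolerance = 1e-12)
  }

  # monotone in theta when all slopes positive
  grid <- seq(-6, 6, by = 0.1)
  expect_true(all(diff(expected_test_score(bank, grid)) >= 0))
})

test_that("information matches a finite-difference oracle and is additive", {
  bank <- gafs8_bank()
  grid <- seq(-4, 4, length.out = 50)
  # additivity
  expect_equal(test_information(bank, grid),
               Reduce(`+`, lapply(bank, item_information, theta = grid)),
               tolerance = 1e-12)
  expect_true(all(test_information(bank, grid) >= 0))
  # zero slope gives zero information
  z <- grm_item(a = 0, d = c(1, 0, -1, -2))
  expect_equal(item_information(z, grid), rep(0, length(grid)))

  # finite-difference oracle: I = sum_k (dP_k/dtheta)^2 / P_k
  h <- 1e-5
  for (th in c(-2, 0, 1.5)) {
    for (item in bank[c(1, 6)]) {
      dp <- (category_probabilities(item, th + h) -
               category_probabilities(item, th - h)) / (2 * h)
      pk <- category_probabilities(item, th)
      expect_equal(item_information(item, th), sum(dp^2 / pk),
                   tolerance = 1e-6)
    }
  }
})

test_that("slope/loading conversion reproduces the published table and inverts exactly", {
  bank <- gafs8_bank()
  published_lambda <- c(0.855, 0.790, 0.808, 0.816, 0.740, 0.587, 0.743, 0.671)
  published_h2 <- c(0.731, 0.623, 0.653, 0.666, 0.547, 0.345, 0.553, 0.450)
  conv <- slope_to_loading(vapply(bank, `[[`, numeric(1), "a"))
  # published loadings derive from unrounded slopes; from the printed 3-d.p.
  # slopes the conversion agrees to within one unit in the third decimal
  expect_lt(max(abs(conv$lambda - published_lambda)), 0.0011)
  expect_lt(max(abs(conv$h2 - published_h2)), 0.0015)
  expect_equal(conv$h2, conv$lambda^2, tolerance = 1e-12)

  expect_equal(slope_to_loading(0)$lambda, 0)
  a <- c(0.3, 1.1, 2.5, -0.7)
  expect_equal(loading_to_slope(slope_to_loading(a)$lambda), a,
               tolerance = 1e-10)
  expect_error(loading_to_slope(1), "lambda")
  expect_error(slope_to_loading(Inf), "finite")
})

test_that("modal category census identifies never-modal middle categories", {
  # binary item: both categories modal somewhere
  b <- grm_item(a = 1.5, d = 0.3)
  expect_equal(modal_category_set(b), c(1L, 2L))

  # widely spaced intercepts: all five categories modal
  wide <- grm_item(a = 2, d = c(6, 2, -2, -6))
  expect_equal(modal_category_set(wide), 1:5)

  # published bank: items 11, 12, 14 lack a modal middle category
  lacking <- names(Filter(function(item) !(3L %in% modal_category_set(item)),
                          gafs8_bank()))
  expect_setequal(lacking, c("11", "12", "14"))

  expect_error(modal_category_set(b, numeric(0)), "empty")
  expect_error(modal_category_set(b, seq(-2, 2, 0.1)), "span")
})

test_that("item and bank constructors validate their invariants", {
  expect_error(grm_item(a = 1, d = c(-1, 0)), "decreasing")
  expect_error(grm_item(a = NaN, d = c(1, -1)), "finite")
  expect_error(grm_item(a = 1, d = numeric(0)), "d")
  expect_error(grm_bank(list()), "non-empty")
  expect_error(grm_bank(list(grm_item(1, c(1, -1), "x"),
                             grm_item(1, c(1, -1), "x"))), "unique")
})

test_that("banks round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".csv")
  bank <- gafs8_bank()
  write_bank(bank, path)
  back <- read_bank(path)
  expect_equal(as.data.frame(back), as.data.frame(bank))
  # mixed K survives the round trip
  mixed <- grm_bank(list(grm_item(1.2, c(1, -1, -2), "a"),
                         grm_item(0.8, 0.5, "b")))
  write_bank(mixed, path)
  expect_equal(as.data.frame(read_bank(path)), as.data.frame(mixed))
})
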