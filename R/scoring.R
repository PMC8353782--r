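#' Normalise a response vector against a bank
#'
#' Responses are coded 1..K internally. An input shim accepts 0-based coding
#' (0..K-1), recognised when at least one 0 is present and no value exceeds
#' K-1; such vectors are shifted up by one. Out-of-range values raise an
#' error naming the offending item.
#' @noRd
.normalise_responses <- function(responses, bank) {
  J <- length(bank)
  K <- vapply(bank, function(i) i$K, integer(1))
  if (!is.null(names(responses)) && all(names(bank) %in% names(responses))) {
    responses <- responses[names(bank)]
  }
  if (length(responses) != J) {
    stop(sprintf("expected %d responses, got %d", J, length(responses)),
         call. = FALSE)
  }
  x <- as.numeric(responses)
  obs <- !is.na(x)
  if (!any(obs)) stop("all responses are missing", call. = FALSE)
  if (any(x[obs] != round(x[obs]))) {
    stop("responses must be integer categories", call. = FALSE)
  }
  # 0-based shim: e.g. scales anchored at 0 rather than 1
  if (any(x[obs] == 0) && all(x[obs] <= K[obs] - 1L)) x <- x + 1L
  bad <- which(obs & (x < 1 | x > K))
  if (length(bad)) {
    stop(sprintf("response out of range 1..%d for item %s", K[bad[1L]],
                 bank[[bad[1L]]]$label), call. = FALSE)
  }
  as.integer(x)
}

## log-likelihood of a (possibly partial) response pattern at theta (vector)
.pattern_loglik <- function(bank, x, theta) {
  ll <- numeric(length(theta))
  for (j in seq_along(bank)) {
    if (is.na(x[j])) next
    pk <- category_probabilities(bank[[j]], theta)
    if (is.null(dim(pk))) pk <- matrix(pk, nrow = 1L)
    ll <- ll + log(pmax(pk[, x[j]], 1e-300))
  }
  ll
}

.score_result <- function(theta_hat, psd, rel, n_used, method) {
  structure(list(theta_hat = theta_hat, posterior_sd = psd,
                 reliability = rel, t_score = 50 + 10 * theta_hat,
                 n_items_used = n_used, method = method),
            class = "gafs8_score")
}

#' @export
print.gafs8_score <- function(x, ...) {
  cat(sprintf("<gafs8_score> theta = %.3f (SE %.3f), T = %.1f, rel = %.3f, items used = %d [%s]\n",
              x$theta_hat, x$posterior_sd, x$t_score, x$reliability,
              x$n_items_used, x$method))
  invisible(x)
}

#' Maximum a posteriori (MAP) latent trait score
#'
#' Scores a response pattern against a graded-response-model bank by
#' maximising the log posterior (pattern log-likelihood plus normal prior
#' density). The default bank is the embedded GAFS-8 calibration and the
#' default prior the normative `N(0, 1)` density, so scores are Z-scores
#' relative to the general population; pass
#' `prior = attr(gafs8_bank(), "groups")$clinical` to score clinical
#' respondents against their own group density (the convention under which
#' the published GAFS-8 score bounds of -2.19 and 3.52 arise).
#'
#' Missing items are dropped from the likelihood and `n_items_used` records
#' how many items contributed. The posterior SD is obtained from the
#' curvature of the log posterior at the mode, and the reported reliability
#' is the conditional reliability [conditional_reliability()] at the mode.
#'
#' @param responses Integer categories (1..K, or 0..K-1 which is shifted up);
#'   `NA` marks missing. Named vectors are matched to bank labels.
#' @param bank A [grm_bank()]; defaults to [gafs8_bank()].
#' @param prior A [latent_dist()] prior; default `N(0, 1)`.
#' @param bounds Search interval for the mode.
#' @return A `gafs8_score` object: `theta_hat`, `posterior_sd`,
#'   `reliability`, `t_score` (`50 + 10 * theta_hat`), `n_items_used`.
#' @examples
#' score_map(rep(5, 8))
#' @export
score_map <- function(responses, bank = gafs8_bank(),
                      prior = latent_dist(0, 1), bounds = c(-8, 8)) {
  stopifnot(inherits(bank, "grm_bank"), inherits(prior, "latent_dist"))
  x <- .normalise_responses(responses, bank)
  negpost <- function(th) {
    -(.pattern_loglik(bank, x, th) +
        stats::dnorm(th, prior$mu, prior$sigma, log = TRUE))
  }
  opt <- stats::optimize(negpost, interval = bounds, tol = 1e-8)
  th <- opt$minimum
  # posterior SD from numeric curvature at the mode
  h <- 1e-4
  curv <- (negpost(th + h) - 2 * negpost(th) + negpost(th - h)) / h^2
  psd <- if (curv > 0) 1 / sqrt(curv) else NA_real_
  used <- bank[!is.na(x)]
  rel <- conditional_reliability(th, bank = grm_bank(unname(used)),
                                 prior_sd = prior$sigma)
  .score_result(th, psd, rel, sum(!is.na(x)), "MAP")
}

#' Expected a posteriori (EAP) latent trait score
#'
#' Posterior mean and SD of the latent trait by fixed-grid quadrature over
#' `prior$mu +/- 6 * prior$sigma`.
#'
#' @inheritParams score_map
#' @param n_quadrature Number of grid points.
#' @return A `gafs8_score` object (see [score_map()]).
#' @export
score_eap <- function(responses, bank = gafs8_bank(),
                      prior = latent_dist(0, 1), n_quadrature = 161L) {
  stopifnot(inherits(bank, "grm_bank"), inherits(prior, "latent_dist"))
  x <- .normalise_responses(responses, bank)
  grid <- seq(prior$mu - 6 * prior$sigma, prior$mu + 6 * prior$sigma,
              length.out = n_quadrature)
  lw <- .pattern_loglik(bank, x, grid) +
    stats::dnorm(grid, prior$mu, prior$sigma, log = TRUE)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  m <- sum(grid * w)
  v <- sum((grid - m)^2 * w)
  used <- bank[!is.na(x)]
  rel <- conditional_reliability(m, bank = grm_bank(unname(used)),
                                 prior_sd = prior$sigma)
  .score_result(m, sqrt(v), rel, sum(!is.na(x)), "EAP")
}

## Vectorised grid MAP for many respondents at once (used by DTF indices);
## dense-grid argmax of the log posterior, accurate to the grid step.
.batch_map <- function(bank, x, prior, step = 0.005) {
  grid <- seq(prior$mu - 6 * prior$sigma, prior$mu + 6 * prior$sigma,
              by = step)
  lp <- matrix(stats::dnorm(grid, prior$mu, prior$sigma, log = TRUE),
               nrow(x), length(grid), byrow = TRUE)
  for (j in seq_along(bank)) {
    pk <- category_probabilities(bank[[j]], grid)   # Q x K
    obs <- which(!is.na(x[, j]))
    if (length(obs)) {
      lp[obs, ] <- lp[obs, ] + t(log(pmax(pk[, x[obs, j], drop = FALSE],
                                          1e-300)))
    }
  }
  grid[max.col(lp, ties.method = "first")]
}

#' Conditional reliability of latent trait scores
#'
#' `r(theta) = I(theta) / (I(theta) + 1 / sigma_prior^2)`, the proportion of
#' posterior precision contributed by the test information at a trait level.
#' For the GAFS-8 calibration this curve stays at or above 0.7 between
#' approximately -2.43 and 3.53.
#'
#' @param theta Trait value(s).
#' @param bank A [grm_bank()]; defaults to the GAFS-8 calibration.
#' @param prior_sd Prior SD (default 1, the normative metric).
#' @return Numeric vector in \[0, 1\].
#' @export
conditional_reliability <- function(theta, bank = gafs8_bank(),
                                    prior_sd = 1) {
  info <- test_information(bank, theta)
  info / (info + 1 / prior_sd^2)
}

#' Classical TAS-20 composite scores
#'
#' Computes the classical TAS-20 total (sum of the 20 items after reversing
#' the reverse-coded items 4, 5, 10, 18, 19 as `6 - x`), the prorated total
#' (mean of available items times 20, requiring at least 16 items), and the
#' conventional "high alexithymia" flag at a total of 61 or above.
#'
#' @param responses Numeric vector of TAS-20 item categories in 1..5, length
#'   20 (or at least 16 with names `tas01`..`tas20` or `1`..`20` identifying
#'   the items present); `NA` marks missing items.
#' @param reverse_items Item numbers reversed before summation.
#' @return A list of class `composite_scores` with `tas20_total` (NA unless
#'   all 20 items present), `prorated_total` and `high_alexithymia`.
#' @examples
#' classical_scores(rep(3, 20))  # prorated total 60, flag FALSE
#' @export
classical_scores <- function(responses, reverse_items = c(4, 5, 10, 18, 19)) {
  x <- rep(NA_real_, 20L)
  if (is.null(names(responses))) {
    if (length(responses) != 20L) {
      stop("unnamed input must have length 20 (use NA for missing items)",
           call. = FALSE)
    }
    x <- as.numeric(responses)
  } else {
    idx <- sub("^tas0?", "", names(responses))
    if (any(!idx %in% as.character(1:20))) {
      stop("names must identify TAS-20 items 1..20 (e.g. tas01)", call. = FALSE)
    }
    x[as.integer(idx)] <- as.numeric(responses)
  }
  obs <- !is.na(x)
  if (any(x[obs] < 1 | x[obs] > 5 | x[obs] != round(x[obs]))) {
    stop("responses must be integer categories in 1..5", call. = FALSE)
  }
  if (sum(obs) < 16L) {
    stop("prorated total needs at least 16 observed items", call. = FALSE)
  }
  x[reverse_items] <- 6 - x[reverse_items]
  total <- if (all(obs)) sum(x) else NA_real_
  prorated <- mean(x[obs]) * 20
  ref <- if (!is.na(total)) total else prorated
  structure(list(tas20_total = total, prorated_total = prorated,
                 high_alexithymia = ref >= 61),
            class = "composite_scores")
}

#' @export
print.composite_scores <- function(x, ...) {
  cat(sprintf("<composite_scores> total = %s, prorated = %.1f, high alexithymia: %s\n",
              ifelse(is.na(x$tas20_total), "NA", x$tas20_total),
              x$prorated_total, x$high_alexithymia))
  invisible(x)
}

#' Score a table of respondents
#'
#' Applies [score_map()] (or [score_eap()]) row-wise to a data frame holding
#' GAFS-8 item columns and appends `theta_hat`, `se`, `t_score`,
#' `reliability` and `n_items_used`; when all 20 TAS-20 columns are present
#' the classical `tas20_total` and `high_alexithymia` columns are appended
#' too.
#'
#' @param data Data frame with item columns `tas01`..`tas20` or the eight
#'   GAFS-8 columns (`tas01`, `tas02`, `tas06`, `tas09`, `tas11`, `tas12`,
#'   `tas13`, `tas14`).
#' @param method `"map"` or `"eap"`.
#' @inheritParams score_map
#' @return `data` with score columns appended.
#' @export
score_respondents <- function(data, method = c("map", "eap"),
                              bank = gafs8_bank(), prior = latent_dist(0, 1)) {
  method <- match.arg(method)
  cols <- paste0("tas", sprintf("%02d", as.integer(names(bank))))
  if (!all(cols %in% names(data))) {
    stop(sprintf("missing item columns: %s",
                 paste(setdiff(cols, names(data)), collapse = ", ")),
         call. = FALSE)
  }
  scorer <- if (method == "map") score_map else score_eap
  res <- lapply(seq_len(nrow(data)), function(i) {
    scorer(as.numeric(data[i, cols]), bank = bank, prior = prior)
  })
  data$theta_hat <- vapply(res, `[[`, numeric(1), "theta_hat")
  data$se <- vapply(res, `[[`, numeric(1), "posterior_sd")
  data$t_score <- vapply(res, `[[`, numeric(1), "t_score")
  data$reliability <- vapply(res, `[[`, numeric(1), "reliability")
  data$n_items_used <- vapply(res, `[[`, integer(1), "n_items_used")
  tcols <- paste0("tas", sprintf("%02d", 1:20))
  if (all(tcols %in% names(data))) {
    cs <- lapply(seq_len(nrow(data)), function(i) {
      classical_scores(as.numeric(data[i, tcols]))
    })
    data$tas20_total <- vapply(cs, `[[`, numeric(1), "tas20_total")
    data$high_alexithymia <- vapply(cs, `[[`, logical(1), "high_alexithymia")
  }
  data
}

#' Marginal reliability of trait scores under a prior
#'
#' Prior-weighted average of the conditional reliability,
#' `integral r(theta) phi(theta; prior) dtheta`, by fixed-grid quadrature.
#'
#' @inheritParams conditional_reliability
#' @param prior A [latent_dist()].
#' @param n_quadrature Grid size.
#' @return Scalar in \[0, 1\].
#' @export
marginal_reliability <- function(bank = gafs8_bank(),
                                 prior = latent_dist(0, 1),
                                 n_quadrature = 201L) {
  grid <- seq(prior$mu - 6 * prior$sigma, prior$mu + 6 * prior$sigma,
              length.out = n_quadrature)
  w <- stats::dnorm(grid, prior$mu, prior$sigma)
  w <- w / sum(w)
  sum(conditional_reliability(grid, bank, prior_sd = prior$sigma) * w)
}
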