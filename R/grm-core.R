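#' Polytomous item under the logistic graded response model
#'
#' Constructs a single graded-response-model item from a discrimination slope
#' and a vector of ordered intercepts. The model is parameterised on the
#' logistic metric in slope/intercept form: the probability of responding in
#' category `k` or above is `P*_k(theta) = plogis(a * theta + d[k - 1])`, so
#' more positive intercepts correspond to "easier" response categories.
#'
#' @param a Discrimination slope (finite, unitless, logistic metric).
#' @param d Numeric vector of `K - 1` intercepts, strictly decreasing.
#' @param label Item identifier (e.g. a TAS-20 item number).
#' @param K Number of response categories; defaults to `length(d) + 1`.
#'
#' @return An object of class `grm_item`: a list with elements `label`, `a`,
#'   `d` and `K`.
#' @examples
#' it <- grm_item(a = 2.0, d = c(2, 0, -2), label = "demo")
#' category_probabilities(it, theta = 0)
#' @export
grm_item <- function(a, d, label = NA_character_, K = length(d) + 1L) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a)) {
    stop("`a` must be a single finite number", call. = FALSE)
  }
  d <- as.numeric(d)
  if (length(d) < 1L || anyNA(d) || any(!is.finite(d))) {
    stop("`d` must be a finite numeric vector of length K - 1", call. = FALSE)
  }
  if (K != length(d) + 1L) {
    stop("`K` must equal length(d) + 1", call. = FALSE)
  }
  if (K < 2L) stop("items need at least two response categories", call. = FALSE)
  if (length(d) > 1L && any(diff(d) >= 0)) {
    stop("intercepts `d` must be strictly decreasing (d1 > d2 > ...)",
         call. = FALSE)
  }
  structure(list(label = as.character(label), a = a, d = d, K = as.integer(K)),
            class = "grm_item")
}

#' @export
print.grm_item <- function(x, ...) {
  cat(sprintf("<grm_item %s> a = %.3f, d = (%s), K = %d\n",
              x$label, x$a, paste(sprintf("%.3f", x$d), collapse = ", "), x$K))
  invisible(x)
}

#' Collection of graded-response-model items
#'
#' @param items A list of [grm_item()] objects (or a single item).
#' @return An object of class `grm_bank` (a list of `grm_item`s).
#' @export
grm_bank <- function(items) {
  if (inherits(items, "grm_item")) items <- list(items)
  if (!is.list(items) || length(items) == 0L ||
      !all(vapply(items, inherits, logical(1), "grm_item"))) {
    stop("`items` must be a non-empty list of grm_item objects", call. = FALSE)
  }
  labs <- vapply(items, function(i) i$label, character(1))
  if (anyDuplicated(labs[!is.na(labs)])) {
    stop("item labels must be unique", call. = FALSE)
  }
  names(items) <- labs
  structure(items, class = "grm_bank")
}

#' @export
print.grm_bank <- function(x, ...) {
  cat(sprintf("<grm_bank> %d items, K = %s\n", length(x),
              paste(unique(vapply(x, function(i) i$K, integer(1))),
                    collapse = "/")))
  invisible(x)
}

#' @export
as.data.frame.grm_bank <- function(x, ...) {
  Kmax <- max(vapply(x, function(i) i$K, integer(1)))
  out <- data.frame(label = vapply(x, function(i) i$label, character(1)),
                    a = vapply(x, function(i) i$a, numeric(1)),
                    stringsAsFactors = FALSE)
  for (k in seq_len(Kmax - 1L)) {
    out[[paste0("d", k)]] <- vapply(x, function(i) {
      if (k <= length(i$d)) i$d[k] else NA_real_
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Latent trait distribution
#'
#' A normal latent distribution `N(mu, sigma^2)` on the trait metric; the
#' normative reference group is fixed at `latent_dist(0, 1)`.
#'
#' @param mu Mean (trait SD units).
#' @param sigma Standard deviation (must be positive).
#' @return An object of class `latent_dist`.
#' @export
latent_dist <- function(mu = 0, sigma = 1) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
    stop("latent distribution needs finite mu and sigma > 0", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma), class = "latent_dist")
}

#' @export
print.latent_dist <- function(x, ...) {
  cat(sprintf("<latent_dist> N(%.3f, %.3f^2)\n", x$mu, x$sigma))
  invisible(x)
}

.check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) == 0L || anyNA(theta) ||
      any(!is.finite(theta))) {
    stop("`theta` must be finite numeric", call. = FALSE)
  }
  as.numeric(theta)
}

#' Cumulative category probabilities
#'
#' `P*_k(theta) = plogis(a * theta + d_k)`, the probability of responding in
#' category `k + 1` or above, for `k = 1, ..., K - 1`. Non-increasing in `k`
#' because the intercepts are ordered.
#'
#' @param item A [grm_item()].
#' @param theta Latent trait value(s).
#' @return For scalar `theta` a vector of `K - 1` probabilities; otherwise a
#'   `length(theta) x (K - 1)` matrix.
#' @export
cumulative_probabilities <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  theta <- .check_theta(theta)
  ps <- stats::plogis(outer(item$a * theta, item$d, `+`))
  if (length(theta) == 1L) drop(ps) else ps
}

## P* matrix padded with the implicit boundaries P*_0 = 1 and P*_K = 0;
## rows = theta, cols = 0..K
.pstar_padded <- function(item, theta) {
  ps <- stats::plogis(outer(item$a * theta, item$d, `+`))
  cbind(1, ps, 0, deparse.level = 0)
}

#' Category response probabilities (trace lines)
#'
#' `P(k) = P*_{k-1} - P*_k` with boundary conventions `P*_0 = 1`, `P*_K = 0`.
#' The returned values are non-negative and sum to one.
#'
#' @inheritParams cumulative_probabilities
#' @return For scalar `theta` a vector of `K` probabilities; otherwise a
#'   `length(theta) x K` matrix.
#' @export
category_probabilities <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  theta <- .check_theta(theta)
  ps <- .pstar_padded(item, theta)
  pk <- ps[, -ncol(ps), drop = FALSE] - ps[, -1L, drop = FALSE]
  pk[pk < 0] <- 0    # guard against roundoff at extreme theta
  if (length(theta) == 1L) drop(pk) else pk
}

#' Expected item and test scores
#'
#' The expected item score is `ES(theta) = sum_k k * P(k)` on the 1..K
#' response metric; the expected test score sums expected item scores over a
#' bank. Both are monotone non-decreasing in `theta` when all slopes are
#' positive.
#'
#' @inheritParams cumulative_probabilities
#' @param bank A [grm_bank()].
#' @return Numeric vector the length of `theta`.
#' @export
expected_item_score <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  theta <- .check_theta(theta)
  pk <- category_probabilities(item, theta)
  if (is.null(dim(pk))) pk <- matrix(pk, nrow = 1L)
  drop(pk %*% seq_len(item$K))
}

#' @rdname expected_item_score
#' @export
expected_test_score <- function(bank, theta) {
  stopifnot(inherits(bank, "grm_bank"))
  theta <- .check_theta(theta)
  Reduce(`+`, lapply(bank, expected_item_score, theta = theta))
}

#' Item and test information functions
#'
#' Fisher information of the graded response model,
#' `I_j(theta) = sum_k (dP(k)/dtheta)^2 / P(k)`, with the convention that a
#' category with vanishing probability contributes zero. Test information is
#' the sum of item informations.
#'
#' @inheritParams expected_item_score
#' @return Numeric vector the length of `theta` (non-negative).
#' @export
item_information <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  theta <- .check_theta(theta)
  ps <- .pstar_padded(item, theta)
  dps <- item$a * ps * (1 - ps)
  dps[, 1L] <- 0; dps[, ncol(dps)] <- 0
  pk <- ps[, -ncol(ps), drop = FALSE] - ps[, -1L, drop = FALSE]
  dpk <- dps[, -ncol(dps), drop = FALSE] - dps[, -1L, drop = FALSE]
  term <- ifelse(pk > 0, dpk^2 / pk, 0)
  rowSums(term)
}

#' @rdname item_information
#' @export
test_information <- function(bank, theta) {
  stopifnot(inherits(bank, "grm_bank"))
  Reduce(`+`, lapply(bank, item_information, theta = theta))
}

#' Convert between logistic slopes and standardized factor loadings
#'
#' Maps a logistic-metric discrimination slope to the equivalent standardized
#' factor loading of the normal-ogive parameterisation,
#' `lambda = (a/D) / sqrt(1 + (a/D)^2)` with scaling constant `D = 1.702`,
#' together with the communality `h2 = lambda^2`. `loading_to_slope()` is the
#' exact inverse.
#'
#' @param a Numeric vector of slopes.
#' @param lambda Numeric vector of loadings, `|lambda| < 1`.
#' @param D Logistic/normal-ogive scaling constant.
#' @return `slope_to_loading()` returns a data frame with columns `lambda`
#'   and `h2`; `loading_to_slope()` returns a numeric vector of slopes.
#' @examples
#' slope_to_loading(2.802)  # lambda 0.855
#' @export
slope_to_loading <- function(a, D = 1.702) {
  if (any(!is.finite(a))) stop("`a` must be finite", call. = FALSE)
  astar <- a / D
  lambda <- astar / sqrt(1 + astar^2)
  data.frame(lambda = lambda, h2 = lambda^2)
}

#' @rdname slope_to_loading
#' @export
loading_to_slope <- function(lambda, D = 1.702) {
  if (any(!is.finite(lambda)) || any(abs(lambda) >= 1)) {
    stop("loadings must satisfy |lambda| < 1", call. = FALSE)
  }
  D * lambda / sqrt(1 - lambda^2)
}

#' Categories that are modal somewhere on a trait grid
#'
#' Returns the set of response categories that are the strictly most probable
#' response at some point of `theta_grid`. Ties are not counted as modal.
#' Used to detect underutilised (never-modal) middle response options.
#'
#' @param item A [grm_item()].
#' @param theta_grid Numeric grid; must span at least \[-6, 6\].
#' @return Sorted integer vector of modal categories.
#' @export
modal_category_set <- function(item, theta_grid = seq(-6, 6, by = 0.01)) {
  stopifnot(inherits(item, "grm_item"))
  if (length(theta_grid) == 0L) stop("empty theta grid", call. = FALSE)
  if (min(theta_grid) > -6 || max(theta_grid) < 6) {
    stop("`theta_grid` must span at least [-6, 6]", call. = FALSE)
  }
  pk <- category_probabilities(item, theta_grid)
  mx <- apply(pk, 1L, max)
  modal <- apply(pk, 1L, which.max)
  strict <- rowSums(pk == mx) == 1L
  sort(unique(modal[strict]))
}

#' Read or write an item bank as delimited text
#'
#' Banks round-trip through CSV with columns `label`, `a`, `d1`, `d2`, ...
#'
#' @param path File path.
#' @param bank A [grm_bank()].
#' @return `read_bank()` returns a `grm_bank`; `write_bank()` invisibly
#'   returns `path`.
#' @export
read_bank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "a", "d1")
  if (!all(need %in% names(df))) {
    stop("bank file must have columns label, a, d1, ...", call. = FALSE)
  }
  dcols <- grep("^d[0-9]+$", names(df), value = TRUE)
  dcols <- dcols[order(as.integer(sub("^d", "", dcols)))]
  items <- lapply(seq_len(nrow(df)), function(i) {
    d <- as.numeric(df[i, dcols])
    d <- d[!is.na(d)]
    grm_item(a = df$a[i], d = d, label = df$label[i])
  })
  grm_bank(items)
}

#' @rdname read_bank
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "grm_bank"))
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE)
  invisible(path)
}

#' Published GAFS-8 calibration
#'
#' The embedded graded-response-model parameters of the eight GAFS-8 items
#' (TAS-20 items 1, 2, 6, 9, 11, 12, 13, 14), estimated by maximum marginal
#' likelihood in a two-group model in which the general-population group's
#' latent trait was fixed to mean 0, SD 1 and item parameters were constrained
#' equal across groups. Latent trait scores against this calibration are
#' therefore Z-scores relative to the general adult population.
#'
#' The attached group densities are the normative reference, `N(0, 1)`, and
#' the clinical (autistic) group's latent density. The published calibration
#' reports the clinical group's score-level moments, mean 1.01 and SD 1.17,
#' together with a marginal reliability of 0.895; because MAP scores shrink
#' toward the prior mean by the reliability factor
#' (`Var(theta_hat) ~ rho * sigma^2`), the latent SD is recovered as
#' `1.17 / sqrt(0.895) ~ 1.237`. Scoring the all-lowest and all-highest
#' response patterns under this clinical density reproduces the published
#' score bounds of approximately -2.19 and 3.52.
#'
#' @return A [grm_bank()] of 8 items with an attribute `groups`, a named list
#'   of [latent_dist()] objects (`normative`, `clinical`).
#' @export
gafs8_bank <- function() {
  pars <- list(
    `1`  = list(a = 2.802, d = c(3.092, -0.689, -2.740, -6.336)),
    `2`  = list(a = 2.190, d = c(3.478,  0.491, -0.931, -3.841)),
    `6`  = list(a = 2.335, d = c(2.090, -0.805, -2.413, -5.497)),
    `9`  = list(a = 2.402, d = c(3.137,  0.072, -1.434, -5.170)),
    `11` = list(a = 1.870, d = c(2.745, -0.234, -1.505, -4.340)),
    `12` = list(a = 1.235, d = c(1.739, -0.526, -1.636, -3.644)),
    `13` = list(a = 1.892, d = c(2.054, -0.646, -2.231, -4.771)),
    `14` = list(a = 1.538, d = c(1.285, -1.133, -2.201, -4.361)))
  bank <- grm_bank(lapply(names(pars), function(nm) {
    grm_item(a = pars[[nm]]$a, d = pars[[nm]]$d, label = nm)
  }))
  attr(bank, "groups") <- list(
    normative = latent_dist(0, 1),
    clinical  = latent_dist(1.01, 1.17 / sqrt(0.895)))
  bank
}

#' TAS-20 item sets used throughout the package
#'
#' Standard item-number sets for the TAS-20: the three subscales (DIF =
#' difficulty identifying feelings, DDF = difficulty describing feelings,
#' EOT = externally oriented thinking), the reverse-coded items, and the
#' eight GAFS-8 items.
#'
#' @return A named list of integer vectors.
#' @export
tas20_item_sets <- function() {
  list(dif = c(1L, 3L, 6L, 7L, 9L, 13L, 14L),
       ddf = c(2L, 4L, 11L, 12L, 17L),
       eot = c(5L, 8L, 10L, 15L, 16L, 18L, 19L, 20L),
       reverse = c(4L, 5L, 10L, 18L, 19L),
       gafs8 = c(1L, 2L, 6L, 9L, 11L, 12L, 13L, 14L))
}
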