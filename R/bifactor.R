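## ---------------------------------------------------------------------------
## Model-based bifactor coefficients: PUC, the ECV family, and Green-Yang
## categorical omega coefficients, plus the polychoric correlation and the
## bivariate-normal CDF they rest on.
## ---------------------------------------------------------------------------

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1L)] <- b
  Jm[cbind(i + 1L, i)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
}

#' Standard bivariate normal CDF
#'
#' `P(Z1 <= a, Z2 <= b)` for standard normal margins with correlation `rho`,
#' by Gauss-Legendre quadrature of Plackett's identity
#' `Phi2(a, b, rho) = Phi(a) Phi(b) + integral_0^rho phi2(a, b, r) dr`.
#' Infinite bounds are handled by reduction to the univariate CDF.
#'
#' @param a,b Upper limits (may be `-Inf`/`Inf`).
#' @param rho Correlation, `|rho| < 1`.
#' @param n_nodes Quadrature size.
#' @return Probability in \[0, 1\].
#' @export
bvnorm_cdf <- function(a, b, rho, n_nodes = 32L) {
  if (!is.finite(rho) || abs(rho) >= 1) {
    if (isTRUE(all.equal(rho, 1)))  return(stats::pnorm(min(a, b)))
    if (isTRUE(all.equal(rho, -1))) return(max(stats::pnorm(a) + stats::pnorm(b) - 1, 0))
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  }
  if (is.infinite(a) && a < 0 || is.infinite(b) && b < 0) return(0)
  if (is.infinite(a)) return(stats::pnorm(b))
  if (is.infinite(b)) return(stats::pnorm(a))
  if (rho == 0) return(stats::pnorm(a) * stats::pnorm(b))
  gl <- .gauss_legendre(n_nodes)
  r <- rho / 2 * (gl$nodes + 1)
  dens <- exp(-(a^2 - 2 * r * a * b + b^2) / (2 * (1 - r^2))) /
    (2 * pi * sqrt(1 - r^2))
  stats::pnorm(a) * stats::pnorm(b) + rho / 2 * sum(gl$weights * dens)
}

#' Bifactor loading/threshold structure
#'
#' Describes a confirmatory bifactor measurement model: every item loads on
#' one general factor; each item may additionally load on at most one
#' specific (subscale) factor and on one method factor (e.g. a reverse-coded
#' wording factor). All factors are orthogonal. Thresholds are probit-scale
#' cut points of the categorised latent response.
#'
#' Loadings and thresholds may be omitted (`NA`) when only the membership
#' pattern is needed (as for [puc()]).
#'
#' @param items Item labels.
#' @param lambda_general General-factor loadings (or `NA`).
#' @param specific Specific-factor membership per item (character or `NA`).
#' @param lambda_specific Specific-factor loadings.
#' @param method Method-factor membership per item (character, logical or
#'   `NA`).
#' @param lambda_method Method-factor loadings.
#' @param thresholds Optional J x (K-1) matrix of strictly increasing probit
#'   thresholds.
#' @return An object of class `bifactor_structure`.
#' @export
bifactor_structure <- function(items, lambda_general = NA_real_,
                               specific = NA_character_,
                               lambda_specific = 0,
                               method = NA_character_,
                               lambda_method = 0,
                               thresholds = NULL) {
  J <- length(items)
  if (J < 1L) stop("need at least one item", call. = FALSE)
  lg <- rep_len(as.numeric(lambda_general), J)
  sp <- rep_len(as.character(specific), J)
  ls <- rep_len(as.numeric(lambda_specific), J)
  if (is.logical(method)) method <- ifelse(method, "method", NA_character_)
  mt <- rep_len(as.character(method), J)
  lm <- rep_len(as.numeric(lambda_method), J)
  ls[is.na(sp)] <- 0
  lm[is.na(mt)] <- 0
  h2 <- lg^2 + ls^2 + lm^2
  if (any(!is.na(h2) & h2 > 1 + 1e-10)) {
    stop("item communality exceeds 1", call. = FALSE)
  }
  if (!is.null(thresholds)) {
    thresholds <- as.matrix(thresholds)
    if (nrow(thresholds) != J) {
      stop("`thresholds` must have one row per item", call. = FALSE)
    }
    if (any(apply(thresholds, 1L, function(t) any(diff(t) <= 0)))) {
      stop("thresholds must be strictly increasing per item", call. = FALSE)
    }
  }
  structure(list(items = as.character(items), lambda_general = lg,
                 specific = sp, lambda_specific = ls,
                 method = mt, lambda_method = lm,
                 thresholds = thresholds),
            class = "bifactor_structure")
}

#' @export
print.bifactor_structure <- function(x, ...) {
  cat(sprintf("<bifactor_structure> %d items; specific factors: %s; method factors: %s\n",
              length(x$items),
              paste(unique(stats::na.omit(x$specific)), collapse = ", "),
              paste(unique(stats::na.omit(x$method)), collapse = ", ")))
  invisible(x)
}

#' Percentage of uncontaminated correlations (PUC)
#'
#' The proportion of item pairs whose correlation is informed only by the
#' general factor. A pair is contaminated if the two items share any
#' non-general factor -- a common specific (subscale) factor or a common
#' method factor. Computed by direct pair enumeration.
#'
#' @param structure A [bifactor_structure()] (loadings not required).
#' @return Proportion in \[0, 1\].
#' @examples
#' # three items in one subscale, one stand-alone
#' s <- bifactor_structure(1:4, specific = c("A", "A", "A", NA))
#' puc(s)  # 1 - 3/6
#' @export
puc <- function(structure) {
  stopifnot(inherits(structure, "bifactor_structure"))
  J <- length(structure$items)
  if (J < 2L) stop("PUC needs at least 2 items", call. = FALSE)
  contaminated <- 0L
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      shares <- (!is.na(structure$specific[i]) &&
                   !is.na(structure$specific[j]) &&
                   structure$specific[i] == structure$specific[j]) ||
        (!is.na(structure$method[i]) && !is.na(structure$method[j]) &&
           structure$method[i] == structure$method[j])
      if (shares) contaminated <- contaminated + 1L
    }
  }
  1 - contaminated / choose(J, 2)
}

#' Explained common variance (ECV) family
#'
#' `ECV = sum(lambda_G^2) / (sum(lambda_G^2) + sum(lambda_spec^2) +
#' sum(lambda_method^2))`, the share of common variance carried by the
#' general factor; `item_ECV` applies the same ratio item-wise and `S_ECV`
#' over the items of each specific factor.
#'
#' @param structure A [bifactor_structure()] with loadings.
#' @return A list with `ECV`, `item_ECV` (named) and `S_ECV` (named, per
#'   specific factor).
#' @export
ecv <- function(structure) {
  stopifnot(inherits(structure, "bifactor_structure"))
  lg2 <- structure$lambda_general^2
  gr2 <- structure$lambda_specific^2 + structure$lambda_method^2
  if (anyNA(lg2)) stop("loadings are required for ECV", call. = FALSE)
  if (sum(lg2 + gr2) == 0) stop("all loadings are zero", call. = FALSE)
  item <- ifelse(lg2 + gr2 > 0, lg2 / (lg2 + gr2), NA_real_)
  names(item) <- structure$items
  subs <- unique(stats::na.omit(structure$specific))
  secv <- vapply(subs, function(s) {
    idx <- which(!is.na(structure$specific) & structure$specific == s)
    sum(lg2[idx]) / sum(lg2[idx] + gr2[idx])
  }, numeric(1))
  list(ECV = sum(lg2) / sum(lg2 + gr2), item_ECV = item, S_ECV = secv)
}

## covariance of two categorised standard-normal variables with latent
## correlation rho and probit thresholds tau_i, tau_j
.cat_cov <- function(tau_i, tau_j, rho) {
  s <- 0
  for (k in seq_along(tau_i)) {
    for (l in seq_along(tau_j)) {
      s <- s + bvnorm_cdf(tau_i[k], tau_j[l], rho) -
        stats::pnorm(tau_i[k]) * stats::pnorm(tau_j[l])
    }
  }
  s
}

#' Green-Yang categorical omega coefficients
#'
#' Model-based reliability of sum scores built from ordinal items, using the
#' categorical-data construction: expected covariances between categorised
#' items are obtained from bivariate-normal probabilities over the implied
#' latent correlations, and omega is the ratio of the targeted true-score
#' variance of the sum score to its total variance.
#'
#' * `total`: all common factors in the numerator (reliability of the
#'   multidimensional total score);
#' * `hierarchical`: general factor only (general-factor saturation);
#' * `subscale`: per specific factor, general + specific over the subscale's
#'   items;
#' * `hier_subscale`: per specific factor, the specific factor only.
#'
#' @param structure A [bifactor_structure()] with loadings and thresholds.
#' @param which Coefficient flavour.
#' @return A scalar (`total`, `hierarchical`) or named vector per subscale.
#' @export
omega_categorical <- function(structure,
                              which = c("total", "hierarchical",
                                        "subscale", "hier_subscale")) {
  which <- match.arg(which)
  stopifnot(inherits(structure, "bifactor_structure"))
  if (is.null(structure$thresholds) || anyNA(structure$lambda_general)) {
    stop("loadings and thresholds are required for omega", call. = FALSE)
  }
  lg <- structure$lambda_general
  ls <- structure$lambda_specific
  lm <- structure$lambda_method
  sp <- structure$specific
  mt <- structure$method
  tau <- structure$thresholds
  J <- length(lg)

  common_rho <- function(i, j, general_only = FALSE, specific_only = FALSE) {
    if (specific_only) {
      r <- ls[i] * ls[j] *
        as.numeric(!is.na(sp[i]) && !is.na(sp[j]) && sp[i] == sp[j])
      if (i == j) r <- ls[i]^2
      return(r)
    }
    r <- lg[i] * lg[j]
    if (!general_only) {
      if (!is.na(sp[i]) && !is.na(sp[j]) && sp[i] == sp[j]) r <- r + ls[i] * ls[j]
      if (!is.na(mt[i]) && !is.na(mt[j]) && mt[i] == mt[j]) r <- r + lm[i] * lm[j]
    }
    r
  }
  ## implied latent correlation matrix must be admissible
  R <- diag(J)
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) R[i, j] <- R[j, i] <- common_rho(i, j)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("implied latent correlation matrix is not positive semi-definite",
         call. = FALSE)
  }

  omega_for <- function(idx, general_only = FALSE, specific_only = FALSE) {
    num <- 0; den <- 0
    for (i in idx) {
      for (j in idx) {
        rho_t <- common_rho(i, j, general_only, specific_only)
        if (i == j && !general_only && !specific_only) {
          rho_t <- lg[i]^2 + ls[i]^2 + lm[i]^2
        }
        if (i == j && general_only) rho_t <- lg[i]^2
        num <- num + .cat_cov(tau[i, ], tau[j, ], rho_t)
        den <- den + if (i == j) .cat_cov(tau[i, ], tau[i, ], 1)
                     else .cat_cov(tau[i, ], tau[j, ], common_rho(i, j))
      }
    }
    num / den
  }

  if (which == "total") return(omega_for(seq_len(J)))
  if (which == "hierarchical") return(omega_for(seq_len(J), general_only = TRUE))
  subs <- unique(stats::na.omit(sp))
  out <- vapply(subs, function(s) {
    idx <- which(!is.na(sp) & sp == s)
    if (which == "subscale") omega_for(idx)
    else omega_for(idx, specific_only = TRUE)
  }, numeric(1))
  out
}

#' All bifactor indices at once
#'
#' @param structure A [bifactor_structure()].
#' @return A list of class `bifactor_indices` with `omega_T`, `omega_H`,
#'   `omega_S`, `omega_HS`, `ECV`, `item_ECV`, `S_ECV` and `PUC` (omegas are
#'   `NA` when thresholds are absent).
#' @export
bifactor_indices <- function(structure) {
  e <- ecv(structure)
  has_tau <- !is.null(structure$thresholds)
  structure(list(
    omega_T = if (has_tau) omega_categorical(structure, "total") else NA_real_,
    omega_H = if (has_tau) omega_categorical(structure, "hierarchical") else NA_real_,
    omega_S = if (has_tau) omega_categorical(structure, "subscale") else NULL,
    omega_HS = if (has_tau) omega_categorical(structure, "hier_subscale") else NULL,
    ECV = e$ECV, item_ECV = e$item_ECV, S_ECV = e$S_ECV,
    PUC = puc(structure)), class = "bifactor_indices")
}

#' @export
print.bifactor_indices <- function(x, ...) {
  cat(sprintf("<bifactor_indices> ECV = %.3f, PUC = %.1f%%", x$ECV,
              100 * x$PUC))
  if (!is.na(x$omega_T)) {
    cat(sprintf(", omega_T = %.3f, omega_H = %.3f", x$omega_T, x$omega_H))
  }
  cat("\n")
  invisible(x)
}

#' TAS-20 bifactor membership structures
#'
#' `tas20_bifactor_structure()` gives the full 20-item membership pattern:
#' three specific factors (DIF, DDF, EOT subscales) plus a method factor on
#' the reverse-coded items (4, 5, 10, 18, 19). With the contamination rule
#' that a pair sharing any non-general factor is contaminated, its PUC is
#' 66.8%. `tas11_bifactor_structure()` is the reduced 11-item form (7 DIF +
#' 4 forward-coded DDF items) with PUC 50.9%. Loadings are not embedded;
#' supply them (e.g. from a confirmatory fit or the synthetic generator) for
#' ECV/omega computations.
#'
#' @return A [bifactor_structure()] without loadings.
#' @export
tas20_bifactor_structure <- function() {
  sets <- tas20_item_sets()
  items <- 1:20
  spec <- character(20)
  spec[sets$dif] <- "DIF"; spec[sets$ddf] <- "DDF"; spec[sets$eot] <- "EOT"
  meth <- rep(NA_character_, 20)
  meth[sets$reverse] <- "REV"
  bifactor_structure(items, specific = spec, method = meth)
}

#' @rdname tas20_bifactor_structure
#' @export
tas11_bifactor_structure <- function() {
  sets <- tas20_item_sets()
  items <- sort(c(sets$dif, setdiff(sets$ddf, sets$reverse)))
  spec <- ifelse(items %in% sets$dif, "DIF", "DDF")
  bifactor_structure(items, specific = spec)
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimator: probit thresholds from the inverse-normal marginal
#' proportions, then the latent correlation by one-dimensional likelihood
#' maximisation over the bivariate-normal cell probabilities.
#'
#' @param x,y Integer-coded ordinal vectors (each with at least 2 observed
#'   categories).
#' @return Correlation estimate in (-1, 1).
#' @export
polychoric <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.integer(factor(x[ok])); y <- as.integer(factor(y[ok]))
  if (length(x) < 10L) stop("too few paired observations", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("degenerate margins: need at least 2 observed categories each",
         call. = FALSE)
  }
  tab <- table(x, y)
  taux <- c(-Inf, stats::qnorm(cumsum(rowSums(tab)) / sum(tab)))
  tauy <- c(-Inf, stats::qnorm(cumsum(colSums(tab)) / sum(tab)))
  taux[length(taux)] <- Inf; tauy[length(tauy)] <- Inf
  nr <- nrow(tab); nc <- ncol(tab)
  negll <- function(rho) {
    ll <- 0
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        if (tab[i, j] == 0) next
        pij <- bvnorm_cdf(taux[i + 1L], tauy[j + 1L], rho) -
          bvnorm_cdf(taux[i], tauy[j + 1L], rho) -
          bvnorm_cdf(taux[i + 1L], tauy[j], rho) +
          bvnorm_cdf(taux[i], tauy[j], rho)
        ll <- ll + tab[i, j] * log(max(pij, 1e-12))
      }
    }
    -ll
  }
  stats::optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)$minimum
}
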