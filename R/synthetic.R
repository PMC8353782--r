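## ---------------------------------------------------------------------------
## Synthetic data: two-group graded-response samples (optionally with
## injected DIF), bifactor ordinal data, and external covariates with
## controlled correlation structure.
## ---------------------------------------------------------------------------

#' Simulation configuration for two-group graded-response data
#'
#' The default scenario emulates a clinical/normative two-sample design:
#' normative group latent trait `N(0, 1)` with n = 721 and clinical group
#' `N(1.01, 1.17^2)` with n = 743, responding to the embedded GAFS-8
#' calibration. DIF can be injected per item and group as a uniform
#' intercept shift (`d_shift`, positive = easier for that group) and/or a
#' slope multiplier (`a_mult`); shifts must preserve the intercept ordering.
#'
#' @param bank A [grm_bank()].
#' @param groups Named list; each element a list with `dist` (a
#'   [latent_dist()]) and `n`.
#' @param dif Optional named list: item label -> list(group =, d_shift =,
#'   a_mult =).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(bank = gafs8_bank(),
                       groups = list(
                         normative = list(dist = latent_dist(0, 1), n = 721L),
                         clinical = list(dist = latent_dist(1.01, 1.17), n = 743L)),
                       dif = NULL, seed = 20210810L) {
  stopifnot(inherits(bank, "grm_bank"))
  for (g in groups) {
    if (!inherits(g$dist, "latent_dist") || !is.numeric(g$n) || g$n < 1) {
      stop("each group needs a latent_dist and n > 0", call. = FALSE)
    }
  }
  if (!is.null(dif)) {
    bad <- setdiff(names(dif), names(bank))
    if (length(bad)) {
      stop(sprintf("DIF spec for unknown item(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (nm in names(dif)) {
      sp <- dif[[nm]]
      if (!sp$group %in% names(groups)) {
        stop("DIF spec names an unknown group", call. = FALSE)
      }
      a_mult <- if (is.null(sp$a_mult)) 1 else sp$a_mult
      if (a_mult <= 0) stop("`a_mult` must be positive", call. = FALSE)
      d_shift <- if (is.null(sp$d_shift)) 0 else sp$d_shift
      d_new <- bank[[nm]]$d * a_mult + d_shift   # shift applied after scaling
      if (any(diff(d_new) >= 0)) {
        stop(sprintf("DIF shift for item %s breaks the intercept ordering", nm),
             call. = FALSE)
      }
    }
  }
  structure(list(bank = bank, groups = groups, dif = dif,
                 seed = as.integer(seed)), class = "sim_config")
}

.shifted_bank <- function(config, group_name) {
  bank <- config$bank
  if (is.null(config$dif)) return(bank)
  items <- lapply(bank, function(it) it)
  for (nm in names(config$dif)) {
    sp <- config$dif[[nm]]
    if (sp$group != group_name) next
    a_mult <- if (is.null(sp$a_mult)) 1 else sp$a_mult
    d_shift <- if (is.null(sp$d_shift)) 0 else sp$d_shift
    it <- items[[nm]]
    items[[nm]] <- grm_item(a = it$a * a_mult, d = it$d * a_mult + d_shift,
                            label = it$label)
  }
  grm_bank(items)
}

#' Simulate graded responses from a configuration
#'
#' Draws each respondent's latent trait from their group's distribution and
#' samples item categories from the (possibly DIF-shifted) bank's category
#' probabilities. Fully reproducible under the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_responses`: `data` (integer matrix with item
#'   labels as columns), `group` (factor), `theta` (true latent values),
#'   `config`.
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rows <- list(); grp <- list(); ths <- list()
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    bank <- .shifted_bank(config, gname)
    th <- stats::rnorm(g$n, g$dist$mu, g$dist$sigma)
    X <- matrix(NA_integer_, g$n, length(bank))
    for (j in seq_along(bank)) {
      pk <- category_probabilities(bank[[j]], th)
      cum <- t(apply(pk, 1L, cumsum))
      u <- stats::runif(g$n)
      X[, j] <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
    }
    rows[[gname]] <- X; grp[[gname]] <- rep(gname, g$n); ths[[gname]] <- th
  }
  data <- do.call(rbind, rows)
  colnames(data) <- names(config$bank)
  structure(list(data = data,
                 group = factor(unlist(grp), levels = names(config$groups)),
                 theta = unlist(ths), config = config),
            class = "sim_responses")
}

#' Simulate ordinal data from a bifactor structure
#'
#' Draws independent standard-normal general, specific and method factors,
#' forms each item's continuous response as the loading-weighted factor sum
#' plus normal residual, and discretises at the structure's thresholds.
#'
#' @param structure A [bifactor_structure()] with loadings and thresholds.
#' @param n Number of respondents (> 0).
#' @param seed Integer seed.
#' @return Integer matrix n x J of categories 1..K.
#' @export
simulate_bifactor_ordinal <- function(structure, n, seed = 1L) {
  stopifnot(inherits(structure, "bifactor_structure"))
  if (!is.numeric(n) || n < 1) stop("`n` must be positive", call. = FALSE)
  if (is.null(structure$thresholds) || anyNA(structure$lambda_general)) {
    stop("loadings and thresholds are required", call. = FALSE)
  }
  h2 <- structure$lambda_general^2 + structure$lambda_specific^2 +
    structure$lambda_method^2
  if (any(h2 > 1 + 1e-10)) stop("communality exceeds 1", call. = FALSE)
  set.seed(seed)
  J <- length(structure$items)
  G <- stats::rnorm(n)
  subs <- unique(stats::na.omit(structure$specific))
  meths <- unique(stats::na.omit(structure$method))
  Fs <- matrix(stats::rnorm(n * length(subs)), n)
  Fm <- matrix(stats::rnorm(n * length(meths)), n)
  X <- matrix(NA_integer_, n, J)
  for (j in seq_len(J)) {
    z <- structure$lambda_general[j] * G
    if (!is.na(structure$specific[j])) {
      z <- z + structure$lambda_specific[j] *
        Fs[, match(structure$specific[j], subs)]
    }
    if (!is.na(structure$method[j])) {
      z <- z + structure$lambda_method[j] *
        Fm[, match(structure$method[j], meths)]
    }
    z <- z + stats::rnorm(n, 0, sqrt(max(1 - h2[j], 0)))
    X[, j] <- 1L + rowSums(outer(z, structure$thresholds[j, ], `>`))
  }
  colnames(X) <- structure$items
  X
}

#' Simulate external covariates with target correlations to a trait
#'
#' Builds each covariate as `a * theta + b * confounder + noise`, where the
#' confounder itself correlates with the trait at `confounder_r` (a
#' neuroticism-like variable). Coefficients are solved so that, in
#' expectation, the covariate's zero-order correlation with the trait equals
#' the target and a fraction `share` of that association runs through the
#' confounder (so `share = 1` gives a fully confounder-mediated covariate
#' whose partial correlation given the confounder is zero).
#'
#' @param theta Trait values (standardised internally).
#' @param targets Named numeric vector of target zero-order correlations
#'   (`|r| < 1`).
#' @param confounder_share Fraction(s) in \[0, 1\] of each association
#'   mediated by the confounder (recycled).
#' @param confounder_r Trait-confounder correlation.
#' @param seed Integer seed.
#' @return Data frame with the confounder and one column per target.
#' @export
simulate_covariates <- function(theta, targets, confounder_share = 0,
                                confounder_r = 0.475, seed = 1L) {
  if (any(abs(targets) >= 1)) stop("target correlations must satisfy |r| < 1",
                                   call. = FALSE)
  if (abs(confounder_r) >= 1) stop("|confounder_r| must be < 1", call. = FALSE)
  set.seed(seed)
  n <- length(theta)
  z <- as.numeric(scale(theta))
  conf <- confounder_r * z + sqrt(1 - confounder_r^2) * stats::rnorm(n)
  share <- rep_len(confounder_share, length(targets))
  out <- data.frame(confounder = conf)
  for (i in seq_along(targets)) {
    r <- targets[i]; s <- share[i]
    b <- if (confounder_r == 0 && s > 0) {
      stop("cannot mediate through an uncorrelated confounder", call. = FALSE)
    } else if (s == 0) 0 else s * r / confounder_r
    a <- (1 - s) * r
    v_eps <- 1 - a^2 - b^2 - 2 * a * b * confounder_r
    if (v_eps <= 0) {
      stop(sprintf("infeasible correlation system for target '%s'",
                   names(targets)[i]), call. = FALSE)
    }
    out[[names(targets)[i]]] <- a * z + b * conf +
      sqrt(v_eps) * stats::rnorm(n)
  }
  out
}
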