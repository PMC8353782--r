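## ---------------------------------------------------------------------------
## Limited-information model fit: the C2 statistic built from univariate
## category margins plus one cross-product moment per item pair, with
## C2-based approximate fit indices, SRMR over residual correlations, and
## model-implied inter-item correlations.
## ---------------------------------------------------------------------------

## Moment system: each moment is a set of items and a per-category value
## vector per item; its model-implied expectation is
## sum_q w_q prod_j f_j' P_j(.|theta_q).
.moment_system <- function(K) {
  J <- length(K)
  mom <- list()
  for (j in seq_len(J)) {
    for (k in 2:K[j]) {
      f <- numeric(K[j]); f[k] <- 1
      mom[[length(mom) + 1L]] <- list(items = j, fns = list(f))
    }
  }
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      mom[[length(mom) + 1L]] <-
        list(items = c(i, j), fns = list(seq_len(K[i]), seq_len(K[j])))
    }
  }
  mom
}

## Per-item conditional expectations E[f(x_j) | theta_q] for all moments
.implied_moments <- function(mom, pmats, w) {
  vapply(mom, function(m) {
    e <- rep(1, length(w))
    for (t in seq_along(m$items)) {
      e <- e * drop(crossprod(m$fns[[t]], pmats[[m$items[t]]]))
    }
    sum(w * e)
  }, numeric(1))
}

## Model-implied covariance matrix of the sample moment vector
.moment_cov <- function(mom, pmats, w, mu) {
  M <- length(mom)
  ## cache per-moment conditional expectation profiles
  prof <- lapply(mom, function(m) {
    e <- rep(1, length(w))
    for (t in seq_along(m$items)) {
      e <- e * drop(crossprod(m$fns[[t]], pmats[[m$items[t]]]))
    }
    e
  })
  Xi <- matrix(0, M, M)
  for (r in seq_len(M)) {
    for (s in r:M) {
      mr <- mom[[r]]; ms <- mom[[s]]
      shared <- intersect(mr$items, ms$items)
      if (length(shared) == 0L) {
        e <- prof[[r]] * prof[[s]]
      } else {
        items <- union(mr$items, ms$items)
        e <- rep(1, length(w))
        for (j in items) {
          ir <- match(j, mr$items); is <- match(j, ms$items)
          f <- NULL
          if (!is.na(ir)) f <- mr$fns[[ir]]
          if (!is.na(is)) f <- if (is.null(f)) ms$fns[[is]] else f * ms$fns[[is]]
          e <- e * drop(crossprod(f, pmats[[j]]))
        }
      }
      Exy <- sum(w * e)
      Xi[r, s] <- Xi[s, r] <- Exy - mu[r] * mu[s]
    }
  }
  Xi
}

.sample_moments <- function(mom, x) {
  vapply(mom, function(m) {
    v <- rep(1, nrow(x))
    for (t in seq_along(m$items)) v <- v * m$fns[[t]][x[, m$items[t]]]
    mean(v)
  }, numeric(1))
}

## Fit the independence baseline (slopes 0, intercepts from margins MLE)
.baseline_pars <- function(x, K) {
  lapply(seq_len(ncol(x)), function(j) {
    xs <- x[, j]
    d <- vapply(seq_len(K[j] - 1L), function(k) {
      stats::qlogis(min(max(mean(xs > k), 1e-4), 1 - 1e-4))
    }, numeric(1))
    for (k in seq_along(d)[-1L]) if (d[k] >= d[k - 1L]) d[k] <- d[k - 1L] - 1e-6
    list(a = 0, d = d)
  })
}

.c2_statistic <- function(x, pars, K, nodes, w, free_slopes = TRUE) {
  J <- length(K)
  mom <- .moment_system(K)
  pmats <- lapply(seq_len(J), function(j) .pmat(pars[[j]]$a, pars[[j]]$d, nodes))
  mu <- .implied_moments(mom, pmats, w)
  Xi <- .moment_cov(mom, pmats, w, mu)
  ehat <- .sample_moments(mom, x) - mu

  ## Jacobian of implied moments wrt free item parameters
  h <- 1e-5
  cols <- list()
  for (j in seq_len(J)) {
    npar <- if (free_slopes) K[j] else K[j] - 1L
    for (t in seq_len(npar)) {
      pj <- pars[[j]]
      v <- c(pj$a, pj$d)
      off <- if (free_slopes) t else t + 1L
      vp <- v; vp[off] <- v[off] + h
      vm <- v; vm[off] <- v[off] - h
      pp <- pmats; pp[[j]] <- .pmat(vp[1L], vp[-1L], nodes)
      pm <- pmats; pm[[j]] <- .pmat(vm[1L], vm[-1L], nodes)
      cols[[length(cols) + 1L]] <-
        (.implied_moments(mom, pp, w) - .implied_moments(mom, pm, w)) / (2 * h)
    }
  }
  Delta <- do.call(cbind, cols)

  M <- length(mom)
  p <- ncol(Delta)
  df <- M - p
  if (df <= 0L) {
    return(list(C2 = NA_real_, df = df, p = NA_real_, flagged = TRUE))
  }
  XiI <- tryCatch(solve(Xi), error = function(e) {
    solve(Xi + diag(1e-10, M))
  })
  A <- crossprod(Delta, XiI %*% Delta)
  W <- XiI - XiI %*% Delta %*% solve(A, crossprod(Delta, XiI))
  C2 <- nrow(x) * drop(crossprod(ehat, W %*% ehat))
  list(C2 = C2, df = df, p = stats::pchisq(C2, df, lower.tail = FALSE),
       flagged = FALSE)
}

## Model-implied Pearson correlations of the integer item scores
.implied_score_corr <- function(pars, K, nodes, w) {
  J <- length(K)
  pmats <- lapply(seq_len(J), function(j) .pmat(pars[[j]]$a, pars[[j]]$d, nodes))
  Em <- vapply(seq_len(J), function(j) {
    sum(w * drop(crossprod(seq_len(K[j]), pmats[[j]])))
  }, numeric(1))
  Em2 <- vapply(seq_len(J), function(j) {
    sum(w * drop(crossprod(seq_len(K[j])^2, pmats[[j]])))
  }, numeric(1))
  V <- Em2 - Em^2
  R <- diag(J)
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      Exy <- sum(w * drop(crossprod(seq_len(K[i]), pmats[[i]])) *
                   drop(crossprod(seq_len(K[j]), pmats[[j]])))
      R[i, j] <- R[j, i] <- (Exy - Em[i] * Em[j]) / sqrt(V[i] * V[j])
    }
  }
  R
}

#' Limited-information fit assessment for a graded response model
#'
#' Computes the C2 statistic from univariate category margins plus one
#' cross-product moment per item pair (degrees of freedom: number of margins
#' minus free item parameters), the C2-based comparative fit index against an
#' independence baseline, `RMSEA_C2 = sqrt(max(C2 - df, 0) / (df * n))`, the
#' SRMR over residual correlations, the matrix of observed-minus-implied
#' inter-item Pearson correlations, and the information-based marginal
#' reliability. Residual correlations above 0.1 in absolute value are the
#' conventional screen for local dependence.
#'
#' Rows with missing responses are dropped (the margins require complete
#' patterns). With two items the model is saturated and `df <= 0` is flagged
#' with the chi-square indices undefined.
#'
#' @param fit A single-group `grm_fit`.
#' @return An object of class `grm_fitstats`: `C2`, `df`, `p`, `CFI_C2`,
#'   `RMSEA_C2`, `SRMR`, `residual_correlations`, `marginal_reliability`,
#'   `loglik`, `n`, `flagged`.
#' @export
limited_info_fit <- function(fit) {
  if (!inherits(fit, "grm_fit")) {
    stop("limited_info_fit() expects a single-group grm_fit", call. = FALSE)
  }
  em <- fit$em
  x <- em$x
  cc <- stats::complete.cases(x)
  if (!all(cc)) {
    warning(sprintf("%d incomplete rows dropped for margin-based fit",
                    sum(!cc)), call. = FALSE)
    x <- x[cc, , drop = FALSE]
  }
  n <- nrow(x)
  K <- em$K
  nodes <- em$nodes
  w <- .latent_weights(nodes, 0, 1)
  pars <- lapply(seq_len(ncol(x)), function(j) em$pars[[em$set_id[j, 1L]]])

  main <- .c2_statistic(x, pars, K, nodes, w, free_slopes = TRUE)
  if (!main$flagged) {
    base <- .c2_statistic(x, .baseline_pars(x, K), K, nodes, w,
                          free_slopes = FALSE)
    CFI <- 1 - max(main$C2 - main$df, 0) / max(base$C2 - base$df, .Machine$double.eps)
    RMSEA <- sqrt(max(main$C2 - main$df, 0) / (main$df * n))
  } else {
    CFI <- RMSEA <- NA_real_
  }

  Rimp <- .implied_score_corr(pars, K, nodes, w)
  Robs <- suppressWarnings(stats::cor(x))
  resid <- Robs - Rimp
  diag(resid) <- 0
  dimnames(resid) <- list(fit$labels, fit$labels)
  lower <- resid[lower.tri(resid)]
  SRMR <- sqrt(mean(lower^2))

  structure(list(C2 = main$C2, df = main$df, p = main$p,
                 CFI_C2 = CFI, RMSEA_C2 = RMSEA, SRMR = SRMR,
                 residual_correlations = resid,
                 marginal_reliability = marginal_reliability(fit$bank),
                 loglik = fit$loglik, n = n, flagged = main$flagged),
            class = "grm_fitstats")
}

#' @export
print.grm_fitstats <- function(x, ...) {
  if (x$flagged) {
    cat("<grm_fitstats> saturated or under-identified margins (df <= 0); chi-square indices undefined\n")
  } else {
    cat(sprintf("<grm_fitstats> C2(%d) = %.1f, p = %.3g, CFI_C2 = %.3f, RMSEA_C2 = %.3f, SRMR = %.3f\n",
                x$df, x$C2, x$p, x$CFI_C2, x$RMSEA_C2, x$SRMR))
  }
  cat(sprintf("  largest |residual correlation| = %.3f; marginal reliability = %.3f\n",
              max(abs(x$residual_correlations)), x$marginal_reliability))
  invisible(x)
}
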