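## ---------------------------------------------------------------------------
## Maximum marginal likelihood estimation of the graded response model by the
## Bock-Aitkin EM algorithm over a fixed rectangular quadrature grid, for one
## group or several groups with equality constraints and free focal moments.
## ---------------------------------------------------------------------------

.as_response_matrix <- function(data) {
  x <- as.matrix(data)
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  x
}

## Collapse unobserved categories per item (pooled over groups); returns the
## recoded matrix, per-item K and the category maps.
.collapse_categories <- function(x, K) {
  J <- ncol(x)
  maps <- vector("list", J)
  Kj <- integer(J)
  for (j in seq_len(J)) {
    obs <- sort(unique(x[, j]))
    obs <- obs[!is.na(obs)]
    if (length(obs) < 2L) {
      stop(sprintf("item %s has fewer than 2 observed categories",
                   colnames(x)[j]), call. = FALSE)
    }
    full <- seq_len(K)
    if (!all(full %in% obs)) {
      warning(sprintf("item %s: unobserved categories collapsed (%s observed of %d)",
                      colnames(x)[j], length(obs), K), call. = FALSE)
      x[, j] <- match(x[, j], obs)
    }
    maps[[j]] <- obs
    Kj[j] <- length(obs)
  }
  list(x = x, K = Kj, maps = maps)
}

## 0/1 indicator matrices (n x K_j) per item for one group's data; NA rows 0.
.indicators <- function(x, K) {
  lapply(seq_len(ncol(x)), function(j) {
    ind <- matrix(0, nrow(x), K[j])
    obs <- which(!is.na(x[, j]))
    ind[cbind(obs, x[obs, j])] <- 1
    ind
  })
}

## Category-probability matrix K x Q for item params at nodes
.pmat <- function(a, d, nodes) {
  ps <- stats::plogis(outer(d, a * nodes, `+`))     # (K-1) x Q
  ps <- rbind(1, ps, 0, deparse.level = 0)
  pm <- ps[-nrow(ps), , drop = FALSE] - ps[-1L, , drop = FALSE]
  pmax(pm, 1e-300)
}

## Expected complete-data log-likelihood for one item and its gradient,
## given the expected count table r (K x Q).
.item_Q <- function(par, r, nodes) {
  K <- nrow(r)
  sum(r * log(.pmat(par[1L], par[-1L], nodes)))
}

.item_Q_grad <- function(par, r, nodes) {
  a <- par[1L]; d <- par[-1L]
  ps <- stats::plogis(outer(d, a * nodes, `+`))     # (K-1) x Q
  s <- ps * (1 - ps)
  psp <- rbind(1, ps, 0, deparse.level = 0)
  P <- pmax(psp[-nrow(psp), , drop = FALSE] - psp[-1L, , drop = FALSE], 1e-300)
  w <- r / P                                        # K x Q
  dif <- w[-1L, , drop = FALSE] - w[-nrow(w), , drop = FALSE]  # (K-1) x Q
  gd <- rowSums(s * dif)
  ga <- sum(t(s * dif) * nodes)
  c(ga, gd)
}

## Normalized discrete latent weights at fixed nodes
.latent_weights <- function(nodes, mu, sigma) {
  w <- stats::dnorm(nodes, mu, sigma)
  w / sum(w)
}

.start_values <- function(x, K) {
  lapply(seq_along(K), function(j) {
    xs <- x[, j]; xs <- xs[!is.na(xs)]
    d <- numeric(K[j] - 1L)
    for (k in seq_len(K[j] - 1L)) {
      p <- mean(xs > k)
      d[k] <- stats::qlogis(min(max(p, 0.02), 0.98))
    }
    # enforce strict ordering in degenerate samples
    for (k in seq_along(d)[-1L]) if (d[k] >= d[k - 1L]) d[k] <- d[k - 1L] - 0.1
    list(a = 1, d = d)
  })
}

## Internal EM engine. `constrained` is a logical vector per item: TRUE means
## one parameter set shared by all groups.
.fit_em <- function(x, group_idx, G, constrained, free_moments,
                    quadrature, bounds, tol, max_iter, start = NULL) {
  J <- ncol(x)
  cc <- .collapse_categories(x, max(x, na.rm = TRUE))
  x <- cc$x; K <- cc$K
  nodes <- seq(bounds[1L], bounds[2L], length.out = quadrature)
  Q <- length(nodes)

  xg <- lapply(seq_len(G), function(g) x[group_idx == g, , drop = FALSE])
  ind <- lapply(xg, .indicators, K = K)
  ng <- vapply(xg, nrow, integer(1))

  ## parameter sets: constrained item -> one set over all groups;
  ## free item -> one set per group
  sets <- list()
  set_id <- matrix(NA_integer_, J, G)
  for (j in seq_len(J)) {
    if (constrained[j]) {
      sets[[length(sets) + 1L]] <- list(item = j, groups = seq_len(G))
      set_id[j, ] <- length(sets)
    } else {
      for (g in seq_len(G)) {
        sets[[length(sets) + 1L]] <- list(item = j, groups = g)
        set_id[j, g] <- length(sets)
      }
    }
  }
  sv <- if (is.null(start)) .start_values(x, K) else start
  pars <- lapply(sets, function(s) sv[[s$item]])
  moments <- cbind(mu = rep(0, G), sigma = rep(1, G))

  mom_free <- free_moments && G > 1L
  pack <- function() {
    v <- unlist(lapply(pars, function(p) c(p$a, p$d)))
    if (mom_free) {
      for (g in 2:G) v <- c(v, moments[g, 1L], log(moments[g, 2L]))
    }
    v
  }
  unpack <- function(v) {
    pos <- 0L
    for (s in seq_along(sets)) {
      len <- K[sets[[s]]$item]
      pars[[s]] <<- list(a = v[pos + 1L], d = v[(pos + 2L):(pos + len)])
      pos <- pos + len
    }
    if (mom_free) {
      for (g in 2:G) {
        moments[g, ] <<- c(v[pos + 1L], exp(v[pos + 2L]))
        pos <- pos + 2L
      }
    }
  }
  estep <- function() {
    pm <- lapply(seq_along(sets), function(s) {
      .pmat(pars[[s]]$a, pars[[s]]$d, nodes)
    })
    ll <- 0
    rtab <- lapply(seq_along(sets), function(s) {
      matrix(0, K[sets[[s]]$item], Q)
    })
    Rq <- matrix(0, G, Q)
    for (g in seq_len(G)) {
      if (ng[g] == 0L) next
      L <- matrix(1, ng[g], Q)
      for (j in seq_len(J)) {
        P <- pm[[set_id[j, g]]]
        obs <- which(!is.na(xg[[g]][, j]))
        if (length(obs)) L[obs, ] <- L[obs, ] * P[xg[[g]][obs, j], , drop = FALSE]
      }
      w <- .latent_weights(nodes, moments[g, 1L], moments[g, 2L])
      Lw <- sweep(L, 2L, w, `*`)
      marg <- rowSums(Lw)
      ll <- ll + sum(log(pmax(marg, 1e-300)))
      post <- Lw / pmax(marg, 1e-300)
      Rq[g, ] <- colSums(post)
      for (j in seq_len(J)) {
        s <- set_id[j, g]
        rtab[[s]] <- rtab[[s]] + crossprod(ind[[g]][[j]], post)
      }
    }
    list(ll = ll, rtab = rtab, Rq = Rq)
  }
  mstep <- function(es) {
    for (s in seq_along(sets)) {
      p0 <- c(pars[[s]]$a, pars[[s]]$d)
      opt <- stats::optim(p0, fn = .item_Q, gr = .item_Q_grad,
                          r = es$rtab[[s]], nodes = nodes, method = "BFGS",
                          control = list(fnscale = -1, maxit = 8))
      pars[[s]] <<- list(a = opt$par[1L], d = opt$par[-1L])
    }
    if (mom_free) {
      for (g in 2:G) {
        obj <- function(p) {
          w <- .latent_weights(nodes, p[1L], exp(p[2L]))
          -sum(es$Rq[g, ] * log(w))
        }
        o <- stats::optim(c(moments[g, 1L], log(moments[g, 2L])), obj,
                          method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-10))
        moments[g, ] <<- c(o$par[1L], exp(o$par[2L]))
      }
    }
  }

  ## EM with Ramsay-type step acceleration; accelerated jumps are reverted
  ## whenever they would decrease the marginal log-likelihood, so the
  ## recorded log-likelihood trace stays monotone.
  loglik_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  d_prev <- NULL
  fallback <- NULL
  accelerated <- FALSE
  repeat {
    it <- it + 1L
    es <- estep()
    if (accelerated && length(loglik_trace) &&
        es$ll < loglik_trace[length(loglik_trace)]) {
      unpack(fallback)           # plain EM point: likelihood ascent is
      accelerated <- FALSE       # guaranteed from there
      d_prev <- NULL
      es <- estep()
    }
    loglik_trace <- c(loglik_trace, es$ll)
    base <- pack()
    mstep(es)
    em_point <- pack()
    step <- em_point - base
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    accelerated <- FALSE
    if (!is.null(d_prev) && it >= 3L) {
      r <- sqrt(sum(step^2) / sum(d_prev^2))
      if (is.finite(r) && r < 0.98) {
        mult <- min(1 / (1 - r), 6)
        unpack(base + mult * step)
        fallback <- em_point
        accelerated <- TRUE
      }
    }
    d_prev <- step
  }

  list(sets = sets, set_id = set_id, pars = pars, moments = moments,
       K = K, maps = cc$maps, nodes = nodes, loglik_trace = loglik_trace,
       loglik = loglik_trace[length(loglik_trace)], converged = converged,
       n_iter = it, x = x, group_idx = group_idx, G = G, ind = ind,
       constrained = constrained, free_moments = free_moments && G > 1L)
}

.bank_from_em <- function(em, g, labels) {
  grm_bank(lapply(seq_len(ncol(em$x)), function(j) {
    p <- em$pars[[em$set_id[j, g]]]
    grm_item(a = p$a, d = sort(p$d, decreasing = TRUE), label = labels[j])
  }))
}

#' Fit a graded response model by maximum marginal likelihood
#'
#' Single-group Bock-Aitkin EM over a fixed rectangular quadrature grid
#' (default 61 points on \[-6, 6\]), with the latent trait fixed to `N(0, 1)`.
#' The marginal log-likelihood is non-decreasing across EM iterations and
#' convergence is declared when the largest absolute parameter change falls
#' below `tol`. Non-convergence within `max_iter` is flagged on the result,
#' not raised; items with unobserved categories are collapsed with a warning.
#'
#' @param data Integer matrix or data frame, respondents by items, categories
#'   `1..K` with `NA` for missing.
#' @param quadrature Number of quadrature nodes.
#' @param bounds Quadrature interval.
#' @param tol Convergence tolerance on parameter changes.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `grm_fit`: `bank`, `loglik`, `loglik_trace`,
#'   `converged`, `n_iter`, `n`, plus internals used by [standard_errors()]
#'   and [limited_info_fit()].
#' @export
fit_grm <- function(data, quadrature = 61L, bounds = c(-6, 6),
                    tol = 1e-4, max_iter = 500L) {
  x <- .as_response_matrix(data)
  if (nrow(x) < 100L) {
    warning("fewer than 100 respondents; estimates may be unstable",
            call. = FALSE)
  }
  em <- .fit_em(x, group_idx = rep(1L, nrow(x)), G = 1L,
                constrained = rep(TRUE, ncol(x)), free_moments = FALSE,
                quadrature = quadrature, bounds = bounds, tol = tol,
                max_iter = max_iter)
  structure(list(bank = .bank_from_em(em, 1L, colnames(x)),
                 loglik = em$loglik, loglik_trace = em$loglik_trace,
                 converged = em$converged, n_iter = em$n_iter,
                 n = nrow(x), em = em, labels = colnames(x)),
            class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit> %d items, n = %d, loglik = %.2f (%s in %d EM iterations)\n",
              length(x$bank), x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Fit a multi-group graded response model
#'
#' Joint Bock-Aitkin EM across two or more groups. The reference group's
#' latent distribution is fixed at `N(0, 1)`; each focal group's mean and SD
#' are freely estimated when `free_focal_moments = TRUE`. Items listed in
#' `constraints` share one parameter set across groups; the remaining items
#' get group-specific parameters (the configuration used when testing
#' differential item functioning with anchor items).
#'
#' @param data Response matrix as in [fit_grm()].
#' @param group Group label per row (2 or more levels).
#' @param constraints `"all"` (default), `"none"`, or a vector of item labels
#'   or column indices to constrain equal across groups.
#' @param reference Label of the reference group (defaults to the first
#'   level).
#' @param free_focal_moments Estimate focal group mean/SD (default `TRUE`).
#' @param start Optional warm start: a [grm_bank()] (or list of
#'   `list(a, d)` per item) used as initial parameter values.
#' @inheritParams fit_grm
#' @return An object of class `grm_mg_fit` with per-group `banks`, `groups`
#'   ([latent_dist()] per group), `constraints`, `loglik`, `converged`.
#' @export
fit_multigroup_grm <- function(data, group, constraints = "all",
                               reference = NULL, free_focal_moments = TRUE,
                               quadrature = 61L, bounds = c(-6, 6),
                               tol = 1e-4, max_iter = 500L, start = NULL) {
  x <- .as_response_matrix(data)
  group <- as.factor(group)
  if (length(group) != nrow(x)) stop("`group` must match rows of `data`",
                                     call. = FALSE)
  levs <- levels(group)
  if (length(levs) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(reference)) reference <- levs[1L]
  if (!reference %in% levs) stop("unknown reference group", call. = FALSE)
  levs <- c(reference, setdiff(levs, reference))
  gi <- match(as.character(group), levs)

  J <- ncol(x)
  labels <- colnames(x)
  constrained <- rep(FALSE, J)
  if (identical(constraints, "all")) {
    constrained[] <- TRUE
  } else if (!identical(constraints, "none")) {
    idx <- if (is.numeric(constraints)) as.integer(constraints)
           else match(as.character(constraints), labels)
    if (anyNA(idx) || any(idx < 1L | idx > J)) {
      stop("constraint on an item not in the data", call. = FALSE)
    }
    constrained[idx] <- TRUE
  }
  if (!is.null(start)) {
    if (inherits(start, "grm_bank")) {
      start <- lapply(labels, function(l) {
        list(a = start[[l]]$a, d = start[[l]]$d)
      })
    }
    if (length(start) != J) stop("`start` must cover every item", call. = FALSE)
  }
  em <- .fit_em(x, group_idx = gi, G = length(levs),
                constrained = constrained,
                free_moments = free_focal_moments,
                quadrature = quadrature, bounds = bounds, tol = tol,
                max_iter = max_iter, start = start)
  banks <- lapply(seq_along(levs), function(g) .bank_from_em(em, g, labels))
  names(banks) <- levs
  groups <- lapply(seq_along(levs), function(g) {
    latent_dist(em$moments[g, 1L], em$moments[g, 2L])
  })
  names(groups) <- levs
  structure(list(banks = banks, groups = groups,
                 constraints = labels[constrained], reference = reference,
                 loglik = em$loglik, loglik_trace = em$loglik_trace,
                 converged = em$converged, n_iter = em$n_iter,
                 n = nrow(x), em = em, labels = labels, levels = levs),
            class = "grm_mg_fit")
}

#' @export
print.grm_mg_fit <- function(x, ...) {
  cat(sprintf("<grm_mg_fit> %d items, %d groups (ref %s), n = %d, loglik = %.2f (%s)\n",
              length(x$labels), length(x$levels), x$reference, x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  for (g in x$levels) {
    cat(sprintf("  %s: latent N(%.3f, %.3f^2)\n", g, x$groups[[g]]$mu,
                x$groups[[g]]$sigma))
  }
  cat(sprintf("  constrained items: %s\n",
              if (length(x$constraints)) paste(x$constraints, collapse = ", ")
              else "none"))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Parameter packing and standard errors
## ---------------------------------------------------------------------------

## Names and layout of the packed free-parameter vector of an EM result
.param_names <- function(em, labels) {
  nm <- unlist(lapply(seq_along(em$sets), function(s) {
    j <- em$sets[[s]]$item
    grp <- if (length(em$sets[[s]]$groups) > 1L) "" else
      paste0("@g", em$sets[[s]]$groups)
    c(paste0(labels[j], grp, ".a"),
      paste0(labels[j], grp, ".d", seq_len(em$K[j] - 1L)))
  }))
  if (em$free_moments) {
    for (g in 2:em$G) nm <- c(nm, paste0("g", g, ".mu"), paste0("g", g, ".log_sigma"))
  }
  nm
}

.pack_em <- function(em) {
  v <- unlist(lapply(em$pars, function(p) c(p$a, p$d)))
  if (em$free_moments) {
    for (g in 2:em$G) v <- c(v, em$moments[g, 1L], log(em$moments[g, 2L]))
  }
  v
}

.unpack_em <- function(em, v) {
  pos <- 0L
  for (s in seq_along(em$sets)) {
    len <- em$K[em$sets[[s]]$item]
    em$pars[[s]] <- list(a = v[pos + 1L], d = v[(pos + 2L):(pos + len)])
    pos <- pos + len
  }
  if (em$free_moments) {
    for (g in 2:em$G) {
      em$moments[g, ] <- c(v[pos + 1L], exp(v[pos + 2L]))
      pos <- pos + 2L
    }
  }
  em
}

## Marginal log-likelihood at the EM result's parameters
.em_loglik <- function(em) {
  nodes <- em$nodes
  ll <- 0
  for (g in seq_len(em$G)) {
    rows <- which(em$group_idx == g)
    if (!length(rows)) next
    xg <- em$x[rows, , drop = FALSE]
    L <- matrix(1, length(rows), length(nodes))
    for (j in seq_len(ncol(em$x))) {
      P <- .pmat(em$pars[[em$set_id[j, g]]]$a, em$pars[[em$set_id[j, g]]]$d,
                 nodes)
      obs <- which(!is.na(xg[, j]))
      if (length(obs)) L[obs, ] <- L[obs, ] * P[xg[obs, j], , drop = FALSE]
    }
    w <- .latent_weights(nodes, em$moments[g, 1L], em$moments[g, 2L])
    ll <- ll + sum(log(pmax(rowSums(sweep(L, 2L, w, `*`)), 1e-300)))
  }
  ll
}

## E-step tables (expected counts per set, focal node counts) at given params
.em_estep_tables <- function(em) {
  nodes <- em$nodes
  Q <- length(nodes)
  rtab <- lapply(seq_along(em$sets), function(s) {
    matrix(0, em$K[em$sets[[s]]$item], Q)
  })
  Rq <- matrix(0, em$G, Q)
  for (g in seq_len(em$G)) {
    rows <- which(em$group_idx == g)
    if (!length(rows)) next
    xg <- em$x[rows, , drop = FALSE]
    L <- matrix(1, length(rows), Q)
    for (j in seq_len(ncol(em$x))) {
      P <- .pmat(em$pars[[em$set_id[j, g]]]$a, em$pars[[em$set_id[j, g]]]$d,
                 nodes)
      obs <- which(!is.na(xg[, j]))
      if (length(obs)) L[obs, ] <- L[obs, ] * P[xg[obs, j], , drop = FALSE]
    }
    w <- .latent_weights(nodes, em$moments[g, 1L], em$moments[g, 2L])
    Lw <- sweep(L, 2L, w, `*`)
    post <- Lw / pmax(rowSums(Lw), 1e-300)
    Rq[g, ] <- colSums(post)
    for (j in seq_len(ncol(em$x))) {
      s <- em$set_id[j, g]
      rtab[[s]] <- rtab[[s]] + crossprod(em$ind[[g]][[j]], post)
    }
  }
  list(rtab = rtab, Rq = Rq)
}

## Gradient of the EM Q-function with respect to eta' evaluated at eta' =
## `em` (parameters), with posteriors computed at `tables`.
.Q_grad <- function(em, tables) {
  g_items <- unlist(lapply(seq_along(em$sets), function(s) {
    .item_Q_grad(c(em$pars[[s]]$a, em$pars[[s]]$d), tables$rtab[[s]], em$nodes)
  }))
  if (!em$free_moments) return(g_items)
  gm <- numeric(0)
  h <- 1e-5
  for (g in 2:em$G) {
    f <- function(mu, ls) {
      sum(tables$Rq[g, ] * log(.latent_weights(em$nodes, mu, exp(ls))))
    }
    mu <- em$moments[g, 1L]; ls <- log(em$moments[g, 2L])
    gm <- c(gm, (f(mu + h, ls) - f(mu - h, ls)) / (2 * h),
            (f(mu, ls + h) - f(mu, ls - h)) / (2 * h))
  }
  c(g_items, gm)
}

## Observed information by the Oakes identity: -[d2Q/deta'2 + d2Q/deta'deta].
.info_oakes <- function(em) {
  p <- length(.pack_em(em))
  eta <- .pack_em(em)
  tab0 <- .em_estep_tables(em)

  ## Block-diagonal complete-data part: numeric Hessian per item set (and
  ## moment block), posteriors held fixed.
  H1 <- matrix(0, p, p)
  pos <- 0L
  h <- 1e-4
  for (s in seq_along(em$sets)) {
    len <- em$K[em$sets[[s]]$item]
    idx <- pos + seq_len(len)
    f <- function(v) .item_Q(v, tab0$rtab[[s]], em$nodes)
    v0 <- c(em$pars[[s]]$a, em$pars[[s]]$d)
    Hs <- matrix(0, len, len)
    for (i in seq_len(len)) {
      ei <- numeric(len); ei[i] <- h
      gp <- .item_Q_grad(v0 + ei, tab0$rtab[[s]], em$nodes)
      gmn <- .item_Q_grad(v0 - ei, tab0$rtab[[s]], em$nodes)
      Hs[, i] <- (gp - gmn) / (2 * h)
    }
    H1[idx, idx] <- (Hs + t(Hs)) / 2
    pos <- pos + len
  }
  if (em$free_moments) {
    for (g in 2:em$G) {
      idx <- pos + 1:2
      f <- function(v) {
        sum(tab0$Rq[g, ] * log(.latent_weights(em$nodes, v[1L], exp(v[2L]))))
      }
      v0 <- c(em$moments[g, 1L], log(em$moments[g, 2L]))
      Hs <- matrix(0, 2, 2)
      for (i in 1:2) {
        ei <- numeric(2); ei[i] <- h
        gp <- c((f(v0 + ei + c(h, 0)) - f(v0 + ei - c(h, 0))) / (2 * h),
                (f(v0 + ei + c(0, h)) - f(v0 + ei - c(0, h))) / (2 * h))
        gm <- c((f(v0 - ei + c(h, 0)) - f(v0 - ei - c(h, 0))) / (2 * h),
                (f(v0 - ei + c(0, h)) - f(v0 - ei - c(0, h))) / (2 * h))
        Hs[, i] <- (gp - gm) / (2 * h)
      }
      H1[idx, idx] <- (Hs + t(Hs)) / 2
      pos <- pos + 2L
    }
  }

  ## Cross part: derivative of the Q-gradient with respect to the posterior
  ## (E-step) parameters, column by column.
  H2 <- matrix(0, p, p)
  for (jp in seq_len(p)) {
    ep <- numeric(p); ep[jp] <- h
    emp <- .unpack_em(em, eta + ep)
    emm <- .unpack_em(em, eta - ep)
    ## eta' stays at eta; only the posteriors move
    gp <- .Q_grad(em, .em_estep_tables(emp))
    gm <- .Q_grad(em, .em_estep_tables(emm))
    H2[, jp] <- (gp - gm) / (2 * h)
  }
  Hess <- H1 + (H2 + t(H2)) / 2
  -(Hess + t(Hess)) / 2
}

.info_numerical <- function(em) {
  eta <- .pack_em(em)
  p <- length(eta)
  h <- 1e-3
  f <- function(v) .em_loglik(.unpack_em(em, v))
  H <- matrix(0, p, p)
  f0 <- f(eta)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- numeric(p); ei[i] <- h
      ej <- numeric(p); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(eta + ei + ej) - f(eta + ei - ej) - f(eta - ei + ej) +
           f(eta - ei - ej)) / (4 * h^2)
    }
  }
  -H
}

#' Standard errors for a fitted graded response model
#'
#' Computes the observed-information covariance matrix of all free parameters
#' (item slopes/intercepts per parameter set, plus focal latent moments in
#' multi-group fits). `method = "oakes"` uses the Oakes identity, writing the
#' log-likelihood Hessian as the complete-data expected Hessian plus the
#' derivative of the EM Q-function gradient with respect to the parameters
#' entering the posterior; `method = "numerical"` is a central-difference
#' Hessian of the marginal log-likelihood (slower; used as a cross-check).
#' Parameters fixed by equality constraints appear once, as the shared set.
#'
#' @param fit A `grm_fit` or `grm_mg_fit`.
#' @param method `"oakes"` (default) or `"numerical"`.
#' @return A list with `se` (named vector), `cov`, `info` and `names`.
#' @export
standard_errors <- function(fit, method = c("oakes", "numerical")) {
  method <- match.arg(method)
  if (!inherits(fit, c("grm_fit", "grm_mg_fit"))) {
    stop("`fit` must come from fit_grm() or fit_multigroup_grm()",
         call. = FALSE)
  }
  if (!isTRUE(fit$converged)) {
    warning("model had not converged; standard errors may be unreliable",
            call. = FALSE)
  }
  em <- fit$em
  info <- if (method == "oakes") .info_oakes(em) else .info_numerical(em)
  nm <- .param_names(em, fit$labels)
  dimnames(info) <- list(nm, nm)
  covm <- tryCatch(solve(info), error = function(e) {
    stop(sprintf("information matrix is singular (%s); parameters: %s",
                 conditionMessage(e), paste(nm, collapse = ", ")),
         call. = FALSE)
  })
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- nm
  list(se = se, cov = covm, info = info, names = nm, method = method)
}
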