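## ---------------------------------------------------------------------------
## Differential item functioning: iterative Wald tests with BH-FDR control,
## follow-up single-parameter tests, and DIF/DTF effect sizes (wABC, ESSD,
## ETSSD, UETSDS).
## ---------------------------------------------------------------------------

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted p-values (a thin wrapper over
#' `stats::p.adjust(method = "BH")` with strict input validation).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, monotone and no smaller than the input.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || anyNA(p) ||
      any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1] with no missing values",
         call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

.focal_grid <- function(focal_dist, step = 0.01) {
  seq(focal_dist$mu - 6 * focal_dist$sigma,
      focal_dist$mu + 6 * focal_dist$sigma, by = step)
}

#' Weighted area between expected item score curves (wABC)
#'
#' The focal-density-weighted area between two groups' expected item score
#' curves, `integral |ES_ref(theta) - ES_foc(theta)| phi(theta; focal) d
#' theta`, evaluated by fixed-grid quadrature over the focal mean +/- 6 SD.
#' Values above 0.30 are conventionally read as practically significant DIF.
#' The measure is symmetric in the two parameter sets.
#'
#' @param item_ref,item_foc [grm_item()] parameter sets for the reference and
#'   focal group (same number of categories).
#' @param focal_dist Focal-group [latent_dist()].
#' @param step Grid step.
#' @return Non-negative scalar in expected-score units.
#' @export
wabc <- function(item_ref, item_foc, focal_dist = latent_dist(0, 1),
                 step = 0.01) {
  stopifnot(inherits(item_ref, "grm_item"), inherits(item_foc, "grm_item"),
            inherits(focal_dist, "latent_dist"))
  if (item_ref$K != item_foc$K) {
    stop("items must have the same number of categories", call. = FALSE)
  }
  grid <- .focal_grid(focal_dist, step)
  w <- stats::dnorm(grid, focal_dist$mu, focal_dist$sigma)
  w <- w / sum(w)
  sum(abs(expected_item_score(item_ref, grid) -
            expected_item_score(item_foc, grid)) * w)
}

## model-implied item-score variance under a latent density
.item_score_var <- function(item, dist, step = 0.01) {
  grid <- .focal_grid(dist, step)
  w <- stats::dnorm(grid, dist$mu, dist$sigma); w <- w / sum(w)
  pk <- category_probabilities(item, grid)
  k <- seq_len(item$K)
  m1 <- drop(pk %*% k); m2 <- drop(pk %*% k^2)
  sum(w * m2) - sum(w * m1)^2
}

#' Expected score standardized difference (ESSD)
#'
#' Signed item-level DIF effect size on the Cohen's d metric: the focal-
#' density-weighted mean of `ES_foc(theta) - ES_ref(theta)`, divided by the
#' pooled model-implied item-score SD. Positive values mean the focal group's
#' expected item score is higher at equal trait level.
#'
#' @inheritParams wabc
#' @return Signed scalar (Cohen's d metric).
#' @export
essd <- function(item_ref, item_foc, focal_dist = latent_dist(0, 1),
                 step = 0.01) {
  stopifnot(inherits(item_ref, "grm_item"), inherits(item_foc, "grm_item"))
  if (item_ref$K != item_foc$K) {
    stop("items must have the same number of categories", call. = FALSE)
  }
  grid <- .focal_grid(focal_dist, step)
  w <- stats::dnorm(grid, focal_dist$mu, focal_dist$sigma); w <- w / sum(w)
  num <- sum((expected_item_score(item_foc, grid) -
                expected_item_score(item_ref, grid)) * w)
  pooled <- sqrt((.item_score_var(item_ref, focal_dist, step) +
                    .item_score_var(item_foc, focal_dist, step)) / 2)
  if (pooled <= 0) stop("pooled item-score SD is zero", call. = FALSE)
  num / pooled
}

#' Test-level DIF effect sizes (ETSSD, UETSDS)
#'
#' `etssd()` is the signed test-level analogue of [essd()]: the focal-
#' density-weighted mean difference in expected test scores divided by the
#' pooled model-implied test-score SD. `uetsds()` is the unsigned expected
#' test score difference in the sample: the mean over supplied focal trait
#' estimates of `|TS_foc(theta_i) - TS_ref(theta_i)|`, in raw score points.
#'
#' @param bank_ref,bank_foc [grm_bank()]s of reference/focal parameters.
#' @param focal_dist Focal [latent_dist()] (for `etssd`).
#' @param focal_thetas Trait estimates of the focal sample (for `uetsds`).
#' @param step Grid step.
#' @return Scalar effect size.
#' @export
etssd <- function(bank_ref, bank_foc, focal_dist = latent_dist(0, 1),
                  step = 0.01) {
  stopifnot(inherits(bank_ref, "grm_bank"), inherits(bank_foc, "grm_bank"))
  grid <- .focal_grid(focal_dist, step)
  w <- stats::dnorm(grid, focal_dist$mu, focal_dist$sigma); w <- w / sum(w)
  num <- sum((expected_test_score(bank_foc, grid) -
                expected_test_score(bank_ref, grid)) * w)
  vr <- sum(vapply(bank_ref, .item_score_var, numeric(1), dist = focal_dist,
                   step = step))
  vf <- sum(vapply(bank_foc, .item_score_var, numeric(1), dist = focal_dist,
                   step = step))
  ## items are conditionally independent given theta; between-item trait
  ## covariance is added from the expected-score curves
  cov_extra <- function(bank) {
    es <- vapply(bank, expected_item_score, numeric(length(grid)),
                 theta = grid)
    tot <- rowSums(es)
    sum(w * tot^2) - sum(w * tot)^2 -
      sum(vapply(seq_along(bank), function(j) {
        sum(w * es[, j]^2) - sum(w * es[, j])^2
      }, numeric(1)))
  }
  pooled <- sqrt(((vr + cov_extra(bank_ref)) + (vf + cov_extra(bank_foc))) / 2)
  if (pooled <= 0) stop("pooled test-score SD is zero", call. = FALSE)
  num / pooled
}

#' @rdname etssd
#' @export
uetsds <- function(bank_ref, bank_foc, focal_thetas) {
  stopifnot(inherits(bank_ref, "grm_bank"), inherits(bank_foc, "grm_bank"))
  if (length(focal_thetas) == 0L) {
    stop("`focal_thetas` must be non-empty", call. = FALSE)
  }
  mean(abs(expected_test_score(bank_foc, focal_thetas) -
             expected_test_score(bank_ref, focal_thetas)))
}

## Wald test of parameter equality for one free item in a two-group fit
.wald_item <- function(fit, ses, label) {
  nm <- ses$names
  i1 <- grep(paste0("^", label, "@g1\\."), nm)
  i2 <- grep(paste0("^", label, "@g2\\."), nm)
  if (length(i1) == 0L || length(i1) != length(i2)) {
    stop(sprintf("item %s is not free in both groups", label), call. = FALSE)
  }
  th <- .pack_em(fit$em)
  delta <- th[i2] - th[i1]
  V <- ses$cov[i2, i2] + ses$cov[i1, i1] - ses$cov[i1, i2] - ses$cov[i2, i1]
  chi2 <- tryCatch(drop(crossprod(delta, solve(V, delta))),
                   error = function(e) NA_real_)
  df <- length(delta)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       delta = delta, V = V,
       par_names = sub("^.*@g1\\.", "", nm[i1]))
}

#' Iterative Wald test of differential item functioning
#'
#' Two-group DIF testing by the iterative Wald procedure. Iteration 1 tests
#' each item with all other items as anchors (parameters constrained equal
#' across groups, focal latent mean/SD free); omnibus Wald statistics
#' (df = number of item parameters) are corrected by Benjamini-Hochberg FDR
#' and items with `p_FDR < alpha` are flagged. Subsequent iterations
#' re-estimate using only unflagged items as anchors (flagged items receive
#' group-specific parameters) and re-test; the flag set grows monotonically
#' and the procedure stops when it is stable or `max_iter` is reached.
#' Flagged items receive follow-up single-parameter Wald tests
#' (chi-square with 1 df, FDR-corrected within item), and wABC/ESSD effect
#' sizes are reported for every item along with test-level ETSSD and UETSDS.
#'
#' @param data Response matrix (respondents x items).
#' @param group Two-level group label per row.
#' @param reference Reference group label (defaults to first level).
#' @param alpha FDR level for flagging.
#' @param wabc_threshold Practical-significance threshold on wABC.
#' @param max_iter Maximum anchor-refinement iterations.
#' @param quadrature,tol Passed to [fit_multigroup_grm()].
#' @return An object of class `dif_result`: a per-item data frame (`chi2`,
#'   `df`, `p`, `p_FDR`, `flagged`, `wABC`, `ESSD`, `flagged_params`), plus
#'   `UETSDS`, `ETSSD`, `anchors`, `n_iterations`, `focal_dist` and the
#'   final `fit`.
#' @export
iterative_wald_dif <- function(data, group, reference = NULL, alpha = 0.05,
                               wabc_threshold = 0.30, max_iter = 10L,
                               quadrature = 61L, tol = 1e-4) {
  x <- .as_response_matrix(data)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly 2 groups are required", call. = FALSE)
  labels <- colnames(x)
  J <- length(labels)
  if (is.null(reference)) reference <- levels(group)[1L]

  ## fully constrained fit provides warm starts for every anchor pattern
  base_fit <- fit_multigroup_grm(x, group, constraints = "all",
                                 reference = reference,
                                 quadrature = quadrature, tol = tol)
  warm <- base_fit$banks[[1L]]

  fit_cache <- new.env(parent = emptyenv())
  fit_cache[["free:"]] <- list(fit = base_fit, ses = NULL)
  get_fit <- function(free_set) {
    key <- paste0("free:", paste(sort(free_set), collapse = "|"))
    if (is.null(fit_cache[[key]])) {
      constraints <- setdiff(labels, free_set)
      fit <- fit_multigroup_grm(x, group, constraints = constraints,
                                reference = reference,
                                quadrature = quadrature, tol = tol,
                                start = warm)
      fit_cache[[key]] <- list(fit = fit,
                               ses = standard_errors(fit, "oakes"))
    }
    fit_cache[[key]]
  }

  ## omnibus statistics are recorded from the iteration at which an item is
  ## flagged (or from the final iteration for items never flagged)
  chi2 <- df <- p <- p_fdr <- stats::setNames(rep(NA_real_, J), labels)
  flagged <- character(0)
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    tests <- lapply(labels, function(lab) {
      fr <- get_fit(union(flagged, lab))
      .wald_item(fr$fit, fr$ses, lab)
    })
    p_it <- vapply(tests, `[[`, numeric(1), "p")
    p_fdr_it <- bh_fdr(p_it)
    newly <- setdiff(labels[p_fdr_it < alpha], flagged)
    upd <- union(newly, setdiff(labels, flagged))
    chi2[upd] <- vapply(tests, `[[`, numeric(1), "chi2")[match(upd, labels)]
    df[upd] <- vapply(tests, `[[`, numeric(1), "df")[match(upd, labels)]
    p[upd] <- p_it[match(upd, labels)]
    p_fdr[upd] <- p_fdr_it[match(upd, labels)]
    new_flagged <- union(flagged, newly)
    if (length(new_flagged) == J) {
      stop("no anchors available: every item is flagged for DIF",
           call. = FALSE)
    }
    if (setequal(new_flagged, flagged) || n_iter >= max_iter) {
      flagged <- new_flagged
      break
    }
    flagged <- new_flagged
  }

  final <- get_fit(if (length(flagged)) flagged else character(0))
  fit <- final$fit
  foc <- fit$levels[2L]
  focal_dist <- fit$groups[[foc]]
  bank_ref <- fit$banks[[fit$reference]]
  bank_foc <- fit$banks[[foc]]

  ## follow-up single-parameter tests on flagged items
  flagged_params <- stats::setNames(vector("list", J), labels)
  for (lab in labels) flagged_params[[lab]] <- character(0)
  for (lab in flagged) {
    wt <- .wald_item(fit, final$ses, lab)
    z2 <- wt$delta^2 / pmax(diag(as.matrix(wt$V)), .Machine$double.eps)
    pp <- bh_fdr(stats::pchisq(z2, 1, lower.tail = FALSE))
    flagged_params[[lab]] <- wt$par_names[pp < alpha]
  }

  wABC <- vapply(labels, function(lab) {
    wabc(bank_ref[[lab]], bank_foc[[lab]], focal_dist)
  }, numeric(1))
  ESSD <- vapply(labels, function(lab) {
    essd(bank_ref[[lab]], bank_foc[[lab]], focal_dist)
  }, numeric(1))

  ## focal-sample trait estimates for the sample-based DTF index
  xf <- x[as.character(group) != reference, , drop = FALSE]
  th_f <- .batch_map(bank_foc, xf, focal_dist)

  items <- data.frame(item = labels,
                      chi2 = unname(chi2), df = as.integer(unname(df)),
                      p = unname(p), p_FDR = unname(p_fdr),
                      flagged = labels %in% flagged,
                      wABC = wABC, ESSD = ESSD,
                      flagged_params = vapply(flagged_params, paste,
                                              character(1), collapse = ","),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(items = items,
                 UETSDS = uetsds(bank_ref, bank_foc, th_f),
                 ETSSD = etssd(bank_ref, bank_foc, focal_dist),
                 anchors = setdiff(labels, flagged),
                 n_iterations = n_iter,
                 focal_dist = focal_dist,
                 wabc_threshold = wabc_threshold,
                 practical = labels[wABC > wabc_threshold],
                 fit = fit),
            class = "dif_result")
}

#' @export
print.dif_result <- function(x, ...) {
  cat(sprintf("<dif_result> %d items, %d iteration(s); anchors: %s\n",
              nrow(x$items), x$n_iterations,
              paste(x$anchors, collapse = ", ")))
  print(x$items[, c("item", "chi2", "df", "p_FDR", "flagged", "wABC",
                    "ESSD", "flagged_params")], digits = 3)
  cat(sprintf("Test level: UETSDS = %.3f score points, ETSSD = %.3f\n",
              x$UETSDS, x$ETSSD))
  if (length(x$practical)) {
    cat(sprintf("Practically significant DIF (wABC > %.2f): %s\n",
                x$wabc_threshold, paste(x$practical, collapse = ", ")))
  }
  invisible(x)
}

#' Scan DIF across several binary subgroup contrasts
#'
#' Runs [iterative_wald_dif()] for each supplied binary partition and
#' aggregates the largest wABC per contrast with a practical-significance
#' flag at the 0.30 threshold.
#'
#' @param data Response matrix.
#' @param contrasts Named list of two-level vectors (one entry per row of
#'   `data`), or a data frame of such columns.
#' @param min_cell Cell size below which a warning is issued.
#' @inheritParams iterative_wald_dif
#' @return A list with `summary` (data frame: contrast, cell sizes, max wABC,
#'   flagged items, practical flag) and `results` (per-contrast
#'   `dif_result`s).
#' @export
subgroup_dif_scan <- function(data, contrasts, alpha = 0.05,
                              wabc_threshold = 0.30, min_cell = 100L,
                              quadrature = 61L) {
  if (is.data.frame(contrasts)) contrasts <- as.list(contrasts)
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts)))) {
    stop("`contrasts` must be named", call. = FALSE)
  }
  res <- list()
  rows <- list()
  for (nm in names(contrasts)) {
    g <- as.factor(contrasts[[nm]])
    if (nlevels(droplevels(g)) != 2L) {
      stop(sprintf("contrast '%s' is degenerate (needs exactly 2 non-empty cells)",
                   nm), call. = FALSE)
    }
    tab <- table(g)
    if (any(tab < min_cell)) {
      warning(sprintf("contrast '%s': cell below %d respondents", nm,
                      min_cell), call. = FALSE)
    }
    r <- iterative_wald_dif(data, g, alpha = alpha,
                            wabc_threshold = wabc_threshold,
                            quadrature = quadrature)
    res[[nm]] <- r
    rows[[nm]] <- data.frame(contrast = nm, n1 = as.integer(tab[1L]),
                             n2 = as.integer(tab[2L]),
                             max_wABC = max(r$items$wABC),
                             n_flagged = sum(r$items$flagged),
                             practical = max(r$items$wABC) > wabc_threshold,
                             stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = res)
}
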