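## ---------------------------------------------------------------------------
## Empirically driven item reduction: residual-correlation cleanup followed
## by DIF screening, with a full trace of every removal.
## ---------------------------------------------------------------------------

#' Empirically driven item reduction
#'
#' Reduces an item pool in two stages, re-fitting after every removal:
#'
#' * **Stage A (local dependence):** a graded response model is fitted per
#'   group and residual correlations are screened at `|r| > resid_threshold`
#'   (default 0.1). While any pair exceeds the screen, the item involved in
#'   the most offending pairs (ties broken by the largest absolute residual)
#'   is removed and the models re-fitted.
#' * **Stage B (differential item functioning):** the iterative Wald DIF
#'   procedure is run between the two groups; while any item's wABC exceeds
#'   `wabc_threshold` (default 0.30), the worst item is removed and the
#'   procedure re-run.
#'
#' @param data Response matrix (respondents x items, labelled columns).
#' @param group Two-level group label per row.
#' @param resid_threshold Residual-correlation screen.
#' @param wabc_threshold Practical-significance DIF screen.
#' @param min_items Smallest admissible final pool (stop with an error if a
#'   removal would go below it).
#' @param quadrature Quadrature size for the underlying fits.
#' @return An object of class `reduction_trace`: `trace` (data frame of
#'   stages, removed items and criterion values), `final_items`,
#'   `final_dif` (the last DIF result) and `final_fit` (constrained
#'   multi-group fit on the final pool).
#' @export
item_reduction_pipeline <- function(data, group, resid_threshold = 0.1,
                                    wabc_threshold = 0.30, min_items = 3L,
                                    quadrature = 61L) {
  x <- .as_response_matrix(data)
  if (ncol(x) < 4L) stop("need at least 4 items to reduce", call. = FALSE)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly 2 groups are required", call. = FALSE)
  items <- colnames(x)
  trace <- list()
  note_removal <- function(stage, item, value, threshold) {
    trace[[length(trace) + 1L]] <<- data.frame(
      stage = stage, action = "remove", item = item,
      criterion = if (stage == "A") "n_residuals>0.1" else "wABC",
      value = value, threshold = threshold, stringsAsFactors = FALSE)
  }

  ## Stage A: local-dependence cleanup
  repeat {
    counts <- stats::setNames(numeric(length(items)), items)
    worst <- stats::setNames(numeric(length(items)), items)
    for (g in levels(group)) {
      fit <- suppressWarnings(
        fit_grm(x[group == g, items, drop = FALSE], quadrature = quadrature))
      res <- limited_info_fit(fit)$residual_correlations
      off <- abs(res) > resid_threshold
      counts <- counts + rowSums(off)
      worst <- pmax(worst, apply(abs(res), 1L, max))
    }
    if (all(counts == 0)) break
    cand <- names(counts)[counts == max(counts)]
    drop_item <- cand[which.max(worst[cand])]
    if (length(items) - 1L < min_items) {
      stop(paste0("stage A would reduce the pool below ", min_items,
                  " items; trace: ",
                  paste(vapply(trace, function(t) t$item, character(1)),
                        collapse = ", ")), call. = FALSE)
    }
    note_removal("A", drop_item, counts[drop_item], resid_threshold)
    items <- setdiff(items, drop_item)
  }

  ## Stage B: DIF screening
  dif <- NULL
  repeat {
    dif <- iterative_wald_dif(x[, items, drop = FALSE], group,
                              wabc_threshold = wabc_threshold,
                              quadrature = quadrature)
    mx <- max(dif$items$wABC)
    if (mx <= wabc_threshold) break
    drop_item <- dif$items$item[which.max(dif$items$wABC)]
    if (length(items) - 1L < min_items) {
      stop(paste0("stage B would reduce the pool below ", min_items,
                  " items"), call. = FALSE)
    }
    note_removal("B", drop_item, mx, wabc_threshold)
    items <- setdiff(items, drop_item)
  }

  final_fit <- fit_multigroup_grm(x[, items, drop = FALSE], group,
                                  constraints = "all",
                                  quadrature = quadrature)
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(stage = character(0), action = character(0),
               item = character(0), criterion = character(0),
               value = numeric(0), threshold = numeric(0))
  structure(list(trace = trace_df, final_items = items, final_dif = dif,
                 final_fit = final_fit),
            class = "reduction_trace")
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(sprintf("<reduction_trace> %d removal(s); final pool: %s\n",
              nrow(x$trace), paste(x$final_items, collapse = ", ")))
  if (nrow(x$trace)) print(x$trace, digits = 3)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Readability formulas
## ---------------------------------------------------------------------------

## Small exception lexicon for words the vowel-group heuristic miscounts.
.syllable_exceptions <- c(
  people = 2L, everyone = 3L, something = 2L, somewhere = 2L,
  science = 2L, being = 2L, doing = 2L, going = 2L, quiet = 2L,
  idea = 3L, area = 3L, really = 3L, business = 2L, interesting = 3L
)

#' Heuristic syllable counter
#'
#' Counts vowel groups (`a e i o u y`), subtracts silent final "e" (but not
#' "-le" after a consonant) and silent "-ed" endings (not after t/d), and
#' never returns less than one; a small exception lexicon overrides known
#' miscounts.
#'
#' @param words Character vector of words.
#' @return Integer vector of syllable counts.
#' @export
count_syllables <- function(words) {
  vapply(words, function(w) {
    w <- tolower(gsub("[^a-z]", "", tolower(w)))
    if (!nzchar(w)) return(0L)
    if (w %in% names(.syllable_exceptions)) {
      return(.syllable_exceptions[[w]])
    }
    groups <- gregexpr("[aeiouy]+", w)[[1L]]
    n <- if (groups[1L] == -1L) 0L else length(groups)
    if (n > 1L && grepl("[aeiouy][^aeiouy]*e$", w) && !grepl("le$", w) &&
        grepl("[^aeiouy]e$", w)) {
      n <- n - 1L
    }
    # silent "-ed" (as in "confused", but not "wanted"/"needed")
    if (n > 1L && grepl("[^aeiouytd]ed$", w)) n <- n - 1L
    max(n, 1L)
  }, integer(1), USE.NAMES = FALSE)
}

.tokenize_words <- function(text) {
  w <- unlist(regmatches(text, gregexpr("[A-Za-z']+", text)))
  w[nzchar(gsub("'", "", w))]
}

.count_sentences <- function(text) {
  parts <- unlist(strsplit(paste(text, collapse = " "), "[.!?]+"))
  sum(vapply(parts, function(p) grepl("[A-Za-z]", p), logical(1)))
}

#' FORCAST readability grade
#'
#' `grade = 20 - (monosyllabic words per 150-word sample) / 10`. Designed
#' for non-prose material (questionnaires, lists): it ignores sentence
#' structure entirely. Texts shorter than 150 words are scaled by their
#' monosyllable rate and flagged.
#'
#' @param text Character vector (concatenated).
#' @return A list with `grade`, `n_words`, `n_monosyllabic` and `scaled`
#'   (TRUE when the text was shorter than 150 words).
#' @export
forcast <- function(text) {
  words <- .tokenize_words(text)
  if (length(words) == 0L) stop("empty text", call. = FALSE)
  syl <- count_syllables(words)
  mono_per_150 <- sum(syl == 1L) / length(words) * 150
  scaled <- length(words) < 150L
  if (scaled) {
    warning("text shorter than 150 words; FORCAST grade scaled from the monosyllable rate",
            call. = FALSE)
  }
  list(grade = 20 - mono_per_150 / 10, n_words = length(words),
       n_monosyllabic = sum(syl == 1L), scaled = scaled)
}

#' Flesch-Kincaid grade level and Flesch Reading Ease
#'
#' `FKGL = 0.39 (words/sentences) + 11.8 (syllables/words) - 15.59`;
#' `FRE = 206.835 - 1.015 (words/sentences) - 84.6 (syllables/words)`.
#'
#' @param text Character vector with at least one sentence.
#' @return A list with `fkgl`, `fre`, `n_words`, `n_sentences`,
#'   `n_syllables`.
#' @export
flesch <- function(text) {
  words <- .tokenize_words(text)
  if (length(words) == 0L) stop("no words in text", call. = FALSE)
  S <- max(.count_sentences(text), 1L)
  syl <- sum(count_syllables(words))
  W <- length(words)
  list(fkgl = 0.39 * W / S + 11.8 * syl / W - 15.59,
       fre = 206.835 - 1.015 * W / S - 84.6 * syl / W,
       n_words = W, n_sentences = S, n_syllables = syl)
}

#' All readability measures at once
#'
#' @param text Character vector.
#' @return A list of class `readability_result` with `forcast_grade`,
#'   `fkgl` and `fre`.
#' @export
text_readability <- function(text) {
  fc <- suppressWarnings(forcast(text))
  fl <- flesch(text)
  structure(list(forcast_grade = fc$grade, fkgl = fl$fkgl, fre = fl$fre,
                 scaled = fc$scaled), class = "readability_result")
}

#' @export
print.readability_result <- function(x, ...) {
  cat(sprintf("<readability_result> FORCAST grade %.1f%s, FKGL %.1f, FRE %.1f\n",
              x$forcast_grade, if (x$scaled) " (scaled)" else "",
              x$fkgl, x$fre))
  invisible(x)
}
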