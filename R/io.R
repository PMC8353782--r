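#' Read a response table from delimited text
#'
#' Reads a UTF-8 comma-separated file with a header row. Item columns are
#' `tas01`..`tas20` (any subset); an optional `group` column carries group
#' labels. Empty cells and `NA` are treated as missing; malformed item
#' values are reported with their line number.
#'
#' @param path CSV path.
#' @param group_col Name of the group column (used if present).
#' @return A list with `data` (integer matrix of the item columns, labelled
#'   by item number), `group` (factor or `NULL`) and `extra` (data frame of
#'   remaining columns).
#' @export
read_responses <- function(path, group_col = "group") {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  item_cols <- grep("^tas[0-9]{2}$", names(df), value = TRUE)
  if (length(item_cols) == 0L) {
    stop("no item columns found (expected tas01..tas20)", call. = FALSE)
  }
  x <- as.matrix(df[item_cols])
  num <- suppressWarnings(apply(x, 2L, as.numeric))
  bad <- which(!is.na(x) & is.na(num) |
                 (!is.na(num) & num != round(num)), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("malformed response in column %s, line %d",
                 item_cols[bad[1L, 2L]], bad[1L, 1L] + 1L), call. = FALSE)
  }
  storage.mode(num) <- "integer"
  colnames(num) <- as.character(as.integer(sub("^tas", "", item_cols)))
  group <- if (group_col %in% names(df)) factor(df[[group_col]]) else NULL
  extra <- df[setdiff(names(df), c(item_cols, group_col))]
  list(data = num, group = group, extra = extra)
}

#' Write a scored table to CSV
#'
#' @param data Data frame (e.g. from [score_respondents()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
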