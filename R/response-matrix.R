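# Respondents x items ordinal data container with optional group labels and
# external criterion scores, plus CSV readers/writers.

#' Construct a response matrix
#'
#' Ordinal survey responses, respondents in rows and items in columns,
#' coded 1..K with `NA` for missing. Optionally carries a per-respondent
#' group label (used by the DIF screen and discriminant validity) and
#' external criterion score columns (used by concurrent validity).
#'
#' @param values Integer matrix (respondents x items); entries in 1..K or NA.
#' @param item_ids Character vector of column names; defaults to the matrix
#'   column names or `item1..itemJ`.
#' @param respondent_ids Character vector of row identifiers; defaults to
#'   `r1..rN`.
#' @param n_categories Number of ordered categories K (default 5).
#' @param group Optional factor/character vector of length N.
#' @param external_scores Optional data frame of numeric columns, N rows.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(values, item_ids = NULL, respondent_ids = NULL,
                            n_categories = 5L, group = NULL,
                            external_scores = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values); j <- ncol(values)
  if (is.null(item_ids)) {
    item_ids <- colnames(values)
    if (is.null(item_ids)) item_ids <- paste0("item", seq_len(j))
  }
  if (is.null(respondent_ids)) {
    respondent_ids <- rownames(values)
    if (is.null(respondent_ids)) respondent_ids <- paste0("r", seq_len(n))
  }
  stopifnot(length(item_ids) == j, length(respondent_ids) == n)
  obs <- values[!is.na(values)]
  if (length(obs) && (any(obs < 1L) || any(obs > n_categories))) {
    stop(sprintf("observed responses must lie in 1..%d", n_categories),
         call. = FALSE)
  }
  if (!is.null(group)) {
    stopifnot(length(group) == n)
    group <- as.factor(group)
  }
  if (!is.null(external_scores)) {
    external_scores <- as.data.frame(external_scores)
    stopifnot(nrow(external_scores) == n)
  }
  dimnames(values) <- list(respondent_ids, item_ids)
  structure(
    list(values = values, item_ids = as.character(item_ids),
         respondent_ids = as.character(respondent_ids),
         n_categories = as.integer(n_categories),
         group = group, external_scores = external_scores),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "response_matrix: %d respondents x %d items (1..%d), %d missing cells\n",
    nrow(x$values), ncol(x$values), x$n_categories, sum(is.na(x$values))))
  if (!is.null(x$group)) {
    cat("  groups:", paste(levels(x$group), table(x$group), sep = "=",
                           collapse = ", "), "\n")
  }
  if (!is.null(x$external_scores)) {
    cat("  external scores:",
        paste(names(x$external_scores), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

# Subset keeping metadata aligned; items by index or id, respondents by index.
subset_response_matrix <- function(data, items = NULL, respondents = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  ii <- if (is.null(items)) seq_along(data$item_ids) else items
  if (is.character(ii)) ii <- match(ii, data$item_ids)
  rr <- if (is.null(respondents)) seq_len(nrow(data$values)) else respondents
  response_matrix(
    data$values[rr, ii, drop = FALSE],
    item_ids = data$item_ids[ii],
    respondent_ids = data$respondent_ids[rr],
    n_categories = data$n_categories,
    group = if (!is.null(data$group)) droplevels(data$group[rr]),
    external_scores = if (!is.null(data$external_scores))
      data$external_scores[rr, , drop = FALSE]
  )
}

#' Read a response matrix from CSV
#'
#' The file must have a header row; the first column is the respondent id
#' and every remaining column is one item with responses coded 1..K. Blank
#' cells and `NA` become missing values. Any non-integer or out-of-range
#' entry is rejected with its row and column named in the error message.
#'
#' @param path Path to the response CSV.
#' @param n_categories Number of ordered categories K (default 5).
#' @param meta_path Optional metadata CSV keyed by respondent id, with an
#'   optional `group` column and any number of numeric external-score
#'   columns.
#' @return A [response_matrix()].
#' @export
read_response_csv <- function(path, n_categories = 5L, meta_path = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("", "NA"))
  if (ncol(raw) < 2L) {
    stop("response CSV needs a respondent-id column plus >= 1 item column",
         call. = FALSE)
  }
  ids <- raw[[1L]]
  items <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(items), nrow = nrow(items)))
  bad <- which(!is.na(items) & (is.na(num) | num != round(num) |
                                  num < 1 | num > n_categories),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid response '%s' at data row %d, column '%s' (expected 1..%d)",
      items[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
      colnames(items)[bad[1L, 2L]], n_categories), call. = FALSE)
  }
  grp <- NULL; ext <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, check.names = FALSE)
    key <- names(meta)[1L]
    m <- match(ids, as.character(meta[[key]]))
    if (anyNA(m)) {
      stop("metadata CSV is missing rows for some respondents",
           call. = FALSE)
    }
    meta <- meta[m, , drop = FALSE]
    if ("group" %in% names(meta)) grp <- meta[["group"]]
    extcols <- setdiff(names(meta), c(key, "group"))
    if (length(extcols)) ext <- meta[, extcols, drop = FALSE]
  }
  response_matrix(num, item_ids = colnames(items), respondent_ids = ids,
                  n_categories = n_categories, group = grp,
                  external_scores = ext)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_response_csv()]; missing entries are written as blank
#' cells. Group and external-score columns, when present, are written to
#' `meta_path`.
#'
#' @param data A [response_matrix()].
#' @param path Output path for the response CSV.
#' @param meta_path Optional output path for the metadata CSV.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(data, path, meta_path = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  df <- data.frame(respondent_id = data$respondent_ids,
                   data$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(meta_path)) {
    meta <- data.frame(respondent_id = data$respondent_ids)
    if (!is.null(data$group)) meta$group <- as.character(data$group)
    if (!is.null(data$external_scores)) meta <- cbind(meta,
                                                      data$external_scores)
    utils::write.csv(meta, meta_path, row.names = FALSE, na = "")
  }
  invisible(path)
}
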