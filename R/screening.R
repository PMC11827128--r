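# Pre-calibration item screening: descriptive exclusions, unidimensionality,
# local dependence and monotonicity, applied in that order with the
# conventional cutoffs (item-remainder r >= 0.3, first component >= 20% of
# variance and >= 4x the second, residual correlations <= 0.2, Loevinger
# H >= 0.3).

#' Drop respondents with any missing answer
#'
#' IRT calibration in this pipeline is complete-case: any respondent with a
#' missing answer to any item is removed before screening.
#'
#' @param data A [response_matrix()].
#' @return A [response_matrix()] with only complete respondents.
#' @export
drop_complete_case <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  keep <- rowSums(is.na(data$values)) == 0L
  if (!any(keep)) stop("no complete-case respondents remain", call. = FALSE)
  subset_response_matrix(data, respondents = which(keep))
}

#' Exclude items with unanswered categories
#'
#' An item whose observed responses never use one of the K categories cannot
#' have all its GRM parameters estimated and is excluded up front.
#'
#' @param data A [response_matrix()].
#' @return A list with `data` (retained items), `excluded` (item ids) and
#'   `n_observed_categories` (named integer vector).
#' @export
drop_unused_categories <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  k <- data$n_categories
  n_used <- apply(data$values, 2L, function(col) {
    length(unique(col[!is.na(col)]))
  })
  keep <- n_used == k
  if (!any(keep)) stop("all items have unused categories", call. = FALSE)
  list(
    data = subset_response_matrix(data, items = which(keep)),
    excluded = data$item_ids[!keep],
    n_observed_categories = stats::setNames(as.integer(n_used),
                                            data$item_ids)
  )
}

#' Item-remainder correlations with a 0.3 exclusion rule
#'
#' For each item, the Pearson correlation between that item and the sum of
#' all remaining items ("item-remainder" or corrected item-total
#' correlation). Items with r strictly below the threshold fail the
#' internal-consistency screen. The filter is one-shot: correlations are
#' computed once on the entering item set.
#'
#' @param data A [response_matrix()] with complete data and >= 3 items.
#' @param threshold Exclusion cutoff (default 0.3); items with
#'   `r < threshold` are excluded.
#' @return A list with `r` (named correlations), `data` (retained items) and
#'   `excluded` (item ids).
#' @export
item_remainder_correlations <- function(data, threshold = 0.3) {
  stopifnot(inherits(data, "response_matrix"))
  v <- data$values
  if (anyNA(v)) stop("item-remainder screen requires complete data",
                     call. = FALSE)
  if (ncol(v) < 3L) stop("need at least 3 items", call. = FALSE)
  total <- rowSums(v)
  r <- vapply(seq_len(ncol(v)), function(i) {
    x <- v[, i]; rem <- total - x
    if (stats::sd(x) == 0 || stats::sd(rem) == 0) return(NA_real_)
    stats::cor(x, rem)
  }, numeric(1L))
  names(r) <- data$item_ids
  if (anyNA(r)) {
    warning("zero-variance item or remainder; affected items excluded",
            call. = FALSE)
  }
  keep <- !is.na(r) & r >= threshold
  list(r = r,
       data = subset_response_matrix(data, items = which(keep)),
       excluded = data$item_ids[!keep])
}

# One-factor maximum-likelihood loadings from a correlation matrix.
# factanal is the workhorse; an iterated principal-axis fit is the fallback
# for matrices on which the ML optimizer fails. Loadings are clamped below
# 1 (Heywood guard).
.fa1_loadings <- function(R, n_obs) {
  fit <- try(stats::factanal(covmat = R, factors = 1L, n.obs = n_obs),
             silent = TRUE)
  if (!inherits(fit, "try-error")) {
    lam <- as.numeric(fit$loadings[, 1L])
  } else {
    lam <- .fa1_principal_axis(R)
  }
  if (any(abs(lam) >= 1)) {
    warning("Heywood case in one-factor fit; loading clamped to 0.999",
            call. = FALSE)
    lam <- pmin(pmax(lam, -0.999), 0.999)
  }
  # orient the factor positively
  if (sum(lam) < 0) lam <- -lam
  lam
}

.fa1_principal_axis <- function(R, max_iter = 200L, tol = 1e-6) {
  h2 <- 1 - 1 / diag(solve(R)) # SMC start
  for (it in seq_len(max_iter)) {
    Rr <- R; diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- e$vectors[, 1L] * sqrt(max(e$values[1L], 0))
    h2_new <- pmin(lam^2, 0.999)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  Rr <- R; diag(Rr) <- h2
  e <- eigen(Rr, symmetric = TRUE)
  e$vectors[, 1L] * sqrt(max(e$values[1L], 0))
}

#' Principal-component unidimensionality check
#'
#' Eigendecomposition of the inter-item Pearson correlation matrix. The
#' scale is accepted as unidimensional when the first component explains at
#' least `first_prop` of the total variance and at least `ratio` times the
#' second component. While either criterion fails, the item with the
#' smallest absolute loading on the first component is removed and the
#' decomposition recomputed.
#'
#' @param data A [response_matrix()] with complete data and >= 3 items.
#' @param first_prop Minimum proportion of variance for the first component
#'   (default 0.20).
#' @param ratio Minimum first/second variance ratio (default 4).
#' @return A list with `data` (retained items), `excluded` (ids in removal
#'   order), `proportions` (first and second component variance proportions
#'   on the final item set) and `passed`.
#' @export
unidimensionality_check <- function(data, first_prop = 0.20, ratio = 4) {
  stopifnot(inherits(data, "response_matrix"))
  if (anyNA(data$values)) stop("unidimensionality check requires complete data",
                               call. = FALSE)
  cur <- data
  excluded <- character(0L)
  repeat {
    if (ncol(cur$values) < 3L) {
      stop("unidimensionality criteria unreachable: fewer than 3 items left",
           call. = FALSE)
    }
    R <- stats::cor(cur$values)
    e <- eigen(R, symmetric = TRUE)
    props <- e$values / sum(e$values)
    if (props[1L] >= first_prop && props[1L] / props[2L] >= ratio) {
      return(list(data = cur, excluded = excluded,
                  proportions = c(first = props[1L], second = props[2L]),
                  passed = TRUE))
    }
    load1 <- abs(e$vectors[, 1L])
    drop_i <- which.min(load1) # ties resolve to the earliest item
    excluded <- c(excluded, cur$item_ids[drop_i])
    cur <- subset_response_matrix(cur, items = -drop_i)
  }
}

#' Local-dependence check via one-factor residual correlations
#'
#' Fits a one-factor maximum-likelihood factor model to the item correlation
#' matrix and inspects the residual matrix `R - lambda lambda'` (off the
#' diagonal). A residual correlation above `threshold` flags the pair as
#' locally dependent; the member with the smaller absolute loading on the
#' first principal component is excluded and the model re-fitted, until no
#' pair is flagged.
#'
#' @param data A [response_matrix()] with complete data and >= 3 items.
#' @param threshold Residual-correlation cutoff (default 0.2); pairs with
#'   residuals strictly above it are flagged.
#' @return A list with `data` (retained items), `excluded` (ids),
#'   `flagged_pairs` (data frame of item pairs and residuals, in flag order).
#' @export
local_dependence_check <- function(data, threshold = 0.2) {
  stopifnot(inherits(data, "response_matrix"))
  if (anyNA(data$values)) stop("local-dependence check requires complete data",
                               call. = FALSE)
  cur <- data
  excluded <- character(0L)
  flagged <- data.frame(item1 = character(0L), item2 = character(0L),
                        residual = numeric(0L))
  repeat {
    if (ncol(cur$values) < 3L) break
    R <- stats::cor(cur$values)
    lam <- .fa1_loadings(R, nrow(cur$values))
    res <- R - tcrossprod(lam)
    diag(res) <- 0
    if (max(res) <= threshold) break
    ij <- which(res == max(res), arr.ind = TRUE)[1L, ] # largest first
    i <- min(ij); j <- max(ij)
    flagged <- rbind(flagged, data.frame(
      item1 = cur$item_ids[i], item2 = cur$item_ids[j],
      residual = res[i, j]))
    # drop the member contributing less to the first principal component
    pc1 <- abs(eigen(R, symmetric = TRUE)$vectors[, 1L])
    drop_i <- if (pc1[i] < pc1[j]) i else if (pc1[j] < pc1[i]) j else j
    excluded <- c(excluded, cur$item_ids[drop_i])
    cur <- subset_response_matrix(cur, items = -drop_i)
  }
  list(data = cur, excluded = excluded, flagged_pairs = flagged)
}

#' Loevinger scalability coefficients for polytomous items
#'
#' Pairwise coefficients `H_ij = cov(X_i, X_j) / covmax(X_i, X_j)`, where
#' `covmax` is the covariance attained under the comonotonic (Frechet
#' upper-bound) coupling of the two observed marginal distributions, and
#' item coefficients
#' `H_i = sum_j cov(X_i, X_j) / sum_j covmax(X_i, X_j)`.
#' For integer-valued variables the comonotone expectation has the closed
#' form `E_max(XY) = sum_{k,l} min(P(X >= k), P(Y >= l))`.
#'
#' @param data A [response_matrix()] with complete data.
#' @return A list with `H_pair` (symmetric matrix, `NA` diagonal) and
#'   `H_item` (named vector).
#' @export
loevinger_h <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  v <- data$values
  if (anyNA(v)) stop("scalability coefficients require complete data",
                     call. = FALSE)
  n <- nrow(v); j <- ncol(v); k <- data$n_categories
  # survival probabilities P(X >= c), c = 1..K, per item
  surv <- vapply(seq_len(j), function(i) {
    vapply(seq_len(k), function(c) mean(v[, i] >= c), numeric(1L))
  }, numeric(k))
  mu <- colMeans(v)
  covm <- stats::cov(v) * (n - 1) / n # population-style, matches E_max below
  covmax <- matrix(0, j, j)
  for (i1 in seq_len(j - 1L)) {
    for (i2 in (i1 + 1L):j) {
      emax <- sum(pmin(rep(surv[, i1], each = k), rep(surv[, i2], k)))
      covmax[i1, i2] <- covmax[i2, i1] <- emax - mu[i1] * mu[i2]
    }
  }
  hp <- covm / covmax
  diag(hp) <- NA_real_
  hi <- vapply(seq_len(j), function(i) {
    sum(covm[i, -i]) / sum(covmax[i, -i])
  }, numeric(1L))
  names(hi) <- data$item_ids
  dimnames(hp) <- list(data$item_ids, data$item_ids)
  list(H_pair = hp, H_item = hi)
}

#' Monotonicity check via Mokken scalability
#'
#' Items whose Loevinger item coefficient `H_i` falls strictly below the
#' threshold are excluded as violations of monotone homogeneity. The filter
#' is one-shot: coefficients are computed once on the entering set.
#'
#' @param data A [response_matrix()] with complete data and >= 3 items.
#' @param threshold Exclusion cutoff on `H_i` (default 0.3).
#' @return A list with `data` (retained items), `excluded` (ids) and
#'   `H_item` (named coefficients on the entering set).
#' @export
monotonicity_check <- function(data, threshold = 0.3) {
  stopifnot(inherits(data, "response_matrix"))
  if (ncol(data$values) < 3L) stop("need at least 3 items", call. = FALSE)
  zerovar <- apply(data$values, 2L, stats::sd) == 0
  if (any(zerovar)) {
    warning("zero-variance item(s); scalability undefined, excluded",
            call. = FALSE)
  }
  sub <- subset_response_matrix(data, items = which(!zerovar))
  h <- loevinger_h(sub)
  hi <- rep(NA_real_, ncol(data$values))
  names(hi) <- data$item_ids
  hi[names(h$H_item)] <- h$H_item
  keep <- !is.na(hi) & hi >= threshold
  list(data = subset_response_matrix(data, items = which(keep)),
       excluded = data$item_ids[!keep],
       H_item = hi)
}

#' Run the full pre-calibration screening battery
#'
#' Applies, in order: complete-case filtering, the unused-category
#' exclusion, the item-remainder filter, the principal-component
#' unidimensionality check, the residual-correlation local-dependence
#' check, and the Mokken monotonicity check. Item counts entering and
#' leaving every stage are recorded.
#'
#' @param data A [response_matrix()].
#' @param config A [run_config()] carrying the cutoffs.
#' @return An object of class `screening_report`: list with `data` (the
#'   screened matrix), `stages` (per-stage data frame), `item_table`
#'   (per-item retained flag, exclusion stage and triggering statistic),
#'   `proportions` and `flagged_pairs`.
#' @export
screen_items <- function(data, config = run_config()) {
  stopifnot(inherits(data, "response_matrix"))
  item_ids <- data$item_ids
  stage_rows <- list()
  note <- function(stage, n_in, n_out) {
    stage_rows[[length(stage_rows) + 1L]] <<-
      data.frame(stage = stage, items_in = n_in, items_out = n_out)
  }
  excl_stage <- stats::setNames(rep("none", length(item_ids)), item_ids)
  excl_stat <- stats::setNames(rep(NA_real_, length(item_ids)), item_ids)

  cur <- drop_complete_case(data)

  uc <- drop_unused_categories(cur)
  note("unused_category", ncol(cur$values), ncol(uc$data$values))
  excl_stage[uc$excluded] <- "unused_category"
  excl_stat[uc$excluded] <- uc$n_observed_categories[uc$excluded]
  cur <- uc$data

  ir <- item_remainder_correlations(cur, config$item_remainder)
  note("item_remainder", ncol(cur$values), ncol(ir$data$values))
  excl_stage[ir$excluded] <- "item_remainder"
  excl_stat[ir$excluded] <- ir$r[ir$excluded]
  cur <- ir$data

  ud <- unidimensionality_check(cur, config$pca_first_proportion,
                                config$pca_ratio)
  note("unidimensionality", ncol(cur$values), ncol(ud$data$values))
  excl_stage[ud$excluded] <- "unidimensionality"
  cur <- ud$data

  ld <- local_dependence_check(cur, config$residual_correlation)
  note("local_dependence", ncol(cur$values), ncol(ld$data$values))
  excl_stage[ld$excluded] <- "local_dependence"
  cur <- ld$data

  mo <- monotonicity_check(cur, config$scalability)
  note("monotonicity", ncol(cur$values), ncol(mo$data$values))
  excl_stage[mo$excluded] <- "monotonicity"
  excl_stat[mo$excluded] <- mo$H_item[mo$excluded]
  cur <- mo$data

  item_table <- data.frame(
    item_id = item_ids,
    retained = excl_stage == "none",
    exclusion_stage = excl_stage,
    statistic = excl_stat,
    row.names = NULL
  )
  structure(
    list(data = cur,
         stages = do.call(rbind, stage_rows),
         item_table = item_table,
         proportions = ud$proportions,
         flagged_pairs = ld$flagged_pairs),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Item screening funnel:\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("retained %d of %d items\n", sum(x$item_table$retained),
              nrow(x$item_table)))
  invisible(x)
}
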