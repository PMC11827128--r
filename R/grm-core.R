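# Graded response model primitives: category probabilities, Fisher
# information, response sampling. Everything downstream (calibration, the
# adaptive engine, the simulator) builds on these.

PROB_FLOOR <- 1e-12

#' Construct a single graded-response-model item
#'
#' An item under Samejima's graded response model (GRM) is described by a
#' positive discrimination `a` (logistic slope) and `K - 1` strictly
#' increasing category boundaries `b` on the latent-trait scale, where `K`
#' is the number of ordered response categories.
#'
#' @param id Item identifier (string).
#' @param a Discrimination parameter, must be positive.
#' @param b Numeric vector of strictly increasing category boundaries
#'   ("difficulty" parameters), length `K - 1`.
#' @return An object of class `grm_item`.
#' @examples
#' it <- grm_item("bored", a = 1.4, b = c(-1, 0, 1, 2))
#' category_probs(it, theta = 0)
#' @export
grm_item <- function(id, a, b) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("discrimination `a` must be a positive finite number", call. = FALSE)
  }
  b <- as.numeric(b)
  if (length(b) < 1L || anyNA(b) || any(!is.finite(b))) {
    stop("thresholds `b` must be finite and non-empty", call. = FALSE)
  }
  if (any(diff(b) <= 0)) {
    stop("thresholds `b` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(id = id, a = as.numeric(a), b = b, n_categories = length(b) + 1L),
    class = "grm_item"
  )
}

#' @export
print.grm_item <- function(x, ...) {
  cat(sprintf("GRM item '%s': a = %.3f, b = (%s), K = %d\n",
              x$id, x$a, paste(sprintf("%.3f", x$b), collapse = ", "),
              x$n_categories))
  invisible(x)
}

#' Construct an item bank
#'
#' A calibrated collection of GRM items sharing a common number of response
#' categories. Internally parameters are stored as a discrimination vector
#' and a threshold matrix for vectorised evaluation.
#'
#' @param items A list of [grm_item()] objects, all with the same number of
#'   categories and unique ids.
#' @return An object of class `grm_bank` with fields `item_ids`, `a`
#'   (numeric vector), `b` (items x (K-1) matrix) and `n_categories`.
#' @export
grm_bank <- function(items) {
  stopifnot(is.list(items), length(items) >= 1L)
  ok <- vapply(items, inherits, logical(1L), what = "grm_item")
  if (!all(ok)) stop("all elements must be grm_item objects", call. = FALSE)
  ks <- vapply(items, `[[`, integer(1L), "n_categories")
  if (length(unique(ks)) != 1L) {
    stop("all items must share the same number of categories", call. = FALSE)
  }
  ids <- vapply(items, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("item ids must be unique", call. = FALSE)
  structure(
    list(
      item_ids = ids,
      a = vapply(items, `[[`, numeric(1L), "a"),
      b = do.call(rbind, lapply(items, `[[`, "b")),
      n_categories = ks[[1L]]
    ),
    class = "grm_bank"
  )
}

#' @export
print.grm_bank <- function(x, ...) {
  cat(sprintf("GRM item bank: %d items, %d categories\n",
              length(x$item_ids), x$n_categories))
  cat(sprintf("  discrimination range: [%.3f, %.3f]\n",
              min(x$a), max(x$a)))
  invisible(x)
}

#' @export
length.grm_bank <- function(x) length(x$item_ids)

#' Extract a subset of an item bank
#'
#' @param x A `grm_bank`.
#' @param i Integer or character index of items to keep (order preserved).
#' @param ... Unused.
#' @return A `grm_bank` with the selected items.
#' @export
`[.grm_bank` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$item_ids)
  if (anyNA(i)) stop("unknown item id in bank subset", call. = FALSE)
  structure(
    list(
      item_ids = x$item_ids[i],
      a = x$a[i],
      b = x$b[i, , drop = FALSE],
      n_categories = x$n_categories
    ),
    class = "grm_bank"
  )
}

#' Retrieve one item of a bank as a `grm_item`
#' @param bank A `grm_bank`.
#' @param i Index or id of the item.
#' @return A `grm_item`.
#' @export
bank_item <- function(bank, i) {
  if (is.character(i)) i <- match(i, bank$item_ids)
  grm_item(bank$item_ids[i], bank$a[i], bank$b[i, ])
}

.as_ab <- function(x) {
  # accept grm_item or grm_bank; return list(a = vector, b = matrix)
  if (inherits(x, "grm_item")) {
    list(a = x$a, b = matrix(x$b, nrow = 1L), ids = x$id,
         K = x$n_categories)
  } else if (inherits(x, "grm_bank")) {
    list(a = x$a, b = x$b, ids = x$item_ids, K = x$n_categories)
  } else {
    stop("expected a grm_item or grm_bank", call. = FALSE)
  }
}

# Cumulative boundary probabilities P*_k(theta) = P(X >= k + 1) for a whole
# parameter block at one scalar theta; returns items x (K + 1) matrix with
# the conventional boundary columns P*_0 = 1 and P*_K = 0.
.cumprobs <- function(a, b, theta) {
  p <- stats::plogis(a * (theta - b))
  cbind(1, p, 0, deparse.level = 0L)
}

# Category probabilities as adjacent differences of the boundary curves,
# floored to keep logs and divisions finite at extreme theta.
.catprobs <- function(a, b, theta, floor = PROB_FLOOR) {
  ps <- .cumprobs(a, b, theta)
  k1 <- ncol(ps)
  pmax(ps[, -k1, drop = FALSE] - ps[, -1L, drop = FALSE], floor)
}

# Fisher information of each item at scalar theta:
#   I_i(theta) = sum_k (dP*_{k-1} - dP*_k)^2 / P_k,  dP*_k = a P*_k (1 - P*_k)
.iteminfo <- function(a, b, theta) {
  ps <- .cumprobs(a, b, theta)
  dps <- a * ps * (1 - ps) # boundary columns contribute exactly 0
  k1 <- ncol(ps)
  num <- (dps[, -k1, drop = FALSE] - dps[, -1L, drop = FALSE])^2
  pk <- pmax(ps[, -k1, drop = FALSE] - ps[, -1L, drop = FALSE], PROB_FLOOR)
  rowSums(num / pk)
}

#' Cumulative category-boundary probabilities
#'
#' Evaluates the GRM boundary curves `P*_k(theta) = P(X >= k + 1)`,
#' `k = 1, ..., K - 1`, each a logistic function
#' `1 / (1 + exp(-a (theta - b_k)))`, padded with the conventional
#' boundaries `P*_0 = 1` and `P*_K = 0`.
#'
#' @param item A [grm_item()].
#' @param theta Latent-trait value (scalar).
#' @return Numeric vector of length `K + 1`, non-increasing.
#' @export
cumulative_probs <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"), is.numeric(theta),
            length(theta) == 1L)
  drop(.cumprobs(item$a, matrix(item$b, nrow = 1L), theta))
}

#' Category response probabilities
#'
#' Probability of each ordered response category under the GRM,
#' `P_k = P*_{k-1} - P*_k`.
#'
#' @inheritParams cumulative_probs
#' @return Numeric vector of length `K`; entries sum to 1.
#' @export
category_probs <- function(item, theta) {
  ps <- cumulative_probs(item, theta)
  diff(-ps)
}

#' Item Fisher information
#'
#' Expected (Fisher) information of one graded item at `theta`, the quantity
#' maximised during adaptive item selection:
#' `I(theta) = sum_k (dP*_{k-1}/dtheta - dP*_k/dtheta)^2 / P_k` with
#' `dP*/dtheta = a P* (1 - P*)`.
#'
#' @inheritParams cumulative_probs
#' @return Nonnegative scalar.
#' @export
item_information <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"), is.numeric(theta),
            length(theta) == 1L)
  .iteminfo(item$a, matrix(item$b, nrow = 1L), theta)
}

#' Test information of a set of items
#'
#' Fisher information is additive over locally independent items; the test
#' information is the plain sum. Its reciprocal square root (plus the prior
#' precision, see [score_map()]) gives the standard error of measurement.
#'
#' @param bank A `grm_bank` (or a `grm_item`, treated as a one-item bank).
#' @param theta Latent-trait value (scalar).
#' @return Nonnegative scalar.
#' @export
test_information <- function(bank, theta) {
  ab <- .as_ab(bank)
  if (length(ab$a) == 0L) stop("empty item set", call. = FALSE)
  sum(.iteminfo(ab$a, ab$b, theta))
}

#' Sample responses from the GRM
#'
#' Draws ordinal responses (coded 1..K) from the model-implied category
#' distribution, one draw per element of `theta`. Used by the CAT simulator
#' and the synthetic-data generator. Uses R's global random number stream;
#' seed with [set.seed()] for reproducibility.
#'
#' @param item A [grm_item()].
#' @param theta Numeric vector of latent-trait values.
#' @return Integer vector of the same length as `theta`, values in 1..K.
#' @export
sample_response <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"), is.numeric(theta))
  .sample_item(item$a, item$b, theta)
}

# Inverse-CDF draw: X = 1 + #{k : u < P*_k}, k = 1..K-1, so that
# P(X = m) = P*_{m-1} - P*_m.
.sample_item <- function(a, b, theta) {
  u <- stats::runif(length(theta))
  ps <- stats::plogis(a * outer(theta, b, `-`)) # n x (K-1)
  1L + as.integer(rowSums(u < ps))
}

#' Convert location thresholds to slope-intercept form and back
#'
#' The package stores GRM items in discrimination/location form,
#' `a (theta - b_k)`; some software reports slope-intercept form
#' `a theta + d_k` with `d_k = -a b_k`. These helpers convert between the
#' two parameterizations.
#'
#' @param a Discrimination.
#' @param b Location thresholds (for `ab_to_intercept`).
#' @param d Intercepts (for `intercept_to_ab`).
#' @return A list with components `a` and `d` (or `a` and `b`).
#' @export
ab_to_intercept <- function(a, b) list(a = a, d = -a * b)

#' @rdname ab_to_intercept
#' @export
intercept_to_ab <- function(a, d) list(a = a, b = -d / a)

#' Read an item bank from JSON
#'
#' Expected schema:
#' `{"n_categories": K, "items": [{"id": str, "a": num, "b": [num, ...]}]}`.
#' The schema is validated and all item invariants are enforced on read;
#' write followed by read reproduces the bank to within 1e-12.
#'
#' @param path Path to a JSON file.
#' @return A `grm_bank`.
#' @export
read_bank_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$n_categories) || is.null(obj$items)) {
    stop("bank JSON must have fields 'n_categories' and 'items'",
         call. = FALSE)
  }
  k <- as.integer(obj$n_categories)
  items <- lapply(obj$items, function(it) {
    if (is.null(it$id) || is.null(it$a) || is.null(it$b)) {
      stop("each bank item needs fields 'id', 'a', 'b'", call. = FALSE)
    }
    b <- as.numeric(unlist(it$b))
    if (length(b) != k - 1L) {
      stop(sprintf("item '%s': expected %d thresholds, found %d",
                   it$id, k - 1L, length(b)), call. = FALSE)
    }
    grm_item(as.character(it$id), as.numeric(it$a), b)
  })
  grm_bank(items)
}

#' Write an item bank to JSON
#'
#' @param bank A `grm_bank`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bank_json <- function(bank, path) {
  stopifnot(inherits(bank, "grm_bank"))
  obj <- list(
    n_categories = bank$n_categories,
    items = lapply(seq_along(bank$item_ids), function(i) {
      list(id = bank$item_ids[i], a = bank$a[i], b = as.numeric(bank$b[i, ]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
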