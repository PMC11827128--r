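# GRM calibration by marginal maximum likelihood (Bock-Aitkin EM over a
# fixed quadrature with a normal latent density), MAP trait scoring, and the
# post-calibration item screens: never-modal categories, S-X2 item fit, DIF
# by multigroup likelihood ratio, and Cronbach's alpha.

# ---- quadrature and probability tables -------------------------------------

.quadrature <- function(n = 61L, range = c(-6, 6), mean = 0, sd = 1) {
  pts <- seq(range[1L], range[2L], length.out = n)
  w <- stats::dnorm(pts, mean, sd)
  list(points = pts, weights = w / sum(w))
}

# Per-item K x Q category-probability tables over a grid.
.prob_tables <- function(a, b, grid) {
  kk <- ncol(b) + 1L
  lapply(seq_along(a), function(i) {
    z <- a[i] * outer(-b[i, ], grid, `+`) # (K-1) x Q of a (theta - b)
    ps <- stats::plogis(z)
    p <- rbind(1, ps) - rbind(ps, 0)
    matrix(pmax(p, PROB_FLOOR), nrow = kk)
  })
}

# ---- E-step ----------------------------------------------------------------

# Marginal log-likelihood, per-item expected category-by-node counts, and
# posterior trait moments, accumulated in compiled code.
# resp: n x I integer matrix (1..K), complete.
.estep <- function(resp, a, b, grid, weights) {
  .estep_cpp(resp, a, b, grid, log(weights))
}

# ---- M-step ----------------------------------------------------------------

# Per-item safeguarded-Newton maximisation of the expected complete-data
# log-likelihood on the unconstrained scale (log a, b_1, log threshold
# gaps) that keeps thresholds ordered by construction; the compiled line
# search never lowers the objective, preserving the EM ascent property.
.mstep_item <- function(r, grid, a0, b0) {
  kk <- nrow(r)
  par0 <- c(log(a0), b0[1L], if (kk > 2L) log(diff(b0)))
  par <- .mstep_newton_cpp(par0, r, grid)
  gaps <- if (kk > 2L) exp(par[3:kk]) else numeric(0L)
  list(a = exp(par[1L]), b = par[2L] + c(0, cumsum(gaps)))
}

# Deterministic start values: unit slopes, thresholds at the logistic
# quantiles of the observed cumulative category proportions.
.start_values <- function(resp, kk) {
  n <- nrow(resp)
  b <- t(vapply(seq_len(ncol(resp)), function(i) {
    pge <- vapply(2:kk, function(c) mean(resp[, i] >= c), numeric(1L))
    pge <- pmin(pmax(pge, 1 / (2 * n)), 1 - 1 / (2 * n))
    bi <- stats::qlogis(pge)
    # enforce a minimal gap so the ordering invariant holds at the start
    for (m in seq_along(bi)[-1L]) bi[m] <- max(bi[m], bi[m - 1L] + 0.05)
    bi
  }, numeric(kk - 1L)))
  list(a = rep(1, ncol(resp)), b = matrix(b, ncol = kk - 1L))
}

# ---- single-group fit ------------------------------------------------------

#' Fit a graded response model by marginal maximum likelihood
#'
#' Bock-Aitkin EM: the latent trait is integrated over a fixed quadrature
#' grid with standard-normal weights; the E-step computes each respondent's
#' posterior over the grid and expected category-by-node counts, and the
#' M-step maximises each item's expected complete-data log-likelihood by
#' quasi-Newton steps on an unconstrained parameterization (log slope,
#' first threshold, log threshold gaps) that keeps thresholds ordered. The
#' marginal log-likelihood is non-decreasing across iterations.
#'
#' After convergence every complete-case respondent is scored by maximum a
#' posteriori ([score_map()]); these full-bank scores serve as the reference
#' trait values (`theta_true`) for CAT simulation.
#'
#' @param data A [response_matrix()]; complete data, every item using all K
#'   categories.
#' @param n_quad Number of quadrature nodes (default 61).
#' @param quad_range Quadrature range (default `c(-6, 6)`).
#' @param tol Convergence tolerance on the maximum absolute parameter change
#'   (default 1e-4).
#' @param max_iter Maximum EM iterations (default 500).
#' @param start Optional list with components `a` and `b` for warm starts.
#' @param score Compute MAP scores for every respondent (default `TRUE`);
#'   disable when only item parameters are needed.
#' @return An object of class `grm_calibration`: `bank` (the estimated
#'   `grm_bank`), `theta` (data frame of MAP `value` and `se` per
#'   respondent; `NULL` when `score = FALSE`), `log_likelihood`,
#'   `ll_trace`, `n_em_iterations`, `converged`, `alpha` (Cronbach's alpha
#'   of the calibrated items).
#' @export
fit_grm <- function(data, n_quad = 61L, quad_range = c(-6, 6), tol = 1e-4,
                    max_iter = 500L, start = NULL, score = TRUE) {
  stopifnot(inherits(data, "response_matrix"))
  resp <- data$values
  if (anyNA(resp)) stop("calibration requires complete data; see drop_complete_case()",
                        call. = FALSE)
  kk <- data$n_categories
  used <- apply(resp, 2L, function(col) length(unique(col)))
  if (any(used < kk)) {
    stop("every item must use all categories; see drop_unused_categories()",
         call. = FALSE)
  }
  quad <- .quadrature(n_quad, quad_range)
  par <- if (is.null(start)) .start_values(resp, kk) else start
  ll_trace <- numeric(0L)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    es <- .estep(resp, par$a, par$b, quad$points, quad$weights)
    ll_trace <- c(ll_trace, es$ll)
    new_a <- par$a; new_b <- par$b
    for (i in seq_len(ncol(resp))) {
      up <- .mstep_item(es$counts[[i]], quad$points, par$a[i], par$b[i, ])
      new_a[i] <- up$a; new_b[i, ] <- up$b
    }
    delta <- max(abs(c(new_a - par$a, new_b - par$b)))
    par <- list(a = new_a, b = new_b)
    if (delta < tol) { converged <- TRUE; break }
  }
  ll_final <- .estep(resp, par$a, par$b, quad$points, quad$weights)$ll
  ll_trace <- c(ll_trace, ll_final)
  if (any(par$a > 8)) {
    warning("item(s) with estimated discrimination > 8 (quasi-Guttman): ",
            paste(data$item_ids[par$a > 8], collapse = ", "), call. = FALSE)
  }
  bank <- grm_bank(lapply(seq_len(ncol(resp)), function(i) {
    grm_item(data$item_ids[i], par$a[i], par$b[i, ])
  }))
  theta <- if (score) score_map_matrix(bank, resp) else NULL
  structure(
    list(bank = bank, theta = theta, log_likelihood = ll_final,
         ll_trace = ll_trace, n_em_iterations = it, converged = converged,
         alpha = cronbach_alpha(data), respondent_ids = data$respondent_ids),
    class = "grm_calibration"
  )
}

#' @export
print.grm_calibration <- function(x, ...) {
  cat(sprintf(
    "GRM calibration: %d items, %d respondents\n  logLik %.2f after %d EM iterations (%s)\n  Cronbach's alpha %.3f\n",
    length(x$bank$item_ids), length(x$respondent_ids), x$log_likelihood,
    x$n_em_iterations, if (x$converged) "converged" else "NOT converged",
    x$alpha))
  invisible(x)
}

# ---- MAP scoring -----------------------------------------------------------

#' Maximum a posteriori trait estimate
#'
#' Bayesian-mode scoring: maximises the GRM log-likelihood of the observed
#' responses plus a normal log prior over a bounded interval. The standard
#' error of measurement is the reciprocal square root of the posterior
#' information, `1 / sqrt(I_test(theta_hat) + 1 / prior_sd^2)`, so it is
#' defined even before any item has been answered (se = `prior_sd`, estimate
#' = `prior_mean`).
#'
#' @param bank A `grm_bank` (the administered items).
#' @param responses Integer vector of responses 1..K aligned with the bank;
#'   `NA` entries (items not administered) are ignored.
#' @param prior_mean,prior_sd Normal prior on the trait (default standard
#'   normal).
#' @param bounds Search interval (default `c(-6, 6)`).
#' @return A list with `value` (the posterior mode) and `se`.
#' @export
score_map <- function(bank, responses, prior_mean = 0, prior_sd = 1,
                      bounds = c(-6, 6)) {
  stopifnot(inherits(bank, "grm_bank"))
  keep <- which(!is.na(responses))
  if (length(responses) != length(bank$item_ids)) {
    stop("responses must align with the bank items", call. = FALSE)
  }
  if (length(keep) == 0L) {
    return(list(value = prior_mean, se = prior_sd))
  }
  a <- bank$a[keep]; b <- bank$b[keep, , drop = FALSE]
  x <- as.integer(responses[keep])
  if (any(x < 1L | x > bank$n_categories)) {
    stop("responses out of category range", call. = FALSE)
  }
  negpost <- function(theta) {
    p <- .catprobs(a, b, theta)
    -(sum(log(p[cbind(seq_along(x), x)])) +
        stats::dnorm(theta, prior_mean, prior_sd, log = TRUE))
  }
  opt <- stats::optimize(negpost, bounds, tol = 1e-6)
  mode <- opt$minimum
  info <- sum(.iteminfo(a, b, mode)) + 1 / prior_sd^2
  list(value = mode, se = 1 / sqrt(info))
}

#' MAP scores for every row of a response matrix
#'
#' @param bank A `grm_bank`.
#' @param values Integer matrix (respondents x items) aligned with the bank.
#' @param ... Passed to [score_map()].
#' @return Data frame with columns `value` and `se`, one row per respondent.
#' @export
score_map_matrix <- function(bank, values, ...) {
  out <- vapply(seq_len(nrow(values)), function(j) {
    s <- score_map(bank, values[j, ], ...)
    c(s$value, s$se)
  }, numeric(2L))
  data.frame(value = out[1L, ], se = out[2L, ])
}

# ---- never-modal category screen -------------------------------------------

#' Exclude items with categories that are never modal
#'
#' A well-behaved graded item has every response category most probable
#' somewhere on the trait continuum. Items with a category that is never
#' the most probable response at any grid point (for example because two
#' thresholds nearly coincide) are flagged for exclusion. Ties at the
#' maximum count for all tied categories.
#'
#' @param bank A `grm_bank`.
#' @param theta_grid Evaluation grid (default `seq(-4, 4, 0.01)`).
#' @return A list with `excluded` (item ids) and `never_modal` (named list
#'   of the offending category indices per excluded item).
#' @export
never_modal_category_screen <- function(bank,
                                        theta_grid = seq(-4, 4, by = 0.01)) {
  stopifnot(inherits(bank, "grm_bank"))
  ptabs <- .prob_tables(bank$a, bank$b, theta_grid)
  never <- lapply(ptabs, function(p) {
    cmx <- matrix(apply(p, 2L, max), nrow(p), ncol(p), byrow = TRUE)
    modal_somewhere <- rowSums(p >= cmx - 1e-12) > 0
    which(!modal_somewhere)
  })
  bad <- vapply(never, length, integer(1L)) > 0L
  list(excluded = bank$item_ids[bad],
       never_modal = stats::setNames(never[bad], bank$item_ids[bad]))
}

# ---- S-X2 item fit ---------------------------------------------------------

# Generalized Lord-Wingersky recursion: distribution of the summed score
# (items scored 0..K-1) conditional on each quadrature node.
# ptabs: list of K x Q matrices. Returns (S_max + 1) x Q matrix, row s + 1
# holding P(summed score = s | theta_q).
.lord_wingersky <- function(ptabs) {
  nq <- ncol(ptabs[[1L]])
  L <- matrix(1, 1L, nq)
  for (p in ptabs) {
    kk <- nrow(p)
    s_old <- nrow(L)
    Lnew <- matrix(0, s_old + kk - 1L, nq)
    for (k in seq_len(kk)) {
      rows <- k:(k + s_old - 1L)
      Lnew[rows, ] <- Lnew[rows, ] + L * rep(p[k, ], each = s_old)
    }
    L <- Lnew
  }
  L
}

# Greedy collapsing of rest-score levels: walk levels in order and merge
# until every expected cell in the running group reaches min_expected; a
# trailing underfull group is merged backwards.
.collapse_rows <- function(O, E, min_expected = 1) {
  groups <- list(); cur <- integer(0L)
  for (s in seq_len(nrow(E))) {
    cur <- c(cur, s)
    if (all(colSums(E[cur, , drop = FALSE]) >= min_expected)) {
      groups[[length(groups) + 1L]] <- cur
      cur <- integer(0L)
    }
  }
  if (length(cur)) {
    if (length(groups)) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
    } else {
      groups[[1L]] <- cur
    }
  }
  o2 <- t(vapply(groups, function(g) colSums(O[g, , drop = FALSE]),
                 numeric(ncol(O))))
  e2 <- t(vapply(groups, function(g) colSums(E[g, , drop = FALSE]),
                 numeric(ncol(E))))
  list(O = o2, E = e2)
}

# Within-row collapsing of adjacent category cells below min_expected.
.collapse_cells <- function(o_row, e_row, min_expected = 1) {
  o <- numeric(0L); e <- numeric(0L)
  co <- 0; ce <- 0
  for (k in seq_along(e_row)) {
    co <- co + o_row[k]; ce <- ce + e_row[k]
    if (ce >= min_expected) { o <- c(o, co); e <- c(e, ce); co <- 0; ce <- 0 }
  }
  if (ce > 0) {
    if (length(e)) {
      o[length(o)] <- o[length(o)] + co
      e[length(e)] <- e[length(e)] + ce
    } else {
      o <- co; e <- ce
    }
  }
  list(o = o, e = e)
}

#' S-X2 item-fit statistics
#'
#' Orlando-Thissen-type fit: for every item, observed category counts
#' conditional on the rest score (summed score over the other items) are
#' compared with the model-expected counts, obtained by the generalized
#' Lord-Wingersky recursion over the latent-density quadrature. Adjacent
#' rest-score levels (and, within a level, adjacent category cells) with
#' expected counts below 1 are collapsed. The statistic
#' `sum((O - E)^2 / E)` is referred to a chi-square distribution with
#' degrees of freedom `sum(cells per level - 1) - (K free item parameters)`.
#' Items with `p < alpha` fail the screen.
#'
#' @param bank A calibrated `grm_bank`.
#' @param data The [response_matrix()] the bank was fitted on (complete).
#' @param alpha Exclusion level (default 0.01).
#' @param n_quad,quad_range Quadrature settings (defaults as in
#'   [fit_grm()]).
#' @return A data frame with one row per item: `item_id`, `statistic`, `df`,
#'   `p_value`, `excluded`. Items whose table collapses to nonpositive
#'   degrees of freedom get `NA` p-values and are retained with a warning.
#' @export
s_x2_item_fit <- function(bank, data, alpha = 0.01, n_quad = 61L,
                          quad_range = c(-6, 6)) {
  stopifnot(inherits(bank, "grm_bank"), inherits(data, "response_matrix"))
  resp <- data$values
  if (anyNA(resp)) stop("item-fit screen requires complete data", call. = FALSE)
  ni <- ncol(resp)
  if (!identical(data$item_ids, bank$item_ids)) {
    stop("bank and data items must align", call. = FALSE)
  }
  kk <- bank$n_categories
  quad <- .quadrature(n_quad, quad_range)
  ptabs <- .prob_tables(bank$a, bank$b, quad$points)
  out <- data.frame(item_id = bank$item_ids, statistic = NA_real_,
                    df = NA_integer_, p_value = NA_real_, excluded = FALSE)
  for (i in seq_len(ni)) {
    lmi <- .lord_wingersky(ptabs[-i])
    denom <- as.numeric(lmi %*% quad$weights)
    # expected P(X_i = k | rest = s): (S+1) x K
    num <- lmi %*% t(ptabs[[i]] * rep(quad$weights, each = kk))
    rest <- rowSums(resp[, -i, drop = FALSE] - 1L)
    ns <- tabulate(rest + 1L, nbins = nrow(lmi))
    obs <- matrix(0, nrow(lmi), kk)
    for (k in seq_len(kk)) {
      obs[, k] <- tabulate(rest[resp[, i] == k] + 1L, nbins = nrow(lmi))
    }
    keep <- ns > 0L
    pred <- num[keep, , drop = FALSE] / denom[keep]
    E <- pred * ns[keep]
    O <- obs[keep, , drop = FALSE]
    cl <- .collapse_rows(O, E)
    x2 <- 0; cells <- 0L
    for (s in seq_len(nrow(cl$E))) {
      cc <- .collapse_cells(cl$O[s, ], cl$E[s, ])
      x2 <- x2 + sum((cc$o - cc$e)^2 / cc$e)
      cells <- cells + length(cc$e)
    }
    df <- cells - nrow(cl$E) - kk # sum(cells - 1) minus K free parameters
    out$statistic[i] <- x2
    out$df[i] <- df
    if (df > 0L) {
      out$p_value[i] <- stats::pchisq(x2, df, lower.tail = FALSE)
      out$excluded[i] <- out$p_value[i] < alpha
    }
  }
  if (any(out$df <= 0L, na.rm = TRUE)) {
    warning("item(s) with nonpositive df after collapsing; fit not testable, retained",
            call. = FALSE)
  }
  out
}

# ---- DIF screen ------------------------------------------------------------

# Two-group Bock-Aitkin EM. Reference group has a fixed standard-normal
# latent density; the focal group's latent mean and variance are free and
# updated from posterior moments each cycle. Items in `free_items` carry
# separate parameters per group; all others are shared.
.fit_grm_twogroup <- function(resp, group, kk, free_items = integer(0L),
                              n_quad = 61L, quad_range = c(-6, 6),
                              tol = 1e-4, max_iter = 500L, start = NULL) {
  g1 <- group == levels(group)[1L]
  resp1 <- resp[g1, , drop = FALSE]
  resp2 <- resp[!g1, , drop = FALSE]
  quad <- .quadrature(n_quad, quad_range)
  par <- if (is.null(start)) .start_values(resp, kk) else start
  a <- list(par$a, par$a); b <- list(par$b, par$b)
  mu2 <- 0; sd2 <- 1
  converged <- FALSE
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    w2 <- stats::dnorm(quad$points, mu2, sd2); w2 <- w2 / sum(w2)
    e1 <- .estep(resp1, a[[1L]], b[[1L]], quad$points, quad$weights)
    e2 <- .estep(resp2, a[[2L]], b[[2L]], quad$points, w2)
    ll <- e1$ll + e2$ll
    old_a <- a; old_b <- b
    for (i in seq_len(ncol(resp))) {
      if (i %in% free_items) {
        u1 <- .mstep_item(e1$counts[[i]], quad$points, a[[1L]][i], b[[1L]][i, ])
        u2 <- .mstep_item(e2$counts[[i]], quad$points, a[[2L]][i], b[[2L]][i, ])
        a[[1L]][i] <- u1$a; b[[1L]][i, ] <- u1$b
        a[[2L]][i] <- u2$a; b[[2L]][i, ] <- u2$b
      } else {
        u <- .mstep_item(e1$counts[[i]] + e2$counts[[i]], quad$points,
                         a[[1L]][i], b[[1L]][i, ])
        a[[1L]][i] <- u$a; b[[1L]][i, ] <- u$b
        a[[2L]][i] <- u$a; b[[2L]][i, ] <- u$b
      }
    }
    # focal-group density update from posterior moments
    mu2_new <- mean(e2$e_theta)
    sd2_new <- sqrt(mean(e2$e_theta2) - mu2_new^2)
    delta <- max(abs(c(unlist(a) - unlist(old_a), unlist(b) - unlist(old_b),
                       mu2_new - mu2, sd2_new - sd2)))
    mu2 <- mu2_new; sd2 <- sd2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  w2 <- stats::dnorm(quad$points, mu2, sd2); w2 <- w2 / sum(w2)
  ll <- .estep(resp1, a[[1L]], b[[1L]], quad$points, quad$weights)$ll +
    .estep(resp2, a[[2L]], b[[2L]], quad$points, w2)$ll
  list(a = a, b = b, mu2 = mu2, sd2 = sd2, ll = ll, converged = converged)
}

#' Differential item functioning screen (two-group likelihood ratio)
#'
#' Tests each item for DIF between two groups (for example sex) with a
#' multigroup GRM likelihood-ratio test. The constrained model holds all
#' item parameters equal across groups while the focal group's latent mean
#' and variance are free; the per-item model additionally frees that item's
#' parameters in both groups (all other items acting as anchors). Twice the
#' log-likelihood gain is referred to a chi-square with K degrees of freedom
#' (one slope plus K - 1 thresholds); items with `p < alpha` fail.
#'
#' Items with a response category unused in either group cannot be tested
#' and are skipped with a warning.
#'
#' @param data A complete-case [response_matrix()] whose `group` field (or
#'   the `group` argument) has exactly two levels, each with at least 50
#'   respondents.
#' @param group Optional two-level factor overriding `data$group`.
#' @param alpha Exclusion level (default 0.01).
#' @param n_quad,quad_range,tol,max_iter EM settings as in [fit_grm()].
#' @return A data frame per item: `item_id`, `statistic`, `df`, `p_value`,
#'   `excluded`, `tested`.
#' @export
dif_screen <- function(data, group = NULL, alpha = 0.01, n_quad = 61L,
                       quad_range = c(-6, 6), tol = 1e-4, max_iter = 500L) {
  stopifnot(inherits(data, "response_matrix"))
  grp <- if (is.null(group)) data$group else as.factor(group)
  if (is.null(grp) || nlevels(grp) != 2L) {
    stop("DIF screen needs a two-level group", call. = FALSE)
  }
  resp <- data$values
  if (anyNA(resp)) stop("DIF screen requires complete data", call. = FALSE)
  if (any(table(grp) < 50L)) {
    stop("each group needs at least 50 complete respondents", call. = FALSE)
  }
  kk <- data$n_categories
  ni <- ncol(resp)
  # testable: all categories used within both groups
  testable <- vapply(seq_len(ni), function(i) {
    all(vapply(levels(grp), function(g) {
      length(unique(resp[grp == g, i])) == kk
    }, logical(1L)))
  }, logical(1L))
  if (any(!testable)) {
    warning("item(s) with group-specific unused categories skipped: ",
            paste(data$item_ids[!testable], collapse = ", "), call. = FALSE)
  }
  base <- .fit_grm_twogroup(resp, grp, kk, integer(0L), n_quad, quad_range,
                            tol, max_iter)
  warm <- list(a = base$a[[1L]], b = base$b[[1L]])
  out <- data.frame(item_id = data$item_ids, statistic = NA_real_,
                    df = as.integer(kk), p_value = NA_real_,
                    excluded = FALSE, tested = testable)
  for (i in which(testable)) {
    free <- .fit_grm_twogroup(resp, grp, kk, i, n_quad, quad_range,
                              tol, max_iter, start = warm)
    lr <- max(0, 2 * (free$ll - base$ll))
    out$statistic[i] <- lr
    out$p_value[i] <- stats::pchisq(lr, kk, lower.tail = FALSE)
    out$excluded[i] <- out$p_value[i] < alpha
  }
  out
}

# ---- Cronbach's alpha ------------------------------------------------------

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = J / (J - 1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param data A complete [response_matrix()] (or a plain numeric matrix)
#'   with at least two items.
#' @return The alpha coefficient (at most 1; can be negative for incoherent
#'   scales).
#' @export
cronbach_alpha <- function(data) {
  v <- if (inherits(data, "response_matrix")) data$values else as.matrix(data)
  if (anyNA(v)) stop("Cronbach's alpha requires complete data", call. = FALSE)
  jj <- ncol(v)
  if (jj < 2L) stop("need at least 2 items", call. = FALSE)
  tot_var <- stats::var(rowSums(v))
  if (tot_var == 0) stop("total score has zero variance", call. = FALSE)
  (jj / (jj - 1)) * (1 - sum(apply(v, 2L, stats::var)) / tot_var)
}
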