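# CAT simulation over a calibrated sample -- how well do adaptive scores
# track full-bank scores? -- plus the concurrent/discriminant validity
# statistics.

#' Simulate adaptive testing over a calibrated sample
#'
#' For every respondent, runs a full CAT session against the supplied bank.
#' In the default (resampling) mode the responses are freshly drawn from
#' the GRM at the respondent's reference trait value `theta_true`; with
#' `replay` the observed response matrix is replayed instead, in which case
#' forcing the full bank (`sem = 0`) reproduces the full-bank MAP score
#' exactly. Accuracy is summarised by the Pearson correlation between the
#' final CAT estimates and `theta_true` (Fisher-z 95% CI) and the average
#' number of items administered.
#'
#' @param bank A calibrated `grm_bank`.
#' @param theta_true Numeric vector of reference trait values (typically
#'   the full-bank MAP scores from [fit_grm()]), one per respondent.
#' @param config A [run_config()]; `sem`, `min_items`, `max_items` govern
#'   stopping.
#' @param seed Optional integer seed for the simulated responses.
#' @param replay Optional integer response matrix (respondents x bank
#'   items); when given, session responses are looked up instead of
#'   sampled.
#' @return An object of class `cat_simulation`: `respondents` (data frame
#'   with `theta_true`, `theta_est`, `se`, `n_items`, `stop_reason`),
#'   `pcc`, `pcc_ci_low`, `pcc_ci_high`, `mean_items`.
#' @export
simulate_cat <- function(bank, theta_true, config = run_config(),
                         seed = NULL, replay = NULL) {
  stopifnot(inherits(bank, "grm_bank"), is.numeric(theta_true))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(replay)) {
    stopifnot(nrow(replay) == length(theta_true),
              ncol(replay) == length(bank$item_ids))
  }
  n <- length(theta_true)
  res <- vector("list", n)
  for (j in seq_len(n)) {
    responder <- if (is.null(replay)) NULL else {
      local({
        row <- replay[j, ]
        function(item_id) row[match(item_id, bank$item_ids)]
      })
    }
    s <- run_session(bank, responder = responder,
                     theta_true = theta_true[j], config = config)
    res[[j]] <- data.frame(theta_true = theta_true[j], theta_est = s$theta,
                           se = s$se, n_items = length(s$administered),
                           stop_reason = s$stop_reason)
  }
  respondents <- do.call(rbind, res)
  pc <- pearson_ci(respondents$theta_est, respondents$theta_true)
  structure(
    list(respondents = respondents,
         pcc = pc$r, pcc_ci_low = pc$ci_low, pcc_ci_high = pc$ci_high,
         mean_items = mean(respondents$n_items)),
    class = "cat_simulation"
  )
}

#' @export
print.cat_simulation <- function(x, ...) {
  cat(sprintf(
    "CAT simulation: %d respondents\n  PCC(theta_est, theta_true) = %.3f (95%% CI %.3f-%.3f)\n  average items administered = %.3f\n",
    nrow(x$respondents), x$pcc, x$pcc_ci_low, x$pcc_ci_high, x$mean_items))
  invisible(x)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length (>= 4), neither constant.
#' @param level Confidence level (default 0.95).
#' @return A list with `r`, `ci_low`, `ci_high`.
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(length(x) - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(r = r, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se))
}

#' Concurrent validity against external criterion scores
#'
#' Pearson correlations (with Fisher-z CIs) between the trait estimates and
#' each external score column, e.g. an established depression or anxiety
#' scale. A negative correlation is the expected direction when the trait
#' (say positive affect) opposes the criterion; the `expected_sign`
#' argument records that convention in the output.
#'
#' @param theta_est Numeric vector of trait estimates.
#' @param external Data frame of numeric criterion columns, same number of
#'   rows.
#' @param expected_sign Optional named vector of +1/-1 per column.
#' @return A data frame per criterion: `criterion`, `r`, `ci_low`,
#'   `ci_high`, `expected_sign`, `sign_consistent`.
#' @export
concurrent_validity <- function(theta_est, external, expected_sign = NULL) {
  external <- as.data.frame(external)
  if (nrow(external) != length(theta_est)) {
    stop("external scores must match the respondents", call. = FALSE)
  }
  out <- lapply(names(external), function(nm) {
    pc <- pearson_ci(theta_est, external[[nm]])
    es <- if (!is.null(expected_sign) && nm %in% names(expected_sign)) {
      sign(expected_sign[[nm]])
    } else {
      NA_real_
    }
    data.frame(criterion = nm, r = pc$r, ci_low = pc$ci_low,
               ci_high = pc$ci_high, expected_sign = es,
               sign_consistent = if (is.na(es)) NA else sign(pc$r) == es)
  })
  do.call(rbind, out)
}

#' Discriminant validity: group comparisons of trait estimates
#'
#' Two-sample t-tests (Welch by default) comparing trait estimates between
#' configured pairs of groups, e.g. a clinical group against healthy
#' controls.
#'
#' @param theta_est Numeric vector of trait estimates.
#' @param group Factor of group labels, same length.
#' @param comparisons List of length-2 character vectors
#'   `c(group_a, group_b)`; default compares the first two levels.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A data frame per comparison: group names, per-group `n`, `mean`,
#'   `sd`, `t`, `df`, `p_value`.
#' @export
discriminant_validity <- function(theta_est, group, comparisons = NULL,
                                  var_equal = FALSE) {
  group <- as.factor(group)
  stopifnot(length(theta_est) == length(group))
  if (is.null(comparisons)) {
    if (nlevels(group) < 2L) stop("need at least two groups", call. = FALSE)
    comparisons <- list(levels(group)[1:2])
  }
  out <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2L)
    xa <- theta_est[group == cmp[1L]]
    xb <- theta_est[group == cmp[2L]]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop(sprintf("comparison %s vs %s: need >= 2 respondents per group",
                   cmp[1L], cmp[2L]), call. = FALSE)
    }
    tt <- stats::t.test(xa, xb, var.equal = var_equal)
    data.frame(group_a = cmp[1L], group_b = cmp[2L],
               n_a = length(xa), n_b = length(xb),
               mean_a = mean(xa), sd_a = stats::sd(xa),
               mean_b = mean(xb), sd_b = stats::sd(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  do.call(rbind, out)
}
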