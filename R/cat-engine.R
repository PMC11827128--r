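# The adaptive test: maximum-Fisher-information item selection, Bayesian
# mode (MAP) trait updating after every response, and precision-based
# stopping (SEM threshold with a minimum item count, or bank exhaustion).

#' Start a computerized adaptive testing session
#'
#' @param bank A calibrated `grm_bank`.
#' @param config A [run_config()]; `sem`, `min_items` and `max_items` govern
#'   stopping. `max_items = NULL` means the full bank size.
#' @param theta_start Trait estimate before any response (default 0).
#' @param prior_mean,prior_sd Normal prior used by the MAP update.
#' @return An object of class `cat_session`.
#' @export
cat_session <- function(bank, config = run_config(), theta_start = 0,
                        prior_mean = 0, prior_sd = 1) {
  stopifnot(inherits(bank, "grm_bank"))
  max_items <- config$max_items
  if (is.null(max_items)) max_items <- length(bank$item_ids)
  max_items <- min(max_items, length(bank$item_ids))
  stopifnot(config$min_items <= max_items)
  structure(
    list(bank = bank,
         administered = integer(0L),
         responses = integer(0L),
         theta = theta_start, se = prior_sd,
         trajectory = list(),
         stopped = FALSE, stop_reason = NA_character_,
         sem_threshold = config$sem,
         min_items = as.integer(config$min_items),
         max_items = as.integer(max_items),
         theta_start = theta_start,
         prior_mean = prior_mean, prior_sd = prior_sd),
    class = "cat_session"
  )
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf(
    "CAT session: %d item(s) administered, theta = %.3f (SEM %.3f)%s\n",
    length(x$administered), x$theta, x$se,
    if (x$stopped) sprintf(", stopped (%s)", x$stop_reason) else ""))
  invisible(x)
}

#' Select the next item by unweighted Fisher information
#'
#' Returns the id of the unadministered item with the largest Fisher
#' information at the current trait estimate; ties are broken by bank
#' order.
#'
#' @param session A [cat_session()].
#' @return The selected item id (string).
#' @export
next_item <- function(session) {
  stopifnot(inherits(session, "cat_session"))
  if (session$stopped) stop("session already stopped", call. = FALSE)
  avail <- setdiff(seq_along(session$bank$item_ids), session$administered)
  if (length(avail) == 0L) stop("all bank items administered", call. = FALSE)
  info <- .iteminfo(session$bank$a[avail],
                    session$bank$b[avail, , drop = FALSE], session$theta)
  session$bank$item_ids[avail[which.max(info)]] # which.max: first = bank order
}

#' Record a response and update the trait estimate
#'
#' Appends the response to the pending item (the one [next_item()] would
#' select), re-scores the trait by MAP over all administered items, and
#' evaluates the stopping rules: stop with reason `sem_criterion` once at
#' least `min_items` have been given and the standard error of measurement
#' is at or below the threshold; otherwise stop with reason `max_items`
#' when the item budget is exhausted.
#'
#' @param session A [cat_session()].
#' @param response Integer response in 1..K.
#' @return The updated `cat_session`.
#' @export
administer <- function(session, response) {
  stopifnot(inherits(session, "cat_session"))
  if (session$stopped) stop("session already stopped", call. = FALSE)
  kk <- session$bank$n_categories
  if (!is.numeric(response) || length(response) != 1L ||
      is.na(response) || response != round(response) ||
      response < 1 || response > kk) {
    stop(sprintf("response must be an integer in 1..%d", kk), call. = FALSE)
  }
  item_idx <- match(next_item(session), session$bank$item_ids)
  session$administered <- c(session$administered, item_idx)
  session$responses <- c(session$responses, as.integer(response))
  resp_vec <- rep(NA_integer_, length(session$bank$item_ids))
  resp_vec[session$administered] <- session$responses
  sc <- score_map(session$bank, resp_vec,
                  prior_mean = session$prior_mean,
                  prior_sd = session$prior_sd)
  session$theta <- sc$value
  session$se <- sc$se
  session$trajectory[[length(session$trajectory) + 1L]] <- sc
  n_adm <- length(session$administered)
  if (n_adm >= session$min_items && sc$se <= session$sem_threshold) {
    session$stopped <- TRUE
    session$stop_reason <- "sem_criterion"
  } else if (n_adm >= session$max_items) {
    session$stopped <- TRUE
    session$stop_reason <- "max_items"
  }
  session
}

#' Run a complete adaptive session
#'
#' Loops select-item / obtain-response / update until a stopping rule
#' fires. Responses come either from a live `responder` callback
#' (`function(item_id)` returning 1..K, e.g. console input) or, for
#' simulation, are sampled from the GRM at a supplied true trait value.
#'
#' @param bank A calibrated `grm_bank`.
#' @param responder Callback `function(item_id) -> response`, or `NULL` to
#'   simulate.
#' @param theta_true True trait value used when simulating responses.
#' @param config A [run_config()].
#' @param theta_start,prior_mean,prior_sd As in [cat_session()].
#' @return The finished `cat_session`.
#' @export
run_session <- function(bank, responder = NULL, theta_true = NULL,
                        config = run_config(), theta_start = 0,
                        prior_mean = 0, prior_sd = 1) {
  if (is.null(responder)) {
    if (is.null(theta_true)) {
      stop("supply a responder callback or theta_true", call. = FALSE)
    }
    responder <- function(item_id) {
      it <- bank_item(bank, item_id)
      sample_response(it, theta_true)
    }
  }
  session <- cat_session(bank, config, theta_start, prior_mean, prior_sd)
  while (!session$stopped) {
    id <- next_item(session)
    session <- administer(session, responder(id))
  }
  session
}
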