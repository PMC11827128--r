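# Synthetic-data generator: Likert-type response matrices with the
# structure of a unidimensional mood survey (theta ~ N(0,1), 5-point items
# under the GRM, ~600 respondents), plus controllable violations that
# target individual screening stages (unused categories, incoherent items,
# locally dependent pairs, non-monotone items, sex-DIF items).

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the structure of the motivating mood-survey study:
#' about 600 respondents, a standard-normal latent trait, 5-point Likert
#' items with discriminations between 1 and 2.5 and thresholds scattered
#' around zero.
#'
#' @param n_respondents Sample size (default 600).
#' @param n_items Number of items (>= 3).
#' @param n_categories Ordered categories K (default 5).
#' @param discrimination_range Uniform range for item slopes (default
#'   `c(1, 2.5)`).
#' @param threshold_spread SD of the normal draws that become (sorted)
#'   thresholds (default 1).
#' @param threshold_min_gap Minimum gap enforced between adjacent
#'   thresholds (default 0.3).
#' @param seed Integer seed; generation is a pure function of the config.
#' @param injections List of violation specs, each a list with `type` (one
#'   of `"unused_category"`, `"low_item_remainder"`,
#'   `"local_dependence_pair"`, `"non_monotone"`, `"dif"`) and `items`
#'   (item indices: one index, or two for the dependent pair). See
#'   [inject_violation()].
#' @param group_fraction Fraction of respondents labelled as the focal
#'   group (default 0.5).
#' @param external_score_noise_sd Noise SD of the external criterion
#'   columns (default 1).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_respondents = 600L, n_items = 20L,
                         n_categories = 5L,
                         discrimination_range = c(1, 2.5),
                         threshold_spread = 1, threshold_min_gap = 0.3,
                         seed = 1L, injections = list(),
                         group_fraction = 0.5,
                         external_score_noise_sd = 1) {
  stopifnot(n_respondents >= 1L, n_items >= 3L, n_categories >= 2L,
            length(discrimination_range) == 2L,
            all(discrimination_range > 0),
            diff(discrimination_range) >= 0,
            threshold_spread > 0, threshold_min_gap >= 0,
            group_fraction > 0, group_fraction < 1,
            external_score_noise_sd >= 0)
  inj_items <- unlist(lapply(injections, `[[`, "items"))
  if (length(inj_items)) {
    if (anyDuplicated(inj_items)) {
      stop("conflicting injections: an item targeted twice", call. = FALSE)
    }
    if (any(inj_items < 1L | inj_items > n_items)) {
      stop("injection item index out of range", call. = FALSE)
    }
  }
  structure(as.list(environment())[names(formals(synth_config))],
            class = "synth_config")
}

#' Generate a random item bank
#'
#' Slopes are uniform on `discrimination_range`; each item's thresholds are
#' sorted normal draws (`sd = threshold_spread`) with the minimum gap
#' enforced by widening around the original centre, keeping the mean
#' location unchanged.
#'
#' @param config A [synth_config()].
#' @return A `grm_bank`.
#' @export
generate_bank <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  .generate_bank_impl(config)
}

.generate_bank_impl <- function(config) {
  kk <- config$n_categories
  items <- lapply(seq_len(config$n_items), function(i) {
    a <- stats::runif(1L, config$discrimination_range[1L],
                      config$discrimination_range[2L])
    b <- .spread_thresholds(sort(stats::rnorm(kk - 1L, 0,
                                              config$threshold_spread)),
                            config$threshold_min_gap)
    grm_item(sprintf("item%02d", i), a, b)
  })
  grm_bank(items)
}

# Evenly spaced reference thresholds on [-1.5, 1.5]; used for regenerated
# (violation-carrying) items so the violation, not threshold placement,
# determines what the screens see.
.standard_thresholds <- function(k) seq(-1.5, 1.5, length.out = k - 1L)

.spread_thresholds <- function(b, min_gap) {
  if (length(b) < 2L) return(b)
  gaps <- pmax(diff(b), min_gap)
  out <- b[1L] + c(0, cumsum(gaps))
  out - mean(out) + mean(b) # keep the original centre
}

#' Generate a synthetic response matrix
#'
#' Draws `theta ~ N(0, 1)`, samples GRM responses from the bank, assigns
#' two-group labels (`"reference"` / `"focal"`) by `group_fraction`, builds
#' two external criterion columns (`ext_aligned = theta + noise`, mimicking
#' a criterion scale measuring the same construct, and
#' `ext_inverse = -theta + noise`, mimicking an opposing one), and applies
#' any configured violations.
#'
#' @param config A [synth_config()].
#' @param bank Optional pre-generated `grm_bank`; by default a bank is
#'   generated from the config.
#' @return A list with `data` (a [response_matrix()]), `bank` (possibly
#'   modified by injections) and `theta` (the true latent values).
#' @export
generate_responses <- function(config, bank = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  if (is.null(bank)) bank <- .generate_bank_impl(config)
  n <- config$n_respondents
  theta <- stats::rnorm(n)
  values <- matrix(NA_integer_, n, length(bank$item_ids))
  for (i in seq_along(bank$item_ids)) {
    values[, i] <- .sample_item(bank$a[i], bank$b[i, ], theta)
  }
  grp <- factor(ifelse(stats::runif(n) < config$group_fraction,
                       "focal", "reference"),
                levels = c("reference", "focal"))
  ext <- data.frame(
    ext_aligned = theta + stats::rnorm(n, 0, config$external_score_noise_sd),
    ext_inverse = -theta + stats::rnorm(n, 0, config$external_score_noise_sd)
  )
  data <- response_matrix(values, item_ids = bank$item_ids,
                          n_categories = config$n_categories,
                          group = grp, external_scores = ext)
  for (inj in config$injections) {
    out <- inject_violation(data, bank, inj, theta,
                            slope = config$discrimination_range[2L])
    data <- out$data; bank <- out$bank
  }
  list(data = data, bank = bank, theta = theta)
}

#' Inject a targeted assumption violation into synthetic data
#'
#' Each violation type is aimed at exactly one screening stage:
#' \describe{
#'   \item{`unused_category`}{remaps the item's rarest category into its
#'     neighbour so one category has zero observations (caught by the
#'     unused-category exclusion).}
#'   \item{`low_item_remainder`}{replaces the item's column with uniform
#'     draws independent of the trait (caught by the item-remainder
#'     filter).}
#'   \item{`local_dependence_pair`}{regenerates two items from
#'     `theta + delta` with a shared nuisance factor
#'     `delta ~ N(0, 0.8^2)` (caught by the residual-correlation check).}
#'   \item{`non_monotone`}{regenerates one item from a trait folded at
#'     0.45, so the top-category probability decreases over the upper
#'     trait range while the item stays moderately correlated with the
#'     scale (caught by the Mokken scalability screen).}
#'   \item{`dif`}{shifts the item's thresholds by +0.75 for the focal group
#'     and resamples that group's responses (caught by the DIF screen).}
#' }
#'
#' Regenerated items (the dependent pair and the non-monotone item) are
#' given the slope in `slope` (by default the top of the generating range)
#' so that the injected violation, not low discrimination, drives what the
#' screens see; the returned bank carries the updated slope.
#'
#' @param data A [response_matrix()].
#' @param bank The generating `grm_bank`.
#' @param injection List with `type` and `items` (see [synth_config()]).
#' @param theta True latent values used to regenerate responses.
#' @param slope Slope used when regenerating violated items (default: keep
#'   the item's own slope).
#' @return A list with modified `data` and `bank`.
#' @export
inject_violation <- function(data, bank, injection, theta, slope = NULL) {
  stopifnot(inherits(data, "response_matrix"), inherits(bank, "grm_bank"))
  type <- injection$type
  idx <- as.integer(injection$items)
  v <- data$values
  if (type == "unused_category") {
    i <- idx[1L]
    tab <- tabulate(v[, i], nbins = data$n_categories)
    rare <- which.min(tab)
    neighbour <- if (rare == 1L) 2L else rare - 1L
    v[v[, i] == rare, i] <- neighbour
  } else if (type == "low_item_remainder") {
    i <- idx[1L]
    v[, i] <- sample.int(data$n_categories, nrow(v), replace = TRUE)
  } else if (type == "local_dependence_pair") {
    stopifnot(length(idx) == 2L)
    delta <- stats::rnorm(nrow(v), 0, 0.8)
    for (i in idx) {
      if (!is.null(slope)) {
        bank$a[i] <- slope
        bank$b[i, ] <- .standard_thresholds(data$n_categories)
      }
      v[, i] <- .sample_item(bank$a[i], bank$b[i, ], theta + delta)
    }
  } else if (type == "non_monotone") {
    i <- idx[1L]
    if (!is.null(slope)) {
      bank$a[i] <- slope
      bank$b[i, ] <- .standard_thresholds(data$n_categories)
    }
    fold <- 0.45
    folded <- ifelse(theta > fold, 2 * fold - theta, theta)
    v[, i] <- .sample_item(bank$a[i], bank$b[i, ], folded)
  } else if (type == "dif") {
    i <- idx[1L]
    if (is.null(data$group)) stop("dif injection needs group labels",
                                  call. = FALSE)
    focal <- data$group == "focal"
    v[focal, i] <- .sample_item(bank$a[i], bank$b[i, ] + 0.75, theta[focal])
  } else {
    stop(sprintf("unknown injection type '%s'", type), call. = FALSE)
  }
  data$values <- v
  dimnames(data$values) <- list(data$respondent_ids, data$item_ids)
  list(data = data, bank = bank)
}
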