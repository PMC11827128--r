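# Shared fixtures, built in code.

# The reference item used throughout: unit slope, thresholds -1, 0, 1, 2.
ref_item <- function() grm_item("ref", a = 1, b = c(-1, 0, 1, 2))

# A well-separated bank whose every category is modal somewhere
# (slope x gap > 1.1), as a real post-selection item pool would be.
wide_bank <- function(n_items = 10L, k = 5L) {
  grm_bank(lapply(seq_len(n_items), function(i) {
    a <- 1.5 + (i %% 4) * 0.3
    g <- 0.9 + (i %% 3) * 0.15
    shift <- ((i %% 5) - 2) * 0.3
    grm_item(sprintf("w%02d", i), a,
             shift + g * seq(-1.5, 1.5, length.out = k - 1L))
  }))
}

# Random valid items for property-style loops.
random_item <- function(id = "r", k = 5L) {
  a <- stats::runif(1L, 0.5, 3)
  b <- sort(stats::rnorm(k - 1L, 0, 1.5))
  b <- b + seq(0, by = 0.05, length.out = k - 1L) # guarantee strict order
  grm_item(id, a, b)
}

# Brute-force comonotonic (Frechet upper bound) covariance: sort both
# margins and pair ranks; population (1/n) denominator.
covmax_sort_oracle <- function(x, y) {
  mean(sort(x) * sort(y)) - mean(x) * mean(y)
}

# MAP grid-search oracle: argmax of log posterior on a fine grid.
map_grid_oracle <- function(bank, responses, step = 1e-4,
                            bounds = c(-6, 6)) {
  grid <- seq(bounds[1L], bounds[2L], by = step)
  keep <- which(!is.na(responses))
  lp <- stats::dnorm(grid, log = TRUE)
  for (i in keep) {
    ps <- stats::plogis(bank$a[i] * outer(grid, bank$b[i, ], `-`))
    p <- cbind(1, ps) - cbind(ps, 0)
    lp <- lp + log(pmax(p[, responses[i]], 1e-12))
  }
  grid[which.max(lp)]
}

# Exhaustive summed-score oracle: enumerate all response patterns of a
# small bank and accumulate P(sum = s | theta) directly.
summed_score_oracle <- function(bank, theta) {
  k <- bank$n_categories
  ni <- length(bank$item_ids)
  probs <- lapply(seq_len(ni), function(i)
    category_probs(bank_item(bank, i), theta))
  smax <- ni * (k - 1L)
  out <- numeric(smax + 1L)
  patterns <- as.matrix(expand.grid(rep(list(seq_len(k)), ni)))
  for (r in seq_len(nrow(patterns))) {
    x <- patterns[r, ]
    p <- prod(vapply(seq_len(ni), function(i) probs[[i]][x[i]], numeric(1L)))
    s <- sum(x - 1L)
    out[s + 1L] <- out[s + 1L] + p
  }
  out
}
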