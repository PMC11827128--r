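test_that("items with unanswered categories are excluded", {
  set.seed(10)
  v <- matrix(sample(1:5, 400, replace = TRUE), 100, 4)
  v[, 2L][v[, 2L] == 5L] <- 4L # category 5 never used
  d <- response_matrix(v)
  out <- drop_unused_categories(d)
  expect_identical(out$excluded, "item2")
  expect_identical(out$data$item_ids, c("item1", "item3", "item4"))
  clean <- response_matrix(matrix(rep(1:5, 20), 20, 5))
  expect_identical(drop_unused_categories(clean)$data$values, clean$values)
})

test_that("complete-case filtering drops exactly the respondents with gaps", {
  set.seed(11)
  v <- matrix(sample(1:5, 50, replace = TRUE), 10, 5)
  v[1L, 2L] <- NA; v[4L, 5L] <- NA; v[7L, 1L] <- NA
  d <- response_matrix(v)
  out <- drop_complete_case(d)
  expect_identical(nrow(out$values), 7L)
  expect_false(anyNA(out$values))
  full <- response_matrix(matrix(sample(1:5, 50, replace = TRUE), 10, 5))
  expect_identical(drop_complete_case(full)$values, full$values)
})

test_that("item-remainder filter applies the strict 0.3 rule one-shot", {
  set.seed(12)
  sc <- synth_config(n_respondents = 600, n_items = 10, seed = 12)
  gen <- generate_responses(sc)
  v <- gen$data$values
  v[, 4L] <- sample(1:5, 600, replace = TRUE) # independent of the trait
  v[, 7L] <- v[, 6L]                          # duplicate of a coherent item
  d <- response_matrix(v)
  out <- item_remainder_correlations(d)
  expect_true("item04" %in% out$excluded)
  expect_lt(abs(out$r[["item04"]]), 0.15)
  expect_false("item07" %in% out$excluded)
  expect_gt(out$r[["item07"]], 0.3)
  # the excluded set is exactly the strict < 0.3 set
  expect_setequal(out$excluded, names(out$r)[out$r < 0.3])
})

test_that("unidimensionality criteria pass on one-factor data and fail otherwise", {
  sc <- synth_config(n_respondents = 600, n_items = 20, seed = 13)
  gen <- generate_responses(sc)
  out <- unidimensionality_check(gen$data)
  expect_true(out$passed)
  expect_length(out$excluded, 0L)
  expect_gte(out$proportions[["first"]], 0.20)
  expect_gte(out$proportions[["first"]] / out$proportions[["second"]], 4)

  # ten mutually independent items: equal eigenvalues, criteria unreachable
  set.seed(14)
  indep <- response_matrix(matrix(sample(1:5, 6000, replace = TRUE), 600, 10))
  expect_error(unidimensionality_check(indep), "fewer than 3")

  # two uncorrelated factors: the ratio criterion forces removals
  set.seed(15)
  f1 <- rnorm(600); f2 <- rnorm(600)
  v <- matrix(NA_integer_, 600, 16)
  for (i in 1:8) v[, i] <- catgrm:::.sample_item(2, seq(-1.5, 1.5, 1), f1)
  for (i in 9:16) v[, i] <- catgrm:::.sample_item(2, seq(-1.5, 1.5, 1), f2)
  two <- response_matrix(v)
  out2 <- unidimensionality_check(two)
  expect_gt(length(out2$excluded), 0L)
  expect_true(out2$passed)
})

test_that("local dependence flags an injected doublet and spares clean scales", {
  sc <- synth_config(n_respondents = 600, n_items = 20, seed = 16,
                     injections = list(list(type = "local_dependence_pair",
                                            items = c(5L, 6L))))
  gen <- generate_responses(sc)
  out <- local_dependence_check(gen$data)
  expect_identical(nrow(out$flagged_pairs), 1L)
  expect_setequal(unlist(out$flagged_pairs[1L, c("item1", "item2")]),
                  c("item05", "item06"))
  expect_length(out$excluded, 1L)
  expect_true(out$excluded %in% c("item05", "item06"))

  clean <- generate_responses(synth_config(n_respondents = 600,
                                           n_items = 20, seed = 17))
  out2 <- local_dependence_check(clean$data)
  expect_identical(nrow(out2$flagged_pairs), 0L)
  expect_length(out2$excluded, 0L)
})

test_that("Loevinger coefficients respect the Frechet bound and match the sort oracle", {
  set.seed(18)
  sc <- synth_config(n_respondents = 300, n_items = 6, seed = 18)
  gen <- generate_responses(sc)
  v <- gen$data$values
  v[, 2L] <- v[, 1L] # exact duplicate: comonotone pair attains cov_max
  d <- response_matrix(v)
  h <- loevinger_h(d)
  expect_equal(h$H_pair[1L, 2L], 1, tolerance = 1e-12)
  n <- nrow(v)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      cov_ij <- stats::cov(v[, i], v[, j]) * (n - 1) / n
      cmx <- covmax_sort_oracle(v[, i], v[, j])
      expect_gte(cmx + 1e-12, cov_ij)          # Frechet bound
      expect_lte(h$H_pair[i, j], 1 + 1e-12)
      # closed-form cov_max equals the sort-based brute force
      expect_equal(cov_ij / h$H_pair[i, j], cmx, tolerance = 1e-10)
    }
  }
  # a tiny table checked by hand: 4 respondents, 2 items
  toy <- response_matrix(matrix(c(1, 3, 4, 5,
                                  2, 2, 5, 3), 4, 2), n_categories = 5)
  ht <- loevinger_h(toy)
  x <- toy$values[, 1L]; y <- toy$values[, 2L]
  expect_equal(ht$H_pair[1L, 2L],
               (mean(x * y) - mean(x) * mean(y)) / covmax_sort_oracle(x, y),
               tolerance = 1e-12)
})

test_that("monotonicity screen excludes incoherent items by item H", {
  set.seed(19)
  sc <- synth_config(n_respondents = 600, n_items = 10, seed = 19)
  gen <- generate_responses(sc)
  v <- gen$data$values
  v[, 3L] <- sample(1:5, 600, replace = TRUE)
  out <- monotonicity_check(response_matrix(v))
  expect_true("item03" %in% out$excluded)
  expect_lt(out$H_item[["item03"]], 0.3)
  expect_false(any(sprintf("item%02d", c(1, 2, 4:10)) %in% out$excluded))
})

test_that("the screening battery runs stages in order and reports the funnel", {
  sc <- synth_config(
    n_respondents = 600, n_items = 20, seed = 20,
    injections = list(list(type = "unused_category", items = 2L),
                      list(type = "low_item_remainder", items = 8L)))
  gen <- generate_responses(sc)
  rep <- screen_items(gen$data)
  expect_identical(rep$stages$stage,
                   c("unused_category", "item_remainder", "unidimensionality",
                     "local_dependence", "monotonicity"))
  # counts chain: items out of one stage enter the next
  expect_identical(rep$stages$items_in[-1L],
                   rep$stages$items_out[-nrow(rep$stages)])
  tab <- rep$item_table
  expect_identical(tab$exclusion_stage[tab$item_id == "item02"],
                   "unused_category")
  expect_identical(tab$exclusion_stage[tab$item_id == "item08"],
                   "item_remainder")
  # pure function of its input
  rep2 <- screen_items(gen$data)
  expect_identical(rep$item_table, rep2$item_table)
})
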