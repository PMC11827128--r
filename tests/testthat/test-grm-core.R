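test_that("cumulative boundary curves follow the logistic closed form", {
  it <- ref_item()
  # logistic at its own location is exactly 1/2
  expect_identical(cumulative_probs(it, 0)[3L], 0.5)
  # direct evaluation of P*_k = plogis(a (theta - b_k)) with padded ends
  expect_equal(cumulative_probs(it, 0),
               c(1, 0.7310586, 0.5, 0.2689414, 0.1192029, 0),
               tolerance = 1e-6)
  # limiting behaviour far above every threshold
  expect_equal(cumulative_probs(it, 50), c(1, 1, 1, 1, 1, 0),
               tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:20) {
    item <- random_item()
    for (theta in seq(-8, 8, length.out = 9)) {
      ps <- cumulative_probs(item, theta)
      expect_true(all(diff(ps) <= 0))
      # strictly decreasing across interior boundaries at finite theta
      expect_true(all(diff(ps[2:(item$n_categories)]) < 0))
    }
  }
})

test_that("category probabilities are adjacent differences summing to one", {
  it <- ref_item()
  expect_equal(category_probs(it, 0),
               c(0.2689414, 0.2310586, 0.2310586, 0.1497385, 0.1192029),
               tolerance = 1e-6)
  sym <- grm_item("sym", 1.7, c(-1.2, -0.4, 0.4, 1.2))
  p <- category_probs(sym, 0)
  expect_equal(p[1L], p[5L], tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:20) {
    item <- random_item()
    for (theta in seq(-8, 8, length.out = 9)) {
      p <- category_probs(item, theta)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-9)
    }
  }
})

test_that("item information matches the finite-difference expected-information oracle", {
  # I(theta) = sum_k P_k * (-d2 log P_k / dtheta2), by central differences
  fd_info <- function(item, theta, h = 1e-3) {
    lp <- function(t) log(category_probs(item, t))
    d2 <- (lp(theta + h) - 2 * lp(theta) + lp(theta - h)) / h^2
    -sum(category_probs(item, theta) * d2)
  }
  set.seed(3)
  for (rep in 1:10) {
    item <- random_item()
    for (theta in seq(-3, 3, length.out = 7)) {
      expect_equal(item_information(item, theta), fd_info(item, theta),
                   tolerance = 1e-4)
    }
  }
  sym <- grm_item("sym", 2, c(-1.5, -0.5, 0.5, 1.5))
  for (d in c(0.3, 0.9, 1.7)) {
    expect_equal(item_information(sym, d), item_information(sym, -d),
                 tolerance = 1e-10)
  }
  expect_lt(item_information(ref_item(), 40), 1e-10)
  expect_lt(item_information(ref_item(), -40), 1e-10)
})

test_that("expected response is non-decreasing in the trait", {
  set.seed(4)
  for (rep in 1:10) {
    item <- random_item()
    ex <- vapply(seq(-6, 6, by = 0.25), function(t) {
      sum(seq_len(item$n_categories) * category_probs(item, t))
    }, numeric(1L))
    expect_true(all(diff(ex) >= -1e-12))
  }
})

test_that("test information is the exact sum of item informations", {
  bank <- wide_bank(5L)
  brute <- sum(vapply(1:5, function(i)
    item_information(bank_item(bank, i), 0), numeric(1L)))
  expect_identical(test_information(bank, 0), brute)
  one <- bank[1L]
  expect_identical(test_information(one, 0.7),
                   item_information(bank_item(bank, 1L), 0.7))
  dup <- grm_bank(list(grm_item("a", 1.4, c(-1, 0, 1)),
                       grm_item("b", 1.4, c(-1, 0, 1))))
  expect_equal(test_information(dup, 0.3),
               2 * item_information(bank_item(dup, 1L), 0.3),
               tolerance = 1e-12)
  empty <- wide_bank(3L)
  expect_error(test_information(empty[integer(0L)], 0), "empty")
})

test_that("response sampling is reproducible and matches the model", {
  it <- ref_item()
  set.seed(7); x1 <- sample_response(it, rep(0.4, 50))
  set.seed(7); x2 <- sample_response(it, rep(0.4, 50))
  expect_identical(x1, x2)
  set.seed(8)
  expect_true(all(sample_response(it, rep(10, 200)) == 5L))
  set.seed(9)
  draws <- sample_response(it, rep(0.25, 100000))
  p <- category_probs(it, 0.25)
  freq <- tabulate(draws, nbins = 5L) / 100000
  se <- sqrt(p * (1 - p) / 100000)
  expect_true(all(abs(freq - p) <= 3 * se))
})

test_that("item and bank invariants are enforced", {
  expect_error(grm_item("x", -1, c(0, 1)), "positive")
  expect_error(grm_item("x", 1, c(1, 0)), "increasing")
  expect_error(grm_item("x", 1, c(0, 0, 1)), "increasing")
  expect_error(grm_bank(list(grm_item("a", 1, 0:2),
                             grm_item("a", 1, 0:2))), "unique")
  expect_error(grm_bank(list(grm_item("a", 1, 0:2),
                             grm_item("b", 1, 0:1))), "categories")
})

test_that("bank JSON round-trips losslessly and rejects bad schemas", {
  bank <- wide_bank(6L)
  path <- withr::local_tempfile(fileext = ".json")
  write_bank_json(bank, path)
  back <- read_bank_json(path)
  expect_identical(back$item_ids, bank$item_ids)
  expect_equal(back$a, bank$a, tolerance = 1e-12)
  expect_equal(back$b, bank$b, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"items": []}', bad)
  expect_error(read_bank_json(bad), "n_categories")
  writeLines('{"n_categories": 5, "items": [{"id": "a", "a": 1, "b": [0, 1]}]}',
             bad)
  expect_error(read_bank_json(bad), "expected 4 thresholds")
})

test_that("location and slope-intercept parameterizations convert back and forth", {
  ab <- list(a = 1.7, b = c(-0.8, 0.2, 1.1))
  d <- ab_to_intercept(ab$a, ab$b)
  back <- intercept_to_ab(d$a, d$d)
  expect_equal(back$b, ab$b, tolerance = 1e-12)
})
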