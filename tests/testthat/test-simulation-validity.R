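test_that("Pearson correlation and its Fisher-z interval behave", {
  x <- rnorm(50)
  expect_equal(pearson_ci(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_ci(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_ci(x, rep(1, 50)), "constant")
  # interval coverage near the nominal level at rho = 0.8
  set.seed(40)
  hits <- 0L; reps <- 500L
  for (r in seq_len(reps)) {
    z <- rnorm(500); e <- rnorm(500)
    y <- 0.8 * z + sqrt(1 - 0.64) * e
    ci <- pearson_ci(z, y)
    if (ci$ci_low <= 0.8 && 0.8 <= ci$ci_high) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})

test_that("replaying all responses reproduces the reference scores exactly", {
  sc <- synth_config(n_respondents = 120, n_items = 8, seed = 41)
  gen <- generate_responses(sc)
  theta_true <- score_map_matrix(gen$bank, gen$data$values)$value
  cfg <- run_config(sem = 0) # force the full bank
  sim <- simulate_cat(gen$bank, theta_true, cfg, replay = gen$data$values)
  expect_equal(sim$respondents$theta_est, theta_true, tolerance = 1e-8)
  expect_equal(sim$pcc, 1, tolerance = 1e-8)
  expect_true(all(sim$respondents$n_items == 8L))
})

test_that("tighter precision thresholds administer more items", {
  sc <- synth_config(n_respondents = 80, n_items = 30, seed = 42)
  gen <- generate_responses(sc)
  theta_true <- score_map_matrix(gen$bank, gen$data$values)$value
  loose <- simulate_cat(gen$bank, theta_true, run_config(sem = 0.32),
                        seed = 1)
  tight <- simulate_cat(gen$bank, theta_true, run_config(sem = 0.25),
                        seed = 1)
  expect_lt(loose$mean_items, tight$mean_items)
  expect_gte(loose$mean_items, 3)
})

test_that("pooled simulation statistics ignore respondent order", {
  sc <- synth_config(n_respondents = 60, n_items = 10, seed = 43)
  gen <- generate_responses(sc)
  theta_true <- score_map_matrix(gen$bank, gen$data$values)$value
  cfg <- run_config(sem = 0)
  s1 <- simulate_cat(gen$bank, theta_true, cfg, replay = gen$data$values)
  perm <- sample(seq_along(theta_true))
  s2 <- simulate_cat(gen$bank, theta_true[perm], cfg,
                     replay = gen$data$values[perm, ])
  expect_equal(s1$pcc, s2$pcc, tolerance = 1e-10)
  expect_equal(s1$mean_items, s2$mean_items, tolerance = 1e-12)
})

test_that("concurrent validity carries magnitudes and signs", {
  set.seed(44)
  theta <- rnorm(400)
  ext <- data.frame(same = theta,
                    aligned = theta + rnorm(400),
                    inverse = -theta + rnorm(400))
  out <- concurrent_validity(theta, ext,
                             expected_sign = c(aligned = 1, inverse = -1))
  expect_equal(out$r[out$criterion == "same"], 1, tolerance = 1e-12)
  expect_gt(out$r[out$criterion == "aligned"], 0.5)
  expect_lt(out$r[out$criterion == "inverse"], -0.5)
  expect_true(all(out$sign_consistent[out$criterion != "same"]))
  expect_error(concurrent_validity(theta, ext[1:10, ]), "match")
})

test_that("discriminant validity separates shifted groups and is label-symmetric", {
  x <- c(rnorm(30, 0, 1), rnorm(30, 0, 1))
  g <- rep(c("a", "b"), each = 30)
  same <- discriminant_validity(c(x[1:30], x[1:30]), g)
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  swapped <- discriminant_validity(x, g, comparisons = list(c("b", "a")))
  forward <- discriminant_validity(x, g, comparisons = list(c("a", "b")))
  expect_equal(swapped$t, -forward$t, tolerance = 1e-12)
  expect_equal(swapped$p_value, forward$p_value, tolerance = 1e-12)
  # power at the observed clinical-vs-healthy effect size
  set.seed(45)
  sig <- 0L; reps <- 60L
  for (r in seq_len(reps)) {
    y <- c(rnorm(120, 0, 0.9), rnorm(120, 0.6, 0.9))
    gg <- rep(c("healthy", "clinical"), each = 120)
    p <- discriminant_validity(y, gg,
                               comparisons = list(c("healthy", "clinical")))$p_value
    if (p < 0.05) sig <- sig + 1L
  }
  expect_gte(sig / reps, 0.9)
})
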