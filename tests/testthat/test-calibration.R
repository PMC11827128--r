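test_that("EM ascends the marginal likelihood and recovers generating parameters", {
  sc <- synth_config(n_respondents = 1000, n_items = 10, seed = 21)
  gen <- generate_responses(sc)
  fit <- fit_grm(gen$data)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  expect_true(fit$converged)
  expect_true(all(apply(fit$bank$b, 1L, function(b) all(diff(b) > 0))))
  expect_gte(stats::cor(fit$bank$a, gen$bank$a), 0.9)
  expect_lte(sqrt(mean((fit$bank$b - gen$bank$b)^2)), 0.2)
  # MAP reference scores track the generating trait
  expect_gte(stats::cor(fit$theta$value, gen$theta), 0.9)
})

test_that("identical response columns yield identical parameter estimates", {
  sc <- synth_config(n_respondents = 500, n_items = 6, seed = 22)
  gen <- generate_responses(sc)
  v <- gen$data$values
  v[, 4L] <- v[, 3L]
  # a duplicated column violates local independence, so the duplicated
  # pair's slopes inflate and the quasi-Guttman warning is expected
  expect_warning(fit <- fit_grm(response_matrix(v)), "quasi-Guttman")
  expect_equal(fit$bank$a[3L], fit$bank$a[4L], tolerance = 1e-3)
  expect_equal(fit$bank$b[3L, ], fit$bank$b[4L, ], tolerance = 1e-3)
})

test_that("MAP scoring matches the grid-search oracle and behaves at the edges", {
  empty <- score_map(wide_bank(5L), rep(NA_integer_, 5L))
  expect_identical(empty$value, 0)
  expect_identical(empty$se, 1)
  set.seed(23)
  for (rep in 1:8) {
    bank <- wide_bank(8L)
    resp <- sample(1:5, 8L, replace = TRUE)
    got <- score_map(bank, resp)
    expect_equal(got$value, map_grid_oracle(bank, resp), tolerance = 1e-3)
    expect_gt(got$se, 0)
  }
  # symmetric bank: all-maximum and all-minimum responses mirror each other
  sym <- grm_bank(lapply(1:6, function(i)
    grm_item(paste0("s", i), 1.8, c(-1.5, -0.5, 0.5, 1.5))))
  hi <- score_map(sym, rep(5L, 6L))
  lo <- score_map(sym, rep(1L, 6L))
  expect_gt(hi$value, 0)
  expect_lt(lo$value, 0)
  expect_equal(hi$value, -lo$value, tolerance = 1e-4)
})

test_that("never-modal category screen follows the grid argmax", {
  keep <- grm_item("wide", 2, c(-2, -0.7, 0.7, 2))
  drop <- grm_item("narrow", 2, c(-1, -0.05, 0, 1.5))  # 0.05 middle gap
  bin <- grm_item("binary", 1.2, 0.3)
  out <- never_modal_category_screen(grm_bank(list(keep)))
  expect_length(out$excluded, 0L)
  out2 <- never_modal_category_screen(grm_bank(list(drop)))
  expect_identical(out2$excluded, "narrow")
  expect_true(3L %in% out2$never_modal[["narrow"]])
  out3 <- never_modal_category_screen(grm_bank(list(bin)))
  expect_length(out3$excluded, 0L)
})

test_that("Lord-Wingersky recursion equals exhaustive pattern enumeration", {
  set.seed(24)
  for (rep in 1:3) {
    bank <- grm_bank(lapply(1:3, function(i) random_item(paste0("e", i), k = 3L)))
    quad <- catgrm:::.quadrature(11L)
    ptabs <- catgrm:::.prob_tables(bank$a, bank$b, quad$points)
    lw <- catgrm:::.lord_wingersky(ptabs)
    for (q in seq_along(quad$points)) {
      expect_equal(lw[, q], summed_score_oracle(bank, quad$points[q]),
                   tolerance = 1e-10)
    }
  }
  # a 4-item K = 3 bank as well
  bank4 <- grm_bank(lapply(1:4, function(i) random_item(paste0("f", i), k = 3L)))
  ptabs <- catgrm:::.prob_tables(bank4$a, bank4$b, c(-1, 0.5))
  lw <- catgrm:::.lord_wingersky(ptabs)
  for (q in 1:2) {
    expect_equal(lw[, q], summed_score_oracle(bank4, c(-1, 0.5)[q]),
                 tolerance = 1e-10)
  }
})

test_that("S-X2 exposes gross misfit and yields proper p-values", {
  sc <- synth_config(n_respondents = 600, n_items = 10, seed = 25,
                     injections = list(list(type = "non_monotone",
                                            items = 4L)))
  gen <- generate_responses(sc)
  fit <- suppressWarnings(fit_grm(gen$data))
  sx <- suppressWarnings(s_x2_item_fit(fit$bank, gen$data))
  expect_true(all(sx$statistic >= 0))
  ok <- !is.na(sx$p_value)
  expect_true(all(sx$p_value[ok] >= 0 & sx$p_value[ok] <= 1))
  # the folded (non-monotone) item cannot be captured by a GRM
  expect_true(sx$excluded[4L])
  expect_lt(sx$p_value[4L], 0.01)
})

test_that("DIF statistics vanish when the groups carry identical data", {
  sc <- synth_config(n_respondents = 150, n_items = 5, seed = 26)
  gen <- generate_responses(sc)
  v <- rbind(gen$data$values, gen$data$values)
  d <- response_matrix(v, group = rep(c("g1", "g2"), each = 150))
  out <- dif_screen(d)
  expect_true(all(out$tested))
  expect_true(all(out$statistic < 0.05))
  expect_true(all(out$p_value > 0.99))
  expect_false(any(out$excluded))
})

test_that("Cronbach's alpha matches closed forms", {
  set.seed(27)
  # parallel items with common correlation r: alpha = J r / (1 + (J-1) r)
  jj <- 8L; r <- 0.4; n <- 5000L
  z <- rnorm(n)
  v <- sqrt(r) * z + sqrt(1 - r) * matrix(rnorm(n * jj), n, jj)
  expect_equal(cronbach_alpha(v), jj * r / (1 + (jj - 1) * r),
               tolerance = 0.01)
  # exact copies are perfectly consistent
  copies <- matrix(rep(sample(1:5, 200, replace = TRUE), 4L), ncol = 4L)
  expect_equal(cronbach_alpha(copies), 1, tolerance = 1e-12)
  # independent items carry no shared variance
  indep <- matrix(sample(1:5, 2000 * 6, replace = TRUE), 2000, 6)
  expect_lt(abs(cronbach_alpha(indep)), 0.1)
  expect_error(cronbach_alpha(matrix(1L, 5, 3)), "zero variance")
})

test_that("the compiled M-step gradient agrees with finite differences", {
  set.seed(28)
  r <- matrix(stats::runif(5 * 21, 0, 10), 5, 21)
  grid <- seq(-4, 4, length.out = 21)
  par <- c(log(1.3), -0.8, log(c(0.6, 0.9, 0.5)))
  og <- catgrm:::.item_objgrad_cpp(par, r, grid)
  h <- 1e-6
  for (d in seq_along(par)) {
    up <- par; up[d] <- up[d] + h
    dn <- par; dn[d] <- dn[d] - h
    fd <- (catgrm:::.item_objgrad_cpp(up, r, grid)$value -
             catgrm:::.item_objgrad_cpp(dn, r, grid)$value) / (2 * h)
    expect_equal(og$gradient[d], fd, tolerance = 1e-4)
  }
})
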