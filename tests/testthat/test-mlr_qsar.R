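test_that("constant descriptors are dropped, order preserved", {
  set.seed(42)
  m <- cbind(a = rnorm(6), b = rep(1, 6), c = rnorm(6), d = rnorm(6),
             e = rnorm(6))
  out <- drop_constant_descriptors(m)
  expect_equal(colnames(out), c("a", "c", "d", "e"))
  expect_equal(drop_constant_descriptors(out), out)
  # planted count: 10 x 50 with 7 constant columns
  m2 <- matrix(rnorm(10 * 43), 10, 43)
  m2 <- cbind(m2, matrix(rep(rnorm(7), each = 10), 10, 7))
  colnames(m2) <- paste0("v", 1:50)
  expect_equal(ncol(drop_constant_descriptors(m2)), 43)
})

test_that("fit_ols solves small exact problems and validates input", {
  # 4 points on an exact line
  fit <- fit_ols(matrix(0:3, ncol = 1, dimnames = list(NULL, "x")),
                 c(1, 3, 5, 7))
  expect_equal(unname(fit$model$coefficients), 2)
  expect_equal(fit$model$intercept, 1)
  expect_equal(fit$stats$r2, 1)
  # noiseless planted model is recovered exactly
  gen <- gen_descriptor_dataset(seed = 11, n_compounds = 20,
                                n_descriptors = 5, noise_sd = 0)
  f2 <- fit_ols(gen$x[, gen$planted_subset], gen$y)
  expect_equal(unname(f2$model$coefficients), gen$planted_coefficients,
               tolerance = 1e-8)
  expect_equal(f2$model$intercept, gen$intercept, tolerance = 1e-8)
  expect_equal(f2$stats$r2, 1, tolerance = 1e-12)
  # errors: collinearity named, too few observations
  x <- cbind(p = 1:6, q = 2 * (1:6))
  expect_error(fit_ols(x, rnorm(6)), "collinear.*q")
  expect_error(fit_ols(matrix(rnorm(9), 3, 3), rnorm(3)),
               "more observations")
})

test_that("OLS residuals are orthogonal to regressors and sum to zero", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(15)
    fit <- fit_ols(x, y)
    expect_lt(abs(sum(fit$residuals)), 1e-10)
    expect_lt(max(abs(crossprod(x, fit$residuals))), 1e-10)
    # validation_stats on (observed, fitted) reproduces the fit's r2
    vs <- validation_stats(y, fit$fitted, 3)
    expect_equal(vs$r2, fit$stats$r2, tolerance = 1e-12)
    expect_equal(vs$r2, vs$r^2, tolerance = 1e-12)
    expect_lte(vs$r2_adj, vs$r2)
  }
})

test_that("validation_stats basics and degenerate input", {
  v <- c(1, 2, 3, 4)
  s <- validation_stats(v, v, 1)
  expect_equal(s$r, 1)
  expect_equal(s$r2, 1)
  expect_error(validation_stats(rep(1, 4), v, 1), "zero variance")
  expect_error(validation_stats(v, v[1:3], 1))
})

test_that("exhaustive search enumerates all subsets and matches the oracle", {
  set.seed(3)
  x <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(NULL, paste0("d", 1:6)))
  y <- rnorm(10)
  res <- exhaustive_subset_search(x, y, k = 3, top_n = 20)
  expect_equal(res$n_evaluated, choose(6, 3))
  orc <- oracle_subset_search(x, y, 3)
  expect_equal(res$table$subset, orc$subset)
  expect_equal(res$table$r2, orc$r2, tolerance = 1e-10)
  # a larger oracle problem, C(12, 3) = 220 subsets
  x2 <- matrix(rnorm(14 * 12), 14, 12,
               dimnames = list(NULL, paste0("d", sprintf("%02d", 1:12))))
  y2 <- rnorm(14)
  res2 <- exhaustive_subset_search(x2, y2, k = 3, top_n = 5)
  orc2 <- oracle_subset_search(x2, y2, 3)
  expect_equal(res2$n_evaluated, 220)
  expect_equal(res2$table$subset, orc2$subset)
  expect_equal(res2$table$r2, orc2$r2, tolerance = 1e-10)
})

test_that("k = 1 search ranks by squared Pearson correlation", {
  set.seed(9)
  x <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- rnorm(12)
  res <- exhaustive_subset_search(x, y, k = 1, top_n = 5)
  closed <- sort(cor(x, y)[, 1]^2, decreasing = TRUE)
  expect_equal(res$table$subset, names(closed))
  expect_equal(res$table$r2, unname(closed), tolerance = 1e-12)
})

test_that("search recovers a planted triple and beats random subsets", {
  gen <- gen_descriptor_dataset(seed = 7, n_compounds = 40,
                                n_descriptors = 30, noise_sd = 0.1)
  res <- exhaustive_subset_search(gen$x, gen$y, k = 3)
  expect_setequal(strsplit(res$table$subset[1], "+", fixed = TRUE)[[1]],
                  gen$planted_subset)
  # property: the best r2 dominates 100 random size-3 subsets
  set.seed(1)
  rand_r2 <- replicate(100, {
    s <- sample(colnames(gen$x), 3)
    fit_ols(gen$x[, s], gen$y)$stats$r2
  })
  expect_true(all(res$table$r2[1] >= rand_r2))
})

test_that("rank-deficient subsets are skipped with a warning, not fatal", {
  set.seed(2)
  x <- cbind(a = rnorm(8), b = rnorm(8))
  x <- cbind(x, c = x[, "a"] * 2, d = rnorm(8))
  y <- rnorm(8)
  expect_warning(res <- exhaustive_subset_search(x, y, k = 2, top_n = 10),
                 "rank-deficient")
  expect_equal(res$n_evaluated, choose(4, 2) - 1)  # {a, c} skipped
  expect_equal(res$skipped, "a+c")
})

test_that("packaged Cx43 model predicts the hand-derived values", {
  m <- cx43_qsar_model()
  zeros <- c(SpMin5_Bhm = 0, SpMax3_Bhi = 0, minHBd = 0)
  expect_equal(predict(m, zeros), -7.24)
  hep <- c(SpMin5_Bhm = 0.81, SpMax3_Bhi = 3.11, minHBd = 0.67)
  expect_equal(round(predict(m, hep), 2), 2.63)
  lim <- c(SpMin5_Bhm = 1.12, SpMax3_Bhi = 3.09, minHBd = 0)
  expect_equal(round(predict(m, lim), 2), 4.83)
  expect_error(predict(m, c(SpMin5_Bhm = 1)), "SpMax3_Bhi")
})

test_that("model serialization round-trips through plain text", {
  m <- cx43_qsar_model()
  f <- withr::local_tempfile(fileext = ".txt")
  write_mlr_model(m, f)
  m2 <- read_mlr_model(f)
  expect_equal(m2$descriptor_names, m$descriptor_names)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  expect_error(read_mlr_model(system.file("extdata", "cx43_inhibitors.csv",
                                          package = "gjqsar")),
               "not a gjqsar model file")
})
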