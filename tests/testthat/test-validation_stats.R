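test_that("cross-validation is seeded, balanced and near-exact on clean data", {
  set <- make_toy_set(n = 24, seed = 30, noise = 1e-6)
  X <- set$x
  y <- set$references$conc
  cv <- cross_validate(X, y, n_factors = 2, n_groups = 6, seed = 5)
  expect_equal(sort(unique(cv$assignments)), 1:6)
  expect_true(all(tabulate(cv$assignments) == 4))
  expect_lt(cv$secv, 1e-3 * sd(y))

  cv2 <- cross_validate(X, y, n_factors = 2, n_groups = 6, seed = 5)
  expect_identical(cv$assignments, cv2$assignments)
  expect_identical(cv$secv, cv2$secv)
  cv3 <- cross_validate(X, y, n_factors = 2, n_groups = 6, seed = 6)
  expect_false(identical(cv$assignments, cv3$assignments))

  expect_error(cross_validate(X, y, 2, n_groups = 25), "between 2 and n")
})

test_that("n_groups = n reproduces a brute-force leave-one-out loop", {
  set <- make_toy_set(n = 14, seed = 31, noise = 0.02)
  X <- apply_treatment(set, "s0")$x
  y <- set$references$conc
  for (scaled in c(TRUE, FALSE)) {
    cv <- cross_validate(X, y, n_factors = 3, n_groups = 14, seed = 1,
                         scale_residuals = scaled)
    oracle <- loo_oracle(X, y, 3, scale_residuals = scaled)
    expect_equal(cv$predictions, oracle, tolerance = 1e-10)
    expect_equal(cv$secv, sqrt(mean((y - oracle)^2)), tolerance = 1e-10)
  }
})

test_that("T-outlier elimination removes corrupted references and only those", {
  set <- make_toy_set(n = 40, seed = 32, noise = 5e-4)
  X <- apply_treatment(set, "s0")$x
  y <- set$references$conc

  # clean data: residuals stay below 2.5 SECV most of the time; allow the
  # procedure to trim at most a couple of borderline samples
  clean <- t_outlier_elimination(X, y, n_factors = 4, n_groups = 5, seed = 2)
  expect_lte(length(unlist(clean$removed_ids)), 3)

  # corrupt one reference by +10 reference SDs
  y_bad <- y
  y_bad[17] <- y[17] + 10 * sd(y)
  elim <- t_outlier_elimination(X, y_bad, n_factors = 4, n_groups = 5, seed = 2)
  expect_true(17 %in% unlist(elim$removed_ids))
  expect_false(17 %in% elim$kept)
  expect_lt(elim$cv$secv, elim$initial_cv$secv)

  # zero rounds is the identity
  none <- t_outlier_elimination(X, y_bad, n_factors = 4, n_groups = 5,
                                seed = 2, max_rounds = 0)
  expect_equal(none$kept, seq_along(y))
  expect_length(none$removed_ids, 0)
  expect_identical(none$cv$secv, none$initial_cv$secv)
})

test_that("the statistics bundle follows its defining formulas", {
  withr::with_seed(33, {
    y <- rnorm(50, 100, 20)
    pred <- y + rnorm(50, 0, 5)
  })
  st <- compute_stats(y, pred, context = "calibration", n_factors = 10,
                      secv = 6)
  r <- y - pred
  n <- 50
  expect_equal(st$rsq, cor(y, pred)^2)
  expect_equal(st$bias, mean(r))
  expect_equal(st$sec, sqrt(sum(r^2) / (n - 10 - 1)))
  expect_equal(st$sep, sqrt(sum(r^2) / n))
  expect_equal(st$rmse, st$sep)
  expect_equal(st$sepc, sqrt(sum((r - mean(r))^2) / (n - 1)))
  expect_equal(st$rpd, sd(y) / st$sep)
  expect_equal(st$secv, 6)

  # formula consistency: sep^2 * n/(n-1) = sepc^2 + bias^2 * n/(n-1)
  expect_equal(st$sep^2 * n / (n - 1), st$sepc^2 + st$bias^2 * n / (n - 1))

  # RPD on SECV via the variant flag
  st2 <- compute_stats(y, pred, context = "internal_validation", secv = 6,
                       rpd_on = "secv")
  expect_equal(st2$rpd, sd(y) / 6)
  expect_true(is.na(st2$sec))

  # translation equivariance: shifting both vectors changes nothing
  st3 <- compute_stats(y + 250, pred + 250, context = "calibration",
                       n_factors = 10, secv = 6)
  for (f in c("sd", "rsq", "sec", "sep", "sepc", "bias", "rpd")) {
    expect_equal(st3[[f]], st[[f]], tolerance = 1e-10)
  }

  # degenerate cases
  expect_equal(compute_stats(y, y, n_factors = 2)$rsq, 1)
  expect_equal(compute_stats(y, y, n_factors = 2)$sep, 0)
  shifted <- compute_stats(y, y + 4, n_factors = 2)
  expect_equal(shifted$bias, -4)
  expect_equal(shifted$sepc, 0)
  expect_error(compute_stats(y, rep(1, 50)), "zero variance")
  expect_error(compute_stats(y[1:2], pred[1:2]), "at least 3")
})

test_that("paired t-test matches the closed-form t distribution", {
  a <- c(10, 20, 30, 40)
  b <- a - c(1, 2, 3, 4)  # differences {1,2,3,4}
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * stats::pt(-abs(tstat), df = 3)
  expect_equal(paired_t_test(a, b), p_oracle)

  expect_equal(paired_t_test(a, a), 1)
  expect_equal(paired_t_test(a, a + 2), 0)
  expect_error(paired_t_test(1, 2), "n >= 2")
  expect_error(paired_t_test(a, a[1:2]), "equal length")
})

test_that("rpd_ratio validates and divides", {
  expect_equal(rpd_ratio(10, 4), 2.5)
  expect_error(rpd_ratio(10, 0), "> 0")
})
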