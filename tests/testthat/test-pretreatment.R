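test_that("treatment codes parse to the documented scatter and numerals", {
  cases <- list(
    s2 = list(scatter = "snv", numerals = c(2, 4, 4, 1)),
    n0 = list(scatter = "none", numerals = c(0, 0, 1, 1)),
    m3 = list(scatter = "snv_dt", numerals = c(2, 10, 10, 1)),
    d1 = list(scatter = "dt", numerals = c(1, 4, 4, 1)),
    n4 = list(scatter = "none", numerals = c(2, 8, 6, 1))
  )
  for (code in names(cases)) {
    tc <- parse_treatment_code(code)
    expect_s3_class(tc, "treatment_code")
    expect_equal(tc$scatter, cases[[code]]$scatter)
    expect_equal(unname(tc$numerals), cases[[code]]$numerals)
  }
  expect_error(parse_treatment_code("x5"), "unknown scatter letter")
  expect_error(parse_treatment_code("n5"), "unknown numeral digit")
  expect_error(parse_treatment_code("snv"), "one letter followed by one digit")
})

test_that("SNV standardizes each spectrum to mean 0, sample SD 1", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(11, {
    for (i in 1:5) {
      v <- rnorm(80, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
      out <- snv(v)
      expect_equal(mean(out), 0)
      expect_equal(sd(out), 1)
      # invariance to offset and positive scaling
      expect_equal(snv(3.7 * v + 12), out)
    }
  })
  expect_error(snv(rep(2, 10)), "constant spectrum")
  m <- snv(rbind(c(1, 2, 3), c(10, 0, 5)))
  expect_equal(unname(rowMeans(m)), c(0, 0))
  expect_equal(unname(apply(m, 1, sd)), c(1, 1))
})

test_that("detrending annihilates polynomials up to its degree", {
  wl <- seq(1100, 2000, by = 2)
  quad <- 2 + 0.003 * wl - 1e-6 * wl^2
  expect_equal(detrend(quad, wl), rep(0, length(wl)), tolerance = 1e-10)
  expect_equal(detrend(rep(5, length(wl)), wl), rep(0, length(wl)),
               tolerance = 1e-10)
  # residual orthogonal to {1, lambda, lambda^2}
  withr::with_seed(2, v <- rnorm(length(wl)))
  res <- detrend(v, wl)
  for (basis in list(rep(1, length(wl)), wl, wl^2)) {
    expect_lt(abs(sum(res * basis)) / sqrt(sum(basis^2)) / sd(res), 1e-8)
  }
  # offset invariance
  expect_equal(detrend(v + 3, wl), res)
})

test_that("gap-segment derivatives follow the numeral semantics", {
  wl <- seq(1100, 1198, by = 2)
  x <- seq_along(wl) * 0.01  # linear ramp

  ident <- gap_segment_derivative(x, c(0, 0, 1, 1), wl)
  expect_equal(as.numeric(ident), x)
  expect_equal(attr(ident, "wavelengths"), wl)

  d1 <- gap_segment_derivative(x, c(1, 4, 4, 1), wl)
  expect_equal(length(d1), length(wl) - 3 - 4)
  expect_true(all(abs(diff(as.numeric(d1))) < 1e-12))  # constant slope

  d2 <- gap_segment_derivative(x, c(2, 4, 4, 1), wl)
  expect_equal(as.numeric(d2), rep(0, length(d2)), tolerance = 1e-12)

  # linearity: T(a x + b y) = a T(x) + b T(y)
  withr::with_seed(3, {
    u <- rnorm(length(wl)); v <- rnorm(length(wl))
  })
  lhs <- gap_segment_derivative(2 * u - 5 * v, c(2, 10, 10, 1), wl)
  rhs <- 2 * gap_segment_derivative(u, c(2, 10, 10, 1), wl) -
    5 * gap_segment_derivative(v, c(2, 10, 10, 1), wl)
  expect_equal(as.numeric(lhs), as.numeric(rhs))

  expect_error(gap_segment_derivative(x[1:5], c(2, 10, 10, 1), wl[1:5]),
               "exceeds the grid")
})

test_that("apply_treatment composes scatter correction then derivative", {
  set <- make_toy_set(n = 6, seed = 4)

  same <- apply_treatment(set, "n0")
  expect_equal(same$x, set$x)
  expect_equal(same$grid$wavelengths, set$grid$wavelengths)

  s0 <- apply_treatment(set, "s0")
  expect_equal(unname(rowMeans(s0$x)), rep(0, 6))
  expect_equal(unname(apply(s0$x, 1, sd)), rep(1, 6))

  # m2 equals detrend(snv(x)) followed by the (2,4,4,1) derivative, composed
  # operation by operation
  m2 <- apply_treatment(set, "m2")
  wl <- set$grid$wavelengths
  manual <- t(apply(set$x, 1, function(row) {
    as.numeric(gap_segment_derivative(detrend(snv(row), wl), c(2, 4, 4, 1), wl))
  }))
  expect_equal(unname(m2$x), unname(manual))

  # row-locality: permuting samples commutes with the treatment
  perm <- c(3, 1, 6, 2, 5, 4)
  permuted <- subset_samples(set, perm)
  expect_equal(unname(apply_treatment(permuted, "m2")$x), unname(m2$x[perm, ]))

  # grid truncation bookkeeping for a derivative code
  s3 <- apply_treatment(set, "s3")
  expect_equal(s3$grid$n_points, 451L - 9L - 20L)
  expect_equal(s3$grid$step_nm, 2)
})
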