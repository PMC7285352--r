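test_that("treatment enumeration gives the 20 codes in scatter-major order", {
  codes <- enumerate_treatments()
  expect_length(codes, 20)
  expect_equal(codes[1], "n0")
  expect_equal(codes[6], "s0")
  expect_equal(codes[20], "m4")
  expect_false(anyDuplicated(codes) > 0)
  # every code parses
  for (code in codes) expect_s3_class(parse_treatment_code(code), "treatment_code")

  grid <- enumerate_equation_grid()
  expect_equal(nrow(grid), 400)
  expect_false(anyDuplicated(paste(grid$pca_code, grid$mpls_code)) > 0)
  expect_equal(grid$pca_code[1:20], rep("n0", 20))
  expect_equal(grid$mpls_code[1:20], codes)
})

test_that("the calibration/validation split is seeded, disjoint and exhaustive", {
  set <- make_toy_set(n = 100, seed = 40)
  parts <- split_calibration_validation(set, 0.75, seed = 9)
  expect_equal(n_spectra(parts$calibration), 75)
  expect_equal(n_spectra(parts$validation), 25)
  expect_length(intersect(parts$calibration$sample_id,
                          parts$validation$sample_id), 0)
  expect_setequal(c(parts$calibration$sample_id, parts$validation$sample_id),
                  set$sample_id)
  parts2 <- split_calibration_validation(set, 0.75, seed = 9)
  expect_identical(parts$calibration$sample_id, parts2$calibration$sample_id)
})

test_that("zero or missing references are excluded per constituent", {
  set <- make_toy_set(n = 10, seed = 41)
  refs <- set$references
  refs$conc[c(2, 5, 9)] <- 0
  set0 <- spectra_set(set$x, set$grid, set$sample_id, set$replicate, refs)
  kept <- exclude_zero_reference(set0, "conc")
  expect_equal(n_spectra(kept), 7)
  expect_equal(attr(kept, "n_excluded"), 3)

  all_pos <- exclude_zero_reference(set, "conc")
  expect_equal(n_spectra(all_pos), 10)

  refs$conc <- 0
  allzero <- spectra_set(set$x, set$grid, set$sample_id, set$replicate, refs)
  expect_error(exclude_zero_reference(allzero, "conc"), "no sample")
  expect_error(exclude_zero_reference(set, "nope"), "no reference column")
})

test_that("select_best applies the lexicographic SECV/RSQ/RPD rule", {
  cand <- data.frame(
    pca_code = "n0", mpls_code = c("n0", "n1", "n2", "n3", "n4"),
    secv = c(5, 3, 3, 3, 9),
    rsq = c(0.9, 0.8, 0.95, 0.95, 0.99),
    rpd = c(2, 2, 1.5, 4, 2),
    ok = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  # ties on secv broken by rsq, then rpd
  expect_equal(select_best(cand)$mpls_code, "n3")

  # brute-force sort oracle over random tables
  withr::with_seed(42, {
    for (i in 1:10) {
      tab <- data.frame(
        pca_code = "x", mpls_code = as.character(1:12),
        secv = sample(c(1, 2, 3), 12, replace = TRUE),
        rsq = round(runif(12), 1),
        rpd = round(runif(12, 1, 4), 1),
        ok = rep(c(TRUE, TRUE, FALSE), 4)
      )
      got <- select_best(tab)
      oracle <- tab[tab$ok, ]
      oracle <- oracle[order(oracle$secv, -oracle$rsq, -oracle$rpd,
                             seq_len(nrow(oracle))), ][1, ]
      expect_equal(got$mpls_code, oracle$mpls_code)
      # invariant to enumeration order of distinct cells
      perm <- sample(nrow(tab))
      got2 <- select_best(tab[perm, ])
      expect_equal(got2[, c("secv", "rsq", "rpd")],
                   got[, c("secv", "rsq", "rpd")],
                   ignore_attr = TRUE)
    }
  })

  single <- cand[3, ]
  expect_equal(select_best(single)$mpls_code, "n2")
  cand$ok <- FALSE
  expect_error(select_best(cand), "no successful")
})

test_that("a restricted grid runs deterministically and records its cells", {
  d <- generate(default_population_config(n_samples = 60, seed = 50))
  codes <- c("n0", "s0", "s2")
  rep1 <- run_grid(d$set, "total_lolines", n_factors = 6, n_groups = 4,
                   seed = 3, codes = codes)
  expect_s3_class(rep1, "grid_report")
  expect_equal(nrow(rep1$candidates), 9)
  expect_true(all(rep1$candidates$ok))
  expect_s3_class(rep1$best, "equation_candidate")
  expect_true(rep1$best$stats$secv > 0)

  # byte-identical on re-run (deterministic given data and seed)
  rep2 <- run_grid(d$set, "total_lolines", n_factors = 6, n_groups = 4,
                   seed = 3, codes = codes)
  expect_identical(rep1$candidates, rep2$candidates)

  # the winning row agrees with select_best on the candidates table
  row <- select_best(rep1$candidates)
  expect_equal(rep1$best$pca_code$code, row$pca_code)
  expect_equal(rep1$best$mpls_code$code, row$mpls_code)
})

test_that("cells that cannot be fit are recorded as failures, not errors", {
  # 10 samples cannot support 10 factors with 6 CV groups: every cell fails
  d <- generate(default_population_config(n_samples = 10, seed = 51))
  rep <- run_grid(d$set, "total_lolines", n_factors = 10, n_groups = 6,
                  seed = 1, codes = c("n0", "s0"))
  expect_equal(nrow(rep$candidates), 4)
  expect_true(all(!rep$candidates$ok))
  expect_true(all(!is.na(rep$candidates$error)))
  expect_null(rep$best)
  expect_error(select_best(rep$candidates), "no successful")
})
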