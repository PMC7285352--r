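#' Enumerate the 20 standard pre-treatment codes
#'
#' The cross of the four scatter corrections (`n`, `s`, `d`, `m`) with the
#' five derivative/smoothing numeral sets (`0`-`4`), in scatter-major
#' order: `n0 ... n4, s0 ... s4, d0 ... d4, m0 ... m4`.
#'
#' @return Character vector of 20 codes.
#' @export
enumerate_treatments <- function() {
  as.vector(t(outer(c("n", "s", "d", "m"), 0:4, paste0)))
}

#' Enumerate the 400-cell equation grid
#'
#' Every combination of a PCA-stage pre-treatment (used for spectral outlier
#' screening) with an MPLS-stage pre-treatment (used for the regression
#' design matrix).
#'
#' @param codes Treatment codes to cross (default the full 20).
#' @return Data frame with columns `pca_code` and `mpls_code`
#'   (`length(codes)^2` rows, PCA-major order).
#' @export
enumerate_equation_grid <- function(codes = enumerate_treatments()) {
  data.frame(
    pca_code = rep(codes, each = length(codes)),
    mpls_code = rep(codes, times = length(codes)),
    stringsAsFactors = FALSE
  )
}

#' Split a spectra set into calibration and validation subsets
#'
#' Seeded random partition; the calibration part gets `round(fraction * n)`
#' samples and the validation part the remainder (disjoint and exhaustive).
#'
#' @param set A `spectra_set`.
#' @param fraction Calibration fraction (default 0.75).
#' @param seed Integer seed.
#' @return A list with `calibration` and `validation` spectra sets.
#' @export
split_calibration_validation <- function(set, fraction = 0.75, seed = 1L) {
  stopifnot(inherits(set, "spectra_set"))
  n <- nrow(set$x)
  if (n < 4L) stop("need at least 4 samples to split", call. = FALSE)
  n_cal <- round(fraction * n)
  if (n_cal < 1L || n_cal >= n) stop("fraction leaves an empty subset", call. = FALSE)
  cal_idx <- sort(withr::with_seed(seed, sample(n, n_cal)))
  list(
    calibration = subset_samples(set, cal_idx),
    validation = subset_samples(set, setdiff(seq_len(n), cal_idx))
  )
}

#' Drop samples with zero or missing reference values
#'
#' Samples whose wet-chemistry determination of the constituent is zero
#' (below the detection limit) or missing cannot inform a calibration and
#' are excluded.
#'
#' @param set A `spectra_set` with references.
#' @param constituent Reference column name.
#' @return The reduced `spectra_set`; the number of removals is recorded in
#'   the `"n_excluded"` attribute.
#' @export
exclude_zero_reference <- function(set, constituent) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.null(set$references) || !(constituent %in% names(set$references))) {
    stop("no reference column '", constituent, "'", call. = FALSE)
  }
  v <- set$references[[constituent]]
  keep <- which(!is.na(v) & v > 0)
  if (length(keep) == 0L) {
    stop("no sample has a positive reference for '", constituent, "'",
         call. = FALSE)
  }
  out <- if (length(keep) == length(v)) set else subset_samples(set, keep)
  attr(out, "n_excluded") <- length(v) - length(keep)
  out
}

#' Evaluate the full pre-treatment grid for one constituent
#'
#' For each PCA-stage code: apply the treatment, fit a PCA, and remove
#' samples with Mahalanobis H above `h_threshold` (single pass). For each
#' MPLS-stage code: treat the surviving raw spectra, fit an MPLS model,
#' cross-validate in `n_groups` groups, apply two-round T-outlier
#' elimination, and compute the statistics bundle. Per-cell failures are
#' recorded in the cell, never aborting the grid. The winning cell (lowest
#' SECV, ties broken by RSQ then RPD then enumeration order) is refitted
#' and returned with its models.
#'
#' @param calibration A replicate-averaged `spectra_set` with references.
#' @param constituent Reference column to calibrate.
#' @param n_factors MPLS factors (default 10).
#' @param n_groups Cross-validation groups (default 6).
#' @param seed Integer seed for group assignment (shared by every cell, so
#'   the grid is a deterministic function of the data and seed).
#' @param codes Treatment codes to cross (default all 20, i.e. 400 cells).
#' @param variance_target,max_k PCA component selection; see [fit_pca()].
#' @param h_threshold Spectral outlier cutoff (default 3.0).
#' @param t_threshold,t_rounds Chemical outlier cutoff and rounds.
#' @param scale_residuals,scale_y Passed to [fit_mpls()].
#' @param verbose Print one line per PCA-stage code.
#' @return An object of class `grid_report`: `constituent`, `candidates`
#'   (one row per cell with codes, outlier counts and statistics), `best`
#'   (an `equation_candidate` holding the refitted PCA and MPLS models,
#'   final cross-validation and statistics), and `selection_rule`.
#' @export
run_grid <- function(calibration, constituent, n_factors = 10L, n_groups = 6L,
                     seed = 1L, codes = enumerate_treatments(),
                     variance_target = 0.99, max_k = 30L, h_threshold = 3.0,
                     t_threshold = 2.5, t_rounds = 2L,
                     scale_residuals = TRUE, scale_y = TRUE, verbose = FALSE) {
  stopifnot(inherits(calibration, "spectra_set"))
  set0 <- exclude_zero_reference(average_replicates(calibration), constituent)
  cells <- enumerate_equation_grid(codes)
  n_cells <- nrow(cells)
  res <- data.frame(
    cells,
    n_pcs = NA_integer_, pca_explained = NA_real_,
    n_spectral_outliers = NA_integer_, n_samples = NA_integer_,
    n_chemical_outliers = NA_integer_, n_factors = NA_integer_,
    rsq = NA_real_, sec = NA_real_, secv = NA_real_, cv_rsq = NA_real_,
    sep = NA_real_, sepc = NA_real_, bias = NA_real_, rpd = NA_real_,
    ok = FALSE, error = NA_character_,
    stringsAsFactors = FALSE
  )

  eval_cell <- function(survivors, mpls_code) {
    treated <- apply_treatment(survivors, mpls_code)
    X <- treated$x
    y <- survivors$references[[constituent]]
    elim <- t_outlier_elimination(
      X, y, n_factors = n_factors, n_groups = n_groups, seed = seed,
      threshold = t_threshold, max_rounds = t_rounds,
      scale_residuals = scale_residuals, scale_y = scale_y,
      ids = survivors$sample_id
    )
    kept <- elim$kept
    Xk <- X[kept, , drop = FALSE]
    yk <- y[kept]
    model <- fit_mpls(Xk, yk, n_factors = n_factors,
                      scale_residuals = scale_residuals, scale_y = scale_y)
    stats <- compute_stats(yk, model$fitted, context = "calibration",
                           n_factors = model$n_factors, secv = elim$cv$secv)
    list(model = model, elim = elim, stats = stats,
         kept_ids = survivors$sample_id[kept])
  }

  for (pc in unique(cells$pca_code)) {
    if (verbose) message("PCA-stage code ", pc)
    rows_pc <- which(cells$pca_code == pc)
    screen <- tryCatch(
      screen_spectral_outliers(set0, pc, variance_target = variance_target,
                               threshold = h_threshold, max_k = max_k),
      error = function(e) e
    )
    if (inherits(screen, "error")) {
      res$error[rows_pc] <- conditionMessage(screen)
      next
    }
    survivors <- if (length(screen$outlier_ids)) {
      subset_samples(set0, !(set0$sample_id %in% screen$outlier_ids))
    } else {
      set0
    }
    for (i in rows_pc) {
      cell <- tryCatch(eval_cell(survivors, cells$mpls_code[i]),
                       error = function(e) e)
      if (inherits(cell, "error")) {
        res$n_pcs[i] <- screen$pca$k
        res$pca_explained[i] <- screen$pca$explained_fraction
        res$n_spectral_outliers[i] <- length(screen$outlier_ids)
        res$error[i] <- conditionMessage(cell)
        next
      }
      st <- cell$stats
      res$n_pcs[i] <- screen$pca$k
      res$pca_explained[i] <- screen$pca$explained_fraction
      res$n_spectral_outliers[i] <- length(screen$outlier_ids)
      res$n_samples[i] <- st$n
      res$n_chemical_outliers[i] <- length(unlist(cell$elim$removed_ids))
      res$n_factors[i] <- cell$model$n_factors
      res$rsq[i] <- st$rsq
      res$sec[i] <- st$sec
      res$secv[i] <- st$secv
      res$cv_rsq[i] <- cell$elim$cv$cv_rsq
      res$sep[i] <- st$sep
      res$sepc[i] <- st$sepc
      res$bias[i] <- st$bias
      res$rpd[i] <- st$rpd
      res$ok[i] <- TRUE
    }
  }

  report <- structure(
    list(constituent = constituent, candidates = res, best = NULL,
         selection_rule = c("min secv", "max rsq", "max rpd", "code order"),
         settings = list(n_factors = n_factors, n_groups = n_groups,
                         seed = seed, variance_target = variance_target,
                         max_k = max_k, h_threshold = h_threshold,
                         t_threshold = t_threshold, t_rounds = t_rounds)),
    class = "grid_report"
  )
  best_row <- tryCatch(select_best(report, refit = FALSE), error = function(e) NULL)
  if (is.null(best_row)) {
    return(report)  # every cell failed; the table records why
  }
  # refit the winning cell so the report carries its fitted models
  screen <- screen_spectral_outliers(set0, best_row$pca_code,
                                     variance_target = variance_target,
                                     threshold = h_threshold, max_k = max_k)
  survivors <- if (length(screen$outlier_ids)) {
    subset_samples(set0, !(set0$sample_id %in% screen$outlier_ids))
  } else {
    set0
  }
  cell <- eval_cell(survivors, best_row$mpls_code)
  report$best <- structure(
    list(pca_code = parse_treatment_code(best_row$pca_code),
         mpls_code = parse_treatment_code(best_row$mpls_code),
         pca_model = screen$pca,
         n_spectral_outliers = length(screen$outlier_ids),
         mpls_model = cell$model,
         n_chemical_outliers = length(unlist(cell$elim$removed_ids)),
         cv = cell$elim$cv, stats = cell$stats, kept_ids = cell$kept_ids),
    class = "equation_candidate"
  )
  report
}

#' Select the best cell of a grid report
#'
#' Lexicographic rule: minimize SECV, break ties by maximal RSQ, then
#' maximal RPD, then enumeration order.
#'
#' @param report A `grid_report` (or its `candidates` data frame).
#' @param refit If `TRUE` (default) and the report carries a fitted `best`
#'   candidate, return it; otherwise return the winning candidates row.
#' @return The winning `equation_candidate` (when available) or the winning
#'   row of the candidates table.
#' @export
select_best <- function(report, refit = TRUE) {
  cand <- if (inherits(report, "grid_report")) report$candidates else report
  ok <- which(cand$ok)
  if (length(ok) == 0L) stop("no successful grid cell to select", call. = FALSE)
  sub <- cand[ok, , drop = FALSE]
  ord <- order(sub$secv, -sub$rsq, -sub$rpd, ok)
  winner <- sub[ord[1L], , drop = FALSE]
  if (refit && inherits(report, "grid_report") && !is.null(report$best)) {
    return(report$best)
  }
  winner
}

#' @export
print.grid_report <- function(x, ...) {
  n_ok <- sum(x$candidates$ok)
  cat(sprintf("<grid_report> %s: %d cells (%d successful)\n",
              x$constituent, nrow(x$candidates), n_ok))
  if (!is.null(x$best)) {
    b <- x$best
    cat(sprintf("  best: PCA %s / MPLS %s | SECV %.4g | RSQ %.3f | RPD %.3f\n",
                b$pca_code$code, b$mpls_code$code, b$stats$secv,
                b$stats$rsq, b$stats$rpd))
  }
  invisible(x)
}

#' @export
print.equation_candidate <- function(x, ...) {
  cat(sprintf(
    "<equation_candidate> PCA %s (%d PCs, %d H-outliers) / MPLS %s (%d factors, %d T-outliers)\n",
    x$pca_code$code, x$pca_model$k, x$n_spectral_outliers,
    x$mpls_code$code, x$mpls_model$n_factors, x$n_chemical_outliers
  ))
  print(x$stats)
  invisible(x)
}
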