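#' Principal component model of treated spectra
#'
#' Fits a PCA (centered, unscaled) to a treated spectra matrix and retains
#' either a fixed number of components or the smallest number whose
#' cumulative explained variance reaches a target. Loadings carry a
#' deterministic sign convention: the largest-magnitude element of each
#' loading is positive.
#'
#' @param set A `spectra_set` (already pre-treated) or a numeric matrix with
#'   spectra in rows.
#' @param variance_target Fraction of total variance to explain (default
#'   0.99); ignored when `k` is given.
#' @param k Optional fixed number of components.
#' @param max_k Cap on the number of retained components (default 30);
#'   always additionally capped at `min(n - 1, p)`.
#' @return An object of class `nirs_pca` with fields `center`, `loadings`
#'   (p x k), `sdev` (per-component score SD, n-1 denominator),
#'   `score_variances`, `k`, `explained_fraction` and `wavelengths`.
#' @export
fit_pca <- function(set, variance_target = 0.99, k = NULL, max_k = 30L) {
  x <- if (inherits(set, "spectra_set")) set$x else as.matrix(set)
  wl <- if (inherits(set, "spectra_set")) set$grid$wavelengths else seq_len(ncol(x))
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("PCA needs at least 2 spectra", call. = FALSE)
  kmax <- min(n - 1L, p)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > kmax) {
      stop("k must be between 1 and min(n - 1, p) = ", kmax, call. = FALSE)
    }
  } else {
    if (!is.numeric(variance_target) || variance_target <= 0 || variance_target > 1) {
      stop("variance_target must be in (0, 1]", call. = FALSE)
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  cumfrac <- cumsum(vars) / total
  if (is.null(k)) {
    k <- which(cumfrac >= variance_target - 1e-12)[1L]
    if (is.na(k)) k <- length(vars)
    k <- min(k, kmax, as.integer(max_k))
  }
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  sdev <- pc$sdev[seq_len(k)]
  # deterministic sign: largest-magnitude loading element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(
    list(center = pc$center, loadings = load, sdev = sdev,
         score_variances = sdev^2, k = k,
         explained_fraction = cumfrac[k], wavelengths = wl),
    class = "nirs_pca"
  )
}

#' @export
print.nirs_pca <- function(x, ...) {
  cat(sprintf("<nirs_pca> %d components explaining %.2f%% of variance\n",
              x$k, 100 * x$explained_fraction))
  invisible(x)
}

#' Mahalanobis H statistic of spectra in PCA score space
#'
#' The "global H": each spectrum is projected onto the retained components,
#' each score is standardized by that component's training SD, and H is the
#' squared Mahalanobis distance divided by the number of components k. Over
#' the training set H averages (n-1)/n; H > 3.0 conventionally marks a
#' spectral outlier.
#'
#' @param model A `nirs_pca` model.
#' @param x A spectrum (vector), spectra matrix, or `spectra_set` on the
#'   model's grid.
#' @return Numeric vector of H values, one per spectrum.
#' @export
h_statistic <- function(model, x) {
  stopifnot(inherits(model, "nirs_pca"))
  if (inherits(x, "spectra_set")) x <- x$x
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$center)) {
    stop("spectrum is not on the model grid", call. = FALSE)
  }
  if (any(model$sdev <= 0)) {
    stop("degenerate component with zero score variance", call. = FALSE)
  }
  scores <- sweep(x, 2L, model$center) %*% model$loadings
  z <- sweep(scores, 2L, model$sdev, "/")
  rowSums(z^2) / model$k
}

#' Screen a spectra set for spectral outliers
#'
#' Applies a pre-treatment, fits a PCA, and flags every sample whose
#' Mahalanobis H exceeds the threshold (single pass: the PCA is not refit
#' after removal unless `iterate = TRUE`).
#'
#' @param set A `spectra_set` (raw, replicate-averaged).
#' @param code Treatment code applied before the PCA.
#' @param variance_target Cumulative explained-variance target for component
#'   selection (default 0.99).
#' @param threshold H cutoff, conventionally 3.0.
#' @param k,max_k Passed to [fit_pca()].
#' @param iterate If `TRUE`, refit and rescreen on the survivors until no
#'   new flags appear.
#' @return An object of class `h_screen` with `h_values` (named by
#'   sample_id), `threshold`, `outlier_ids`, the fitted `pca` and `code`.
#' @export
screen_spectral_outliers <- function(set, code, variance_target = 0.99,
                                     threshold = 3.0, k = NULL, max_k = 30L,
                                     iterate = FALSE) {
  stopifnot(inherits(set, "spectra_set"))
  treated <- apply_treatment(set, code)
  keep <- seq_len(nrow(treated$x))
  repeat {
    pca <- fit_pca(treated$x[keep, , drop = FALSE], variance_target, k, max_k)
    h <- h_statistic(pca, treated$x[keep, , drop = FALSE])
    flagged <- which(h > threshold)
    if (!iterate || length(flagged) == 0L) break
    keep <- keep[-flagged]
    if (length(keep) < 3L) break
  }
  h_all <- h_statistic(pca, treated$x)
  names(h_all) <- treated$sample_id
  out_ids <- unique(c(
    treated$sample_id[setdiff(seq_len(nrow(treated$x)), keep)],
    treated$sample_id[keep][h_statistic(pca, treated$x[keep, , drop = FALSE]) > threshold]
  ))
  structure(
    list(h_values = h_all, threshold = threshold, outlier_ids = out_ids,
         pca = pca, code = parse_treatment_code(code)),
    class = "h_screen"
  )
}

#' @export
print.h_screen <- function(x, ...) {
  cat(sprintf("<h_screen> code %s, %d/%d samples with H > %.2f\n",
              x$code$code, length(x$outlier_ids), length(x$h_values), x$threshold))
  invisible(x)
}
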