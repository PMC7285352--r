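#' Grouped cross-validation of an MPLS calibration
#'
#' Samples are assigned to `n_groups` near-equal groups by a seeded random
#' permutation; each group is predicted by a model fitted on the remaining
#' samples. The standard error of cross-validation (SECV) is the root mean
#' square of the pooled held-out residuals, and each sample's T value is its
#' held-out residual divided by the SECV.
#'
#' @param X Treated spectra matrix.
#' @param y Reference vector.
#' @param n_factors Factors per fold model (default 10).
#' @param n_groups Number of cross-validation groups (default 6);
#'   `n_groups = n` gives leave-one-out.
#' @param seed Integer seed controlling the group assignment.
#' @param scale_residuals,scale_y Passed to [fit_mpls()].
#' @return An object of class `cv_result` with `assignments`, held-out
#'   `predictions`, `residuals` (reference minus predicted), `secv`,
#'   `t_values`, `cv_rsq` (squared correlation of held-out predictions with
#'   the reference) and the call settings.
#' @export
cross_validate <- function(X, y, n_factors = 10L, n_groups = 6L, seed = 1L,
                           scale_residuals = TRUE, scale_y = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("y must have one value per row of X", call. = FALSE)
  n_groups <- as.integer(n_groups)
  if (n_groups < 2L || n_groups > n) {
    stop("n_groups must be between 2 and n", call. = FALSE)
  }
  assignments <- withr::with_seed(seed, sample(rep(seq_len(n_groups), length.out = n)))
  pred <- rep(NA_real_, n)
  for (g in seq_len(n_groups)) {
    hold <- which(assignments == g)
    train <- which(assignments != g)
    fit <- fit_mpls(X[train, , drop = FALSE], y[train],
                    n_factors = min(n_factors, length(train) - 1L),
                    scale_residuals = scale_residuals, scale_y = scale_y)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  res <- y - pred
  secv <- sqrt(mean(res^2))
  t_values <- if (secv > 0) res / secv else rep(0, n)
  cv_rsq <- if (stats::sd(pred) > 0) stats::cor(y, pred)^2 else NA_real_
  structure(
    list(n_groups = n_groups, assignments = assignments, predictions = pred,
         residuals = res, secv = secv, t_values = t_values, cv_rsq = cv_rsq,
         n_factors = n_factors, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d groups, SECV = %.4g, CV RSQ = %.3f\n",
              x$n_groups, x$secv, x$cv_rsq))
  invisible(x)
}

#' Two-round elimination of chemical (T) outliers during cross-validation
#'
#' After an initial cross-validation, every sample whose |T| =
#' |residual| / SECV exceeds the threshold (conventionally 2.5) is
#' eliminated and the cross-validation re-run; the process is applied at
#' most `max_rounds` times (conventionally twice).
#'
#' @param X Treated spectra matrix.
#' @param y Reference vector.
#' @param n_factors,n_groups,seed,scale_residuals,scale_y Passed to
#'   [cross_validate()].
#' @param threshold T cutoff (default 2.5).
#' @param max_rounds Maximum elimination rounds (default 2); 0 performs the
#'   initial cross-validation only.
#' @param ids Optional sample identifiers (defaults to row index) used in
#'   the removal record.
#' @return A list with `kept` (row indices retained), `removed_ids` (list,
#'   one element per round), `cv` (final `cv_result` on the kept samples)
#'   and `initial_cv`.
#' @export
t_outlier_elimination <- function(X, y, n_factors = 10L, n_groups = 6L,
                                  seed = 1L, threshold = 2.5, max_rounds = 2L,
                                  scale_residuals = TRUE, scale_y = TRUE,
                                  ids = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n) stop("ids must have one entry per row", call. = FALSE)
  kept <- seq_len(n)
  cv <- cross_validate(X, y, n_factors, n_groups, seed, scale_residuals, scale_y)
  initial_cv <- cv
  removed <- list()
  for (round in seq_len(max_rounds)) {
    out <- which(abs(cv$t_values) > threshold)
    if (length(out) == 0L) break
    removed[[length(removed) + 1L]] <- ids[kept[out]]
    kept <- kept[-out]
    if (length(kept) < max(n_groups, n_factors + 2L)) {
      stop("T-outlier elimination left too few samples", call. = FALSE)
    }
    cv <- cross_validate(X[kept, , drop = FALSE], y[kept], n_factors,
                         n_groups, seed, scale_residuals, scale_y)
  }
  list(kept = kept, removed_ids = removed, cv = cv, initial_cv = initial_cv)
}

#' Paired two-sided Student's t-test of reference vs predicted values
#'
#' @param y_ref,y_pred Numeric vectors of equal length (n >= 2).
#' @return Two-sided p-value. If the paired differences have zero variance,
#'   returns 1 when they are all zero (methods agree exactly) and 0 for a
#'   constant nonzero shift.
#' @export
paired_t_test <- function(y_ref, y_pred) {
  if (length(y_ref) != length(y_pred)) stop("vectors must have equal length", call. = FALSE)
  if (length(y_ref) < 2L) stop("paired t-test needs n >= 2", call. = FALSE)
  d <- y_ref - y_pred
  scale <- max(abs(d), abs(y_ref), 1)
  if (stats::sd(d) <= 1e-12 * scale) {
    return(if (abs(mean(d)) <= 1e-12 * scale) 1 else 0)
  }
  stats::t.test(y_ref, y_pred, paired = TRUE)$p.value
}

#' Calibration and validation statistics for a NIRS equation
#'
#' Computes the standard chemometric statistics bundle from reference and
#' predicted values:
#' \itemize{
#'   \item RSQ: squared Pearson correlation;
#'   \item BIAS: mean(reference - predicted);
#'   \item SEC (calibration context): `sqrt(SSE / (n - n_factors - 1))`,
#'     the degrees-of-freedom-corrected calibration error;
#'   \item SEP = RMSE: `sqrt(SSE / n)`;
#'   \item SEPc: bias-corrected SEP, `sqrt(sum((r - BIAS)^2) / (n - 1))`;
#'   \item RPD: `sd(reference) / SEP` by default, or `sd / SECV` with
#'     `rpd_on = "secv"` (an RPD above 2.0 conventionally indicates a
#'     usable calibration);
#'   \item a paired two-sided t-test p-value.
#' }
#'
#' @param y_ref,y_pred Numeric vectors of equal length (n >= 3).
#' @param context One of `"calibration"`, `"internal_validation"`,
#'   `"external_validation"`; SEC is only computed in calibration context.
#' @param n_factors Number of model factors (required for SEC).
#' @param secv Optional SECV from cross-validation, stored and used when
#'   `rpd_on = "secv"`.
#' @param rpd_on Denominator for RPD: `"sep"` (default) or `"secv"`.
#' @return An object of class `calibration_stats` (a list of the named
#'   statistics plus `n`, `sd`, `context` and `rpd_on`).
#' @export
compute_stats <- function(y_ref, y_pred,
                          context = c("calibration", "internal_validation",
                                      "external_validation"),
                          n_factors = NULL, secv = NULL,
                          rpd_on = c("sep", "secv")) {
  context <- match.arg(context)
  rpd_on <- match.arg(rpd_on)
  y_ref <- as.numeric(y_ref)
  y_pred <- as.numeric(y_pred)
  n <- length(y_ref)
  if (length(y_pred) != n) stop("vectors must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(y_ref) == 0 || stats::sd(y_pred) == 0) {
    stop("zero variance: RSQ undefined", call. = FALSE)
  }
  r <- y_ref - y_pred
  sse <- sum(r^2)
  bias <- mean(r)
  sd_ref <- stats::sd(y_ref)
  sec <- NA_real_
  if (context == "calibration" && !is.null(n_factors)) {
    dof <- n - n_factors - 1L
    if (dof > 0L) sec <- sqrt(sse / dof)
  }
  sep <- sqrt(sse / n)
  sepc <- sqrt(sum((r - bias)^2) / (n - 1L))
  rpd_err <- if (rpd_on == "secv") {
    if (is.null(secv)) stop("rpd_on = 'secv' requires secv", call. = FALSE)
    secv
  } else {
    sep
  }
  rpd <- if (rpd_err > 0) rpd_ratio(sd_ref, rpd_err) else Inf
  structure(
    list(n = n, sd = sd_ref, rsq = stats::cor(y_ref, y_pred)^2,
         sec = sec, secv = if (is.null(secv)) NA_real_ else secv,
         sep = sep, sepc = sepc, bias = bias, rmse = sep,
         rpd = rpd,
         t_test_p = paired_t_test(y_ref, y_pred),
         context = context, rpd_on = rpd_on),
    class = "calibration_stats"
  )
}

#' Ratio of performance to deviation (RPD)
#'
#' The reference-set standard deviation divided by a prediction error (SEP
#' or SECV). Values above 2.0 conventionally indicate a calibration good
#' enough for quantitative use.
#'
#' @param sd Standard deviation of the reference values.
#' @param error Prediction error (SEP or SECV), > 0.
#' @return `sd / error`.
#' @examples
#' rpd_ratio(1008, 310)  # 3.252
#' @export
rpd_ratio <- function(sd, error) {
  if (!is.numeric(sd) || !is.numeric(error)) stop("rpd_ratio needs numbers", call. = FALSE)
  if (any(error <= 0)) stop("error term must be > 0", call. = FALSE)
  sd / error
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf("<calibration_stats> (%s) n = %d\n", x$context, x$n))
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, format = "g", digits = 4))
  cat(sprintf("  RSQ %s | SEC %s | SECV %s | SEP %s | SEPc %s | BIAS %s | RPD %s\n",
              fmt(x$rsq), fmt(x$sec), fmt(x$secv), fmt(x$sep), fmt(x$sepc),
              fmt(x$bias), fmt(x$rpd)))
  invisible(x)
}
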