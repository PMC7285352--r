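#' Modified partial least squares (MPLS) regression
#'
#' PLS1 with between-factor residual standardization: after each factor is
#' extracted, every column of the spectral residual matrix (and, optionally,
#' the reference residual) is divided by its standard deviation before the
#' next factor is calculated. The divisors are stored so that prediction
#' replays them in training order. With `scale_residuals = FALSE` the fit is
#' exactly classical NIPALS PLS1.
#'
#' Per factor: the weight vector is proportional to the covariance of the
#' current spectral residual with the current reference residual; the score
#' is the residual projected on the weight; both the spectral matrix and
#' the reference are deflated by the score projection.
#'
#' @param X Numeric matrix of treated spectra (samples in rows).
#' @param y Numeric reference vector (mg kg^-1 or mg g^-1), one per row.
#' @param n_factors Number of latent factors (default 10, the conventional
#'   setting for this workflow); at most `min(n - 1, p)`.
#' @param scale_residuals Apply the between-factor standardization
#'   (default `TRUE`). Columns whose residual SD collapses below `tol` are
#'   left unscaled (unit divisor).
#' @param scale_y Also standardize the reference residual between factors
#'   (default `TRUE`).
#' @param tol Numeric tolerance for degenerate SDs and exhausted residuals.
#' @return An object of class `mpls` with the centering, per-factor weight
#'   vectors `W`, x-loadings `P`, y-loadings `q`, stored divisors
#'   (`x_divisors`, `y_divisors`, applied *before* each factor's
#'   extraction; all ones for factor 1), `n_factors` actually extracted,
#'   and training `fitted` values.
#' @export
fit_mpls <- function(X, y, n_factors = 10L, scale_residuals = TRUE,
                     scale_y = TRUE, tol = 1e-12) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y must have one value per row of X", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  n_factors <- as.integer(n_factors)
  if (n_factors < 1L || n_factors > min(n - 1L, p)) {
    stop("n_factors must be between 1 and min(n - 1, p)", call. = FALSE)
  }
  if (stats::var(y) <= 0) stop("y has zero variance", call. = FALSE)

  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2L, x_center)
  f <- y - y_center

  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  x_div <- matrix(1, p, n_factors)
  y_div <- rep(1, n_factors)
  scores <- matrix(0, n, n_factors)
  actual <- 0L

  for (a in seq_len(n_factors)) {
    if (scale_residuals && a > 1L) {
      cm <- colMeans(E)
      s <- sqrt(pmax(colSums(E^2) - n * cm^2, 0) / (n - 1L))
      s[s < tol] <- 1
      E <- sweep(E, 2L, s, "/")
      x_div[, a] <- s
      if (scale_y) {
        sy <- stats::sd(f)
        if (!is.finite(sy) || sy < tol) sy <- 1
        f <- f / sy
        y_div[a] <- sy
      }
    }
    w <- crossprod(E, f)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < tol) break
    pl <- crossprod(E, t)[, 1L] / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pl; q[a] <- qa; scores[, a] <- t
    actual <- a
  }
  if (actual == 0L) stop("no extractable factor: X residual is degenerate", call. = FALSE)
  if (actual < n_factors) {
    W <- W[, seq_len(actual), drop = FALSE]
    P <- P[, seq_len(actual), drop = FALSE]
    q <- q[seq_len(actual)]
    x_div <- x_div[, seq_len(actual), drop = FALSE]
    y_div <- y_div[seq_len(actual)]
  }
  model <- structure(
    list(x_center = x_center, y_center = y_center, W = W, P = P, q = q,
         x_divisors = x_div, y_divisors = y_div, n_factors = actual,
         scale_residuals = scale_residuals, scale_y = scale_y,
         requested_factors = n_factors, p = p),
    class = "mpls"
  )
  model$fitted <- predict(model, X)
  model$y <- y
  model
}

#' Predict reference concentrations from an MPLS model
#'
#' Applies the stored centering and per-factor residual scalings in training
#' order; output is on the original reference scale.
#'
#' @param object A fitted `mpls` model.
#' @param X Treated spectra matrix on the model's grid.
#' @param n_factors Optionally truncate to the first `n_factors` factors
#'   (0 returns the training mean for every row).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mpls <- function(object, X, n_factors = NULL, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$p) {
    stop("X has ", ncol(X), " columns but the model expects ", object$p,
         call. = FALSE)
  }
  A <- if (is.null(n_factors)) object$n_factors else as.integer(n_factors)
  if (A < 0L || A > object$n_factors) {
    stop("n_factors must be between 0 and ", object$n_factors, call. = FALSE)
  }
  yhat <- rep(object$y_center, nrow(X))
  if (A == 0L) return(yhat)
  E <- sweep(X, 2L, object$x_center)
  yscale <- 1
  for (a in seq_len(A)) {
    if (a > 1L) {
      E <- sweep(E, 2L, object$x_divisors[, a], "/")
      yscale <- yscale * object$y_divisors[a]
    }
    t <- drop(E %*% object$W[, a])
    yhat <- yhat + t * object$q[a] * yscale
    E <- E - tcrossprod(t, object$P[, a])
  }
  yhat
}

#' Regression coefficients of an MPLS model
#'
#' The prediction map is affine in the input spectrum, so coefficients are
#' recovered exactly by probing the map with unit vectors.
#'
#' @param object A fitted `mpls` model.
#' @param ... Unused.
#' @return Numeric vector of length p with the intercept in the
#'   `"intercept"` attribute: `yhat = intercept + x %*% coef`.
#' @export
coef.mpls <- function(object, ...) {
  p <- object$p
  base <- predict(object, matrix(0, 1L, p))
  b <- predict(object, diag(p)) - base
  attr(b, "intercept") <- as.numeric(base)
  b
}

#' @export
print.mpls <- function(x, ...) {
  cat(sprintf(
    "<mpls> %d factors (%s residual scaling), %d wavelengths\n",
    x$n_factors,
    if (x$scale_residuals) "with" else "without", x$p
  ))
  invisible(x)
}
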