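# Independent oracles and small fixture builders used across the suite.

# Textbook NIPALS PLS1 (orthogonal-score form), kept deliberately separate
# from the package implementation: returns the overall regression
# coefficients and a prediction closure.
nipals_pls1_oracle <- function(X, y, A) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- X - matrix(x_mean, n, p, byrow = TRUE)
  f <- y - y_mean
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Q <- numeric(A)
  for (a in 1:A) {
    w <- t(E) %*% f
    w <- w / sqrt(sum(w * w))
    t_ <- E %*% w
    tt <- sum(t_ * t_)
    p_ <- t(E) %*% t_ / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %*% t(p_)
    f <- f - q_ * t_
    W[, a] <- w
    P[, a] <- p_
    Q[a] <- q_
  }
  # beta such that yhat = y_mean + (x - x_mean) %*% beta
  beta <- W %*% solve(t(P) %*% W, Q)
  list(
    beta = as.numeric(beta),
    predict = function(Xnew) {
      Xnew <- as.matrix(Xnew)
      y_mean + as.numeric((Xnew - matrix(x_mean, nrow(Xnew), p, byrow = TRUE)) %*% beta)
    }
  )
}

# Brute-force leave-one-out cross-validation of plain PLS1 via fit_mpls.
loo_oracle <- function(X, y, n_factors, scale_residuals = TRUE, scale_y = TRUE) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_mpls(X[-i, , drop = FALSE], y[-i], n_factors,
                    scale_residuals = scale_residuals, scale_y = scale_y)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  pred
}

# Small deterministic spectra set: smooth baseline plus one analyte band,
# with known references. Returns a spectra_set with a "conc" reference.
make_toy_set <- function(n = 20, seed = 42, noise = 1e-4, replicates = 1) {
  withr::with_seed(seed, {
    wl <- seq(1100, 2000, by = 2)
    conc <- runif(n, 10, 100)
    band <- exp(-0.5 * ((wl - 1650) / 40)^2)
    base <- 0.5 + 1e-4 * (wl - 1100)
    x <- outer(rep(conc, each = replicates), band * 5e-3) +
      matrix(base, n * replicates, length(wl), byrow = TRUE) +
      matrix(rnorm(n * replicates * length(wl), 0, noise), n * replicates)
    spectra_set(
      x, wl,
      sample_id = rep(sprintf("T%02d", seq_len(n)), each = replicates),
      replicate = rep(seq_len(replicates), times = n),
      references = data.frame(conc = rep(conc, each = replicates))
    )
  })
}
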