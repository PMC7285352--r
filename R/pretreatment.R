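#' Parse a two-character pre-treatment code
#'
#' Pre-treatments are named by a scatter-correction letter followed by a
#' derivative/smoothing digit. Letters: `n` = none, `s` = standard normal
#' variate (SNV), `d` = detrend (DT), `m` = SNV followed by DT. Digits map
#' to the four numerals (a, b, c, d) = (derivative order, derivative gap in
#' points, first smoothing segment, second smoothing segment):
#' `0` = (0,0,1,1), `1` = (1,4,4,1), `2` = (2,4,4,1), `3` = (2,10,10,1),
#' `4` = (2,8,6,1).
#'
#' @param code A string such as `"s2"`, or an existing `treatment_code`
#'   (returned unchanged).
#' @return An object of class `treatment_code` with fields `code`,
#'   `scatter` (one of `"none"`, `"snv"`, `"dt"`, `"snv_dt"`) and `numerals`
#'   (integer vector `c(a, b, c, d)`).
#' @examples
#' parse_treatment_code("s2")$numerals  # 2 4 4 1
#' @export
parse_treatment_code <- function(code) {
  if (inherits(code, "treatment_code")) return(code)
  if (!is.character(code) || length(code) != 1L || !grepl("^[a-z][0-9]$", code)) {
    stop("treatment code must be one letter followed by one digit", call. = FALSE)
  }
  letter <- substr(code, 1L, 1L)
  digit <- substr(code, 2L, 2L)
  scatter <- switch(letter,
    n = "none", s = "snv", d = "dt", m = "snv_dt",
    stop("unknown scatter letter '", letter, "' in treatment code", call. = FALSE)
  )
  numerals <- switch(digit,
    "0" = c(0L, 0L, 1L, 1L),
    "1" = c(1L, 4L, 4L, 1L),
    "2" = c(2L, 4L, 4L, 1L),
    "3" = c(2L, 10L, 10L, 1L),
    "4" = c(2L, 8L, 6L, 1L),
    stop("unknown numeral digit '", digit, "' in treatment code", call. = FALSE)
  )
  names(numerals) <- c("a", "b", "c", "d")
  structure(list(code = code, scatter = scatter, numerals = numerals),
            class = "treatment_code")
}

#' @export
print.treatment_code <- function(x, ...) {
  cat(sprintf("<treatment_code> %s: scatter=%s, numerals=(%s)\n",
              x$code, x$scatter, paste(x$numerals, collapse = ",")))
  invisible(x)
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum to mean 0 and unit sample standard
#' deviation (n-1 denominator), removing multiplicative scatter and additive
#' baseline offsets.
#'
#' @param x Numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return The transformed vector or matrix.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (is.matrix(x)) {
    p <- ncol(x)
    m <- rowMeans(x)
    s <- sqrt(pmax(rowSums((x - m)^2), 0) / (p - 1))
    if (any(s <= 0)) stop("constant spectrum: SNV undefined", call. = FALSE)
    (x - m) / s
  } else {
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) stop("constant spectrum: SNV undefined", call. = FALSE)
    (x - mean(x)) / s
  }
}

#' Detrend a spectrum against its wavelength axis
#'
#' Returns the residual of a least-squares polynomial fit (default degree 2,
#' the convention for scatter detrending of powdered samples) of absorbance
#' against wavelength.
#'
#' @param x Numeric vector or matrix (spectra in rows).
#' @param wavelengths Wavelength axis, one value per point.
#' @param degree Polynomial degree; must be < number of points.
#' @return The detrended vector or matrix.
#' @export
detrend <- function(x, wavelengths, degree = 2L) {
  p <- if (is.matrix(x)) ncol(x) else length(x)
  if (length(wavelengths) != p) {
    stop("wavelengths must match the number of spectral points", call. = FALSE)
  }
  if (p <= degree) stop("need more points than the polynomial degree", call. = FALSE)
  Q <- detrend_basis(wavelengths, degree)
  if (is.matrix(x)) {
    x - (x %*% Q) %*% t(Q)
  } else {
    drop(x - Q %*% crossprod(Q, x))
  }
}

# Orthonormal polynomial basis (including intercept) for the residual maker.
detrend_basis <- function(wavelengths, degree) {
  B <- cbind(1, stats::poly(as.numeric(wavelengths), degree = degree))
  qr.Q(qr(B))
}

#' Linear operator for the gap-segment derivative stage
#'
#' Builds the matrix `L` implementing: boxcar smoothing over `c` points,
#' then the `a`-th order gap difference with gap `b` points, then boxcar
#' smoothing over `d` points, together with the wavelengths of the surviving
#' (truncated) window. Numerals (0,0,1,1) give the identity.
#'
#' First derivative: difference of points `b` apart, assigned to the window
#' midpoint. Second derivative: `x[i-b] - 2 x[i] + x[i+b]`. No step-size
#' normalization is applied (the raw difference convention of NIR
#' processing software).
#'
#' @param wavelengths Input wavelength axis.
#' @param numerals Integer vector `c(a, b, c, d)`.
#' @return A list with `L` (matrix, `length(out) x length(in)`) and
#'   `wavelengths` (output axis).
#' @keywords internal
gap_segment_operator <- function(wavelengths, numerals) {
  stopifnot(length(numerals) == 4L)
  a <- numerals[[1L]]; b <- numerals[[2L]]
  c_ <- numerals[[3L]]; d_ <- numerals[[4L]]
  if (!(a %in% 0:2)) stop("derivative order must be 0, 1 or 2", call. = FALSE)
  if (a > 0 && b < 1) stop("derivative gap must be positive", call. = FALSE)
  if (c_ < 1 || d_ < 1) stop("smoothing segments must be >= 1", call. = FALSE)
  wl <- as.numeric(wavelengths)

  boxcar <- function(n, w) {
    m <- n - w + 1L
    if (m < 1L) stop("smoothing window exceeds the grid length", call. = FALSE)
    M <- matrix(0, m, n)
    for (i in seq_len(m)) M[i, i:(i + w - 1L)] <- 1 / w
    M
  }
  gap_diff <- function(n, order, gap) {
    if (order == 0L) return(diag(n))
    if (order == 1L) {
      m <- n - gap
      if (m < 1L) stop("derivative gap exceeds the grid length", call. = FALSE)
      M <- matrix(0, m, n)
      for (i in seq_len(m)) {
        M[i, i] <- -1
        M[i, i + gap] <- 1
      }
    } else {
      m <- n - 2L * gap
      if (m < 1L) stop("derivative gap exceeds the grid length", call. = FALSE)
      M <- matrix(0, m, n)
      for (i in seq_len(m)) {
        M[i, i] <- 1
        M[i, i + gap] <- -2
        M[i, i + 2L * gap] <- 1
      }
    }
    M
  }
  smooth_wl <- function(w, width) {
    if (width == 1L) return(w)
    n <- length(w)
    vapply(seq_len(n - width + 1L), function(i) mean(w[i:(i + width - 1L)]), 0)
  }
  diff_wl <- function(w, order, gap) {
    if (order == 0L) return(w)
    n <- length(w)
    if (order == 1L) (w[seq_len(n - gap)] + w[seq_len(n - gap) + gap]) / 2
    else w[(gap + 1L):(n - gap)]
  }

  n0 <- length(wl)
  S1 <- boxcar(n0, as.integer(c_)); wl1 <- smooth_wl(wl, as.integer(c_))
  D <- gap_diff(nrow(S1), as.integer(a), as.integer(b))
  wl2 <- diff_wl(wl1, as.integer(a), as.integer(b))
  S2 <- boxcar(nrow(D), as.integer(d_)); wl3 <- smooth_wl(wl2, as.integer(d_))
  list(L = S2 %*% D %*% S1, wavelengths = wl3)
}

#' Gap-segment derivative of a single spectrum
#'
#' @param x Numeric vector.
#' @param numerals Integer vector `c(a, b, c, d)`; see
#'   [parse_treatment_code()].
#' @param wavelengths Optional wavelength axis (defaults to point index).
#' @return Numeric vector on the truncated window, with the output
#'   wavelengths as the `"wavelengths"` attribute.
#' @export
gap_segment_derivative <- function(x, numerals, wavelengths = seq_along(x)) {
  op <- gap_segment_operator(wavelengths, numerals)
  out <- drop(op$L %*% x)
  attr(out, "wavelengths") <- op$wavelengths
  out
}

#' Apply a full pre-treatment to a spectra set
#'
#' The scatter correction runs first on each spectrum over the full grid
#' (SNV, detrend, or SNV then detrend), then the gap-segment
#' derivative/smoothing stage, which truncates to the valid window. All
#' operations are per-spectrum (row-local).
#'
#' @param set A `spectra_set`.
#' @param code A treatment code string (e.g. `"s2"`) or `treatment_code`.
#' @param detrend_degree Polynomial degree for the detrending stage.
#' @return A `spectra_set` on the (possibly truncated) output grid;
#'   sample metadata and references are carried through.
#' @export
apply_treatment <- function(set, code, detrend_degree = 2L) {
  stopifnot(inherits(set, "spectra_set"))
  tc <- parse_treatment_code(code)
  x <- set$x
  wl <- set$grid$wavelengths
  if (tc$scatter %in% c("snv", "snv_dt")) x <- snv(x)
  if (tc$scatter %in% c("dt", "snv_dt")) x <- detrend(x, wl, detrend_degree)
  op <- gap_segment_operator(wl, tc$numerals)
  out <- tcrossprod(x, op$L)
  res <- spectra_set(out, wavelength_grid(op$wavelengths),
                     set$sample_id, set$replicate, set$references)
  res$treatment <- tc
  res
}
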