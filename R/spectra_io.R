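#' Wavelength grid for NIR spectra
#'
#' A uniformly spaced wavelength axis. The conventional acquisition grid for
#' the instruments this package targets runs from 1100 to 2000 nm at 2 nm
#' intervals (451 points), but derivative pre-treatments produce shorter
#' (possibly half-step shifted) grids, so any strictly increasing uniform
#' axis is accepted.
#'
#' @param wavelengths Numeric vector of strictly increasing, uniformly
#'   spaced wavelengths in nm.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `end_nm`, `step_nm`, `n_points` and `wavelengths`.
#' @examples
#' g <- wavelength_grid(seq(1100, 2000, by = 2))
#' g$n_points  # 451
#' @export
wavelength_grid <- function(wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L || anyNA(wavelengths)) {
    stop("wavelengths must be a non-empty numeric vector", call. = FALSE)
  }
  if (length(wavelengths) > 1L) {
    steps <- diff(wavelengths)
    if (any(steps <= 0)) {
      stop("wavelengths must be strictly increasing", call. = FALSE)
    }
    if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
      stop("non-uniform wavelength spacing", call. = FALSE)
    }
    step <- mean(steps)
  } else {
    step <- NA_real_
  }
  structure(
    list(
      start_nm = wavelengths[1L],
      end_nm = wavelengths[length(wavelengths)],
      step_nm = step,
      n_points = length(wavelengths),
      wavelengths = wavelengths
    ),
    class = "wavelength_grid"
  )
}

#' Default acquisition grid: 1100-2000 nm at 2 nm (451 points)
#' @return A `wavelength_grid`.
#' @export
default_grid <- function() wavelength_grid(seq(1100, 2000, by = 2))

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %g-%g nm, step %g nm, %d points\n",
    x$start_nm, x$end_nm, x$step_nm, x$n_points
  ))
  invisible(x)
}

#' Construct a spectra set
#'
#' The central data container: a matrix of log(1/R) absorbance spectra on a
#' common wavelength grid, with per-row sample metadata and (optionally) a
#' table of reference concentrations from wet chemistry. Before replicate
#' averaging a set holds one row per (sample, replicate); afterwards one row
#' per sample.
#'
#' @param x Numeric matrix, one spectrum per row, `ncol(x)` equal to the
#'   number of grid points. All values must be finite.
#' @param wavelengths Numeric wavelength axis (nm) or a `wavelength_grid`.
#' @param sample_id Character vector of sample identifiers, one per row.
#' @param replicate Integer replicate index per row; defaults to 1.
#' @param references Optional data.frame of reference concentrations
#'   (mg kg^-1 for alkaloids, mg g^-1 for mycelium), one row per spectrum.
#'   Values must be non-negative where present; `NA` marks a missing
#'   determination.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(x, wavelengths, sample_id, replicate = NULL,
                        references = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  grid <- if (inherits(wavelengths, "wavelength_grid")) wavelengths else wavelength_grid(wavelengths)
  if (ncol(x) != grid$n_points) {
    stop("spectra have ", ncol(x), " points but the grid has ",
         grid$n_points, call. = FALSE)
  }
  if (nrow(x) == 0L) stop("empty spectra set", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite absorbance values", call. = FALSE)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(x)) {
    stop("sample_id length does not match the number of spectra", call. = FALSE)
  }
  if (is.null(replicate)) replicate <- rep(1L, nrow(x))
  replicate <- as.integer(replicate)
  if (length(replicate) != nrow(x)) {
    stop("replicate length does not match the number of spectra", call. = FALSE)
  }
  key <- paste(sample_id, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (sample_id, replicate) pair", call. = FALSE)
  }
  if (!is.null(references)) {
    references <- as.data.frame(references)
    if (nrow(references) != nrow(x)) {
      stop("references must have one row per spectrum", call. = FALSE)
    }
    for (cn in names(references)) {
      v <- references[[cn]]
      if (!is.numeric(v)) stop("reference column '", cn, "' is not numeric", call. = FALSE)
      if (any(v < 0, na.rm = TRUE)) {
        stop("negative reference value in column '", cn, "'", call. = FALSE)
      }
    }
    rownames(references) <- NULL
  }
  dimnames(x) <- list(NULL, format_wavelength(grid$wavelengths))
  structure(
    list(grid = grid, sample_id = sample_id, replicate = replicate,
         x = x, references = references),
    class = "spectra_set"
  )
}

format_wavelength <- function(w) formatC(w, format = "g", digits = 10)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d spectra (%d samples) on %g-%g nm (%d points)\n",
    nrow(x$x), length(unique(x$sample_id)),
    x$grid$start_nm, x$grid$end_nm, x$grid$n_points
  ))
  if (!is.null(x$references)) {
    cat("  reference constituents:", paste(names(x$references), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count of rows (spectra).
#' @export
n_spectra <- function(set) nrow(set$x)

#' Subset a spectra set by row
#'
#' @param set A `spectra_set`.
#' @param keep Integer or logical row index.
#' @return A `spectra_set` with the selected spectra; references carried.
#' @export
subset_samples <- function(set, keep) {
  stopifnot(inherits(set, "spectra_set"))
  idx <- seq_len(nrow(set$x))[keep]
  if (length(idx) == 0L) stop("subset would leave an empty spectra set", call. = FALSE)
  spectra_set(
    set$x[idx, , drop = FALSE], set$grid,
    set$sample_id[idx], set$replicate[idx],
    if (is.null(set$references)) NULL else set$references[idx, , drop = FALSE]
  )
}

#' Convert reflectance to log(1/R) absorbance
#'
#' NIR reflectance spectra are conventionally stored as the reciprocal
#' logarithm of reflectance, `log10(1/R)`, where R is the intensity of
#' reflected light relative to a ceramic reference.
#'
#' @param r Numeric vector/matrix of reflectance fractions, `0 < r`.
#' @return `log10(1/r)`, same shape as `r`.
#' @examples
#' reflectance_to_absorbance(c(1, 0.1))  # 0 1
#' @export
reflectance_to_absorbance <- function(r) {
  if (!is.numeric(r)) stop("reflectance must be numeric", call. = FALSE)
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("reflectance must be finite and > 0", call. = FALSE)
  }
  if (any(r > 1)) {
    warning("reflectance values > 1 give negative absorbance")
  }
  -log10(r)
}

#' Average replicate spectra
#'
#' Collapses a set to one spectrum per sample: the arithmetic mean over that
#' sample's replicates (acquisition protocols typically record a triplicate
#' without moving the fiberoptic probe). Reference values are carried through
#' from the first replicate of each sample. Idempotent on an
#' already-averaged set.
#'
#' @param set A `spectra_set`.
#' @return A `spectra_set` with one row per unique `sample_id`
#'   (first-occurrence order), `replicate` set to 1.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  ids <- unique(set$sample_id)
  g <- match(set$sample_id, ids)
  counts <- tabulate(g, nbins = length(ids))
  xm <- rowsum(set$x, group = g, reorder = TRUE) / counts
  first <- match(ids, set$sample_id)
  refs <- if (is.null(set$references)) NULL else set$references[first, , drop = FALSE]
  spectra_set(xm, set$grid, ids, rep(1L, length(ids)), refs)
}

#' Write a spectra set to a delimited text file
#'
#' Wide layout, one row per (sample, replicate): `sample_id`, `replicate`,
#' one column per reference constituent, then one column per wavelength with
#' the numeric nm value as header. Values are written with 17 significant
#' digits so that [read_spectra()] round-trips the matrix exactly.
#'
#' @param set A `spectra_set`.
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, sep = ",") {
  stopifnot(inherits(set, "spectra_set"))
  num <- function(v) {
    out <- formatC(v, format = "g", digits = 17)
    out[is.na(v)] <- "NA"
    out
  }
  cols <- list(sample_id = set$sample_id, replicate = as.character(set$replicate))
  if (!is.null(set$references)) {
    for (cn in names(set$references)) cols[[cn]] <- num(set$references[[cn]])
  }
  tab <- do.call(cbind, cols)
  wl <- format_wavelength(set$grid$wavelengths)
  spec <- matrix(num(set$x), nrow = nrow(set$x))
  out <- cbind(tab, spec)
  colnames(out) <- c(colnames(tab), wl)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectra set from a delimited text file
#'
#' Expects the wide layout written by [write_spectra()]: a `sample_id`
#' column, an optional `replicate` column, any number of numeric reference
#' columns, and wavelength columns whose headers parse as numeric nm values
#' on a uniform grid.
#'
#' @param path Path to a comma- or tab-delimited UTF-8 text file.
#' @param sep Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param already_absorbance If `FALSE` the spectral values are reflectance
#'   fractions and are converted with [reflectance_to_absorbance()].
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path, sep = NULL, already_absorbance = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  raw_names <- strsplit(header, sep, fixed = TRUE)[[1L]]
  dup <- raw_names[duplicated(raw_names)]
  if (length(dup)) {
    stop("duplicated column header(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty data section in ", path, call. = FALSE)
  nm <- names(df)
  wl_num <- suppressWarnings(as.numeric(nm))
  is_wl <- !is.na(wl_num)
  if (!any(is_wl)) stop("no wavelength columns found", call. = FALSE)
  if (!("sample_id" %in% nm)) stop("missing 'sample_id' column", call. = FALSE)
  wl <- wl_num[is_wl]
  x <- as.matrix(df[, is_wl, drop = FALSE])
  storage.mode(x) <- "double"
  if (is.unsorted(wl, strictly = TRUE)) {
    ord <- order(wl)
    wl <- wl[ord]
    x <- x[, ord, drop = FALSE]
  }
  if (!already_absorbance) x <- reflectance_to_absorbance(x)
  meta <- df[, !is_wl, drop = FALSE]
  replicate <- if ("replicate" %in% names(meta)) meta$replicate else NULL
  refs <- meta[, setdiff(names(meta), c("sample_id", "replicate")), drop = FALSE]
  if (ncol(refs) == 0L) refs <- NULL
  spectra_set(x, wavelength_grid(wl), meta$sample_id, replicate, refs)
}
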