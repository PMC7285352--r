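#' Configuration for the synthetic NIR spectra generator
#'
#' Describes a population of powdered-plant NIR spectra with known ground
#' truth: Beer-Lambert mixing of Gaussian absorption bands on a smooth
#' baseline, multiplicative/additive/tilt scatter artifacts, instrument
#' noise, triplicate acquisition, and reference values reported with
#' multiplicative analytical noise. Loline composition is drawn as a total
#' concentration (log-uniform over the configured range) split into
#' NFL/NANL/NAL shares by a Dirichlet draw; mycelium concentration is
#' coupled to total lolines through a Gaussian copula at a configurable
#' Kendall rank correlation.
#'
#' @param n_samples Number of distinct samples.
#' @param seed Integer seed; the generator is a pure function of the
#'   configuration, seed included.
#' @param grid A `wavelength_grid` (default 1100-2000 nm at 2 nm).
#' @param total_range Range (mg kg^-1) for total lolines, sampled
#'   log-uniformly.
#' @param shares_mean Mean NFL/NANL/NAL shares of total lolines.
#' @param shares_concentration Dirichlet concentration (larger = less
#'   sample-to-sample variation in composition).
#' @param mycelium_range Range (mg g^-1) for mycelium, sampled
#'   log-uniformly.
#' @param mycelium_tau Target Kendall rank correlation between total
#'   lolines and mycelium.
#' @param bands Named list (NAL, NANL, NFL, mycelium) of data frames with
#'   columns `center` (nm), `width` (nm, Gaussian sigma) and `amplitude`
#'   (absorbance units per concentration unit).
#' @param baseline_coef Polynomial coefficients (intercept, linear,
#'   quadratic) of the baseline in `(lambda - start_nm)`.
#' @param scatter List with `multiplicative_sd` (SD of log amplitude
#'   factor), `additive_sd` (absorbance units) and `tilt_sd` (absorbance
#'   units per nm).
#' @param noise_sd Per-point instrument noise SD (absorbance units), drawn
#'   independently per replicate.
#' @param reference_noise_cv Coefficient of variation of the reported
#'   reference values around the true concentrations.
#' @param replicate_count Replicates per sample (default 3).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 190L,
                             seed = 1L,
                             grid = default_grid(),
                             total_range = c(101, 5629),
                             shares_mean = c(NFL = 0.73, NANL = 0.16, NAL = 0.11),
                             shares_concentration = 100,
                             mycelium_range = c(0.22, 3.97),
                             mycelium_tau = 0.48,
                             bands = default_bands(),
                             baseline_coef = c(0.40, 2.5e-4, 1.2e-7),
                             scatter = list(multiplicative_sd = 0.08,
                                            additive_sd = 0.03,
                                            tilt_sd = 2e-5),
                             noise_sd = 3e-4,
                             reference_noise_cv = 0.03,
                             replicate_count = 3L) {
  stopifnot(n_samples >= 2L, replicate_count >= 1L,
            all(total_range > 0), all(mycelium_range > 0),
            abs(sum(shares_mean) - 1) < 1e-8)
  for (cn in names(bands)) {
    b <- bands[[cn]]
    if (any(b$center < grid$start_nm | b$center > grid$end_nm)) {
      stop("band center outside the grid for '", cn, "'", call. = FALSE)
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), seed = as.integer(seed),
         grid = grid, total_range = total_range, shares_mean = shares_mean,
         shares_concentration = shares_concentration,
         mycelium_range = mycelium_range, mycelium_tau = mycelium_tau,
         bands = bands, baseline_coef = baseline_coef, scatter = scatter,
         noise_sd = noise_sd, reference_noise_cv = reference_noise_cv,
         replicate_count = as.integer(replicate_count)),
    class = "synthetic_config"
  )
}

#' Default absorption bands of the synthetic constituents
#'
#' Idealized Gaussian overtone/combination bands in the 1100-2000 nm window.
#' Alkaloid amplitudes are in absorbance units per mg kg^-1, mycelium per
#' mg g^-1; at the top of the configured concentration ranges each
#' constituent contributes bands of roughly 0.03-0.06 absorbance units,
#' typical of minor analytes on a powdered-forage baseline.
#'
#' @return Named list of band tables (see [synthetic_config()]).
#' @export
default_bands <- function() {
  list(
    NFL = data.frame(center = c(1672, 1726, 1912),
                     width = c(30, 24, 40),
                     amplitude = c(9e-6, 1.2e-5, 6e-6)),
    NANL = data.frame(center = c(1646, 1762),
                      width = c(28, 26),
                      amplitude = c(1.1e-5, 8e-6)),
    NAL = data.frame(center = c(1608, 1784),
                     width = c(26, 30),
                     amplitude = c(1.2e-5, 9e-6)),
    mycelium = data.frame(center = c(1208, 1492),
                          width = c(30, 35),
                          amplitude = c(1.0e-2, 1.3e-2))
  )
}

#' Default reference population configuration
#'
#' The default population the package's own benchmarks use: 190 samples in
#' triplicate on the 1100-2000 nm grid; total lolines log-uniform over
#' 101-5629 mg kg^-1 split on average 73% NFL, 16% NANL, 11% NAL;
#' mycelium over 0.22-3.97 mg g^-1 with Kendall tau 0.48 to total lolines.
#'
#' @param n_samples,seed Overrides for size and randomness.
#' @param ... Further overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
default_population_config <- function(n_samples = 190L, seed = 1L, ...) {
  synthetic_config(n_samples = n_samples, seed = seed, ...)
}

band_profile <- function(wl, band_table) {
  prof <- numeric(length(wl))
  for (i in seq_len(nrow(band_table))) {
    prof <- prof + band_table$amplitude[i] *
      exp(-0.5 * ((wl - band_table$center[i]) / band_table$width[i])^2)
  }
  prof
}

qloguniform <- function(u, range) exp(log(range[1]) + u * (log(range[2]) - log(range[1])))

#' Generate a synthetic NIR dataset with known ground truth
#'
#' Each sample's noiseless spectrum is
#' `alpha_i * (baseline(lambda) + sum_c conc_ic * band_c(lambda))
#'  + beta_i + gamma_i * (lambda - lambda_mid)`,
#' with per-replicate independent instrument noise added on top. Reported
#' reference values carry multiplicative analytical noise around the true
#' concentrations; total lolines is reported as the sum of the three
#' reported alkaloids.
#'
#' @param config A `synthetic_config`.
#' @return A list with `set` (a `spectra_set`, one row per replicate, with
#'   reference columns NAL, NANL, NFL, total_lolines, mycelium) and `truth`
#'   (data frame of true per-sample concentrations and scatter parameters).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  wl <- cfg$grid$wavelengths
  p <- length(wl)
  n <- cfg$n_samples
  reps <- cfg$replicate_count

  withr::with_seed(cfg$seed, {
    # latent Gaussian copula coupling total lolines and mycelium
    rho <- sin(pi * cfg$mycelium_tau / 2)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    total <- qloguniform(stats::pnorm(z1), cfg$total_range)
    mycelium <- qloguniform(stats::pnorm(z2), cfg$mycelium_range)

    alpha_par <- cfg$shares_concentration * cfg$shares_mean
    g <- matrix(stats::rgamma(n * 3L, shape = rep(alpha_par, each = n)), n, 3L)
    shares <- g / rowSums(g)
    colnames(shares) <- names(cfg$shares_mean)
    conc <- cbind(
      NAL = shares[, "NAL"] * total,
      NANL = shares[, "NANL"] * total,
      NFL = shares[, "NFL"] * total,
      mycelium = mycelium
    )

    profiles <- sapply(colnames(conc), function(cn) band_profile(wl, cfg$bands[[cn]]))
    chem <- conc %*% t(profiles)                       # n x p analyte signal
    dl <- wl - cfg$grid$start_nm
    baseline <- cfg$baseline_coef[1] + cfg$baseline_coef[2] * dl +
      cfg$baseline_coef[3] * dl^2
    clean <- sweep(chem, 2L, baseline, "+")

    alpha <- exp(stats::rnorm(n, 0, cfg$scatter$multiplicative_sd))
    beta <- stats::rnorm(n, 0, cfg$scatter$additive_sd)
    gamma <- stats::rnorm(n, 0, cfg$scatter$tilt_sd)
    tilt_axis <- wl - mean(range(wl))
    scattered <- clean * alpha +
      outer(beta, rep(1, p)) + outer(gamma, tilt_axis)

    X <- scattered[rep(seq_len(n), each = reps), , drop = FALSE]
    if (cfg$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(length(X), 0, cfg$noise_sd), nrow(X), p)
    }

    ref_noise <- function(v) {
      if (cfg$reference_noise_cv <= 0) return(v)
      pmax(v * (1 + cfg$reference_noise_cv * stats::rnorm(length(v))), 0.01 * v)
    }
    rep_nal <- ref_noise(conc[, "NAL"])
    rep_nanl <- ref_noise(conc[, "NANL"])
    rep_nfl <- ref_noise(conc[, "NFL"])
    rep_myc <- ref_noise(conc[, "mycelium"])
    refs_sample <- data.frame(
      NAL = rep_nal, NANL = rep_nanl, NFL = rep_nfl,
      total_lolines = rep_nal + rep_nanl + rep_nfl,
      mycelium = rep_myc
    )

    ids <- sprintf("S%03d", seq_len(n))
    set <- spectra_set(
      X, cfg$grid,
      sample_id = rep(ids, each = reps),
      replicate = rep(seq_len(reps), times = n),
      references = refs_sample[rep(seq_len(n), each = reps), , drop = FALSE]
    )
    truth <- data.frame(
      sample_id = ids,
      NAL = conc[, "NAL"], NANL = conc[, "NANL"], NFL = conc[, "NFL"],
      total_lolines = rowSums(conc[, c("NAL", "NANL", "NFL")]),
      mycelium = conc[, "mycelium"],
      alpha = alpha, beta = beta, gamma = gamma
    )
    list(set = set, truth = truth)
  })
}

#' Inject known outliers into a spectra set
#'
#' Spectral outliers have all their replicate spectra multiplied by a
#' random 5-10x amplitude factor and a spurious narrow absorption band
#' added, so they are anomalous both in scale and in shape. Chemical
#' outliers have the target reference value displaced upward by 5-8
#' reference SDs (upward so the corrupted value stays positive).
#'
#' @param set A `spectra_set`.
#' @param n_spectral,n_chemical Counts of each outlier type (distinct
#'   samples are chosen for the two types).
#' @param seed Integer seed.
#' @param constituent Reference column corrupted for chemical outliers.
#' @param band_amplitude Absorbance amplitude of the spurious band.
#' @return A list with the modified `set`, `spectral_ids` and
#'   `chemical_ids`.
#' @export
inject_outliers <- function(set, n_spectral = 0L, n_chemical = 0L, seed = 1L,
                            constituent = "total_lolines",
                            band_amplitude = 0.4) {
  stopifnot(inherits(set, "spectra_set"))
  ids <- unique(set$sample_id)
  if (n_spectral + n_chemical > length(ids)) {
    stop("more outliers requested than samples", call. = FALSE)
  }
  if (n_spectral + n_chemical == 0L) {
    return(list(set = set, spectral_ids = character(), chemical_ids = character()))
  }
  wl <- set$grid$wavelengths
  withr::with_seed(seed, {
    chosen <- sample(ids, n_spectral + n_chemical)
    spectral_ids <- if (n_spectral > 0L) chosen[seq_len(n_spectral)] else character()
    chemical_ids <- if (n_chemical > 0L) chosen[n_spectral + seq_len(n_chemical)] else character()
    x <- set$x
    for (id in spectral_ids) {
      rows <- which(set$sample_id == id)
      fac <- stats::runif(1, 5, 10)
      center <- stats::runif(1, min(wl) + 50, max(wl) - 50)
      spike <- band_amplitude * exp(-0.5 * ((wl - center) / 15)^2)
      x[rows, ] <- x[rows, , drop = FALSE] * fac +
        matrix(spike, length(rows), length(wl), byrow = TRUE)
    }
    refs <- set$references
    for (id in chemical_ids) {
      rows <- which(set$sample_id == id)
      shift <- stats::runif(1, 5, 8) * stats::sd(refs[[constituent]], na.rm = TRUE)
      refs[rows, constituent] <- refs[rows, constituent] + shift
    }
    out <- spectra_set(x, set$grid, set$sample_id, set$replicate, refs)
    list(set = out, spectral_ids = spectral_ids, chemical_ids = chemical_ids)
  })
}
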