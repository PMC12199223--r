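#' Peak specification for the synthetic Raman model
#'
#' @param center Band center, cm^-1.
#' @param amplitude Peak amplitude (arbitrary units, >= 0).
#' @param width Full width at half maximum, cm^-1 (> 0).
#' @param shape `"gaussian"` (default) or `"lorentzian"`.
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, amplitude, width, shape = "gaussian") {
  shape <- match.arg(shape, c("gaussian", "lorentzian"))
  if (width <= 0) stop("peak width must be > 0")
  if (amplitude < 0) stop("peak amplitude must be >= 0")
  structure(list(center = center, amplitude = amplitude, width = width,
                 shape = shape), class = "peak_spec")
}

eval_peak <- function(p, nu) {
  if (p$shape == "gaussian") {
    p$amplitude * exp(-4 * log(2) * (nu - p$center)^2 / p$width^2)
  } else {
    hw <- p$width / 2
    p$amplitude * hw^2 / ((nu - p$center)^2 + hw^2)
  }
}

# Marker bands of the two disease panels, with widths/amplitudes on the
# scale of tissue spectra (background dominates peaks by ~5-10x).
default_peaks_fp <- function() {
  list(
    peak_spec(854, 0.60, 10), peak_spec(879, 0.55, 10),
    peak_spec(1157, 0.45, 9), peak_spec(1298, 0.70, 12),
    peak_spec(1441, 1.00, 14), peak_spec(1449, 0.85, 10),
    peak_spec(1526, 0.40, 9), peak_spec(1588, 0.50, 9),
    peak_spec(1620, 0.45, 9)
  )
}

default_peaks_hwvn <- function() {
  list(peak_spec(2885, 1.20, 25), peak_spec(2940, 1.00, 30))
}

#' Configuration of a synthetic two-group cohort
#'
#' Defines the study design the generator emulates: per-group FOV counts,
#' the Raman acquisition grid, the spectral model (marker-band peaks on a
#' smooth polynomial autofluorescence background plus Gaussian noise),
#' group effect factors, and the PWS stack model (instrument response
#' times a spatially correlated spectral fluctuation, plus camera noise).
#'
#' The default design mirrors a gastroesophageal comparison: 10 control
#' vs 26 disease FOVs, 10 x 10 Raman grids, fingerprint region sampled at
#' 2 cm^-1, PWS stacks of 151 wavelengths (550-700 nm at 1 nm), with
#' amino-acid bands (854/879 cm^-1) elevated and lipid/carotenoid bands
#' (1157/1298/1441/1526 cm^-1) reduced in the disease group.
#'
#' @param n_fov_per_group Named integer pair, FOVs per group,
#'   e.g. `c(control = 10, disease = 26)`.
#' @param grid_shape Raman grid rows x cols (default `c(10, 10)`).
#' @param wavenumber_grid Strictly increasing cm^-1 axis.
#' @param region Region tag of the generated spectra.
#' @param peaks List of [peak_spec()] objects.
#' @param effect_map Named numeric vector: band center -> multiplicative
#'   amplitude factor applied in the disease group. Every name must match
#'   a peak center.
#' @param background_coeffs Polynomial coefficients (constant first) of
#'   the autofluorescence background in the scaled coordinate
#'   `t = (nu - min) / (max - min)`; order <= 5.
#' @param noise_sd Additive Gaussian noise sd on intensities.
#' @param pws_wavelengths Ascending uniform-step nm axis
#'   (default `550:700`, 151 samples).
#' @param image_shape PWS frame height x width in pixels.
#' @param disorder_amplitude Named per-group spectral fluctuation scale
#'   (mean per-pixel sd of the relative reflectance fluctuation).
#' @param pws_noise_sd Additive camera noise sd on recorded PWS
#'   intensities (same scale as reflectance).
#' @param spatial_correlation_length Gaussian correlation length of the
#'   PWS fluctuation fields, pixels.
#' @param spatial_heterogeneity Log-scale sd of the spatial amplitude
#'   field that modulates the fluctuation strength across pixels.
#' @param fov_effect_sd Log-scale sd of per-FOV peak-amplitude
#'   multipliers, emulating FOV-to-FOV biological variability of band
#'   intensities (shared by all spectra of a FOV; default 0.05, i.e.
#'   ~5\% between-FOV variation).
#' @param fov_disorder_sd Log-scale sd of the per-FOV multiplier on the
#'   PWS disorder amplitude (default 0.15).
#' @param outlier_rate Fraction of Raman spectra per FOV deliberately
#'   corrupted (cosmic-ray-like spikes + baseline jump) and flagged in
#'   ground truth; `floor(rate * n)` spectra are corrupted.
#' @param seed Integer cohort seed; all per-FOV and per-pixel seeds are
#'   derived from it deterministically.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_fov_per_group = c(control = 10, disease = 26),
                          grid_shape = c(10, 10),
                          wavenumber_grid = seq(800, 1800, by = 2),
                          region = "FP",
                          peaks = default_peaks_fp(),
                          effect_map = c(`854` = 1.25, `879` = 1.25,
                                         `1157` = 0.8, `1298` = 0.85,
                                         `1441` = 0.75, `1526` = 0.8),
                          background_coeffs = c(8, -6, 3, -1, 0.5, -0.2),
                          noise_sd = 0.01,
                          pws_wavelengths = 550:700,
                          image_shape = c(64, 64),
                          disorder_amplitude = c(control = 0.02,
                                                 disease = 0.04),
                          pws_noise_sd = 0.005,
                          spatial_correlation_length = 3,
                          spatial_heterogeneity = 0.5,
                          fov_effect_sd = 0.05,
                          fov_disorder_sd = 0.15,
                          outlier_rate = 0,
                          seed = 1L) {
  if (length(n_fov_per_group) != 2L || any(n_fov_per_group < 1))
    stop("n_fov_per_group must give >= 1 FOV for each of two groups")
  if (is.null(names(n_fov_per_group)))
    names(n_fov_per_group) <- c("control", "disease")
  if (length(disorder_amplitude) != 2L)
    stop("disorder_amplitude must be given for both groups")
  if (is.null(names(disorder_amplitude)))
    names(disorder_amplitude) <- names(n_fov_per_group)
  if (any(disorder_amplitude < 0)) stop("disorder_amplitude must be >= 0")
  if (any(diff(wavenumber_grid) <= 0))
    stop("wavenumber_grid must be strictly increasing")
  if (length(background_coeffs) > 6L)
    stop("background polynomial order must be <= 5")
  centers <- vapply(peaks, function(p) p$center, numeric(1))
  lim <- region_limits(match.arg(region, c("FP", "HWVN", "full")))
  in_axis <- centers >= min(wavenumber_grid) & centers <= max(wavenumber_grid)
  if (length(effect_map)) {
    ek <- as.numeric(names(effect_map))
    missing_peak <- setdiff(ek, centers)
    if (length(missing_peak))
      stop("effect_map keys with no matching peak: ",
           paste(missing_peak, collapse = ", "))
  }
  steps <- diff(pws_wavelengths)
  if (length(pws_wavelengths) < 2L ||
      any(abs(steps - steps[1]) > 1e-9) || steps[1] <= 0)
    stop("pws_wavelengths must be uniform-step ascending")
  n_expect <- (max(pws_wavelengths) - min(pws_wavelengths)) / steps[1] + 1
  if (abs(length(pws_wavelengths) - n_expect) > 1e-9)
    stop("pws_wavelengths length inconsistent with its range and step")
  if (outlier_rate < 0 || outlier_rate >= 1)
    stop("outlier_rate must be in [0, 1)")
  cfg <- list(n_fov_per_group = n_fov_per_group,
              grid_shape = as.integer(grid_shape),
              wavenumber_grid = as.numeric(wavenumber_grid),
              region = region, peaks = peaks, effect_map = effect_map,
              background_coeffs = as.numeric(background_coeffs),
              noise_sd = noise_sd,
              pws_wavelengths = as.numeric(pws_wavelengths),
              image_shape = as.integer(image_shape),
              disorder_amplitude = disorder_amplitude,
              pws_noise_sd = pws_noise_sd,
              spatial_correlation_length = spatial_correlation_length,
              spatial_heterogeneity = spatial_heterogeneity,
              fov_effect_sd = fov_effect_sd,
              fov_disorder_sd = fov_disorder_sd,
              outlier_rate = outlier_rate, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Deterministic splittable seed derivation: each (parent, index) pair maps
# to a child seed < 2^31 - 1. Doubles stay below 2^53 so arithmetic is
# exact.
child_seed <- function(parent, index) {
  m <- 2147483647
  s <- (as.numeric(parent) %% m) * 48271 + as.numeric(index) * 2654435 + 7919
  as.integer(s %% m) + 1L
}

background_eval <- function(coeffs, nu) {
  t <- (nu - min(nu)) / max(max(nu) - min(nu), .Machine$double.eps)
  drop(outer(t, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

effect_factor <- function(config, group, center) {
  disease <- names(config$n_fov_per_group)[2]
  if (!identical(group, disease) || !length(config$effect_map)) return(1)
  i <- match(as.character(center), names(config$effect_map))
  if (is.na(i)) 1 else unname(config$effect_map[i])
}

#' Generate one synthetic Raman spectrum
#'
#' Intensity model: sum of group-scaled peaks, plus the polynomial
#' autofluorescence background, plus additive Gaussian noise.
#'
#' @param config A [cohort_config()].
#' @param group Group label (must be one of the configured groups).
#' @param seed Integer seed for the noise draw.
#' @param amp_factors Optional per-peak amplitude multipliers (FOV-level
#'   biological variability); defaults to 1 for every peak.
#' @return A [raman_spectrum()] with group and seed recorded in `meta`.
#' @export
generate_spectrum <- function(config, group, seed, amp_factors = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$n_fov_per_group))
    stop("unknown group: ", group)
  if (is.null(amp_factors)) amp_factors <- rep(1, length(config$peaks))
  nu <- config$wavenumber_grid
  y <- background_eval(config$background_coeffs, nu)
  for (i in seq_along(config$peaks)) {
    p <- config$peaks[[i]]
    y <- y + amp_factors[i] *
      effect_factor(config, group, p$center) * eval_peak(p, nu)
  }
  if (config$noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(nu), sd = config$noise_sd)
  }
  raman_spectrum(nu, y, region = config$region,
                 meta = list(group = group, seed = seed))
}

corrupt_spectrum <- function(s, seed) {
  set.seed(seed)
  y <- s$intensity
  scale <- max(abs(y), 1)
  n_spike <- sample(1:3, 1)
  idx <- sample(seq_along(y), n_spike)
  for (i in idx) {
    w <- sample(1:3, 1)
    lo <- max(1, i - w); hi <- min(length(y), i + w)
    y[lo:hi] <- y[lo:hi] + stats::runif(1, 20, 60) * scale
  }
  y <- y + stats::runif(1, 2, 5) * scale
  s$intensity <- y
  s$meta$outlier <- TRUE
  s
}

#' Generate a full Raman FOV grid
#'
#' Produces `rows * cols` spectra (default 10 x 10 = 100 per FOV) with
#' per-pixel seeds derived from the FOV seed. When `outlier_rate > 0`,
#' `floor(rate * n)` spectra -- chosen without replacement from a seeded
#' permutation -- are corrupted with cosmic-ray-like spikes and a
#' baseline jump, and flagged in ground-truth metadata.
#'
#' @inheritParams generate_spectrum
#' @param seed Integer FOV seed.
#' @param fov_id FOV identifier.
#' @return A [fov_grid()]; `attr(, "truth_outliers")` holds the indices
#'   of corrupted spectra.
#' @export
generate_fov_grid <- function(config, group, seed, fov_id = "fov1") {
  n <- prod(config$grid_shape)
  amp_factors <- rep(1, length(config$peaks))
  if (config$fov_effect_sd > 0 && length(config$peaks)) {
    set.seed(child_seed(seed, 7777L))
    amp_factors <- exp(stats::rnorm(length(config$peaks),
                                    sd = config$fov_effect_sd))
  }
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    spectra[[i]] <- generate_spectrum(config, group, child_seed(seed, i),
                                      amp_factors = amp_factors)
    spectra[[i]]$fov_id <- fov_id
    spectra[[i]]$grid_pos <- c((i - 1L) %/% config$grid_shape[2] + 1L,
                               (i - 1L) %% config$grid_shape[2] + 1L)
  }
  truth <- integer(0)
  n_out <- floor(config$outlier_rate * n)
  if (n_out > 0) {
    set.seed(child_seed(seed, 0L))
    truth <- sort(sample(n)[seq_len(n_out)])
    for (j in seq_along(truth)) {
      i <- truth[j]
      spectra[[i]] <- corrupt_spectrum(spectra[[i]],
                                       child_seed(seed, n + j))
    }
  }
  g <- fov_grid(spectra, fov_id = fov_id, group = group,
                grid_shape = config$grid_shape)
  attr(g, "truth_outliers") <- truth
  g
}

# Smooth instrument-response spectrum on the reflectance scale (0, 1);
# broad maximum near 620 nm as for a white-LED + tunable-filter chain.
default_irf_spectrum <- function(wl) {
  0.4 * exp(-((wl - 620) / 180)^2) + 0.15
}

# Gaussian spatial smoothing by separable kernel matrices, normalized so
# smoothed white noise has exactly unit pointwise variance.
smooth_field <- function(z, ell) {
  if (ell <= 0) return(z)
  h <- nrow(z); w <- ncol(z)
  kr <- outer(seq_len(h), seq_len(h),
              function(i, j) exp(-(i - j)^2 / (2 * ell^2)))
  kc <- outer(seq_len(w), seq_len(w),
              function(i, j) exp(-(i - j)^2 / (2 * ell^2)))
  s <- kr %*% z %*% kc
  norm <- sqrt(outer(rowSums(kr^2), rowSums(kc^2)))
  s / norm
}

#' Generate a synthetic PWS wavelength stack with matched IRF
#'
#' Per-pixel model: `I(lambda) = IRF(lambda) * (1 + f(lambda, x, y)) +
#' camera noise`, where `f` is a zero-mean spectral fluctuation whose
#' per-pixel standard deviation equals `A(x, y)`, a spatially correlated
#' log-normal amplitude field with mean `disorder_amplitude[group]`. The
#' fluctuation fields are Gaussian-smoothed white noise, so neighbouring
#' pixels fluctuate coherently over the configured correlation length.
#'
#' @inheritParams generate_spectrum
#' @param seed Integer stack seed.
#' @param fov_id FOV identifier.
#' @return A [pws_stack()] whose `irf` is the matched empty-slide stack.
#' @export
generate_pws_stack <- function(config, group, seed, fov_id = "fov1") {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$n_fov_per_group))
    stop("unknown group: ", group)
  wl <- config$pws_wavelengths
  h <- config$image_shape[1]; w <- config$image_shape[2]
  n_w <- length(wl)
  irf_spec <- default_irf_spectrum(wl)
  if (any(irf_spec <= 0)) stop("IRF model must be strictly positive")
  amp <- unname(config$disorder_amplitude[group])
  if (config$fov_disorder_sd > 0 && amp > 0) {
    set.seed(child_seed(seed, 4L))
    amp <- amp * exp(stats::rnorm(1, sd = config$fov_disorder_sd) -
                       config$fov_disorder_sd^2 / 2)
  }

  set.seed(child_seed(seed, 1L))
  het <- config$spatial_heterogeneity
  z_amp <- smooth_field(matrix(stats::rnorm(h * w), h, w),
                        config$spatial_correlation_length)
  a_field <- amp * exp(het * z_amp - het^2 / 2)

  # unit-variance smooth noise per wavelength, then exact per-pixel
  # standardization over lambda so sd(f) = A(x, y) holds exactly
  set.seed(child_seed(seed, 2L))
  u <- array(stats::rnorm(n_w * h * w), c(h, w, n_w))
  for (k in seq_len(n_w)) {
    u[, , k] <- smooth_field(u[, , k], config$spatial_correlation_length)
  }
  um <- matrix(aperm(u, c(3, 1, 2)), n_w, h * w)
  um <- sweep(um, 2, colMeans(um))
  sdv <- sqrt(colMeans(um^2))
  sdv[sdv == 0] <- 1
  um <- sweep(um, 2, sdv, `/`)

  f <- um * rep(as.vector(a_field), each = n_w)
  cube <- array(irf_spec * (1 + f), c(n_w, h, w))
  cube <- aperm(cube, c(2, 3, 1))
  if (config$pws_noise_sd > 0) {
    set.seed(child_seed(seed, 3L))
    cube <- cube + array(stats::rnorm(h * w * n_w,
                                      sd = config$pws_noise_sd),
                         c(h, w, n_w))
  }
  cube[cube < 1e-6] <- 1e-6
  cube[cube > 1] <- 1
  irf_cube <- array(rep(irf_spec, each = h * w), c(h, w, n_w))
  st <- pws_stack(wl, cube, irf_cube, fov_id = fov_id,
                  meta = list(group = group, seed = seed,
                              amplitude_field = a_field))
  st
}

#' Generate a labeled two-group cohort
#'
#' One Raman FOV grid plus one PWS stack per FOV, with group-B effect
#' factors applied to Raman peaks and group-specific disorder amplitude
#' applied to the PWS fluctuations. Ground truth (labels, effect map,
#' per-FOV outlier indices) is stored for recovery tests.
#'
#' @param config A [cohort_config()].
#' @param pws Logical; set `FALSE` to skip PWS stack generation when only
#'   the Raman arm is needed.
#' @return An object of class `rpws_cohort`: a list with `fovs` (each a
#'   list of `fov_id`, `group`, `raman`, `pws`), the `config`, and
#'   ground-`truth` metadata.
#' @export
generate_cohort <- function(config, pws = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$n_fov_per_group)
  fovs <- list()
  truth_out <- list()
  idx <- 0L
  for (gi in seq_along(groups)) {
    for (j in seq_len(config$n_fov_per_group[gi])) {
      idx <- idx + 1L
      fid <- sprintf("%s_%02d", groups[gi], j)
      fseed <- child_seed(config$seed, idx)
      g <- generate_fov_grid(config, groups[gi], fseed, fov_id = fid)
      p <- if (pws) generate_pws_stack(config, groups[gi],
                                       child_seed(fseed, 999L),
                                       fov_id = fid) else NULL
      truth_out[[fid]] <- attr(g, "truth_outliers")
      fovs[[idx]] <- list(fov_id = fid, group = groups[gi],
                          raman = g, pws = p)
    }
  }
  structure(list(fovs = fovs, config = config,
                 truth = list(effect_map = config$effect_map,
                              outliers = truth_out,
                              groups = groups)),
            class = "rpws_cohort")
}

#' @export
print.rpws_cohort <- function(x, ...) {
  tab <- table(vapply(x$fovs, `[[`, "", "group"))
  cat("<rpws_cohort>", paste(sprintf("%s: %d FOVs", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}
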