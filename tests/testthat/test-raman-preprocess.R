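test_that("Savitzky-Golay reproduces polynomials of its order and denoises", {
  nu <- seq(800, 1000, by = 2)
  const <- raman_spectrum(nu, rep(3.7, length(nu)))
  expect_equal(savgol_smooth(const, 7, 1)$intensity, const$intensity,
               tolerance = 1e-12)

  lin <- raman_spectrum(nu, 0.01 * nu - 5)
  expect_equal(savgol_smooth(lin, 9, 1)$intensity, lin$intensity,
               tolerance = 1e-9)

  set.seed(4)
  clean <- sin(nu / 30)
  noisy <- raman_spectrum(nu, clean + rnorm(length(nu), sd = 0.1))
  sm <- savgol_smooth(noisy, 7, 1)
  expect_lt(sqrt(mean((sm$intensity - clean)^2)),
            sqrt(mean((noisy$intensity - clean)^2)))

  expect_error(savgol_smooth(const, 6, 1), "odd")
  expect_error(savgol_smooth(const, 203, 1), "exceeds")
})

test_that("iModPoly recovers polynomial backgrounds under peaks", {
  # exactly a polynomial of fit order: corrected ~ 0
  fx <- fixture_spectrum(noise_sd = 0, peaks = list())
  r <- imodpoly_baseline(fx$spectrum, 5)
  rng <- diff(range(fx$spectrum$intensity))
  expect_lt(max(abs(r$corrected$intensity)), 1e-6 * rng)

  # all-zero input: zero baseline, zero corrected, one iteration
  z <- raman_spectrum(seq(800, 900, 2), rep(0, 51))
  rz <- imodpoly_baseline(z, 3)
  expect_true(all(rz$baseline$intensity == 0))
  expect_true(all(rz$corrected$intensity == 0))
  expect_identical(rz$iterations, 1L)
  expect_true(rz$converged)

  # known background + three narrow peaks, light noise: RMS baseline
  # error under 1% of the maximum peak amplitude
  fx <- fixture_spectrum(seed = 9, noise_sd = 0.01)
  r <- imodpoly_baseline(fx$spectrum, 5)
  rms <- sqrt(mean((r$baseline$intensity - fx$background)^2))
  expect_lt(rms, 0.01 * 1.2)
  expect_true(r$converged)

  # non-convergence is flagged, not thrown
  r1 <- imodpoly_baseline(fx$spectrum, 5, max_iter = 2, tol = 1e-12)
  expect_false(r1$converged)
})

test_that("region cropping keeps exactly the in-region samples", {
  nu <- seq(400, 3400, by = 10)
  s <- raman_spectrum(nu, rnorm(length(nu)))
  fp <- crop_region(s, "FP")
  expect_true(all(fp$wavenumber >= 800 & fp$wavenumber <= 1800))
  expect_identical(fp$region, "FP")
  hw <- crop_region(s, "HWVN")
  expect_true(all(hw$wavenumber >= 2800 & hw$wavenumber <= 3050))

  inside <- raman_spectrum(seq(900, 1700, 10), rnorm(81))
  expect_equal(crop_region(inside, "FP")$intensity, inside$intensity)

  low <- raman_spectrum(seq(100, 700, 10), rnorm(61))
  expect_error(crop_region(low, "FP"), "overlap")
})

test_that("vector normalization lands on the unit sphere", {
  s <- raman_spectrum(c(1000, 1100), c(3, 4))
  expect_equal(vector_normalize(s)$intensity, c(0.6, 0.8))
  expect_equal(vector_normalize(vector_normalize(s))$intensity,
               c(0.6, 0.8), tolerance = 1e-15)
  set.seed(2)
  r <- raman_spectrum(seq(800, 1800, 2), rnorm(501))
  expect_equal(sqrt(sum(vector_normalize(r)$intensity^2)), 1,
               tolerance = 1e-12)
  z <- raman_spectrum(c(1000, 1100), c(0, 0))
  expect_error(vector_normalize(z), "all-zero")
})

test_that("DBSCAN screening flags displaced spectra and nothing else", {
  nu <- seq(800, 1000, 4)
  set.seed(8)
  base <- sin(nu / 40)
  specs <- lapply(1:20, function(i)
    raman_spectrum(nu, base + rnorm(length(nu), sd = 0.01)))
  specs[[21]] <- raman_spectrum(nu, base + 5)   # far beyond any eps
  r <- dbscan_filter(specs, min_pts = 5)
  expect_length(r$outliers, 1L)
  expect_identical(which(r$labels == 0L), 21L)
  # brute-force neighborhood count at the chosen eps confirms point 21
  # is no core point and in nobody's neighborhood
  x <- t(vapply(specs, `[[`, numeric(length(nu)), "intensity"))
  d <- as.matrix(dist(x))
  expect_lt(sum(d[21, ] <= r$eps), 5)
  expect_true(all(d[21, -21] > r$eps))

  # eps beyond the data diameter: one dense cluster, zero outliers
  r2 <- dbscan_filter(specs, eps = max(d) + 1, min_pts = 5)
  expect_length(r2$outliers, 0L)

  # rerunning on the kept set removes nothing new
  r3 <- dbscan_filter(r$kept, eps = r$eps, min_pts = 5)
  expect_length(r3$outliers, 0L)

  expect_error(dbscan_filter(list()), "empty")
})

test_that("generator ground-truth outliers are recovered by the screen", {
  cfg <- cohort_config(grid_shape = c(5, 5),
                       wavenumber_grid = seq(800, 1800, 4),
                       outlier_rate = 0.04, seed = 3)
  g <- generate_fov_grid(cfg, "control", 17)
  truth <- attr(g, "truth_outliers")
  expect_length(truth, 1L)
  pp <- preprocess_fov(g)
  expect_identical(which(pp$processed$qc_flags == "outlier"),
                   as.integer(truth))
  # the FOV mean is computed on kept spectra only
  kept_idx <- setdiff(seq_along(g$spectra), truth)
  manual <- rowMeans(vapply(
    pp$processed$spectra[kept_idx], `[[`,
    numeric(length(pp$fov_mean$wavenumber)), "intensity"))
  manual <- manual / sqrt(sum(manual^2))
  expect_equal(pp$fov_mean$intensity, manual, tolerance = 1e-12)
})

test_that("preprocessing pipeline output is unit-norm; identical inputs give the mean back", {
  cfg <- small_config(noise_sd = 0)
  g <- generate_fov_grid(cfg, "control", 1)
  pp <- preprocess_fov(g)
  norms <- vapply(pp$processed$spectra, function(s)
    sqrt(sum(s$intensity^2)), numeric(1))
  expect_true(all(abs(norms - 1) < 1e-12))
  # zero noise -> identical spectra -> fov mean equals any one of them
  expect_equal(pp$fov_mean$intensity,
               pp$processed$spectra[[1]]$intensity, tolerance = 1e-12)
})

test_that("HWVN region uses the third-order baseline", {
  cfg <- small_config(
    region = "HWVN", wavenumber_grid = seq(2800, 3050, 2),
    peaks = default_peaks_hwvn(), effect_map = numeric(0),
    background_coeffs = c(4, -2, 1, 0.5))
  g <- generate_fov_grid(cfg, "control", 5)
  pp <- preprocess_fov(g, region = "HWVN")
  expect_identical(pp$fov_mean$region, "HWVN")
  expect_equal(sqrt(sum(pp$fov_mean$intensity^2)), 1, tolerance = 1e-12)
})
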