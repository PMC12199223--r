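# Shared fixtures, built in code at test time.

# Small, fast cohort configuration: coarse fingerprint axis, 2x2 Raman
# grids, 16x16 PWS frames. Everything else at package defaults.
small_config <- function(..., seed = 11L) {
  args <- list(n_fov_per_group = c(control = 4, disease = 4),
               grid_shape = c(2, 2),
               wavenumber_grid = seq(800, 1800, by = 4),
               image_shape = c(24, 24),
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# One clean synthetic spectrum with known components, for baseline and
# band oracles.
fixture_spectrum <- function(seed = 1, noise_sd = 0,
                             coeffs = c(5, -3, 2, 0.5, -1, 0.3),
                             peaks = list(peak_spec(1000, 1, 12),
                                          peak_spec(1300, 0.8, 15),
                                          peak_spec(1600, 1.2, 10))) {
  nu <- seq(800, 1800, by = 2)
  bg <- ramanpws:::background_eval(coeffs, nu)
  y <- bg
  for (p in peaks) y <- y + ramanpws:::eval_peak(p, nu)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(nu), sd = noise_sd)
  }
  list(spectrum = raman_spectrum(nu, y, region = "FP"),
       background = bg, peaks = peaks)
}

# Exhaustive pair-enumeration GLCM oracle (independent of the package
# implementation): loops over every pixel explicitly.
glcm_oracle <- function(img, offset, levels, symmetric = TRUE,
                        normalized = TRUE) {
  p <- matrix(0, levels, levels)
  h <- nrow(img); w <- ncol(img)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        p[img[r, c], img[r2, c2]] <- p[img[r, c], img[r2, c2]] + 1
      }
    }
  }
  if (symmetric) p <- p + t(p)
  if (normalized) p <- p / sum(p)
  p
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# label assignments (oracle for small samples, no ties).
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  n <- length(pooled)
  u_obs <- sum(rank(pooled)[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- combn(n, n_a)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n_a * (n_a + 1) / 2
  })
  mu <- n_a * (n - n_a) / 2
  # two-sided: as extreme or more extreme in distance from the mean
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# One modality block with a single latent discriminant direction of a
# given strength plus isotropic noise: the building block for cohorts
# carrying independent discriminative signal in two modalities.
modality_block <- function(y, p, shift, noise, tag, seed) {
  set.seed(seed)
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  x <- outer(y - 0.5, w) * 2 * shift +
    matrix(rnorm(length(y) * p, sd = noise), length(y), p)
  colnames(x) <- sprintf("%s%02d", tag, seq_len(p))
  feature_matrix(x, y, fov_ids = sprintf("f%02d", seq_along(y)),
                 modality = tag)
}

# Rank-one discriminant data: class signal along one latent direction
# plus isotropic noise.
rank1_features <- function(n_per_class = 20, p = 20, noise = 0.1,
                           seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n_per_class)
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  x <- outer(y - 0.5, w) * 2 + matrix(rnorm(2 * n_per_class * p,
                                            sd = noise),
                                      2 * n_per_class, p)
  colnames(x) <- sprintf("v%03d", seq_len(p))
  feature_matrix(x, y, fov_ids = sprintf("o%02d", seq_len(2 * n_per_class)))
}
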