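#' Marker-band panels
#'
#' Default marker-band centers (cm^-1) for the two tissue comparisons:
#' the gastroesophageal panel (854, 879 amino acids; 1157, 1526
#' carotenoids; 1298, 1441 lipids; 2885 CH stretch) and the intestinal
#' panel (854, 879, 1588, 1620 amino acids; 1449 lipids/proteins).
#'
#' @param panel `"gastroesophageal"` or `"intestinal"`.
#' @return Numeric vector of band centers.
#' @export
band_panel <- function(panel = c("gastroesophageal", "intestinal")) {
  panel <- match.arg(panel)
  switch(panel,
         gastroesophageal = c(854, 879, 1157, 1298, 1441, 1526, 2885),
         intestinal = c(854, 879, 1449, 1588, 1620))
}

#' Band intensity of a spectrum
#'
#' Mean intensity over the window `[center - half_width, center +
#' half_width]`; with `half_width = 0` the nearest channel is returned.
#'
#' @param s A [raman_spectrum()].
#' @param center Band center, cm^-1.
#' @param half_width Window half width, cm^-1 (default 4).
#' @return Scalar band intensity.
#' @export
band_intensity <- function(s, center, half_width = 4) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (half_width < 0) stop("half_width must be >= 0")
  if (half_width == 0) {
    i <- which.min(abs(s$wavenumber - center))
    if (abs(s$wavenumber[i] - center) > diff(range(s$wavenumber)))
      stop("center outside axis")
    return(s$intensity[i])
  }
  keep <- s$wavenumber >= center - half_width &
    s$wavenumber <= center + half_width
  if (!any(keep))
    stop(sprintf("window around %g cm-1 does not overlap the axis",
                 center))
  mean(s$intensity[keep])
}

#' Unpaired Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. The p-value is
#' exact (permutation distribution) when the combined sample size is at
#' most 20 and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param a,b Numeric samples (group A, group B).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max Combined-n threshold for the exact p-value
#'   (default 20).
#' @return A `band_test` list: `u_statistic` (U for sample A), `u_b`,
#'   `p_value`, `direction` (sign of `median(b) - median(a)`),
#'   `group_medians`, `exact` flag and sample sizes.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less",
                                                 "greater"),
                           exact_max = 20L) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty sample")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  ties <- any(duplicated(c(a, b)))
  use_exact <- (n_a + n_b) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  med_a <- stats::median(a); med_b <- stats::median(b)
  structure(list(u_statistic = u_a, u_b = u_b,
                 p_value = min(wt$p.value, 1),
                 direction = sign(med_b - med_a),
                 group_medians = c(A = med_a, B = med_b),
                 exact = use_exact, n = c(n_a = n_a, n_b = n_b),
                 alternative = alternative),
            class = "band_test")
}

#' @export
print.band_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: U_A = %g, p = %.4g (%s), direction %+d\n",
              x$u_statistic, x$p_value,
              if (x$exact) "exact" else "normal approx.", x$direction))
  invisible(x)
}

#' Band-wise Mann-Whitney panel across groups
#'
#' Extracts band intensities from per-FOV processed spectra and tests
#' each band for a group difference. Bands outside the spectral axis are
#' skipped with a warning. No multiple-testing correction is applied by
#' default, matching per-band reporting; Benjamini-Hochberg adjusted
#' p-values can be added.
#'
#' @param spectra List of processed (typically per-FOV mean)
#'   [raman_spectrum()] objects.
#' @param groups Group label per spectrum (exactly two levels, >= 2
#'   FOVs each).
#' @param bands Numeric band centers (cm^-1), e.g. [band_panel()].
#' @param half_width Band window half width, cm^-1.
#' @param adjust Add a `p_adj` column with Benjamini-Hochberg adjusted
#'   p-values (default `FALSE`).
#' @return Data frame with one row per tested band: `band`, `u`, `p`,
#'   `direction`, group medians and sample sizes.
#' @export
band_test_panel <- function(spectra, groups,
                            bands = band_panel("gastroesophageal"),
                            half_width = 4, adjust = FALSE) {
  if (length(spectra) != length(groups))
    stop("spectra and groups must have equal length")
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups are required")
  if (min(table(groups)) < 2L)
    stop("need at least 2 FOVs per group")
  ax <- range(spectra[[1]]$wavenumber)
  rows <- list()
  for (bctr in bands) {
    if (bctr + half_width < ax[1] || bctr - half_width > ax[2]) {
      warning(sprintf("band %g cm-1 outside the spectral axis; skipped",
                      bctr))
      next
    }
    v <- vapply(spectra, band_intensity, numeric(1), center = bctr,
                half_width = half_width)
    bt <- mann_whitney_u(v[groups == lv[1]], v[groups == lv[2]])
    rows[[length(rows) + 1L]] <-
      data.frame(band = bctr, u = bt$u_statistic, p = bt$p_value,
                 direction = bt$direction,
                 median_a = bt$group_medians[["A"]],
                 median_b = bt$group_medians[["B"]],
                 n_a = bt$n[["n_a"]], n_b = bt$n[["n_b"]])
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no band overlapped the spectral axis")
  rownames(out) <- NULL
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "groups") <- lv
  out
}

#' PCA scores for QC plots
#'
#' Centered principal-component scores of a feature matrix, for the
#' standard two-component score plot used to confirm group structure.
#'
#' @param x Numeric matrix, rows = observations.
#' @param n_components Number of components to return (default 2).
#' @return A list with `scores` (n x n_components), `explained`
#'   (fraction of variance per component) and the `prcomp` fit.
#' @export
pca_scores <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 observations")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- length(fit$sdev)
  rk <- sum(fit$sdev > fit$sdev[1] * 1e-12)
  if (n_components > rk)
    stop("n_components exceeds the rank of the centered matrix")
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)], fit = fit)
}
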