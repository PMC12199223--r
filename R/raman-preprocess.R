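#' Savitzky-Golay smoothing of a spectrum
#'
#' First-order Savitzky-Golay by default, as used for tissue Raman
#' denoising. Endpoints are handled by evaluating the boundary
#' least-squares polynomial fits rather than padding.
#'
#' @param s A [raman_spectrum()].
#' @param window Odd window length in samples (> `polyorder`,
#'   <= axis length).
#' @param polyorder Polynomial order of the local fits (default 1).
#' @return The smoothed spectrum on the same axis.
#' @export
savgol_smooth <- function(s, window = 7L, polyorder = 1L) {
  stopifnot(inherits(s, "raman_spectrum"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > length(s$intensity)) stop("window exceeds axis length")
  s$intensity <- signal::sgolayfilt(s$intensity, p = polyorder, n = window)
  s
}

# One polynomial least-squares fit on a fixed design matrix; the design
# is precomputed by the caller so the iModPoly loop stays cheap.
poly_design <- function(x, order) {
  t <- (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)
  outer(t, 0:order, `^`)
}

polyfit_eval <- function(design, y) {
  drop(design %*% qr.coef(qr(design), y))
}

#' iModPoly fluorescence baseline estimation
#'
#' Iterative modified multi-polynomial fitting: fit a polynomial, compute
#' the residual deviation `DEV = sd(y - fit)`; at each iteration clip
#' intensities above `fit + DEV` down to `fit + DEV` so Raman peaks are
#' progressively excluded from the next fit. The first iteration already
#' applies the clip, accounting for the noise contribution to `DEV` in
#' the presence of peaks. Iteration stops when the relative change of
#' `DEV` drops below `tol` or `max_iter` is reached.
#'
#' @param s A [raman_spectrum()].
#' @param poly_order Polynomial order (5 for FP, 3 for HWVN backgrounds).
#' @param max_iter Maximum iterations (default 100).
#' @param tol Relative `DEV` change stopping threshold (default 0.05).
#' @return A list with `baseline` and `corrected` spectra, the number of
#'   `iterations` used, and a `converged` flag (non-convergence is
#'   flagged, not an error).
#' @export
imodpoly_baseline <- function(s, poly_order = 5L, max_iter = 100L,
                              tol = 0.05) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (poly_order < 1L) stop("poly_order must be >= 1")
  n <- length(s$intensity)
  if (n <= poly_order + 1L) stop("axis too short for poly_order")
  design <- poly_design(s$wavenumber, poly_order)
  y <- s$intensity
  if (max(y) - min(y) < .Machine$double.eps * max(1, max(abs(y)))) {
    baseline <- s; corrected <- s
    corrected$intensity <- rep(0, n)
    return(list(baseline = baseline, corrected = corrected,
                iterations = 1L, converged = TRUE))
  }
  dev_prev <- NA_real_
  converged <- FALSE
  iter <- 0L
  fit <- polyfit_eval(design, y)
  repeat {
    iter <- iter + 1L
    dev <- stats::sd(y - fit)
    cap <- fit + dev
    y <- pmin(y, cap)
    if (!is.na(dev_prev) && dev > 0 &&
        abs(dev - dev_prev) / dev < tol) {
      converged <- TRUE
      break
    }
    if (dev == 0) { converged <- TRUE; break }
    if (iter >= max_iter) break
    dev_prev <- dev
    fit <- polyfit_eval(design, y)
  }
  baseline <- s; corrected <- s
  baseline$intensity <- fit
  corrected$intensity <- s$intensity - fit
  list(baseline = baseline, corrected = corrected, iterations = iter,
       converged = converged)
}

#' Crop a spectrum to a standard analysis region
#'
#' Fingerprint (FP) keeps 800-1800 cm^-1; high wavenumber (HWVN) keeps
#' 2800-3050 cm^-1.
#'
#' @param s A [raman_spectrum()].
#' @param region `"FP"` or `"HWVN"`.
#' @return The cropped spectrum with its region tag updated.
#' @export
crop_region <- function(s, region) {
  stopifnot(inherits(s, "raman_spectrum"))
  region <- match.arg(region, c("FP", "HWVN"))
  lim <- region_limits(region)
  keep <- s$wavenumber >= lim[1] & s$wavenumber <= lim[2]
  if (!any(keep))
    stop(sprintf("axis [%g, %g] does not overlap region %s",
                 min(s$wavenumber), max(s$wavenumber), region))
  raman_spectrum(s$wavenumber[keep], s$intensity[keep], region = region,
                 fov_id = s$fov_id, grid_pos = s$grid_pos, meta = s$meta)
}

#' Vector (Euclidean) normalization
#'
#' Divides intensities by the spectrum norm, the square root of the sum
#' of squared intensities, so all spectra lie on the unit sphere.
#'
#' @param s A [raman_spectrum()].
#' @return The unit-norm spectrum.
#' @export
vector_normalize <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  nrm <- sqrt(sum(s$intensity^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  s$intensity <- s$intensity / nrm
  s
}

#' DBSCAN outlier screening of a spectral set
#'
#' Density-based clustering on the spectra (rows = spectra, Euclidean
#' distance on intensities by default); points labeled as noise are
#' returned as outliers. With the default `eps = NULL`, a scale-adaptive
#' radius is used: the 95th percentile of each spectrum's distance to its
#' `min_pts`-th nearest neighbour.
#'
#' @param spectra List of [raman_spectrum()] on a common axis.
#' @param eps Neighbourhood radius, or `NULL` for the adaptive default.
#' @param min_pts Core-point neighbourhood size (default 5, the point
#'   itself included).
#' @return A list with `kept` and `outliers` (disjoint, covering the
#'   input), `labels` (cluster id per spectrum, 0 = noise) and the `eps`
#'   used.
#' @export
dbscan_filter <- function(spectra, eps = NULL, min_pts = 5L) {
  n <- length(spectra)
  if (n == 0L) stop("empty input")
  if (n < min_pts)
    stop("need at least min_pts spectra")
  x <- t(vapply(spectra, function(s) s$intensity,
                numeric(length(spectra[[1]]$intensity))))
  d <- as.matrix(stats::dist(x))
  if (is.null(eps)) {
    kdist <- apply(d, 1, function(r) sort(r)[min_pts])
    eps <- as.numeric(stats::quantile(kdist, 0.95, names = FALSE))
  }
  labels <- dbscan_labels(d, eps, min_pts)
  keep <- labels > 0L
  list(kept = spectra[keep], outliers = spectra[!keep],
       labels = labels, eps = eps)
}

# Classic DBSCAN on a precomputed distance matrix. min_pts counts the
# point itself. Label 0 = noise.
dbscan_labels <- function(d, eps, min_pts) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!is.na(labels[j]) && labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) queue <- c(queue, nb[[j]][is.na(labels[nb[[j]]]) |
                                               labels[nb[[j]]] == 0L])
    }
  }
  labels[is.na(labels)] <- 0L
  labels
}

#' Default preprocessing parameters
#'
#' @param sg_window Savitzky-Golay window (odd, samples).
#' @param sg_polyorder Savitzky-Golay order.
#' @param baseline_order_fp,baseline_order_hwvn iModPoly orders for the
#'   FP and HWVN regions.
#' @param baseline_tol,baseline_max_iter iModPoly stopping rule.
#' @param dbscan_min_pts,dbscan_eps DBSCAN screening parameters
#'   (`dbscan_eps = NULL` for the adaptive radius).
#' @return A named list of parameters for [preprocess_fov()].
#' @export
preprocess_params <- function(sg_window = 7L, sg_polyorder = 1L,
                              baseline_order_fp = 5L,
                              baseline_order_hwvn = 3L,
                              baseline_tol = 0.05,
                              baseline_max_iter = 100L,
                              dbscan_min_pts = 5L, dbscan_eps = NULL) {
  list(sg_window = sg_window, sg_polyorder = sg_polyorder,
       baseline_order_fp = baseline_order_fp,
       baseline_order_hwvn = baseline_order_hwvn,
       baseline_tol = baseline_tol,
       baseline_max_iter = baseline_max_iter,
       dbscan_min_pts = dbscan_min_pts, dbscan_eps = dbscan_eps)
}

#' Preprocess all spectra of a FOV and aggregate to one observation
#'
#' Applies, in order: Savitzky-Golay smoothing, iModPoly baseline
#' correction (order 5 for FP, order 3 for HWVN), region cropping,
#' vector normalization, then DBSCAN outlier screening across the grid.
#' The FOV aggregate is the arithmetic mean of kept spectra,
#' re-normalized to unit norm.
#'
#' @param g A [fov_grid()].
#' @param region `"FP"` or `"HWVN"`.
#' @param params A [preprocess_params()] list.
#' @return A list with the `processed` grid (qc_flags mark outliers) and
#'   `fov_mean`, the unit-norm mean spectrum of kept spectra.
#' @export
preprocess_fov <- function(g, region = "FP", params = preprocess_params()) {
  stopifnot(inherits(g, "fov_grid"))
  region <- match.arg(region, c("FP", "HWVN"))
  order <- if (region == "FP") params$baseline_order_fp else
    params$baseline_order_hwvn
  proc <- lapply(g$spectra, function(s) {
    s <- savgol_smooth(s, params$sg_window, params$sg_polyorder)
    s <- imodpoly_baseline(s, poly_order = order,
                           max_iter = params$baseline_max_iter,
                           tol = params$baseline_tol)$corrected
    s <- crop_region(s, region)
    vector_normalize(s)
  })
  n <- length(proc)
  if (n >= params$dbscan_min_pts && n > 1L) {
    scr <- dbscan_filter(proc, eps = params$dbscan_eps,
                         min_pts = params$dbscan_min_pts)
    flags <- ifelse(scr$labels > 0L, "keep", "outlier")
  } else {
    flags <- rep("keep", n)
  }
  if (!any(flags == "keep"))
    stop("all spectra in FOV ", g$fov_id, " rejected as outliers")
  kept <- proc[flags == "keep"]
  m <- rowMeans(vapply(kept, function(s) s$intensity,
                       numeric(length(kept[[1]]$intensity))))
  fov_mean <- raman_spectrum(kept[[1]]$wavenumber, m, region = region,
                             fov_id = g$fov_id,
                             meta = list(group = g$group,
                                         n_kept = length(kept)))
  fov_mean <- vector_normalize(fov_mean)
  out <- fov_grid(proc, fov_id = g$fov_id, group = g$group,
                  grid_shape = g$grid_shape, qc_flags = flags)
  list(processed = out, fov_mean = fov_mean)
}
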