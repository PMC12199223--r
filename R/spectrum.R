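#' Construct a Raman spectrum
#'
#' A `raman_spectrum` holds one spectrum: a strictly increasing wavenumber
#' axis (cm^-1), matching intensities (arbitrary units), a spectral-region
#' tag and acquisition metadata (FOV id and grid position).
#'
#' @param wavenumber Numeric vector, strictly increasing, cm^-1.
#' @param intensity Numeric vector, same length, finite.
#' @param region One of `"FP"` (fingerprint, 800-1800 cm^-1), `"HWVN"`
#'   (high wavenumber, 2800-3050 cm^-1) or `"full"`.
#' @param fov_id Field-of-view identifier (character).
#' @param grid_pos Integer pair `(row, col)` within the acquisition grid,
#'   or `NULL`.
#' @param meta Optional named list of extra metadata (group label, seed,
#'   outlier flag, ...).
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, region = "full",
                           fov_id = NA_character_, grid_pos = NULL,
                           meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length")
  if (length(wavenumber) == 0L)
    stop("empty spectrum")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop("intensities must be finite")
  region <- match.arg(region, c("FP", "HWVN", "full"))
  lim <- region_limits(region)
  if (!is.null(lim) &&
      (min(wavenumber) < lim[1] - 1e-9 || max(wavenumber) > lim[2] + 1e-9))
    stop(sprintf("region '%s' requires wavenumbers within [%g, %g]",
                 region, lim[1], lim[2]))
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 region = region, fov_id = fov_id, grid_pos = grid_pos,
                 meta = meta),
            class = "raman_spectrum")
}

region_limits <- function(region) {
  switch(region, FP = c(800, 1800), HWVN = c(2800, 3050), full = NULL)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.1f-%.1f cm-1, region %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$region))
  invisible(x)
}

#' Bundle per-FOV spectra into a grid
#'
#' A `fov_grid` is the unit of Raman acquisition: a rows x cols grid of
#' spectra sharing one wavenumber axis and region tag, plus per-spectrum
#' QC flags (`"keep"` or `"outlier"`).
#'
#' @param spectra List of [raman_spectrum()] objects on a common axis.
#' @param fov_id FOV identifier.
#' @param group Group label (e.g. `"control"` / `"disease"`).
#' @param grid_shape Integer pair `(rows, cols)`; `rows * cols` must equal
#'   the number of spectra.
#' @param qc_flags Character vector per spectrum; defaults to `"keep"`.
#' @return An object of class `fov_grid`.
#' @export
fov_grid <- function(spectra, fov_id, group, grid_shape,
                     qc_flags = rep("keep", length(spectra))) {
  if (length(spectra) == 0L) stop("fov_grid needs at least one spectrum")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("grid_shape must be two positive integers")
  if (prod(grid_shape) != length(spectra))
    stop("grid_shape does not match the number of spectra")
  ax <- spectra[[1]]$wavenumber
  reg <- spectra[[1]]$region
  for (s in spectra) {
    if (!identical(s$region, reg) || length(s$wavenumber) != length(ax) ||
        any(s$wavenumber != ax))
      stop("all spectra in a FOV must share one wavenumber axis and region")
  }
  if (length(qc_flags) != length(spectra))
    stop("qc_flags must match the number of spectra")
  structure(list(fov_id = fov_id, group = group, spectra = spectra,
                 grid_shape = grid_shape, qc_flags = qc_flags),
            class = "fov_grid")
}

#' @export
print.fov_grid <- function(x, ...) {
  cat(sprintf("<fov_grid> %s (%s): %d x %d grid, %d spectra (%d flagged)\n",
              x$fov_id, x$group, x$grid_shape[1], x$grid_shape[2],
              length(x$spectra), sum(x$qc_flags != "keep")))
  invisible(x)
}

# Intensities of a fov_grid as a channels x spectra matrix.
grid_intensity_matrix <- function(g) {
  vapply(g$spectra, function(s) s$intensity,
         numeric(length(g$spectra[[1]]$wavenumber)))
}
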