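#' Construct a PWS wavelength stack
#'
#' A `pws_stack` holds a wavelength-resolved reflectance cube (height x
#' width x wavelength) together with its matched instrument-response
#' (empty-slide) stack.
#'
#' @param wavelengths Ascending uniform-step nm axis (default design:
#'   550-700 nm at 1 nm, 151 frames).
#' @param cube Numeric array `(H, W, n_wavelengths)`.
#' @param irf Matched IRF array of the same shape (strictly positive), or
#'   a per-wavelength vector replicated over pixels.
#' @param fov_id FOV identifier.
#' @param meta Optional metadata list.
#' @return An object of class `pws_stack`.
#' @export
pws_stack <- function(wavelengths, cube, irf, fov_id = NA_character_,
                      meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  steps <- diff(wavelengths)
  if (length(wavelengths) < 2L || any(steps <= 0) ||
      any(abs(steps - steps[1]) > 1e-9))
    stop("wavelengths must be uniform-step ascending")
  if (length(dim(cube)) != 3L)
    stop("cube must be a 3-d array (H, W, n_wavelengths)")
  if (dim(cube)[3] != length(wavelengths))
    stop("cube depth must equal the number of wavelengths")
  if (is.null(dim(irf))) {
    if (length(irf) != length(wavelengths))
      stop("per-wavelength irf must match the wavelength axis")
    irf <- array(rep(irf, each = prod(dim(cube)[1:2])), dim(cube))
  }
  if (!identical(dim(irf), dim(cube)))
    stop("irf shape must match the cube")
  if (any(irf <= 0)) stop("IRF must be strictly positive")
  structure(list(wavelengths = wavelengths, cube = cube, irf = irf,
                 fov_id = fov_id, meta = meta),
            class = "pws_stack")
}

#' @export
print.pws_stack <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<pws_stack> %s: %d x %d px, %d wavelengths (%g-%g nm)\n",
              x$fov_id, d[1], d[2], d[3], min(x$wavelengths),
              max(x$wavelengths)))
  invisible(x)
}

#' Form the PWS spectral-fluctuation image from a stack
#'
#' Per pixel, the normalized reflectance `m(lambda) = I(lambda) /
#' I_IRF(lambda)` is detrended over wavelength (mean removal by default,
#' or a linear fit), and the fluctuation magnitude `sigma` is the
#' standard deviation of the detrended signal. The resulting `sigma_map`
#' is the texture substrate for GLCM analysis.
#'
#' @param stack A [pws_stack()].
#' @param detrend `"mean"` (default) or `"linear"`.
#' @return An object of class `pws_image` with a non-negative
#'   `sigma_map` matrix.
#' @export
compute_pws_image <- function(stack, detrend = c("mean", "linear")) {
  stopifnot(inherits(stack, "pws_stack"))
  detrend <- match.arg(detrend)
  d <- dim(stack$cube)
  n_w <- d[3]
  m <- matrix(aperm(stack$cube / stack$irf, c(3, 1, 2)), n_w,
              d[1] * d[2])
  if (detrend == "mean") {
    r <- sweep(m, 2, colMeans(m))
  } else {
    x <- cbind(1, stack$wavelengths)
    r <- m - x %*% qr.coef(qr(x), m)
  }
  # population sd over wavelength (detrended mean is zero by construction)
  sig <- sqrt(colMeans(r^2))
  structure(list(sigma_map = matrix(sig, d[1], d[2]),
                 fov_id = stack$fov_id, detrend = detrend),
            class = "pws_image")
}

#' @export
print.pws_image <- function(x, ...) {
  cat(sprintf("<pws_image> %s: %d x %d, sigma in [%.4g, %.4g]\n",
              x$fov_id, nrow(x$sigma_map), ncol(x$sigma_map),
              min(x$sigma_map), max(x$sigma_map)))
  invisible(x)
}

#' Uniform gray-level quantization
#'
#' Bins `[min, max]` of the image uniformly into `levels` gray levels; a
#' constant image maps to a single level.
#'
#' @param img A `pws_image` or a numeric matrix.
#' @param levels Number of gray levels (>= 2; default 16).
#' @return An integer matrix with values in `1:levels`.
#' @export
quantize_image <- function(img, levels = 16L) {
  x <- if (inherits(img, "pws_image")) img$sigma_map else img
  if (!is.matrix(x)) stop("img must be a matrix or pws_image")
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2])
    return(matrix(1L, nrow(x), ncol(x)))
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  q <- findInterval(x, breaks, rightmost.closed = TRUE,
                    all.inside = TRUE)
  matrix(as.integer(q), nrow(x), ncol(x))
}

#' Gray-level co-occurrence matrix at a fixed pixel offset
#'
#' `P[i, j]` counts pixel pairs `(p, p + offset)` with gray levels
#' `(i, j)`. In symmetric mode the transpose is added (each pair counted
#' in both directions); in normalized mode the matrix is divided by the
#' total pair count so it sums to one.
#'
#' @param img Integer matrix of gray levels in `1:levels`.
#' @param offset Integer pair `(dr, dc)`, nonzero, within image bounds.
#' @param levels Number of gray levels (defaults to `max(img)`).
#' @param symmetric Add the transposed counts (default `TRUE`).
#' @param normalized Normalize to unit sum (default `TRUE`).
#' @return A `levels x levels` co-occurrence matrix.
#' @export
compute_glcm <- function(img, offset, levels = max(img),
                         symmetric = TRUE, normalized = TRUE) {
  if (!is.matrix(img)) stop("img must be a matrix")
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0L && dc == 0L) stop("offset must be nonzero")
  h <- nrow(img); w <- ncol(img)
  if (abs(dr) >= h || abs(dc) >= w)
    stop("offset exceeds image bounds")
  rows <- seq_len(h - abs(dr)); cols <- seq_len(w - abs(dc))
  r1 <- if (dr >= 0) rows else rows + abs(dr)
  c1 <- if (dc >= 0) cols else cols + abs(dc)
  a <- img[r1, c1, drop = FALSE]
  b <- img[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate(as.vector(a) + (as.vector(b) - 1L) * levels,
                     nbins = levels * levels)
  p <- matrix(as.numeric(counts), levels, levels)
  if (symmetric) p <- p + t(p)
  if (normalized) {
    tot <- sum(p)
    if (tot == 0) stop("no valid pixel pairs at this offset")
    p <- p / tot
  }
  p
}

#' Inverse difference moment of a normalized GLCM
#'
#' `IDM = sum_ij P(i, j) / (1 + (i - j)^2)`, a homogeneity statistic in
#' (0, 1]: 1 when all co-occurrence mass is diagonal, smaller as mass
#' moves off-diagonal.
#'
#' @param p Normalized co-occurrence matrix (sums to 1).
#' @return The IDM scalar.
#' @export
idm <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p))
    stop("p must be a square matrix")
  if (abs(sum(p) - 1) > 1e-8)
    stop("p must be normalized (sum to 1)")
  i <- row(p); j <- col(p)
  sum(p / (1 + (i - j)^2))
}

glcm_directions <- function() {
  # 0, 45, 90, 135 degrees for unit distance (dr, dc)
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

#' IDM as a function of pixel offset
#'
#' For each distance `d = 1..max_offset`, computes the IDM of the GLCM
#' at offset `d` along each requested direction (0, 45, 90, 135 degrees)
#' and averages over directions (default policy).
#'
#' @param img A `pws_image`, or an already-quantized integer matrix.
#' @param max_offset Largest pixel distance (must be < min image
#'   dimension; default 20).
#' @param levels Gray levels for quantization (default 16).
#' @param directions Character subset of `c("0", "45", "90", "135")`.
#' @param average Average over directions (default) or keep per
#'   direction.
#' @return An `idm_curve`: data.frame with `offset`, `idm` (and
#'   `direction` when `average = FALSE`), plus the FOV id as an
#'   attribute.
#' @export
idm_curve <- function(img, max_offset = 20L, levels = 16L,
                      directions = c("0", "45", "90", "135"),
                      average = TRUE) {
  fid <- if (inherits(img, "pws_image")) img$fov_id else NA_character_
  q <- if (is.integer(img) && is.matrix(img)) img else
    quantize_image(img, levels)
  lev <- max(q)
  max_offset <- as.integer(max_offset)
  if (max_offset >= min(dim(q)))
    stop("max_offset must be smaller than the image dimensions")
  if (max_offset < 1L) stop("max_offset must be >= 1")
  directions <- match.arg(directions, c("0", "45", "90", "135"),
                          several.ok = TRUE)
  dirs <- glcm_directions()[directions]
  rows <- list()
  for (d in seq_len(max_offset)) {
    vals <- vapply(dirs, function(dd) {
      idm(compute_glcm(q, dd * d, levels = lev))
    }, numeric(1))
    if (average) {
      rows[[d]] <- data.frame(offset = d, idm = mean(vals))
    } else {
      rows[[d]] <- data.frame(offset = d, direction = names(dirs),
                              idm = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fov_id") <- fid
  class(out) <- c("idm_curve", "data.frame")
  out
}

#' Per-group mean and sd bands of IDM curves
#'
#' Pointwise mean and standard deviation of IDM-vs-offset curves within
#' each group, for distribution plots and as classifier features.
#'
#' @param curves List of [idm_curve()] results sharing one offset axis.
#' @param groups Group label per curve.
#' @return A data.frame with `group`, `offset`, `mean_idm`, `sd_idm`,
#'   `n`.
#' @export
summarize_group_curves <- function(curves, groups) {
  if (length(curves) != length(groups))
    stop("curves and groups must have equal length")
  if (!length(curves)) stop("no curves given")
  off <- curves[[1]]$offset
  for (cv in curves) {
    if (length(cv$offset) != length(off) || any(cv$offset != off))
      stop("all curves must share the same offsets")
  }
  m <- vapply(curves, function(cv) cv$idm, numeric(length(off)))
  m <- matrix(m, nrow = length(off))
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    sel <- m[, groups == g, drop = FALSE]
    data.frame(group = g, offset = off,
               mean_idm = rowMeans(sel),
               sd_idm = apply(sel, 1, function(r)
                 if (length(r) > 1) stats::sd(r) else 0),
               n = ncol(sel))
  }))
  rownames(out) <- NULL
  out
}
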