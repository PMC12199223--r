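#' Construct a labeled feature matrix
#'
#' Rows are FOV observations, columns named features from one or more
#' modalities (Raman channels, IDM offsets). Labels use the 0/1 class
#' code (control = 0, disease = 1).
#'
#' @param x Numeric matrix with column names; no missing values.
#' @param labels 0/1 integer vector (or two-level factor) per row.
#' @param fov_ids Unique row identifiers.
#' @param modality Per-column modality tag (single string recycled, or
#'   vector).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, fov_ids = rownames(x),
                           modality = "feature") {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix must not contain missing values")
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.integer(factor(labels)) - 1L
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be coded 0/1")
  if (length(labels) != nrow(x)) stop("one label per row required")
  if (is.null(fov_ids)) fov_ids <- sprintf("obs%03d", seq_len(nrow(x)))
  if (anyDuplicated(fov_ids)) stop("fov_ids must be unique")
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  modality <- rep_len(modality, ncol(x))
  rownames(x) <- fov_ids
  structure(list(x = x, labels = labels, fov_ids = fov_ids,
                 modality = modality),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d obs x %d features (%s); classes %d/%d\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$modality), collapse = "+"),
              sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' Column z-scoring
#'
#' Standardizes each column to mean 0 and sd 1 (sample-sd convention,
#' denominator n - 1), recording the scaling parameters for reuse on new
#' data.
#'
#' @param fm A [feature_matrix()].
#' @return The standardized `feature_matrix`, with `center` and `scale`
#'   attributes.
#' @export
zscore_columns <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  ctr <- colMeans(fm$x)
  scl <- apply(fm$x, 2, stats::sd)
  bad <- which(scl == 0 | !is.finite(scl))
  if (length(bad))
    stop("constant column(s): ",
         paste(colnames(fm$x)[bad], collapse = ", "))
  fm$x <- sweep(sweep(fm$x, 2, ctr), 2, scl, `/`)
  attr(fm, "center") <- ctr
  attr(fm, "scale") <- scl
  fm
}

#' Concatenate two modality feature matrices
#'
#' Column-binds matrices observed on the same FOVs, canonicalizing row
#' order by fov_id and checking label agreement.
#'
#' @param rs,pws [feature_matrix()] objects with identical fov_id sets
#'   and labels.
#' @return The fused `feature_matrix` with provenance tags preserved.
#' @export
concat_features <- function(rs, pws) {
  stopifnot(inherits(rs, "feature_matrix"), inherits(pws, "feature_matrix"))
  ids <- sort(rs$fov_ids)
  if (!identical(ids, sort(pws$fov_ids))) {
    bad <- c(setdiff(rs$fov_ids, pws$fov_ids),
             setdiff(pws$fov_ids, rs$fov_ids))
    stop("fov_id sets differ: ", paste(bad, collapse = ", "))
  }
  i1 <- match(ids, rs$fov_ids); i2 <- match(ids, pws$fov_ids)
  if (any(rs$labels[i1] != pws$labels[i2])) {
    bad <- ids[rs$labels[i1] != pws$labels[i2]]
    stop("label disagreement for: ", paste(bad, collapse = ", "))
  }
  cn <- c(paste0(colnames(rs$x)), paste0(colnames(pws$x)))
  x <- cbind(rs$x[i1, , drop = FALSE], pws$x[i2, , drop = FALSE])
  colnames(x) <- make.unique(cn)
  feature_matrix(x, rs$labels[i1], fov_ids = ids,
                 modality = c(rs$modality, pws$modality))
}

# SIMPLS partial least squares for a single response. Returns the
# regression coefficients for every component count 1..ncomp at once
# (coefficient matrix per count), plus centering info for prediction.
simpls_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1L) stop("cannot fit: need ncomp >= 1")
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm); yc <- y - ym
  s <- drop(crossprod(xc, yc))
  rr <- matrix(0, p, ncomp)   # weights
  qq <- numeric(ncomp)        # y loadings
  vv <- matrix(0, p, ncomp)   # orthogonalized x loadings
  for (a in seq_len(ncomp)) {
    r <- s
    t <- drop(xc %*% r)
    tn <- sqrt(sum(t^2))
    if (tn < .Machine$double.eps^0.5) { ncomp <- a - 1L; break }
    t <- t / tn; r <- r / tn
    pa <- drop(crossprod(xc, t))
    qq[a] <- sum(yc * t)
    v <- pa
    if (a > 1L) {
      vprev <- vv[, seq_len(a - 1L), drop = FALSE]
      v <- v - vprev %*% crossprod(vprev, v)
    }
    v <- v / sqrt(sum(v^2))
    vv[, a] <- v
    rr[, a] <- r
    s <- s - v * drop(crossprod(v, s))
  }
  if (ncomp < 1L) stop("degenerate fit: no usable component")
  coefs <- sapply(seq_len(ncomp), function(a) {
    drop(rr[, seq_len(a), drop = FALSE] %*% qq[seq_len(a)])
  })
  coefs <- matrix(coefs, nrow = p)
  list(coefficients = coefs, x_center = xm, y_center = ym,
       ncomp = ncomp)
}

simpls_predict <- function(fit, newx, ncomp = fit$ncomp) {
  newx <- as.matrix(newx)
  ncomp <- min(ncomp, fit$ncomp)
  drop(sweep(newx, 2, fit$x_center) %*%
         fit$coefficients[, ncomp]) + fit$y_center
}

# Stratified k-fold assignment, deterministic given the seed: indices of
# each class are shuffled and dealt round-robin.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated PLS-DA component selection (one-sigma rule)
#'
#' Runs stratified k-fold cross-validation of the PLS regression of the
#' 0/1 class code on the features, computing the mean squared prediction
#' error per candidate component count. The selected count is the
#' smallest one whose mean error is within one standard error of the
#' minimum, where the standard error is taken across the fold errors of
#' the minimizing count.
#'
#' @param fm A [feature_matrix()] (typically z-scored).
#' @param k Number of folds (default 4); must not exceed the smaller
#'   class count.
#' @param max_components Largest candidate component count (default 10,
#'   capped by the training-set rank).
#' @param seed Integer seed for the fold assignment.
#' @param scale `"none"` (default; features are scaled beforehand,
#'   matching a global z-score) or `"fold"` for leakage-safe per-fold
#'   standardization.
#' @return A list: `cv_errors` data.frame (`ncomp`, `mean_mse`, `se`),
#'   per-fold error matrix, `selected_n`, `fold_assignment`, `k`.
#' @export
plsda_cv <- function(fm, k = 4L, max_components = 10L, seed = 1L,
                     scale = c("none", "fold")) {
  stopifnot(inherits(fm, "feature_matrix"))
  scale <- match.arg(scale)
  k <- as.integer(k)
  cls <- table(fm$labels)
  if (length(cls) < 2L) stop("both classes must be present")
  if (k > min(cls))
    stop(sprintf("k = %d exceeds the smaller class count (%d)", k,
                 min(cls)))
  n <- nrow(fm$x)
  max_components <- min(max_components, ncol(fm$x),
                        n - ceiling(n / k) - 1L)
  if (max_components < 1L) stop("too few observations for CV")
  fold <- stratified_folds(fm$labels, k, seed)
  fold_mse <- matrix(NA_real_, k, max_components)
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- fm$x[tr, , drop = FALSE]
    xte <- fm$x[!tr, , drop = FALSE]
    if (scale == "fold") {
      ctr <- colMeans(xtr)
      scl <- apply(xtr, 2, stats::sd)
      scl[scl == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, ctr), 2, scl, `/`)
      xte <- sweep(sweep(xte, 2, ctr), 2, scl, `/`)
    }
    fit <- simpls_fit(xtr, fm$labels[tr], max_components)
    for (a in seq_len(max_components)) {
      pr <- simpls_predict(fit, xte, min(a, fit$ncomp))
      fold_mse[f, a] <- mean((fm$labels[!tr] - pr)^2)
    }
  }
  mean_mse <- colMeans(fold_mse)
  se_all <- apply(fold_mse, 2, stats::sd) / sqrt(k)
  best <- which.min(mean_mse)
  thr <- mean_mse[best] + se_all[best]
  selected <- which(mean_mse <= thr)[1]
  list(cv_errors = data.frame(ncomp = seq_len(max_components),
                              mean_mse = mean_mse, se = se_all),
       fold_mse = fold_mse, selected_n = as.integer(selected),
       argmin_n = as.integer(best), fold_assignment = fold, k = k,
       seed = seed)
}

# Direct statement of the selection rule, reusable on any error profile.
one_sigma_select <- function(mean_err, se_err) {
  best <- which.min(mean_err)
  which(mean_err <= mean_err[best] + se_err[best])[1]
}

#' Fit PLS-DA and report fitted responses, R-squared and residual norm
#'
#' PLS (SIMPLS) regression of the 0/1 class code on the features with a
#' fixed number of latent components. Performance is summarized as in
#' chemometric practice by `R2 = 1 - SS_res / SS_tot` (SS_tot about the
#' label mean) and the residual norm `||r|| = sqrt(sum(residuals^2))`.
#'
#' @param fm A [feature_matrix()].
#' @param n_components Number of latent components (>= 1).
#' @return An object of class `plsda_result` with `fitted_response`,
#'   `residuals`, `r_squared`, `residual_norm`, `n_components`,
#'   `predicted_class` (0.5 threshold) and the underlying fit for
#'   prediction on new data.
#' @export
plsda_fit_predict <- function(fm, n_components) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$labels)) < 2L)
    stop("both classes must be present")
  if (n_components < 1L) stop("n_components must be >= 1")
  fit <- simpls_fit(fm$x, fm$labels, n_components)
  if (fit$ncomp < n_components)
    n_components <- fit$ncomp
  fitted <- simpls_predict(fit, fm$x, n_components)
  res <- fm$labels - fitted
  ss_tot <- sum((fm$labels - mean(fm$labels))^2)
  r2 <- 1 - sum(res^2) / ss_tot
  structure(list(n_components = n_components,
                 fitted_response = fitted, residuals = res,
                 r_squared = r2, residual_norm = sqrt(sum(res^2)),
                 ss_tot = ss_tot,
                 predicted_class = as.integer(fitted >= 0.5),
                 labels = fm$labels, fov_ids = fm$fov_ids, fit = fit),
            class = "plsda_result")
}

#' @export
print.plsda_result <- function(x, ...) {
  cat(sprintf(
    "<plsda_result> %d components: R2 = %.3f, ||r|| = %.3f (n = %d)\n",
    x$n_components, x$r_squared, x$residual_norm, length(x$labels)))
  invisible(x)
}

# z-score + CV + final fit for one modality; cross-validated predictions
# at the selected count are recomputed so both in-sample and CV metrics
# can be reported.
fit_one_modality <- function(fm, k, max_components, seed, scale) {
  fmz <- if (scale == "global") zscore_columns(fm) else fm
  cv_scale <- if (scale == "fold") "fold" else "none"
  cv <- plsda_cv(fmz, k = k, max_components = max_components,
                 seed = seed, scale = cv_scale)
  fitres <- plsda_fit_predict(fmz, cv$selected_n)
  cv_pred <- numeric(nrow(fmz$x))
  for (f in seq_len(k)) {
    tr <- cv$fold_assignment != f
    xtr <- fmz$x[tr, , drop = FALSE]
    xte <- fmz$x[!tr, , drop = FALSE]
    if (cv_scale == "fold") {
      ctr <- colMeans(xtr); scl <- apply(xtr, 2, stats::sd)
      scl[scl == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, ctr), 2, scl, `/`)
      xte <- sweep(sweep(xte, 2, ctr), 2, scl, `/`)
    }
    fit <- simpls_fit(xtr, fmz$labels[tr], cv$selected_n)
    cv_pred[!tr] <- simpls_predict(fit, xte, min(cv$selected_n,
                                                 fit$ncomp))
  }
  cv_res <- fmz$labels - cv_pred
  ss_tot <- sum((fmz$labels - mean(fmz$labels))^2)
  list(cv = cv, fit = fitres,
       cv_r_squared = 1 - sum(cv_res^2) / ss_tot,
       cv_residual_norm = sqrt(sum(cv_res^2)))
}

#' Compare PWS-only, RS-only and fused PLS-DA classification
#'
#' Runs the full classification per modality and for the standardized
#' concatenation, reporting the selected component count, in-sample R2
#' and residual norm, and their cross-validated counterparts (labelled
#' explicitly), plus the fused-vs-best-single R2 improvement in both
#' absolute and relative terms.
#'
#' @param rs,pws [feature_matrix()] objects for the two modalities.
#' @param k CV folds (default 4).
#' @param max_components Candidate component cap (default 10).
#' @param seed Fold-assignment seed.
#' @param scale `"global"` (z-score all data before CV, matching the
#'   fusion recipe) or `"fold"` (leakage-safe per-fold scaling).
#' @return A `modality_report`: per-modality results plus a summary
#'   data.frame.
#' @export
compare_modalities <- function(rs, pws, k = 4L, max_components = 10L,
                               seed = 1L, scale = c("global", "fold")) {
  scale <- match.arg(scale)
  fused <- concat_features(rs, pws)
  mods <- list(pws = pws, rs = rs, fused = fused)
  res <- lapply(mods, fit_one_modality, k = k,
                max_components = max_components, seed = seed,
                scale = scale)
  summary <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(modality = nm, selected_n = r$cv$selected_n,
               r_squared = r$fit$r_squared,
               residual_norm = r$fit$residual_norm,
               cv_r_squared = r$cv_r_squared,
               cv_residual_norm = r$cv_residual_norm)
  }))
  best_single <- max(summary$r_squared[summary$modality != "fused"])
  fused_r2 <- summary$r_squared[summary$modality == "fused"]
  structure(list(results = res, summary = summary,
                 fused_gain_absolute = fused_r2 - best_single,
                 fused_gain_relative =
                   (fused_r2 - best_single) / abs(best_single)),
            class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("fused R2 gain over best single modality: %+.3f (%+.1f%%)\n",
              x$fused_gain_absolute, 100 * x$fused_gain_relative))
  invisible(x)
}
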