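#' Plot per-group IDM curves with sd bands
#'
#' Distribution-style plot of the IDM textural feature versus pixel
#' offset: one mean curve per group with a shaded +/- 1 sd band.
#'
#' @param idm_summary Output of [summarize_group_curves()].
#' @param cols Colors per group.
#' @return Invisibly, `idm_summary`.
#' @export
plot_idm_summary <- function(idm_summary,
                             cols = c("#1b9e77", "#d95f02")) {
  gs <- unique(idm_summary$group)
  cols <- rep_len(cols, length(gs))
  ylim <- range(idm_summary$mean_idm - idm_summary$sd_idm,
                idm_summary$mean_idm + idm_summary$sd_idm)
  plot(NA, xlim = range(idm_summary$offset), ylim = ylim,
       xlab = "pixel offset", ylab = "IDM",
       main = "IDM vs pixel offset (mean +/- sd per group)")
  for (i in seq_along(gs)) {
    d <- idm_summary[idm_summary$group == gs[i], ]
    graphics::polygon(c(d$offset, rev(d$offset)),
                      c(d$mean_idm - d$sd_idm,
                        rev(d$mean_idm + d$sd_idm)),
                      col = grDevices::adjustcolor(cols[i], 0.25),
                      border = NA)
    graphics::lines(d$offset, d$mean_idm, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = gs, col = cols, lwd = 2,
                   bty = "n")
  invisible(idm_summary)
}

#' Plot PLS-DA fitted responses and residuals
#'
#' Two stacked panels in the standard layout: fitted response per
#' observation (top, with the 0/1 class code and 0.5 threshold) and
#' residuals per observation (bottom), annotated with R2 and ||r||.
#'
#' @param res A [plsda_fit_predict()] result.
#' @param title Plot title prefix.
#' @return Invisibly, `res`.
#' @export
plot_plsda_fit <- function(res, title = "PLS-DA") {
  stopifnot(inherits(res, "plsda_result"))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  n <- length(res$labels)
  cols <- ifelse(res$labels == 1, "#d95f02", "#1b9e77")
  plot(seq_len(n), res$fitted_response, col = cols, pch = 19,
       xlab = "observation", ylab = "fitted response",
       main = sprintf("%s: R2 = %.3f, ||r|| = %.3f (%d comp.)",
                      title, res$r_squared, res$residual_norm,
                      res$n_components))
  graphics::abline(h = 0.5, lty = 2)
  graphics::abline(h = c(0, 1), lty = 3, col = "gray")
  plot(seq_len(n), res$residuals, col = cols, pch = 19,
       xlab = "observation", ylab = "residual")
  graphics::abline(h = 0, lty = 2)
  invisible(res)
}
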