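# Optional base-graphics views of the main objects; never required by the
# pipeline or the tests.

#' Histogram of cohort enhancement
#'
#' @param enhancement Result of [compute_enhancement()].
#' @param site `"aorta"` or `"liver"`.
#' @param threshold Optional diagnostic threshold to mark (HU).
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot_enhancement_hist <- function(enhancement, site = c("aorta", "liver"),
                                  threshold = NULL, ...) {
  site <- match.arg(site)
  x <- if (site == "aorta") enhancement$aorta_enh_hu else enhancement$liver_enh_hu
  h <- graphics::hist(x, main = sprintf("%s enhancement", site),
                      xlab = "Contrast enhancement (HU)", ...)
  if (!is.null(threshold)) graphics::abline(v = threshold, lty = 2)
  invisible(h)
}

#' Per-chain posterior densities
#'
#' Overlays the kernel density of each chain for the location and scale,
#' the visual analogue of the R-hat diagnostic.
#'
#' @param x A `posterior_draws` object.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.posterior_draws <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (par_name in c("mu", "sigma")) {
    mat <- x[[par_name]]
    dens <- lapply(seq_len(ncol(mat)), function(c) stats::density(mat[, c]))
    xlim <- range(vapply(dens, function(d) range(d$x), numeric(2)))
    ylim <- c(0, max(vapply(dens, function(d) max(d$y), numeric(1))))
    graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = par_name,
                   ylab = "posterior density", main = par_name)
    for (c in seq_along(dens)) graphics::lines(dens[[c]], col = c)
  }
  invisible(x)
}
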