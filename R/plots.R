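## Base-graphics displays of the method's intermediate surfaces and the
## distance statistics: p-value diagrams, efficiency curves, joint and
## conditional distributions with the Wbar curve and its 1-sigma band.

#' @describeIn efficiency Plot an efficiency curve with its threshold.
#' @param x,y,... standard plot arguments.
#' @param threshold efficiency threshold drawn as a reference line.
#' @method plot EfficiencyCurve
#' @export
plot.EfficiencyCurve <- function(x, y, threshold = 0.5, ...) {
  plot(x@widths, x@eta, type = "l", xlab = "window width w (s)",
       ylab = expression(eta(w)), ylim = c(0, 1), ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  W <- observabilityTimescale(x, threshold)
  if (is.finite(W)) graphics::abline(v = W, lty = 3, col = "red")
  invisible(x)
}

diagramImage <- function(values, centers, widths, xlab, ylab, main) {
  graphics::image(centers, widths, values, xlab = xlab, ylab = ylab,
                  main = main, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"))
}

#' @describeIn pvalueDiagram Plot the p-value diagram (centers x widths).
#' @param x a [PValueDiagram-class].
#' @param ... passed to [graphics::image()].
#' @method plot PValueDiagram
#' @export
plot.PValueDiagram <- function(x, ...) {
  diagramImage(log10(x@values), x@centers, x@widths,
               "window center t (s)", "window width w (s)",
               expression(log[10] ~ p(k, w)))
  invisible(x)
}

#' @describeIn jointDistribution Plot the joint distribution with marginals.
#' @param x a [JointDistribution-class].
#' @param ... passed to [graphics::image()].
#' @method plot JointDistribution
#' @export
plot.JointDistribution <- function(x, ...) {
  bn <- x@binning
  dC <- (bn@dEdges[-1] + bn@dEdges[-length(bn@dEdges)]) / 2
  wC <- (bn@wEdges[-1] + bn@wEdges[-length(bn@wEdges)]) / 2
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  lay <- graphics::layout(matrix(c(2, 4, 1, 3), 2, 2, byrow = TRUE),
                          widths = c(3, 1), heights = c(1, 3))
  graphics::par(mar = c(4, 4, 0.5, 0.5))
  graphics::image(dC, wC, x@f,
                  xlab = if (bn@logD) "ln d (d in mm)" else "d (mm)",
                  ylab = "W (s)", useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"))
  mg <- marginals(x)
  graphics::par(mar = c(0.5, 4, 0.5, 0.5))
  plot(dC, mg$gD, type = "h", axes = FALSE, xlab = "", ylab = "g_d")
  graphics::axis(2)
  graphics::par(mar = c(4, 0.5, 0.5, 0.5))
  plot(mg$gW, wC, type = "s", axes = FALSE, xlab = "g_W", ylab = "")
  graphics::axis(1)
  invisible(x)
}

#' @describeIn conditionalCurve Plot the conditional map, the Wbar curve and
#'   its 1-sigma (68%) band; optionally overlay a piecewise fit.
#' @param x a [ConditionalCurve-class].
#' @param fit optional [PiecewiseFit-class] to overlay.
#' @param ... passed to [graphics::image()].
#' @method plot ConditionalCurve
#' @export
plot.ConditionalCurve <- function(x, fit = NULL, ...) {
  bn <- x@binning
  dC <- x@table$x
  wC <- (bn@wEdges[-1] + bn@wEdges[-length(bn@wEdges)]) / 2
  graphics::image(dC, wC, t(x@conditional),
                  xlab = if (bn@logD) "ln d (d in mm)" else "d (mm)",
                  ylab = "W (s)", useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  ok <- x@table$n > 0
  graphics::points(dC[ok], x@table$wbar[ok], pch = 20, col = "white")
  graphics::lines(dC[ok], (x@table$wbar + x@table$sd)[ok], lty = 2,
                  col = "white")
  graphics::lines(dC[ok], (x@table$wbar - x@table$sd)[ok], lty = 2,
                  col = "white")
  if (!is.null(fit)) {
    stopifnot(is(fit, "PiecewiseFit"))
    xs <- if (bn@logD) dC else log(dC)
    bks <- log(fit@breakpoints)
    cuts <- list(c(min(xs), bks[1]), c(bks[1], bks[2]), c(bks[2], max(xs)))
    for (s in 1:3) {
      xx <- seq(cuts[[s]][1], cuts[[s]][2], length.out = 20)
      yy <- fit@intercepts[s] + fit@slopes[s] * xx
      graphics::lines(if (bn@logD) xx else exp(xx), yy, lwd = 2)
    }
    graphics::abline(v = if (bn@logD) bks else fit@breakpoints, lty = 3)
  }
  invisible(x)
}
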