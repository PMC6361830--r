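#' @export
plot.spike_record <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$spikes$time / 1000, x$spikes$cell, pch = "|", cex = 0.4,
                 xlab = "time (s)", ylab = "cell index",
                 main = "chain raster", ...)
  graphics::plot(x$inhibition$time / 1000, x$inhibition$N, type = "s",
                 xlab = "time (s)", ylab = "inhibition count N",
                 main = "inhibition staircase")
  invisible(x)
}

#' @export
plot.scalar_stats <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$mean / 1000, x$cv, type = "b", cex = 0.5,
                 xlab = "mean spike time (s)", ylab = "CV",
                 main = "coefficient of variation", ...)
  graphics::abline(h = attr(x, "cv_asymptotic"), col = 2)
  graphics::plot(x$mean / 1000, x$sd / 1000, type = "p", cex = 0.5,
                 xlab = "mean spike time (s)", ylab = "SD (s)",
                 main = sprintf("SD vs mean (R^2 = %.3f)",
                                attr(x, "r_squared")))
  graphics::abline(attr(x, "intercept") / 1000, attr(x, "slope"), col = 2)
  invisible(x)
}

#' @export
plot.fig2_result <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$time / 1000, tr$v, type = "l",
                 xlab = "time (s)", ylab = "v (mV)",
                 main = "membrane potential", ...)
  graphics::abline(v = x$delays$spike_time / 1000, col = 2, lty = 3)
  graphics::plot(tr$time / 1000, tr$h_d, type = "l",
                 xlab = "time (s)", ylab = "h_d",
                 main = "D-current inactivation gate")
  invisible(x)
}

#' @export
plot.normalized_histograms <- function(x, ...) {
  h1 <- x$histograms[[1]]
  mids <- (h1$breaks[-1] + h1$breaks[-length(h1$breaks)]) / 2
  masses <- sapply(x$histograms, `[[`, "mass")
  graphics::matplot(mids, masses, type = "s", lty = 1,
                    xlab = "spike time / mean spike time",
                    ylab = "probability mass",
                    main = "mean-normalized spike-time distributions", ...)
  graphics::legend("topright", legend = sapply(x$histograms, `[[`, "cell"),
                   col = seq_along(x$histograms), lty = 1, bty = "n",
                   title = "cell")
  invisible(x)
}
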