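#' Plot an excitation profile
#'
#' Image of the dithered (z, y) excitation intensity with the beam focus at
#' the origin.
#'
#' @param x an `excitation_profile`.
#' @param zlim_show z range to display (wavelengths).
#' @param ... passed to [graphics::image()].
#' @export
plot.excitation_profile <- function(x, zlim_show = c(-15, 15), ...) {
  z <- attr(x, "z"); y <- attr(x, "y")
  sel <- z >= zlim_show[1L] & z <= zlim_show[2L]
  graphics::image(y, z[sel], t(unclass(x)[sel, ]),
                  col = grDevices::hcl.colors(128, "inferno"),
                  xlab = "y (wavelengths)", ylab = "z (wavelengths)", ...)
  invisible(x)
}

#' Plot an axial profile
#'
#' @param x an `axial_profile`.
#' @param xlim z range to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.axial_profile <- function(x, xlim = c(-10, 10), ...) {
  graphics::plot(x$z, x$intensity / max(x$intensity), type = "l",
                 xlim = xlim, xlab = "z (wavelengths)",
                 ylab = "normalized intensity", ...)
  invisible(x)
}

#' Plot the averaged Fourier plane correlation map
#'
#' @param x an `fpc_result`.
#' @param cutoff contour level to overlay (default 1/7).
#' @param ... passed to [graphics::image()].
#' @export
plot.fpc_result <- function(x, cutoff = 1 / 7, ...) {
  graphics::image(x$axis1, x$axis2, x$average,
                  zlim = c(-0.2, 1), col = grDevices::hcl.colors(128, "viridis"),
                  xlab = "k (cycles/unit)", ylab = "k_z (cycles/unit)", ...)
  graphics::contour(x$axis1, x$axis2, x$average, levels = cutoff,
                    add = TRUE, col = "white", drawlabels = FALSE)
  invisible(x)
}
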