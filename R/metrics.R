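#' Beam metrics
#'
#' Quantities used to characterize light-sheet excitation profiles and overall
#' PSFs. All widths are in wavelengths (in the medium), found by linear
#' interpolation between samples, and are invariant to uniform intensity
#' scaling.
#'
#' @name beam-metrics
NULL

as_zI <- function(z, intensity) {
  if (is.list(z) && !is.null(z$z)) list(z = z$z, I = z$intensity)
  else list(z = z, I = intensity)
}

# walk outward from index `ic` until the profile crosses `level`; returns the
# interpolated crossing coordinate on side `dir` (+1/-1), or NA at the edge
outward_crossing <- function(z, I, ic, level, dir) {
  i <- ic
  n <- length(I)
  while (i + dir >= 1L && i + dir <= n && I[i + dir] >= level) i <- i + dir
  if (i + dir < 1L || i + dir > n) return(NA_real_)
  j <- i + dir
  z[i] + (I[i] - level) / (I[i] - I[j]) * (z[j] - z[i])
}

#' Axial FWHM with prominence-based half level
#'
#' Full width of the central peak at the half level defined from the peak
#' prominence: the reference floor is the minimum intensity within
#' `window` wavelengths of the peak, and the half level is floor + 50% of
#' (peak - floor). For multi-lobed profiles only the central lobe is measured
#' (the first crossing walking outward from the peak).
#'
#' @param z axis (wavelengths) or an `axial_profile`.
#' @param intensity profile values (omit when `z` is an `axial_profile`).
#' @param window half-width of the floor search window around the peak.
#' @return FWHM in wavelengths.
#' @export
axial_fwhm <- function(z, intensity = NULL, window = 10) {
  p <- as_zI(z, intensity)
  ic <- which.max(p$I)
  if (ic == 1L || ic == length(p$I)) stop("no interior peak found")
  near <- abs(p$z - p$z[ic]) <= window
  floorv <- min(p$I[near])
  level <- floorv + 0.5 * (p$I[ic] - floorv)
  hi <- outward_crossing(p$z, p$I, ic, level, +1L)
  lo <- outward_crossing(p$z, p$I, ic, level, -1L)
  if (is.na(hi) || is.na(lo))
    stop("profile does not cross the half level within its span")
  hi - lo
}

#' Main-lobe width at a fractional threshold of the peak
#'
#' Width of the central excitation lobe where the intensity first drops to
#' `threshold` (default 63%) of the peak, walking outward from the central
#' maximum. A profile that never drops below the threshold inside its span
#' (e.g. a rectangle) returns the full span of the super-threshold region.
#'
#' @inheritParams axial_fwhm
#' @param threshold fraction of the peak (0.63 by default; 0.37 reproduces the
#'   older convention that overestimates widths of multi-lobed beams).
#' @export
main_lobe_width <- function(z, intensity = NULL, threshold = 0.63) {
  p <- as_zI(z, intensity)
  ic <- which.max(p$I)
  if (diff(range(p$I)) == 0) stop("flat profile has no main lobe")
  level <- threshold * p$I[ic]
  hi <- outward_crossing(p$z, p$I, ic, level, +1L)
  lo <- outward_crossing(p$z, p$I, ic, level, -1L)
  if (is.na(hi)) hi <- p$z[length(p$z)]
  if (is.na(lo)) lo <- p$z[1L]
  hi - lo
}

# symmetric cumulative intensity about z = 0 by trapezoidal quadrature:
# returns half-widths h and the enclosed fraction F(h)
cumulative_about_zero <- function(z, I) {
  ic <- which.min(abs(z))
  dz <- z[2L] - z[1L]
  n <- length(I)
  m <- min(ic - 1L, n - ic)
  # trapezoid area of each outward step, right and left of the centre
  right <- (I[ic + seq_len(m) - 1L] + I[ic + seq_len(m)]) / 2 * dz
  left  <- (I[ic - seq_len(m) + 1L] + I[ic - seq_len(m)]) / 2 * dz
  enc <- cumsum(right + left)
  total <- sum((I[-1L] + I[-n]) / 2 * dz)
  if (total <= 0) stop("zero-energy profile")
  list(h = seq_len(m) * dz, fraction = pmin(enc / total, 1), total = total)
}

#' Optical sectioning: 63% cumulative-intensity half-width
#'
#' Smallest half-width h such that the symmetric integral of the excitation
#' profile over \[-h, h\] contains `fraction` (default 63%) of its total
#' integral, interpolated linearly.
#'
#' @inheritParams axial_fwhm
#' @param fraction enclosed-energy fraction defining the half-width.
#' @export
optical_sectioning <- function(z, intensity = NULL, fraction = 0.63) {
  p <- as_zI(z, intensity)
  cum <- cumulative_about_zero(p$z, p$I)
  i <- which(cum$fraction >= fraction)[1L]
  if (is.na(i)) stop("profile never encloses the requested fraction")
  if (i == 1L) return(cum$h[1L] * fraction / cum$fraction[1L])
  f0 <- cum$fraction[i - 1L]
  cum$h[i - 1L] + (fraction - f0) / (cum$fraction[i] - f0) *
    (cum$h[i] - cum$h[i - 1L])
}

#' Cumulative axial energy profile
#'
#' Fraction of the total profile energy enclosed in \[-h, h\], integrating
#' outward from z = 0; monotone non-decreasing with endpoint 1.
#'
#' @inheritParams axial_fwhm
#' @return Data frame with columns `h` and `fraction`.
#' @export
cumulative_z_profile <- function(z, intensity = NULL) {
  p <- as_zI(z, intensity)
  cum <- cumulative_about_zero(p$z, p$I)
  data.frame(h = cum$h, fraction = cum$fraction)
}

#' OTF support: largest frequency above a relative amplitude threshold
#'
#' @param k frequency axis (any units; may span both signs).
#' @param amplitude OTF amplitude values.
#' @param threshold fraction of the DC amplitude (default 0.1%).
#' @return Largest |k| where the amplitude is at least `threshold` times the
#'   DC (k = 0) amplitude.
#' @export
otf_support <- function(k, amplitude, threshold = 1e-3) {
  dc <- amplitude[which.min(abs(k))]
  max(abs(k[amplitude >= threshold * dc]))
}

#' Propagation FWHM of the on-axis intensity
#'
#' Full width along y where the on-axis excitation intensity exceeds 50% of
#' its value at the focus (y = 0).
#'
#' @param y propagation axis.
#' @param intensity on-axis intensity values (or a data frame with columns
#'   `y` and `intensity`, as returned by [onaxis_intensity()]).
#' @export
propagation_fwhm <- function(y, intensity = NULL) {
  if (is.data.frame(y)) { intensity <- y$intensity; y <- y$y }
  i0 <- which.min(abs(y))
  level <- intensity[i0] / 2
  hi <- outward_crossing(y, intensity, i0, level, +1L)
  lo <- outward_crossing(y, intensity, i0, level, -1L)
  if (is.na(hi) && is.na(lo)) return(Inf)
  if (is.na(hi)) return(2 * abs(lo))
  if (is.na(lo)) return(2 * hi)
  hi - lo
}

#' Propagation length from optical-sectioning doubling
#'
#' The y at which the optical sectioning of the excitation profile reaches
#' twice its focal value, interpolated linearly; `Inf` when the sectioning
#' never doubles over the sampled range.
#'
#' @param stack an `excitation_profile`.
#' @export
os_doubling_length <- function(stack) {
  stopifnot(inherits(stack, "excitation_profile"))
  ys <- attr(stack, "y")
  z <- attr(stack, "z")
  sel <- ys >= 0
  yy <- ys[sel]
  os <- vapply(which(sel), function(j) optical_sectioning(z, stack[, j]),
               numeric(1L))
  o <- order(yy); yy <- yy[o]; os <- os[o]
  target <- 2 * os[yy == 0][1L]
  i <- which(os >= target)[1L]
  if (is.na(i)) return(Inf)
  if (i == 1L) return(0)
  yy[i - 1L] + (target - os[i - 1L]) / (os[i] - os[i - 1L]) *
    (yy[i] - yy[i - 1L])
}

#' h90: axial height containing 90% of the beam energy
#'
#' Full height (symmetric about z = 0) enclosing 90% of the excitation
#' profile's energy; used with the sheet width for average-power-density
#' estimates.
#'
#' @inheritParams axial_fwhm
#' @export
h90 <- function(z, intensity = NULL) {
  2 * optical_sectioning(z, intensity, fraction = 0.9)
}

#' Intensity-equalization scale factors
#'
#' Multiplicative scales bringing a set of excitation profiles to either the
#' same focal peak intensity or the same integrated intensity over a fixed
#' axial envelope (10 um in the reference instrument, 24 wavelengths here).
#' The first profile is the reference (scale 1).
#'
#' @param profiles list of `axial_profile`s (or lists with `z`, `intensity`).
#' @param mode `"peak"` or `"integrated"`.
#' @param envelope full axial envelope (wavelengths) for integrated mode.
#' @return Numeric vector of per-beam scale factors.
#' @export
equalize_intensity <- function(profiles, mode = c("peak", "integrated"),
                               envelope = 24) {
  mode <- match.arg(mode)
  stat <- vapply(profiles, function(p) {
    p <- as_zI(p, NULL)
    if (mode == "peak") {
      max(p$I)
    } else {
      sel <- abs(p$z) <= envelope / 2
      dz <- p$z[2L] - p$z[1L]
      sum(p$I[sel]) * dz
    }
  }, numeric(1L))
  stat[1L] / stat
}

#' Average power density over the sheet cross-section
#'
#' Total excitation power divided by the area spanned by the sheet width and
#' the 90%-energy axial height.
#'
#' @param total_power beam power at the excitation objective pupil.
#' @param sheet_width_w dithered sheet width.
#' @param h90 axial 90%-energy height (see [h90()]).
#' @export
average_power_density <- function(total_power, sheet_width_w, h90) {
  total_power / (sheet_width_w * h90)
}

#' Full metric report for a beam
#'
#' Evaluates the standard characterization metrics at one propagation
#' position. When a detection PSF is supplied, the axial FWHM and OTF support
#' are those of the overall PSF; otherwise they are excitation-only and the
#' support is `NA`.
#'
#' @param stack an `excitation_profile`.
#' @param det optional detection `psf_volume`.
#' @param y propagation position at which to evaluate (must be sampled).
#' @return One-row data frame with columns `evaluated_at_y`, `axial_fwhm`,
#'   `main_lobe_width`, `optical_sectioning`, `otf_support`,
#'   `propagation_fwhm`, `os_doubling_length`, `h90`.
#' @export
beam_metrics <- function(stack, det = NULL, y = 0) {
  prof <- profile_at_y(stack, y)
  if (is.null(det)) {
    fwhm <- axial_fwhm(prof)
    support <- NA_real_
  } else {
    ax <- detection_axial(prof$z)
    fwhm <- axial_fwhm(prof$z, prof$intensity * ax)
    line <- overall_otf_axial(prof, det)
    support <- otf_support(line$frac_4pi, line$amplitude)
  }
  data.frame(
    evaluated_at_y = prof$y,
    axial_fwhm = fwhm,
    main_lobe_width = main_lobe_width(prof),
    optical_sectioning = optical_sectioning(prof),
    otf_support = support,
    propagation_fwhm = propagation_fwhm(onaxis_intensity(stack)),
    os_doubling_length = os_doubling_length(stack),
    h90 = h90(prof)
  )
}
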