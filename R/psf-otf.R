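#' Overall PSF and OTF
#'
#' The overall PSF of a dithered light-sheet microscope is the pixel-wise
#' product of the (laterally uniform) excitation z-profile and the widefield
#' detection PSF; the overall OTF is its Fourier transform, with axes reported
#' both in cycles per wavelength and as fractions of 4*pi/lambda (twice the
#' wave vector, the diameter of the fluorescence-accessible frequency sphere).
#'
#' @name psf-otf
NULL

psf_z_axis <- function(vol) {
  nz <- dim(vol)[3L]
  (seq_len(nz) - (nz / 2 + 1L)) * attr(vol, "spacing")[3L]
}

#' Resample an axial profile onto a new z axis
#'
#' Linear interpolation; the target axis must lie inside the sampled range.
#'
#' @param profile an `axial_profile` (list with `z`, `intensity`).
#' @param z_new target axis.
#' @export
resample_profile <- function(profile, z_new) {
  if (min(z_new) < min(profile$z) - 1e-9 || max(z_new) > max(profile$z) + 1e-9)
    stop("target z axis extends beyond the sampled profile")
  structure(list(z = z_new,
                 intensity = stats::approx(profile$z, profile$intensity,
                                           xout = z_new, rule = 2)$y,
                 y = profile$y),
            class = "axial_profile")
}

#' Overall PSF from an excitation profile and a detection PSF
#'
#' Broadcasts the excitation z-profile (taken at one propagation position)
#' over the lateral axes of the detection volume and multiplies pixel-wise.
#' `z_offset` shifts the excitation sheet along z before multiplying,
#' modelling excitation/detection focal misalignment.
#'
#' @param exc an `axial_profile` (e.g. from [profile_at_y()]); its z sampling
#'   must be at least as fine as the detection volume's (use
#'   [resample_profile()] first otherwise).
#' @param det a detection `psf_volume`.
#' @param z_offset axial misalignment of the sheet, wavelengths.
#' @return A `psf_volume` with `role = "overall"`.
#' @export
overall_psf <- function(exc, det, z_offset = 0) {
  stopifnot(inherits(det, "psf_volume"))
  zd <- psf_z_axis(det)
  dz_exc <- exc$z[2L] - exc$z[1L]
  if (dz_exc > attr(det, "spacing")[3L] + 1e-9)
    stop("excitation profile is sampled coarser than the detection volume; ",
         "resample_profile() it first")
  need <- zd - z_offset
  if (min(need) < min(exc$z) - 1e-9 || max(need) > max(exc$z) + 1e-9)
    stop("excitation profile does not cover the detection z range")
  ez <- stats::approx(exc$z, exc$intensity, xout = need, rule = 2)$y
  vol <- det * rep(ez, each = prod(dim(det)[1:2]))
  structure(vol, spacing = attr(det, "spacing"), role = "overall",
            evaluated_at_y = exc$y, z_offset = z_offset,
            class = c("psf_volume", "array"))
}

#' Overall OTF (Fourier transform of a PSF volume)
#'
#' @param psf a `psf_volume`.
#' @return An `otf_volume`: complex 3D array with DC at the centre and
#'   attributes `freq` (list of axes in cycles per wavelength) and `spacing`.
#' @export
overall_otf <- function(psf) {
  O <- fftshift_nd(stats::fft(ifftshift_nd(unclass(psf))))
  sp <- attr(psf, "spacing")
  d <- dim(psf)
  structure(O,
            freq = list(kx = freq_axis(d[1L], sp[1L]),
                        ky = freq_axis(d[2L], sp[2L]),
                        kz = freq_axis(d[3L], sp[3L])),
            spacing = sp, class = c("otf_volume", "array"))
}

#' Axial line profile of an OTF along k_x = k_y = 0
#'
#' @param otf an `otf_volume`.
#' @return Data frame with `kz` (cycles/wavelength), `frac_4pi` (fraction of
#'   4*pi/lambda, i.e. kz/2), `amplitude`, and `relative` (amplitude / DC).
#' @export
otf_axial_profile <- function(otf) {
  d <- dim(otf)
  cx <- d[1L] %/% 2L + 1L; cy <- d[2L] %/% 2L + 1L; cz <- d[3L] %/% 2L + 1L
  amp <- Mod(otf[cx, cy, ])
  kz <- attr(otf, "freq")$kz
  data.frame(kz = kz, frac_4pi = kz / 2, amplitude = amp,
             relative = amp / amp[cz])
}

#' Axial OTF line computed without forming the 3D transform
#'
#' The value of the 3D OTF on the k_x = k_y = 0 line equals the 1D Fourier
#' transform of the laterally summed PSF. Since the overall PSF is the
#' excitation profile times the detection PSF, this is the transform of
#' exc(z) * D(z), with D the laterally integrated detection intensity. Exact
#' (tested against [overall_otf()]) and far cheaper for line profiles.
#'
#' @inheritParams overall_psf
#' @return Same data frame as [otf_axial_profile()].
#' @export
overall_otf_axial <- function(exc, det, z_offset = 0) {
  zd <- psf_z_axis(det)
  need <- zd - z_offset
  if (min(need) < min(exc$z) - 1e-9 || max(need) > max(exc$z) + 1e-9)
    stop("excitation profile does not cover the detection z range")
  ez <- stats::approx(exc$z, exc$intensity, xout = need, rule = 2)$y
  D <- apply(unclass(det), 3L, sum)
  prod <- ez * D
  amp <- Mod(fftshift_vec(stats::fft(ifftshift_vec(prod))))
  nz <- length(prod)
  kz <- freq_axis(nz, attr(det, "spacing")[3L])
  data.frame(kz = kz, frac_4pi = kz / 2, amplitude = amp,
             relative = amp / amp[nz %/% 2L + 1L])
}

#' Amplitude ratio map of two OTFs
#'
#' `|otf_a| / pmax(|otf_b|, floor)`, with the floor expressed as a fraction of
#' the DC amplitude of `otf_b` so log-scaled displays stay finite.
#'
#' @param otf_a,otf_b `otf_volume`s on identical grids.
#' @param floor relative amplitude floor (fraction of DC of `otf_b`).
#' @return Real array of ratios with the grid attributes of `otf_a`.
#' @export
otf_ratio_map <- function(otf_a, otf_b, floor = 1e-6) {
  if (!identical(dim(otf_a), dim(otf_b))) stop("OTF grids differ")
  d <- dim(otf_b)
  dc <- Mod(otf_b[d[1L] %/% 2L + 1L, d[2L] %/% 2L + 1L, d[3L] %/% 2L + 1L])
  ratio <- Mod(unclass(otf_a)) / pmax(Mod(unclass(otf_b)), floor * dc)
  structure(ratio, freq = attr(otf_a, "freq"), floor = floor * dc)
}
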