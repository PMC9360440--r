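#' Richards-Wolf detection model
#'
#' Widefield detection PSF from the vectorial Richards-Wolf diffraction
#' integrals for an aplanatic objective, with the aperture half-angle set by
#' sin(alpha) = NA / n. Emission is treated as unpolarized: the intensity is
#' the incoherent azimuthal average |I0|^2 + 2|I1|^2 + |I2|^2 of the three
#' annular field integrals. Lengths are in wavelengths in the medium, matching
#' the excitation model, so the index enters only through the aperture angle.
#'
#' @name detection
NULL

# annular field integrals I0, I1, I2 on a (rho, z) grid, by trapezoidal
# quadrature over the aperture angle
rw_integrals <- function(rho, z, na = 1.0, n_index = 1.33, n_theta = 2000L) {
  if (na > n_index) stop("detection NA cannot exceed the medium index")
  alpha <- asin(na / n_index)
  th <- seq(0, alpha, length.out = n_theta)
  w <- rep(1, n_theta); w[c(1L, n_theta)] <- 0.5
  dth <- th[2L] - th[1L]
  ct <- cos(th); st <- sin(th); ap <- sqrt(ct)
  arg <- 2 * pi * outer(rho, st)
  P <- exp(2i * pi * outer(ct, z))                  # n_theta x nz defocus
  I0 <- (besselJ(arg, 0) * rep(ap * st * (1 + ct) * w, each = length(rho))) %*% P
  I1 <- (besselJ(arg, 1) * rep(ap * st^2 * w,        each = length(rho))) %*% P
  I2 <- (besselJ(arg, 2) * rep(ap * st * (1 - ct) * w, each = length(rho))) %*% P
  list(I0 = I0 * dth, I1 = I1 * dth, I2 = I2 * dth)
}

# unpolarized intensity on a (rho, z) grid
rw_intensity <- function(rho, z, na = 1.0, n_index = 1.33, n_theta = 2000L) {
  I <- rw_integrals(rho, z, na, n_index, n_theta)
  Mod(I$I0)^2 + 2 * Mod(I$I1)^2 + Mod(I$I2)^2
}

#' On-axis (defocus) profile of the detection PSF
#'
#' @param z defocus positions in wavelengths.
#' @param na detection numerical aperture.
#' @param n_index refractive index of the medium.
#' @param n_theta quadrature points over the aperture angle.
#' @return Intensity values, normalized to 1 at z = 0.
#' @export
detection_axial <- function(z, na = 1.0, n_index = 1.33, n_theta = 2000L) {
  I <- rw_intensity(0, z, na, n_index, n_theta)[1L, ]
  I / rw_intensity(0, 0, na, n_index, n_theta)[1L, 1L]
}

#' Widefield detection PSF volume
#'
#' Samples the unpolarized Richards-Wolf PSF on a centred (x, y, z) grid by
#' radial interpolation of the (rho, z) quadrature. z is the optical
#' (defocus) axis of the detection objective.
#'
#' @param nx,ny,nz samples per axis (even; origin at n/2 + 1).
#' @param dxy,dz sample spacings in wavelengths.
#' @inheritParams detection_axial
#' @return A `psf_volume`: a 3D array with unit peak, attributes `spacing`
#'   (c(dx, dy, dz)) and `role = "detection"`.
#' @export
detection_psf <- function(nx = 128L, ny = 128L, nz = 256L,
                          dxy = 0.1, dz = 0.1,
                          na = 1.0, n_index = 1.33, n_theta = 2000L) {
  xax <- (seq_len(nx) - (nx / 2 + 1L)) * dxy
  yax <- (seq_len(ny) - (ny / 2 + 1L)) * dxy
  zax <- (seq_len(nz) - (nz / 2 + 1L)) * dz
  rho2 <- outer(xax^2, yax^2, `+`)
  rho_max <- sqrt(max(rho2))
  rho <- seq(0, rho_max + dxy, by = dxy / 2)
  Irz <- rw_intensity(rho, zax, na, n_index, n_theta)
  rr <- sqrt(rho2)
  vol <- array(0, c(nx, ny, nz))
  ri <- pmin(length(rho) - 1L, findInterval(rr, rho))
  frac <- (rr - rho[ri]) / (rho[ri + 1L] - rho[ri])
  for (iz in seq_len(nz)) {
    col <- Irz[, iz]
    vol[, , iz] <- col[ri] * (1 - frac) + col[ri + 1L] * frac
  }
  vol <- vol / max(vol)
  structure(vol, spacing = c(dxy, dxy, dz), role = "detection",
            class = c("psf_volume", "array"))
}

#' @export
print.psf_volume <- function(x, ...) {
  sp <- attr(x, "spacing")
  cat(sprintf("<psf_volume> %s, %s voxels of %s wavelengths, peak %.4g\n",
              attr(x, "role"), paste(dim(x), collapse = " x "),
              paste(signif(sp, 3), collapse = " x "), max(x)))
  invisible(x)
}
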