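#' Fourier plane correlation
#'
#' Resolution statistic for anisotropic 3D imaging: two independently noised
#' acquisitions of the same scene are Fourier transformed, and for each output
#' pixel q in a principal plane the normalized cross-correlation
#' Re(sum F_a conj(F_b)) / sqrt(sum|F_a|^2 sum|F_b|^2) is computed over the
#' plane of 3D frequency samples perpendicular to q through q (samples whose
#' projection onto the unit vector of q lies within half a frequency sample of
#' |q|). The maps for the k_x = 0 and k_y = 0 planes and their average are
#' returned; resolution support is the area where the average exceeds a
#' cutoff (1/7 by default).
#'
#' @name fpc
NULL

# integer frequency coordinates of an FFT axis (DC-centred ordering not
# needed; we use the wrapped layout directly)
fft_int_coords <- function(n) {
  c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
}

# correlation values for all multiples m of one primitive direction
# d = (d1, d2) within one principal plane; J1/J2 are the wrapped integer
# coordinate arrays of the two in-plane axes
ray_correlations <- function(d, J1, J2, re_ab, aa, bb, m_max) {
  L <- sqrt(sum(d^2))
  t <- (J1 * d[1L] + J2 * d[2L]) / L
  m <- round(t / L)
  keep <- abs(t - m * L) <= 0.5 & m != 0L & abs(m) <= m_max
  if (!any(keep)) return(NULL)
  am <- abs(m[keep])
  sums <- rowsum(cbind(re_ab[keep], aa[keep], bb[keep]), am)
  denom <- sqrt(sums[, 2L] * sums[, 3L])
  corr <- ifelse(denom > 0, sums[, 1L] / denom, 0)
  list(m = as.integer(rownames(sums)), corr = corr)
}

fpc_plane_map <- function(ax1, ax2, J1, J2, re_ab, aa, bb) {
  n1 <- ax1; n2 <- ax2
  map <- matrix(NA_real_, n1, n2)
  i1 <- fft_int_coords(n1); i2 <- fft_int_coords(n2)
  # DC-centred pixel coordinates of the output map
  c1 <- sort(i1); c2 <- sort(i2)
  ctr1 <- which(c1 == 0L); ctr2 <- which(c2 == 0L)
  map[ctr1, ctr2] <- 1 # DC convention
  done <- matrix(FALSE, n1, n2)
  done[ctr1, ctr2] <- TRUE
  for (p1 in seq_len(n1)) for (p2 in seq_len(n2)) {
    if (done[p1, p2]) next
    q <- c(c1[p1], c2[p2])
    g <- gcd2(abs(q[1L]), abs(q[2L]))
    d <- q / g
    # canonical sign: first nonzero component positive
    if (d[1L] < 0 || (d[1L] == 0 && d[2L] < 0)) d <- -d
    m_max <- max(abs(c(c1, c2)))
    rc <- ray_correlations(d, J1, J2, re_ab, aa, bb, m_max)
    for (m in seq_len(m_max)) {
      for (sgn in c(1L, -1L)) {
        pix <- sgn * m * d
        j1 <- match(pix[1L], c1); j2 <- match(pix[2L], c2)
        if (is.na(j1) || is.na(j2) || done[j1, j2]) next
        v <- if (!is.null(rc) && m %in% rc$m) rc$corr[match(m, rc$m)] else 0
        map[j1, j2] <- v
        done[j1, j2] <- TRUE
      }
    }
  }
  map
}

gcd2 <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  max(a, 1L)
}

#' Fourier plane correlation maps of two acquisitions
#'
#' @param img_a,img_b same-shape 3D arrays: independently noised realizations
#'   of the same scene.
#' @param voxel voxel size (one number, isotropic), used only to express map
#'   areas in physical frequency units.
#' @return An `fpc_result`: list with the `kx0` and `ky0` plane maps, their
#'   `average`, the map axes in cycles per physical unit, and the frequency
#'   pixel area.
#' @export
fpc_map <- function(img_a, img_b, voxel = 1) {
  if (!identical(dim(img_a), dim(img_b))) stop("image shapes differ")
  if (stats::var(as.vector(img_a)) == 0 || stats::var(as.vector(img_b)) == 0)
    stop("zero-variance image")
  d <- dim(img_a)
  Fa <- stats::fft(unclass(img_a))
  Fb <- stats::fft(unclass(img_b))
  re_ab <- Re(Fa * Conj(Fb))
  aa <- Mod(Fa)^2
  bb <- Mod(Fb)^2
  ix <- fft_int_coords(d[1L]); iy <- fft_int_coords(d[2L])
  iz <- fft_int_coords(d[3L])
  # wrapped-layout 3D integer coordinate arrays for the two in-plane axes
  JY <- array(rep(iy, each = d[1L]), d)
  JZ <- array(rep(iz, each = d[1L] * d[2L]), d)
  JX <- array(ix, d)
  kx0 <- fpc_plane_map(d[2L], d[3L], JY, JZ, re_ab, aa, bb)
  ky0 <- fpc_plane_map(d[1L], d[3L], JX, JZ, re_ab, aa, bb)
  if (!identical(dim(kx0), dim(ky0)))
    stop("principal-plane maps differ in shape; use cubic volumes")
  dnu <- 1 / (d * voxel)
  structure(list(kx0 = kx0, ky0 = ky0, average = (kx0 + ky0) / 2,
                 axis1 = sort(fft_int_coords(d[2L])) * dnu[2L],
                 axis2 = sort(fft_int_coords(d[3L])) * dnu[3L],
                 pixel_area = dnu[2L] * dnu[3L]),
            class = "fpc_result")
}

#' Super-cutoff FPC area
#'
#' Area of the averaged FPC map above the cutoff (1/7 by default), in squared
#' frequency units, with the super-threshold pixel count; optionally
#' normalized by a reference area (e.g. the Gaussian beam at the propagation
#' centre).
#'
#' @param result an `fpc_result`.
#' @param cutoff correlation cutoff.
#' @param reference_area optional area for normalization.
#' @return List with `area`, `n_pixels`, and `relative` (NA when no reference
#'   is given).
#' @export
fpc_area <- function(result, cutoff = 1 / 7, reference_area = NULL) {
  stopifnot(inherits(result, "fpc_result"))
  n <- sum(result$average > cutoff)
  area <- n * result$pixel_area
  list(area = area, n_pixels = n,
       relative = if (is.null(reference_area)) NA_real_
                  else area / reference_area)
}

#' @export
print.fpc_result <- function(x, ...) {
  cat(sprintf("<fpc_result> %d x %d plane maps; super-1/7 pixels: %d\n",
              nrow(x$average), ncol(x$average), sum(x$average > 1 / 7)))
  invisible(x)
}
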