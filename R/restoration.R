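#' Deskew, deconvolution and spectral fusion
#'
#' Restoration steps for stage-scanned light-sheet acquisitions: the shear
#' transform from stage-scan to orthogonal detection coordinates,
#' Richardson-Lucy deconvolution with a convergence-based stopping rule,
#' Wiener filtering, and OTF-weighted spectral fusion of dual-light-sheet
#' acquisitions.
#'
#' @name restoration
NULL

#' Deskew geometry of a stage-scanned acquisition
#'
#' @param angle_deg angle between the sample-stage motion and the detection
#'   optical axis (57.6 degrees in the reference instrument; equivalently
#'   32.4 degrees between the detection image plane and the stage motion).
#' @param stage_step stage step per acquired plane (same units as the pixel
#'   size passed to [deskew()]; 0.2 um by default).
#' @return A `deskew_geometry` with the derived per-plane axial step
#'   `stage_step * cos(angle)` (107 nm at the defaults) and lateral shear
#'   `stage_step * sin(angle)`.
#' @export
deskew_geometry <- function(angle_deg = 57.6, stage_step = 0.2) {
  if (angle_deg <= 0 || angle_deg >= 90) stop("angle must be in (0, 90)")
  a <- angle_deg * pi / 180
  structure(list(angle_deg = angle_deg, stage_step = stage_step,
                 axial_step = stage_step * cos(a),
                 lateral_step = stage_step * sin(a)),
            class = "deskew_geometry")
}

#' Shear a stage-scanned stack into orthogonal coordinates
#'
#' Each plane i of the raw stack (array \[x, y, plane\]) is displaced along x
#' by i * stage_step * sin(angle) relative to the first; deskewing shifts it
#' back by that amount (integer part plus linear or nearest-neighbour
#' interpolation), widening the x axis to hold the sheared extent. The output
#' carries the per-plane axial step as an attribute.
#'
#' @param raw_stack 3D array, planes along the third axis.
#' @param geometry a `deskew_geometry`.
#' @param pixel_size lateral pixel size, same units as `stage_step`.
#' @param interpolation `"linear"` (default) or `"nearest"` for
#'   photometry-critical use.
#' @return Deskewed 3D array with attributes `axial_step` and `pixel_size`.
#' @export
deskew <- function(raw_stack, geometry = deskew_geometry(),
                   pixel_size = 0.1,
                   interpolation = c("linear", "nearest")) {
  stopifnot(inherits(geometry, "deskew_geometry"))
  interpolation <- match.arg(interpolation)
  d <- dim(raw_stack)
  shift_px <- (seq_len(d[3L]) - 1L) * geometry$lateral_step / pixel_size
  nx_out <- d[1L] + ceiling(max(shift_px))
  out <- array(0, c(nx_out, d[2L], d[3L]))
  for (i in seq_len(d[3L])) {
    s <- shift_px[i]
    if (interpolation == "nearest") {
      s0 <- round(s)
      out[s0 + seq_len(d[1L]), , i] <- raw_stack[, , i]
    } else {
      s0 <- floor(s); f <- s - s0
      out[s0 + seq_len(d[1L]), , i] <-
        out[s0 + seq_len(d[1L]), , i] + (1 - f) * raw_stack[, , i]
      out[s0 + 1L + seq_len(d[1L]), , i] <-
        out[s0 + 1L + seq_len(d[1L]), , i] + f * raw_stack[, , i]
    }
  }
  structure(out, axial_step = geometry$axial_step, pixel_size = pixel_size)
}

# reflective padding of a 3D array by `pad` voxels per side (per dimension)
pad_reflect <- function(a, pad) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(i) {
    n <- d[i]; p <- min(pad[i], n - 1L)
    c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Richardson-Lucy deconvolution with convergence stopping
#'
#' Standard multiplicative RL updates with FFT convolutions on a reflectively
#' padded volume (one half PSF support per side, avoiding edge ringing that
#' would contaminate the stopping statistic). The camera dark current is
#' subtracted first and negative pixels clipped to zero. Iteration stops when
#' the root-mean-square difference between neighbouring iterates falls below
#' `convergence_fraction` (default 25%) of the first iteration's RMS
#' difference, so beams with different convergence rates reach the same
#' degree of convergence.
#'
#' @param image non-negative 3D array (after deskewing, for experimental
#'   stacks).
#' @param psf overall PSF; normalized internally to unit sum and
#'   centre-embedded into the padded image grid.
#' @param max_iter iteration cap; exceeding it flags `converged = FALSE`.
#' @param convergence_fraction stopping threshold relative to the first
#'   iteration's RMS update.
#' @param dark_current constant camera offset subtracted before clipping.
#' @param boundary `"reflect"` (default) pads reflectively by half the PSF
#'   support; `"circular"` runs on the raw periodic grid (useful for
#'   comparisons against the literal update formula).
#' @return Deconvolved array with attributes `iterations`, `converged`, and
#'   the per-iteration RMS trace `rms`.
#' @export
rl_deconvolve <- function(image, psf, max_iter = 500L,
                          convergence_fraction = 0.25, dark_current = 0,
                          boundary = c("reflect", "circular")) {
  boundary <- match.arg(boundary)
  img <- pmax(unclass(image) - dark_current, 0)
  d <- dim(img)
  psfv <- unclass(psf) / sum(psf)
  pad <- if (boundary == "reflect") pmin(dim(psfv) %/% 2L, d - 1L)
         else c(0L, 0L, 0L)
  work <- pad_reflect(array(img, d), pad)
  dw <- dim(work)
  K <- stats::fft(ifftshift_nd(pad_or_crop_center(psfv, dw)))
  convK <- function(x, kern) {
    Re(stats::fft(stats::fft(x) * kern, inverse = TRUE)) / length(x)
  }
  eps <- .Machine$double.eps
  est <- work
  rms <- numeric(0)
  converged <- FALSE
  # updates at the level of FFT round-off count as converged (delta-like PSFs
  # reach their fixed point on the first iteration)
  rms_floor <- 1e-10 * sqrt(mean(work^2))
  for (it in seq_len(max_iter)) {
    blur <- pmax(convK(est, K), eps)
    est_new <- est * convK(work / blur, Conj(K))
    rms[it] <- sqrt(mean((est_new - est)^2))
    est <- est_new
    if (rms[it] <= rms_floor || rms[it] < convergence_fraction * rms[1L]) {
      converged <- TRUE
      break
    }
  }
  core <- est[pad[1L] + seq_len(d[1L]), pad[2L] + seq_len(d[2L]),
              pad[3L] + seq_len(d[3L]), drop = FALSE]
  structure(array(core, d), iterations = length(rms), converged = converged,
            rms = rms)
}

#' Wiener deconvolution
#'
#' Frequency-space filter conj(H) / (|H|^2 + NSR) with a constant
#' noise-to-signal ratio (0.005 for all conditions in the reference study).
#'
#' @param image 3D array.
#' @param psf overall PSF (normalized internally to unit sum).
#' @param nsr constant noise-to-signal power ratio.
#' @return Real-valued filtered array.
#' @export
wiener_deconvolve <- function(image, psf, nsr = 0.005) {
  if (nsr < 0) stop("nsr must be >= 0")
  d <- dim(image)
  H <- stats::fft(ifftshift_nd(pad_or_crop_center(unclass(psf) / sum(psf), d)))
  G <- stats::fft(unclass(image)) * Conj(H) / (Mod(H)^2 + nsr)
  Re(stats::fft(G, inverse = TRUE)) / length(image)
}

#' OTF-weighted spectral fusion of two acquisitions
#'
#' Fuses two images of the same scene taken with complementary light sheets.
#' Both spectra are normalized by their DC amplitude, then combined with
#' convex weights O_a/(O_a + O_b) and O_b/(O_a + O_b) given by the OTF
#' amplitudes of the two beams, filling the OTF dips of one beam with support
#' from the other; frequencies where both OTFs vanish get equal weights. The
#' result is inverse transformed and rescaled so its DC equals the mean of
#' the two input DC amplitudes.
#'
#' @param img_a,img_b same-shape 3D arrays of the same scene.
#' @param otf_a,otf_b OTF amplitude volumes on the image grid (DC-centred,
#'   e.g. `Mod()` of [overall_otf()] output, or `otf_volume`s directly).
#' @return Fused real-valued array.
#' @export
spectral_fuse <- function(img_a, img_b, otf_a, otf_b) {
  d <- dim(img_a)
  if (!identical(d, dim(img_b))) stop("image grids differ")
  oa <- ifftshift_nd(pad_or_crop_center(Mod(unclass(otf_a)), d))
  ob <- ifftshift_nd(pad_or_crop_center(Mod(unclass(otf_b)), d))
  oa <- oa / oa[1L]; ob <- ob / ob[1L]
  Fa <- stats::fft(unclass(img_a)); Fb <- stats::fft(unclass(img_b))
  dca <- Mod(Fa[1L]); dcb <- Mod(Fb[1L])
  Fa <- Fa / Fa[1L]; Fb <- Fb / Fb[1L]
  s <- oa + ob
  wa <- ifelse(s > 0, oa / pmax(s, .Machine$double.xmin), 0.5)
  fused <- Fa * wa + Fb * (1 - wa)
  Re(stats::fft(fused, inverse = TRUE)) / length(fused) * mean(c(dca, dcb))
}
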