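#' Synthetic point-emitter imaging
#'
#' Ground-truth volumes of randomly placed point emitters and their rendering
#' into noisy acquisitions: a constant background (the autofluorescence
#' pedestal) is added to the ground truth, the volume is convolved with a
#' Poisson-noised copy of the overall PSF, and Poisson noise is applied to the
#' result. Noise is sampled independently for every image/PSF pair so that
#' paired renders of the same scene are valid Fourier-plane-correlation
#' inputs.
#'
#' @name synthetic-imaging
NULL

#' Generate a random point-emitter volume
#'
#' Draws a Poisson number of emitters at the requested density, places them
#' uniformly at random, and snaps them to voxel centres (several emitters may
#' share a voxel).
#'
#' @param density emitters per cubic micron.
#' @param volume_um physical extents c(x, y, z) in microns.
#' @param voxel_um isotropic voxel size in microns.
#' @param brightness expected photon count per emitter.
#' @param seed RNG seed (reproducible for a fixed seed).
#' @return An `emitter_volume`: 3D array of expected counts with attributes
#'   `density`, `voxel_um`, `brightness`, `n_emitters`, `seed`.
#' @export
generate_emitters <- function(density, volume_um = c(6.4, 6.4, 6.4),
                              voxel_um = 0.1, brightness = 1000,
                              seed = NULL) {
  if (density < 0) stop("density must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dims <- as.integer(round(volume_um / voxel_um))
  n <- if (density == 0) 0L else stats::rpois(1L, density * prod(volume_um))
  vol <- array(0, dims)
  if (n > 0L) {
    ix <- sample.int(dims[1L], n, replace = TRUE)
    iy <- sample.int(dims[2L], n, replace = TRUE)
    iz <- sample.int(dims[3L], n, replace = TRUE)
    idx <- ix + dims[1L] * (iy - 1L + dims[2L] * (iz - 1L))
    counts <- tabulate(idx, nbins = prod(dims))
    vol <- array(counts * brightness, dims)
  }
  structure(vol, density = density, voxel_um = voxel_um,
            brightness = brightness, n_emitters = n, seed = seed,
            class = c("emitter_volume", "array"))
}

# centre-crop or zero-pad `a` to dimensions `d`, keeping the centre voxel
# (n/2 + 1 convention) fixed
pad_or_crop_center <- function(a, d) {
  da <- dim(a)
  out <- array(0, d)
  ctr_a <- da %/% 2L + 1L
  ctr_o <- d %/% 2L + 1L
  lo <- pmax(1L, ctr_a - (ctr_o - 1L))
  hi <- pmin(da, ctr_a + (d - ctr_o))
  olo <- ctr_o - (ctr_a - lo)
  ohi <- olo + (hi - lo)
  out[olo[1L]:ohi[1L], olo[2L]:ohi[2L], olo[3L]:ohi[3L]] <-
    a[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
  out
}

#' Noise-free expectation of a rendered acquisition
#'
#' Ground truth plus the constant background, convolved with the (noise-free)
#' PSF. The background is chosen so that the peak signal of an isolated
#' emitter divided by the rendered background equals `sbr`.
#'
#' @param emitters an `emitter_volume`.
#' @param psf overall PSF (`psf_volume` or plain array); centre-cropped or
#'   padded to the emitter volume and normalized to unit peak.
#' @param sbr signal-to-background ratio (> 0; `Inf` for no background).
#' @export
expected_image <- function(emitters, psf, sbr = 3) {
  if (sbr <= 0) stop("sbr must be > 0")
  psfv <- pad_or_crop_center(unclass(psf) / max(psf), dim(emitters))
  brightness <- attr(emitters, "brightness")
  bg <- if (is.infinite(sbr)) 0 else brightness / (sbr * sum(psfv))
  conv_fft(unclass(emitters) + bg, psfv)
}

#' Render a pair of independently noised acquisitions
#'
#' Renders the same ground truth twice with independent Poisson noise on both
#' the PSF (before convolution) and the image (after convolution), per seed.
#'
#' @inheritParams expected_image
#' @param seed_pair two RNG seeds, one per realization.
#' @param psf_counts peak count scale at which the PSF is Poisson-noised
#'   (mimicking an experimentally measured PSF).
#' @param psf_noise,image_noise enable the two noise sources.
#' @return List of two `simulated_image`s (non-negative integer arrays with
#'   provenance attributes).
#' @export
render_volume <- function(emitters, psf, sbr = 3, seed_pair = c(1L, 2L),
                          psf_counts = 1000, psf_noise = TRUE,
                          image_noise = TRUE) {
  if (sbr <= 0) stop("sbr must be > 0")
  psfv <- pad_or_crop_center(unclass(psf) / max(psf), dim(emitters))
  brightness <- attr(emitters, "brightness")
  bg <- if (is.infinite(sbr)) 0 else brightness / (sbr * sum(psfv))
  truth <- unclass(emitters) + bg
  lapply(seed_pair, function(s) {
    set.seed(s)
    p <- if (psf_noise) {
      array(stats::rpois(length(psfv), psfv * psf_counts) / psf_counts,
            dim(psfv))
    } else psfv
    expect <- pmax(conv_fft(truth, p), 0)
    img <- if (image_noise) {
      array(stats::rpois(length(expect), expect), dim(expect))
    } else expect
    structure(img, seed = s, sbr = sbr, background = bg,
              voxel_um = attr(emitters, "voxel_um"),
              class = c("simulated_image", "array"))
  })
}
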