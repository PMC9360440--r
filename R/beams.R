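#' Pupil sampling grid
#'
#' Square grid of pupil coordinates (k_x, k_z) in numerical-aperture units,
#' spanning `[-k_max, k_max]` on both axes with an odd number of samples so a
#' sample sits exactly at the origin.
#'
#' @param n odd number of samples per axis (default 1025, giving
#'   dk ~ 1.95e-3 over \[-1, 1\]).
#' @param k_max half-extent of the grid in NA units.
#' @return An object of class `pupil_grid` with elements `n`, `dk`, `k`
#'   (the shared axis for k_x and k_z).
#' @export
pupil_grid <- function(n = 1025L, k_max = 1) {
  n <- as.integer(n)
  if (n < 3L || n %% 2L == 0L) stop("`n` must be an odd integer >= 3")
  if (k_max <= 0) stop("`k_max` must be positive")
  k <- seq(-k_max, k_max, length.out = n)
  structure(list(n = n, dk = k[2L] - k[1L], k = k, k_max = k_max),
            class = "pupil_grid")
}

#' Light-sheet beam specification
#'
#' Parameters defining one of the four supported beam types.
#'
#' @param beam_type one of `"gaussian"`, `"flat_top"`, `"mb_square"`,
#'   `"hexagonal"`.
#' @param na Gaussian 1/e-amplitude NA or flat-top hard-cutoff NA.
#' @param na_max,na_min outer and inner NA of the bounding annulus
#'   (lattice beams).
#' @param fill_factor dimensionless fill factor FC of the hexagonal beamlet
#'   envelope (default 1).
#' @param side_beamlet_kx k_x position of the 90/270-degree MB-square
#'   beamlets in NA units, or `"auto"` to place them on the first grid column
#'   outside the inner annulus.
#' @param amplitude_scale peak pupil amplitude E0 (arbitrary units).
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(beam_type = c("gaussian", "flat_top", "mb_square", "hexagonal"),
                      na = NULL, na_max = NULL, na_min = NULL,
                      fill_factor = 1, side_beamlet_kx = "auto",
                      amplitude_scale = 1) {
  beam_type <- match.arg(beam_type)
  if (beam_type %in% c("gaussian", "flat_top")) {
    if (is.null(na) || na <= 0 || na > 1)
      stop("gaussian/flat_top beams need 0 < na <= 1")
  } else {
    if (is.null(na_max) || is.null(na_min) ||
        !(na_min > 0 && na_min < na_max && na_max <= 1))
      stop("lattice beams need 0 < na_min < na_max <= 1")
    if (beam_type == "hexagonal" && (!is.numeric(fill_factor) || fill_factor <= 0))
      stop("hexagonal beams need fill_factor > 0")
    if (is.numeric(side_beamlet_kx) && side_beamlet_kx < na_min)
      stop("side_beamlet_kx must be >= na_min")
  }
  structure(list(beam_type = beam_type, na = na, na_max = na_max,
                 na_min = na_min, fill_factor = fill_factor,
                 side_beamlet_kx = side_beamlet_kx,
                 amplitude_scale = amplitude_scale),
            class = "beam_spec")
}

new_pupil_field <- function(field, grid, annulus = "none", spec = NULL) {
  structure(list(field = field, grid = grid, annulus = annulus, spec = spec),
            class = "pupil_field")
}

#' @export
print.pupil_field <- function(x, ...) {
  ann <- if (identical(x$annulus, "none")) "none"
         else sprintf("[%.3g, %.3g]", x$annulus[1L], x$annulus[2L])
  cat(sprintf("<pupil_field> %d x %d grid, dk = %.4g, annulus %s, energy %.4g\n",
              x$grid$n, x$grid$n, x$grid$dk, ann, pupil_energy(x)))
  invisible(x)
}

#' Total pupil energy sum(|field|^2) * dk^2
#' @param pupil a `pupil_field`.
#' @export
pupil_energy <- function(pupil) {
  sum(Mod(pupil$field)^2) * pupil$grid$dk^2
}

# index of the grid sample at k = 0
grid_origin <- function(grid) (grid$n + 1L) / 2L

#' Gaussian light-sheet pupil
#'
#' Real-valued Gaussian amplitude along the single column k_x = 0, with
#' amplitude `E0 * exp(-(k_z/NA)^2)` so the field drops to E0/e at
#' `k_z = NA`. Gaussian beams bypass the SLM/mask chain.
#'
#' @param spec a `beam_spec` with `beam_type = "gaussian"`.
#' @param grid a `pupil_grid`.
#' @return A `pupil_field`.
#' @export
gaussian_pupil <- function(spec, grid = pupil_grid()) {
  stopifnot(inherits(spec, "beam_spec"), inherits(grid, "pupil_grid"))
  if (spec$beam_type != "gaussian") stop("spec is not a gaussian beam")
  f <- matrix(0, grid$n, grid$n) # rows k_z, cols k_x
  f[, grid_origin(grid)] <- spec$amplitude_scale * exp(-(grid$k / spec$na)^2)
  new_pupil_field(f + 0i, grid, "none", spec)
}

#' Flat-top light-sheet pupil
#'
#' Constant real amplitude E0 for |k_z| <= NA on the column k_x = 0.
#'
#' @inheritParams gaussian_pupil
#' @export
flat_top_pupil <- function(spec, grid = pupil_grid()) {
  stopifnot(inherits(spec, "beam_spec"), inherits(grid, "pupil_grid"))
  if (spec$beam_type != "flat_top") stop("spec is not a flat_top beam")
  if (spec$na > grid$k_max) stop("cutoff NA exceeds the grid extent")
  f <- matrix(0, grid$n, grid$n)
  f[abs(grid$k) <= spec$na, grid_origin(grid)] <- spec$amplitude_scale
  new_pupil_field(f + 0i, grid, "none", spec)
}

# resolve the "auto" MB-square side-beamlet position: first grid column
# strictly outside the inner annulus
resolve_side_kx <- function(spec, grid) {
  if (identical(spec$side_beamlet_kx, "auto")) {
    cand <- grid$k[grid$k > spec$na_min]
    if (!length(cand)) stop("no grid column outside the inner annulus")
    cand[1L]
  } else {
    spec$side_beamlet_kx
  }
}

#' Multi-Bessel square-lattice pupil (ideal, pre-SLM)
#'
#' Four real-valued constant-amplitude beamlets: the 0/180-degree pair lies on
#' the column k_x = 0, extended along k_z and cropped radially to the annulus
#' `[na_min, na_max]`; the 90/270-degree pair lies on columns
#' k_x = +/- `side_beamlet_kx` (just outside the inner annulus when `"auto"`)
#' and is extended along k_z to the radial chord of the outer annulus. This
#' geometry gives all four beamlets the same spread of the propagation
#' component k_y, hence the same propagation length.
#'
#' @inheritParams gaussian_pupil
#' @export
mb_square_pupil <- function(spec, grid = pupil_grid()) {
  stopifnot(inherits(spec, "beam_spec"), inherits(grid, "pupil_grid"))
  if (spec$beam_type != "mb_square") stop("spec is not an mb_square beam")
  kxs <- resolve_side_kx(spec, grid)
  if (kxs > spec$na_max) stop("side beamlets fall outside the outer annulus")
  f <- matrix(0, grid$n, grid$n)
  o <- grid_origin(grid)
  f[abs(grid$k) >= spec$na_min & abs(grid$k) <= spec$na_max, o] <-
    spec$amplitude_scale
  side <- as.numeric(abs(grid$k) <= sqrt(spec$na_max^2 - kxs^2)) *
    spec$amplitude_scale
  for (kx in c(-kxs, kxs)) {
    j <- which.min(abs(grid$k - kx))
    f[, j] <- f[, j] + side
  }
  new_pupil_field(f + 0i, grid, "none", spec)
}

#' Hexagonal-lattice pupil (ideal, pre-SLM)
#'
#' Six beamlets centred on the circle of radius `(na_max + na_min)/2`: two on
#' the k_z axis and four at +/-60 degrees of azimuth from it. Each beamlet is a
#' single-column stripe with a Gaussian k_z intensity envelope whose full 1/e
#' width is `dkz = fill_factor * (na_max - na_min)` (field amplitude
#' `E0 * exp(-2 ((k_z - c)/dkz)^2)`), confined radially to the annulus.
#'
#' @inheritParams gaussian_pupil
#' @export
hexagonal_pupil <- function(spec, grid = pupil_grid()) {
  stopifnot(inherits(spec, "beam_spec"), inherits(grid, "pupil_grid"))
  if (spec$beam_type != "hexagonal") stop("spec is not a hexagonal beam")
  dkz <- spec$fill_factor * (spec$na_max - spec$na_min)
  if (dkz <= 0) stop("degenerate beamlet envelope: dkz = 0")
  r <- (spec$na_max + spec$na_min) / 2
  f <- matrix(0, grid$n, grid$n)
  centers <- list(c(0, r), c(0, -r)) # (k_x, k_z) of the on-axis pair
  for (sx in c(-1, 1)) for (sz in c(-1, 1)) {
    centers[[length(centers) + 1L]] <- c(sx * r * sin(pi / 3), sz * r * cos(pi / 3))
  }
  for (ctr in centers) {
    j <- which.min(abs(grid$k - ctr[1L]))
    f[, j] <- f[, j] +
      spec$amplitude_scale * exp(-2 * ((grid$k - ctr[2L]) / dkz)^2)
  }
  kr <- sqrt(outer(grid$k^2, grid$k^2, `+`)) # rows k_z, cols k_x
  f[kr < spec$na_min | kr > spec$na_max] <- 0
  new_pupil_field(f + 0i, grid, "none", spec)
}

#' SLM real-part step and annular mask
#'
#' Models the experimental beam-forming chain for lattice beams: the ideal
#' pupil is Fourier transformed to the sample plane, only the real part of the
#' field is kept (the spatial light modulator displays a zero/pi phase
#' pattern), the result is transformed back to the pupil, and an annular mask
#' zeroes all samples with radius outside `[na_min, na_max]` (blocking the DC
#' component). Gaussian and flat-top beams bypass this step.
#'
#' @param pupil a `pupil_field` from [mb_square_pupil()] or
#'   [hexagonal_pupil()].
#' @param annulus length-2 numeric `(na_min, na_max)`; defaults to the
#'   annulus recorded in the beam spec.
#' @return A masked `pupil_field` whose energy does not exceed the input's.
#' @export
slm_and_mask <- function(pupil, annulus = NULL) {
  stopifnot(inherits(pupil, "pupil_field"))
  if (is.null(annulus)) {
    if (is.null(pupil$spec) || is.null(pupil$spec$na_min))
      stop("no annulus given and none recorded in the beam spec")
    annulus <- c(pupil$spec$na_min, pupil$spec$na_max)
  }
  if (annulus[2L] > pupil$grid$k_max) stop("annulus extends beyond the grid")
  if (max(abs(Im(pupil$field))) > 1e-8 * max(Mod(pupil$field)))
    stop("pupil must be real-valued before the SLM step")
  n <- pupil$grid$n
  dk <- pupil$grid$dk
  focal <- ft_centered_2d(pupil$field, n + 1L, dk) # even pad for speed
  focal <- Re(focal) + 0i                          # SLM keeps the real part
  back <- ift_centered_2d(focal, n, dk)
  kr <- sqrt(outer(pupil$grid$k^2, pupil$grid$k^2, `+`))
  back[kr < annulus[1L] | kr > annulus[2L]] <- 0
  new_pupil_field(back, pupil$grid, annulus, pupil$spec)
}

#' Synthesize the final pupil for a beam specification
#'
#' Dispatches on the beam type and applies the SLM + annular-mask chain for
#' lattice beams (Gaussian and flat-top bypass it).
#'
#' @inheritParams gaussian_pupil
#' @param apply_slm apply the SLM/mask chain to lattice beams (default TRUE).
#' @export
beam_pupil <- function(spec, grid = pupil_grid(), apply_slm = TRUE) {
  p <- switch(spec$beam_type,
    gaussian  = gaussian_pupil(spec, grid),
    flat_top  = flat_top_pupil(spec, grid),
    mb_square = mb_square_pupil(spec, grid),
    hexagonal = hexagonal_pupil(spec, grid))
  if (apply_slm && spec$beam_type %in% c("mb_square", "hexagonal")) {
    p <- slm_and_mask(p)
  }
  p
}

#' The three default 20-micron-class beams
#'
#' Gaussian NA 0.21, MB-square lattice NA 0.35/0.25 with auto side-beamlet
#' spacing, and hexagonal lattice NA 0.46/0.36 with fill factor 1.
#'
#' @return Named list of `beam_spec` objects.
#' @export
default_beams <- function() {
  list(
    gaussian  = beam_spec("gaussian", na = 0.21),
    mb_square = beam_spec("mb_square", na_max = 0.35, na_min = 0.25),
    hexagonal = beam_spec("hexagonal", na_max = 0.46, na_min = 0.36,
                          fill_factor = 1)
  )
}
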