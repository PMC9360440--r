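#' Propagation and dithering
#'
#' Pupil coordinates are NA units; the propagation model converts them to
#' direction sines s = k / n_medium (n_medium = 1.33 for aqueous samples), so
#' the defocus component is k_y = sqrt(1 - s^2) and all real-space distances
#' come out in units of the wavelength in the medium. The defocus phase
#' exp(2*pi*i*k_y*y) is applied at the pupil before transforming to the
#' sample plane.
#'
#' @name propagation
NULL

# per-sample defocus factor matrix for the full pupil (rows k_z, cols k_x)
defocus_matrix <- function(grid, y, n_medium) {
  s2 <- outer(grid$k^2, grid$k^2, `+`) / n_medium^2
  ky <- sqrt(pmax(0, 1 - s2))
  ph <- exp(2i * pi * ky * y)
  ph[s2 > 1] <- 0 # evanescent: amplitude forced to zero
  ph
}

#' Propagate a pupil field to a plane y along the sheet axis
#'
#' Multiplies the pupil by the defocus phase exp(2*pi*i*k_y*y) and Fourier
#' transforms to the sample plane. Energy is independent of y (Parseval).
#'
#' @param pupil a `pupil_field`.
#' @param y propagation offset from the beam focus, in wavelengths (in the
#'   imaging medium); any sign.
#' @param n_medium refractive index converting NA-unit pupil coordinates to
#'   direction sines.
#' @param pad_factor real-space oversampling: the transform is zero-padded to
#'   the next even multiple `pad_factor * n`.
#' @return A `focal_field` with complex field over (z, x) (rows z, columns x)
#'   and centred axes in wavelength units.
#' @export
propagate_to_y <- function(pupil, y, n_medium = 1.33, pad_factor = 1) {
  stopifnot(inherits(pupil, "pupil_field"))
  grid <- pupil$grid
  ds <- grid$dk / n_medium
  n_pad <- grid$n * pad_factor
  if (n_pad %% 2L == 1L) n_pad <- n_pad + 1L
  f <- pupil$field * defocus_matrix(grid, y, n_medium)
  field <- ft_centered_2d(f, n_pad, ds)
  ax <- ft_axis(n_pad, ds)
  structure(list(field = field, z = ax, x = ax, y = y,
                 ds = ds, n_medium = n_medium),
            class = "focal_field")
}

#' Dither average of a focal field
#'
#' Squares the field to intensity and averages along x, modelling the rapid
#' lateral dithering that turns a lattice into a uniform sheet. For pupils
#' confined to the single column k_x = 0 the result equals any single x slice.
#'
#' @param field a `focal_field` (or a list of them, one per y; a list returns
#'   a matrix with one column per element).
#' @return An `axial_profile` (list with `z`, `intensity`, `y`) or, for a
#'   list input, a z-by-y intensity matrix.
#' @export
dither_average <- function(field) {
  if (is.list(field) && !inherits(field, "focal_field")) {
    if (!length(field)) stop("empty field stack")
    profs <- vapply(field, function(f) dither_average(f)$intensity,
                    numeric(length(field[[1L]]$z)))
    return(profs)
  }
  stopifnot(inherits(field, "focal_field"))
  structure(list(z = field$z,
                 intensity = rowMeans(Mod(field$field)^2),
                 y = field$y),
            class = "axial_profile")
}

# --- sparse-column fast path -------------------------------------------------
#
# Every supported pupil occupies a handful of k_x columns (one for Gaussian /
# flat-top, three for the lattices after masking). The x-average of the
# intensity then separates exactly into a sum over columns of |FT_kz(column)|^2
# (cross terms between distinct k_x carriers vanish under the x average), so
# dithered profiles can be computed from padded 1D transforms at a fraction of
# the 2D cost. Columns below `tol` of the peak column energy are dropped.
sparse_columns <- function(pupil, tol = 1e-12) {
  en <- colSums(Mod(pupil$field)^2)
  keep <- which(en > tol * max(en))
  lapply(keep, function(j) list(kx = pupil$grid$k[j], col = pupil$field[, j]))
}

dithered_profile_sparse <- function(cols, grid, y, n_medium, n_pad) {
  ds <- grid$dk / n_medium
  origin <- grid_origin(grid)
  intensity <- numeric(n_pad)
  for (cl in cols) {
    s2 <- (cl$kx^2 + grid$k^2) / n_medium^2
    ky <- sqrt(pmax(0, 1 - s2))
    v <- cl$col * exp(2i * pi * ky * y)
    v[s2 > 1] <- 0
    intensity <- intensity + Mod(ft_centered_1d(v, origin, n_pad, ds))^2
  }
  intensity
}

#' Dithered excitation profile over a grid of propagation positions
#'
#' Synthesizes the pupil for `spec` (applying the SLM/mask chain for lattice
#' beams), propagates it to every requested y, forms the intensity and
#' averages along x. The y grid must contain 0: the focal profile anchors the
#' normalization.
#'
#' @param spec a `beam_spec` or an already-built `pupil_field`.
#' @param y numeric vector of propagation positions (wavelengths); must
#'   include 0.
#' @param grid pupil grid (ignored when `spec` is a `pupil_field`).
#' @param n_medium refractive index of the sample medium.
#' @param pad_factor zero-padding factor for the z axis; the default 16 gives
#'   dz ~ 0.031 wavelengths on the default grid.
#' @param normalize scale so the peak of the y = 0 profile is 1.
#' @return An `excitation_profile`: a z-by-y intensity matrix with attributes
#'   `z`, `y` (axes in wavelengths) and `normalized`.
#' @export
excitation_stack <- function(spec, y = seq(-48, 48, by = 0.5),
                             grid = pupil_grid(), n_medium = 1.33,
                             pad_factor = 16, normalize = TRUE) {
  if (!any(y == 0)) stop("the y grid must include 0 (the beam focus)")
  pupil <- if (inherits(spec, "pupil_field")) spec else beam_pupil(spec, grid)
  grid <- pupil$grid
  n_pad <- grid$n * pad_factor
  if (n_pad %% 2L == 1L) n_pad <- n_pad + 1L
  cols <- sparse_columns(pupil)
  prof <- vapply(y, function(yy) {
    dithered_profile_sparse(cols, grid, yy, n_medium, n_pad)
  }, numeric(n_pad))
  if (normalize) prof <- prof / max(prof[, which(y == 0)[1L]])
  structure(prof, z = ft_axis(n_pad, grid$dk / n_medium), y = y,
            n_medium = n_medium, normalized = normalize,
            class = "excitation_profile")
}

#' Extract the axial profile of an excitation stack at one y position
#'
#' @param stack an `excitation_profile`.
#' @param y requested position; the nearest sampled column is returned (an
#'   error if no column lies within half a y step).
#' @return An `axial_profile`.
#' @export
profile_at_y <- function(stack, y = 0) {
  stopifnot(inherits(stack, "excitation_profile"))
  ys <- attr(stack, "y")
  j <- which.min(abs(ys - y))
  step <- if (length(ys) > 1L) max(diff(sort(ys))) else Inf
  if (abs(ys[j] - y) > step / 2 + 1e-9)
    stop("no sampled y position near ", y)
  structure(list(z = attr(stack, "z"), intensity = stack[, j], y = ys[j]),
            class = "axial_profile")
}

#' On-axis (z = 0) intensity of an excitation stack as a function of y
#'
#' @param stack an `excitation_profile`.
#' @return A data frame with columns `y` and `intensity`.
#' @export
onaxis_intensity <- function(stack) {
  stopifnot(inherits(stack, "excitation_profile"))
  z <- attr(stack, "z")
  data.frame(y = attr(stack, "y"), intensity = stack[which.min(abs(z)), ])
}

#' @export
print.excitation_profile <- function(x, ...) {
  cat(sprintf("<excitation_profile> %d z-samples (dz = %.4g) x %d y-positions\n",
              nrow(x), attr(x, "z")[2L] - attr(x, "z")[1L], ncol(x)))
  invisible(x)
}
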