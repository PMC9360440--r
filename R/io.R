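#' Volume I/O
#'
#' Multi-page TIFF interchange for 3D volumes: 32-bit float pages for fields,
#' PSFs and OTF amplitudes, 16-bit unsigned pages for simulated camera images.
#' The array axis order is (x, y, z) with one page per z; voxel sizes, axis
#' names and the storage dtype travel in a JSON sidecar (`<path>.json`), and
#' a round trip reproduces the stored values exactly at the stored precision.
#'
#' @name volume-io
NULL

#' Write a 3D volume as multi-page TIFF plus JSON sidecar
#'
#' @param volume 3D numeric array (axis order x, y, z).
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @param dtype `"float32"` (default) or `"uint16"` (values must be
#'   non-negative integers below 2^16).
#' @param spacing voxel sizes c(dx, dy, dz) recorded in the sidecar.
#' @param metadata optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dtype = c("float32", "uint16"),
                         spacing = attr(volume, "spacing"),
                         metadata = list()) {
  dtype <- match.arg(dtype)
  if (length(dim(volume)) == 2L) dim(volume) <- c(dim(volume), 1L)
  if (length(dim(volume)) != 3L) stop("volume must be a 2D or 3D array")
  d <- dim(volume)
  # TIFF pages hold [0, 1] samples; float32 volumes are affinely normalized
  # and the offset/scale recorded in the sidecar for exact reconstruction
  offset <- 0; scale <- 1
  if (dtype == "float32") {
    rng <- range(volume)
    offset <- rng[1L]
    scale <- diff(rng)
    if (scale == 0) scale <- 1
  } else if (any(volume < 0) || any(volume > 65535) ||
             any(volume != round(volume))) {
    stop("uint16 volumes must hold integers in [0, 65535]")
  }
  pages <- lapply(seq_len(d[3L]), function(i) {
    m <- matrix(volume[, , i], d[1L], d[2L])
    if (dtype == "uint16") m / 65535 else (m - offset) / scale
  })
  bits <- if (dtype == "uint16") 16L else 32L
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  side <- c(list(dtype = dtype, dim = d, axes = c("x", "y", "z"),
                 offset = offset, scale = scale,
                 spacing = if (is.null(spacing)) NA else spacing),
            metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path.
#' @return 3D array with attributes `spacing` (when recorded) and `sidecar`
#'   (the parsed sidecar list, or NULL if absent).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- NULL
  sp <- paste0(path, ".json")
  if (file.exists(sp)) side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  d <- c(dim(pages[[1L]]), length(pages))
  vol <- array(0, d)
  for (i in seq_along(pages)) vol[, , i] <- pages[[i]]
  if (!is.null(side) && identical(side$dtype, "uint16")) {
    vol <- round(vol * 65535)
  } else if (!is.null(side) && identical(side$dtype, "float32")) {
    vol <- vol * side$scale + side$offset
  }
  structure(vol,
            spacing = if (!is.null(side) && !all(is.na(side$spacing)))
              side$spacing else NULL,
            sidecar = side)
}
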