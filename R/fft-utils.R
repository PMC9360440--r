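#' Centered FFT helpers
#'
#' Internal utilities implementing origin-centered discrete Fourier transforms:
#' the frequency origin of every pupil/OTF array lives at the array centre, and
#' the real-space origin of every field/PSF array lives at the array centre.
#' Forward transforms map pupil -> sample plane throughout the package.
#'
#' @name fft-utils
#' @keywords internal
NULL

fftshift_vec <- function(x) {
  n <- length(x)
  p <- ceiling(n / 2)
  c(x[(p + 1L):n], x[1L:p])
}

ifftshift_vec <- function(x) {
  n <- length(x)
  p <- floor(n / 2)
  c(x[(p + 1L):n], x[1L:p])
}

shift_indices <- function(n, inverse = FALSE) {
  p <- if (inverse) floor(n / 2) else ceiling(n / 2)
  c((p + 1L):n, 1L:p)
}

fftshift_nd <- function(a, inverse = FALSE) {
  d <- dim(a)
  if (is.null(d)) {
    return(if (inverse) ifftshift_vec(a) else fftshift_vec(a))
  }
  idx <- lapply(d, shift_indices, inverse = inverse)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

ifftshift_nd <- function(a) fftshift_nd(a, inverse = TRUE)

#' Centered 1D transform of a pupil column with zero padding
#'
#' `values` are samples on a frequency axis whose origin sits at index
#' `origin`. Returns the complex field on a centred real-space axis of length
#' `n_pad` (even), with spacing `1 / (n_pad * df)`.
#'
#' @keywords internal
ft_centered_1d <- function(values, origin, n_pad, df) {
  n <- length(values)
  stopifnot(n_pad >= n, n_pad %% 2L == 0L)
  buf <- complex(length.out = n_pad)
  buf[seq_len(n)] <- values
  # rotate so the frequency origin lands on FFT index 1 (wrapped layout)
  buf <- c(buf[origin:n_pad], if (origin > 1L) buf[1L:(origin - 1L)])
  f <- stats::fft(buf)
  fftshift_vec(f) * df
}

#' Real-space axis matching [ft_centered_1d()]
#' @keywords internal
ft_axis <- function(n_pad, df) {
  dz <- 1 / (n_pad * df)
  (seq_len(n_pad) - (n_pad / 2 + 1L)) * dz
}

# embed an odd-sized centred matrix into an n_pad^2 wrapped-layout buffer
pad_center_wrap <- function(m, n_pad) {
  d <- dim(m)
  ctr <- (d + 1L) / 2L
  buf <- matrix(complex(length.out = n_pad^2), n_pad, n_pad)
  ri <- ((seq_len(d[1L]) - ctr[1L]) %% n_pad) + 1L
  ci <- ((seq_len(d[2L]) - ctr[2L]) %% n_pad) + 1L
  buf[ri, ci] <- m
  buf
}

#' Centered 2D transform of a pupil matrix
#' @keywords internal
ft_centered_2d <- function(m, n_pad, df) {
  buf <- pad_center_wrap(m, n_pad)
  fftshift_nd(stats::fft(buf)) * df^2
}

#' Inverse centred 2D transform back to a pupil-sized matrix
#' @keywords internal
ift_centered_2d <- function(f, n_out, df) {
  n_pad <- dim(f)[1L]
  buf <- stats::fft(ifftshift_nd(f), inverse = TRUE) / (n_pad^2 * df^2)
  ctr <- (n_out + 1L) / 2L
  ri <- ((seq_len(n_out) - ctr) %% n_pad) + 1L
  buf[ri, ri]
}

# frequency axis of an FFT of length n with sample spacing d, DC-centred
freq_axis <- function(n, d) {
  (seq_len(n) - (floor(n / 2) + 1L)) / (n * d)
}

# circular FFT convolution of two same-sized real arrays, kernel centred
conv_fft <- function(x, kernel) {
  stopifnot(identical(dim(x), dim(kernel)))
  K <- stats::fft(ifftshift_nd(kernel))
  out <- stats::fft(stats::fft(x) * K, inverse = TRUE) / length(x)
  Re(out)
}
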