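# Shared fixtures, cached across test files (helpers are sourced once per
# test run). Heavy objects -- default-grid excitation stacks and the detection
# volume -- are built on first use.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# excitation stack of a default beam on the full grid, y in {0, 11, 22}
default_stack <- function(name) {
  cached(paste0("stack_", name), {
    excitation_stack(default_beams()[[name]], y = c(0, 11, 22))
  })
}

# on-axis propagation curve of a default beam, y = 0..40
default_onaxis <- function(name) {
  cached(paste0("onaxis_", name), {
    onaxis_intensity(excitation_stack(default_beams()[[name]],
                                      y = seq(0, 40, by = 1)))
  })
}

# detection PSF volume used for OTF line profiles (fine z for good frequency
# resolution; modest lateral window)
default_detection <- function() {
  cached("det_line", detection_psf(nx = 96L, ny = 96L, nz = 1024L,
                                   dxy = 0.1, dz = 0.05))
}

# small detection volume for rendering tests: voxel 0.2 wavelengths
small_detection <- function() {
  cached("det_small", detection_psf(nx = 32L, ny = 32L, nz = 32L,
                                    dxy = 0.2, dz = 0.2, n_theta = 500L))
}

# overall PSF of a default beam at focus on the small 32^3 rendering grid
small_overall_psf <- function(name) {
  cached(paste0("psf32_", name), {
    det <- small_detection()
    st <- default_stack(name)
    zfine <- ((1:32) - 17) * 0.2
    overall_psf(resample_profile(profile_at_y(st, 0), zfine), det)
  })
}

# detection axial profile evaluated on an excitation z axis (cached per call
# signature is overkill; profiles share the default stack axis)
default_det_axial <- function(z) {
  cached("det_axial", detection_axial(z))
}

# tiny separable Gaussian PSF for deconvolution/imaging tests
gaussian_test_psf <- function(n = 16L, sigma = c(1.2, 1.2, 2.5)) {
  ax <- seq_len(n) - (n / 2 + 1L)
  gx <- exp(-ax^2 / (2 * sigma[1L]^2))
  gy <- exp(-ax^2 / (2 * sigma[2L]^2))
  gz <- exp(-ax^2 / (2 * sigma[3L]^2))
  outer(outer(gx, gy), gz)
}

# independent wrapped-shift oracle: place `kernel` (centred) at voxel `at`
# (circularly), used to cross-check FFT convolutions
shift_kernel_oracle <- function(kernel, at) {
  d <- dim(kernel)
  ctr <- d %/% 2L + 1L
  out <- array(0, d)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    src <- ((c(i, j, k) - at + ctr - 1L) %% d) + 1L
    out[i, j, k] <- kernel[src[1L], src[2L], src[3L]]
  }
  out
}
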