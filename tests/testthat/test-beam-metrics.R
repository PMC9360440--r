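# Width and sectioning metrics on closed-form profiles, plus the orderings
# the three default beams must satisfy.

test_that("axial_fwhm reproduces the analytic Gaussian width, floor or not", {
  z <- seq(-20, 20, by = 0.02)
  sigma <- 1.3
  I <- exp(-z^2 / (2 * sigma^2))
  expect_equal(axial_fwhm(z, I), 2.3548 * sigma, tolerance = 0.005)
  # prominence handling: a constant pedestal must not change the width
  expect_equal(axial_fwhm(z, I + 0.4), 2.3548 * sigma, tolerance = 0.005)
})

test_that("axial_fwhm measures only the central lobe of a modulated profile", {
  z <- seq(-20, 20, by = 0.005)
  I <- cos(z)^2 * exp(-z^2 / 200) # lobes under a slow envelope
  # half level ~ 0.5 (floor ~ 0 at the cos zeros): cos^2 = 1/2 at z = pi/4
  expect_equal(axial_fwhm(z, I), pi / 2, tolerance = 0.01)
})

test_that("axial_fwhm rejects profiles without a usable peak", {
  z <- seq(0, 10, by = 0.1)
  expect_error(axial_fwhm(z, z), "peak")
})

test_that("main_lobe_width: rectangle gives its full width, Gaussian the 63% chord", {
  z <- seq(-10, 10, by = 0.01)
  rect <- as.numeric(abs(z) <= 2.5)
  expect_equal(main_lobe_width(z, rect), 5, tolerance = 0.02)
  sigma <- 1.1
  I <- exp(-z^2 / (2 * sigma^2))
  expect_equal(main_lobe_width(z, I), 2 * sigma * sqrt(2 * log(1 / 0.63)),
               tolerance = 0.005)
  expect_error(main_lobe_width(z, rep(1, length(z))), "flat")
})

test_that("the 37% threshold overestimates the hexagonal main lobe", {
  p <- profile_at_y(default_stack("hexagonal"), 0)
  w63 <- main_lobe_width(p$z, p$intensity, threshold = 0.63)
  w37 <- main_lobe_width(p$z, p$intensity, threshold = 0.37)
  expect_gte(w37, w63)
  expect_gt(w37 / w63, 1.2) # the side lobes inflate the 37% chord
})

test_that("optical sectioning: uniform slab and Gaussian closed forms", {
  z <- seq(-12, 12, by = 0.005)
  slab <- as.numeric(abs(z) <= 3)
  expect_equal(optical_sectioning(z, slab), 0.63 * 3, tolerance = 0.005)
  sigma <- 1.4
  I <- exp(-z^2 / (2 * sigma^2))
  # erf(h / (sigma sqrt 2)) = 0.63  =>  h = 0.89648 sigma
  expect_equal(optical_sectioning(z, I), 0.89648 * sigma, tolerance = 0.003)
  expect_error(optical_sectioning(z, numeric(length(z))), "zero-energy")
})

test_that("cumulative profile is monotone, ends at 1, and matches a trapezoid oracle", {
  z <- seq(-8, 8, by = 0.01)
  I <- exp(-abs(z)) * (1 + 0.3 * cos(3 * z))
  cum <- cumulative_z_profile(z, I)
  expect_true(all(diff(cum$fraction) >= -1e-12))
  expect_equal(cum$fraction[nrow(cum)], 1, tolerance = 1e-6)
  # independent trapezoid oracle at one interior half-width
  h <- cum$h[300L]
  sel <- abs(z) <= h + 1e-12
  trap <- function(x, y) sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
  oracle <- trap(z[sel], I[sel]) / trap(z, I)
  expect_equal(cum$fraction[300L], oracle, tolerance = 1e-6)
})

test_that("the Gaussian cumulative curve dominates the hexagonal one", {
  pg <- profile_at_y(default_stack("gaussian"), 0)
  ph <- profile_at_y(default_stack("hexagonal"), 0)
  cg <- cumulative_z_profile(pg$z, pg$intensity)
  ch <- cumulative_z_profile(ph$z, ph$intensity)
  expect_true(all(cg$fraction >= ch$fraction - 1e-9))
})

test_that("otf_support: delta spectrum reaches the grid edge; scan oracle agrees", {
  k <- seq(-1, 1, by = 0.01)
  flat <- rep(1, length(k))
  expect_equal(otf_support(k, flat), 1)
  set.seed(7)
  amp <- exp(-(k / 0.3)^2) * (1 + 0.1 * runif(length(k)))
  got <- otf_support(k, amp, threshold = 1e-2)
  # exhaustive linear scan
  dc <- amp[k == 0]
  oracle <- 0
  for (i in seq_along(k)) if (amp[i] >= 1e-2 * dc) oracle <- max(oracle, abs(k[i]))
  expect_equal(got, oracle)
})

test_that("propagation FWHM: Lorentzian closed form and interpolation accuracy", {
  yr <- 7.3
  y <- seq(-40, 40, by = 0.5)
  I <- 1 / (1 + (y / yr)^2)
  expect_equal(propagation_fwhm(y, I), 2 * yr, tolerance = 0.005 * 2 * yr)
  yf <- seq(-40, 40, by = 0.01)
  dense <- propagation_fwhm(yf, 1 / (1 + (yf / yr)^2))
  expect_lt(abs(propagation_fwhm(y, I) - dense) / dense, 0.005)
  expect_identical(propagation_fwhm(y, rep(1, length(y))), Inf)
})

test_that("os_doubling_length: invariant profiles flag Inf; widening Gaussian interpolates", {
  z <- seq(-30, 30, by = 0.05)
  mk_stack <- function(sigmas, ys) {
    m <- vapply(sigmas, function(s) exp(-z^2 / (2 * s^2)), numeric(length(z)))
    structure(m, z = z, y = ys, class = "excitation_profile")
  }
  const <- mk_stack(rep(1.5, 4L), c(0, 5, 10, 15))
  expect_identical(os_doubling_length(const), Inf)
  # sigma(y) = sigma0 sqrt(1 + (y/yr)^2) doubles at y = sqrt(3) yr
  yr <- 9; ys <- seq(0, 30, by = 0.5)
  widening <- mk_stack(1.2 * sqrt(1 + (ys / yr)^2), ys)
  expect_equal(os_doubling_length(widening), sqrt(3) * yr, tolerance = 0.01)
})

test_that("h90 closed forms and the sectioning/h90 ordering", {
  z <- seq(-12, 12, by = 0.005)
  slab <- as.numeric(abs(z) <= 4)
  expect_equal(h90(z, slab), 0.9 * 8, tolerance = 0.01)
  p <- profile_at_y(default_stack("gaussian"), 0)
  expect_gte(h90(p$z, p$intensity), optical_sectioning(p))
  # hexagonal spreads more energy than the Gaussian
  ph <- profile_at_y(default_stack("hexagonal"), 0)
  expect_gt(h90(ph$z, ph$intensity), h90(p$z, p$intensity))
})

test_that("intensity equalization: identity, mode swap, and the lattice asymmetry", {
  z <- seq(-20, 20, by = 0.01)
  a <- list(z = z, intensity = 2 * exp(-z^2 / 2))
  expect_equal(equalize_intensity(list(a, a, a), "peak"), c(1, 1, 1))
  expect_equal(equalize_intensity(list(a, a), "integrated"), c(1, 1))
  # two-beam case built so the peak ratio is the inverse of the integral
  # ratio: peak scales and integrated scales are then exact reciprocals
  b <- list(z = z, intensity = 1 * exp(-z^2 / (2 * 16)))
  sp <- equalize_intensity(list(a, b), "peak", envelope = 40)
  si <- equalize_intensity(list(a, b), "integrated", envelope = 40)
  expect_equal(sp[2L], 1 / si[2L], tolerance = 1e-6)
  # peak-equalized hexagonal sheet delivers more integrated dose than the
  # Gaussian over the 10 um (24 wavelength) envelope
  pg <- profile_at_y(default_stack("gaussian"), 0)
  ph <- profile_at_y(default_stack("hexagonal"), 0)
  s <- equalize_intensity(list(pg, ph), "peak")
  dzg <- pg$z[2L] - pg$z[1L]
  dose <- function(p, sc) sum(p$intensity[abs(p$z) <= 12] * sc) * dzg
  expect_gt(dose(ph, s[2L]), dose(pg, s[1L]))
})

test_that("average power density follows the stated algebra", {
  expect_equal(average_power_density(1, 1, 1), 1)
  expect_equal(average_power_density(2, 0.5, 4), 1)
  expect_equal(average_power_density(1, 1, 2),
               average_power_density(1, 1, 1) / 2)
})

test_that("width metrics are invariant to uniform intensity scaling", {
  p <- profile_at_y(default_stack("mb_square"), 0)
  for (f in list(axial_fwhm, main_lobe_width, optical_sectioning, h90)) {
    expect_equal(f(p$z, p$intensity * 7.3), f(p$z, p$intensity),
                 tolerance = 1e-12)
  }
})

test_that("FWHM and sectioning orderings hold at focus and at the propagation FWHM", {
  names <- c("gaussian", "mb_square", "hexagonal")
  ax <- NULL
  fw0 <- os0 <- fwh <- numeric(3L)
  for (i in 1:3) {
    st <- default_stack(names[i])
    p0 <- profile_at_y(st, 0)
    if (is.null(ax)) ax <- default_det_axial(p0$z)
    fw0[i] <- axial_fwhm(p0$z, p0$intensity * ax)
    os0[i] <- optical_sectioning(p0)
    # y = 22 is within 15% of each beam's propagation half-length
    ph <- profile_at_y(st, 22)
    fwh[i] <- axial_fwhm(ph$z, ph$intensity * ax)
  }
  expect_true(fw0[3L] < fw0[2L] && fw0[2L] < fw0[1L])
  expect_true(fwh[3L] < fwh[2L] && fwh[2L] < fwh[1L])
  expect_true(os0[1L] < os0[2L] && os0[2L] < os0[3L])
})

test_that("beam_metrics assembles a consistent one-row report", {
  st <- default_stack("gaussian")
  rep0 <- beam_metrics(st, det = NULL, y = 0)
  expect_s3_class(rep0, "data.frame")
  expect_identical(nrow(rep0), 1L)
  expect_true(is.na(rep0$otf_support))
  expect_equal(rep0$evaluated_at_y, 0)
  expect_gte(rep0$h90, rep0$optical_sectioning)
  expect_gt(rep0$propagation_fwhm, 40) # both-sign width of a ~22-lambda half
  p0 <- profile_at_y(st, 0)
  expect_equal(rep0$axial_fwhm, axial_fwhm(p0))
})
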