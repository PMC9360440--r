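# Pupil synthesis: beam definitions, the SLM + annular-mask chain, and their
# invariants. Small 257-sample grids keep the oracles cheap; the default
# 1025-sample grid is exercised by the metrics and acceptance tests.

grid257 <- pupil_grid(257L)

test_that("gaussian pupil follows the 1/e NA definition and analytic energy", {
  spec <- beam_spec("gaussian", na = 0.21, amplitude_scale = 2)
  p <- gaussian_pupil(spec, grid257)
  o <- (grid257$n + 1L) / 2L
  col <- Re(p$field[, o])
  expect_equal(col[o], 2)                         # E0 at the origin
  at_na <- approx(grid257$k, col, xout = 0.21)$y  # E0/e at k_z = NA
  expect_equal(at_na, 2 / exp(1), tolerance = 1e-3)
  # off-column samples are all zero
  expect_equal(sum(Mod(p$field[, -o])), 0)
  # closed-form Gaussian integral: sum |E|^2 dk = E0^2 * NA * sqrt(pi/2)
  energy_1d <- sum(Mod(col)^2) * grid257$dk
  expect_equal(energy_1d, 4 * 0.21 * sqrt(pi / 2), tolerance = 0.01)
  expect_error(gaussian_pupil(beam_spec("flat_top", na = 0.5), grid257))
})

test_that("flat-top pupil has a hard cutoff and a sinc-like focal field", {
  spec <- beam_spec("flat_top", na = 0.5)
  p <- flat_top_pupil(spec, grid257)
  o <- (grid257$n + 1L) / 2L
  col <- Re(p$field[, o])
  expect_true(all(col[abs(grid257$k) <= 0.5] == 1))
  expect_true(all(col[abs(grid257$k) > 0.5] == 0))

  # first zero of the focal field: discrete-FT oracle (direct phase sum,
  # independent of the package transform); n_medium = 1 so the closed form
  # z = 1/(2 NA) applies in these units
  ff <- propagate_to_y(p, 0, n_medium = 1, pad_factor = 4)
  ctr_x <- which.min(abs(ff$x))
  prof <- Re(ff$field[, ctr_x])
  pos <- ff$z > 0
  first_zero <- ff$z[pos][which(diff(sign(prof[pos])) != 0)[1L]]
  k_in <- grid257$k[abs(grid257$k) <= 0.5]
  oracle <- function(z) sum(exp(2i * pi * k_in * z))
  zs <- seq(0.5, 1.5, by = 1e-3)
  oz <- zs[which(diff(sign(Re(sapply(zs, oracle)))) != 0)[1L]]
  expect_lt(abs(first_zero - oz), ff$z[2L] - ff$z[1L])
  expect_lt(abs(oz - 1 / (2 * 0.5)), 0.01)

  expect_error(flat_top_pupil(beam_spec("flat_top", na = 0.9),
                              pupil_grid(257L, k_max = 0.5)),
               "exceeds the grid")
})

test_that("MB-square beamlets share the printed delta-k_y within 2 dk", {
  spec <- beam_spec("mb_square", na_max = 0.35, na_min = 0.25)
  p <- mb_square_pupil(spec, grid257)
  k <- grid257$k
  cols <- which(colSums(Mod(p$field)) > 0)
  expect_length(cols, 3L) # centre column plus the two side beamlets
  kxs <- k[cols]
  expect_true(all(abs(kxs[kxs != 0]) > 0.25))     # just outside the inner annulus
  expect_true(all(abs(kxs[kxs != 0]) <= 0.25 + 2 * grid257$dk))

  # per-beamlet k_y extents (NA-unit convention, n = 1)
  dky <- vapply(cols, function(j) {
    kz_on <- k[Mod(p$field[, j]) > 0]
    pos <- kz_on[kz_on >= 0] # one beamlet of the pair
    kr2 <- k[j]^2 + pos^2
    diff(range(sqrt(1 - kr2)))
  }, numeric(1L))
  printed <- sqrt(1 - 0.25^2) - sqrt(1 - 0.35^2)
  expect_lt(max(dky) - min(dky), 2 * grid257$dk)
  expect_lt(max(abs(dky - printed)), 2 * grid257$dk)

  expect_error(mb_square_pupil(
    beam_spec("mb_square", na_max = 0.35, na_min = 0.25,
              side_beamlet_kx = 0.4), grid257),
    "outside the outer annulus")
})

test_that("MB-square with a tiny inner annulus degenerates toward flat-top", {
  spec <- beam_spec("mb_square", na_max = 0.35, na_min = 1e-3)
  p <- mb_square_pupil(spec, grid257)
  o <- (grid257$n + 1L) / 2L
  col <- Mod(p$field[, o])
  on <- grid257$k[col > 0]
  expect_lt(min(abs(on)), 3 * grid257$dk)     # central column reaches k_z ~ 0
  expect_equal(max(abs(on)), max(grid257$k[abs(grid257$k) <= 0.35]))
})

test_that("hexagonal beamlets sit at the annulus centre with the stated envelope", {
  spec <- beam_spec("hexagonal", na_max = 0.46, na_min = 0.36, fill_factor = 1)
  p <- hexagonal_pupil(spec, grid257)
  k <- grid257$k
  cols <- which(colSums(Mod(p$field)) > 0)
  kxs <- sort(k[cols])
  # columns at 0 and +/- R sin(60), R = 0.41 (to the nearest grid column)
  expect_lt(max(abs(kxs - c(-0.41 * sin(pi / 3), 0, 0.41 * sin(pi / 3)))),
            grid257$dk)
  o <- (grid257$n + 1L) / 2L
  env <- Mod(p$field[, o])^2
  pk <- which.max(env * (k > 0))
  expect_lt(abs(k[pk] - 0.41), grid257$dk)
  # Gaussian envelope with full 1/e intensity width dkz = 0.1: the intensity
  # ratio between interior offsets from the true centre follows
  # exp(-4 d^2 / dkz^2)
  r <- approx(k, env, xout = 0.41)$y / approx(k, env, xout = 0.38)$y
  expect_equal(r, exp(4 * 0.03^2 / 0.1^2), tolerance = 0.05)
  # radial confinement to the annulus
  kr <- sqrt(outer(k^2, k^2, `+`))
  expect_true(all(Mod(p$field)[kr < 0.36 - 1e-12 | kr > 0.46 + 1e-12] == 0))
})

test_that("a very large fill factor flattens the beamlet envelope", {
  spec <- beam_spec("hexagonal", na_max = 0.46, na_min = 0.36,
                    fill_factor = 100)
  p <- hexagonal_pupil(spec, grid257)
  o <- (grid257$n + 1L) / 2L
  on <- Mod(p$field[, o])[Mod(p$field[, o]) > 0]
  expect_gt(min(on) / max(on), 0.99)
  expect_error(hexagonal_pupil(
    beam_spec("hexagonal", na_max = 0.46, na_min = 0.36,
              fill_factor = 1e-12), grid257),
    NA) # tiny but positive FC is legal...
  expect_error(beam_spec("hexagonal", na_max = 0.46, na_min = 0.36,
                         fill_factor = 0)) # ...zero is not
})

test_that("SLM real-part step is the identity for these symmetric pupils", {
  for (bt in c("mb_square", "hexagonal")) {
    spec <- if (bt == "mb_square") {
      beam_spec("mb_square", na_max = 0.35, na_min = 0.25)
    } else {
      beam_spec("hexagonal", na_max = 0.46, na_min = 0.36)
    }
    ideal <- beam_pupil(spec, grid257, apply_slm = FALSE)
    expect_equal(max(abs(Im(ideal$field))), 0) # real before the SLM
    masked <- slm_and_mask(ideal)
    # oracle: the ideal focal field of an inversion-symmetric real pupil is
    # real, so the chain reduces to the annular mask alone
    k <- grid257$k
    kr <- sqrt(outer(k^2, k^2, `+`))
    direct <- ideal$field
    direct[kr < spec$na_min | kr > spec$na_max] <- 0
    expect_lt(max(Mod(masked$field - direct)), 1e-9 * max(Mod(direct)))
  }
})

test_that("annular mask blocks DC, loses no more than the masked energy, and is idempotent", {
  spec <- beam_spec("hexagonal", na_max = 0.46, na_min = 0.36)
  p <- beam_pupil(spec, grid257)
  o <- (grid257$n + 1L) / 2L
  expect_equal(Mod(p$field[o, o]), 0)
  ideal <- beam_pupil(spec, grid257, apply_slm = FALSE)
  expect_lte(pupil_energy(p), pupil_energy(ideal) + 1e-12)
  twice <- slm_and_mask(p, annulus = c(0.36, 0.46))
  expect_identical(dim(twice$field), dim(p$field))
  expect_lt(max(Mod(twice$field - p$field)), 1e-9 * max(Mod(p$field)))
  expect_error(slm_and_mask(ideal, annulus = c(0.36, 1.5)), "beyond the grid")
})

test_that("retained energy after the mask matches a brute-force FFT-chain oracle", {
  spec <- beam_spec("hexagonal", na_max = 0.46, na_min = 0.36)
  ideal <- beam_pupil(spec, grid257, apply_slm = FALSE)
  masked <- slm_and_mask(ideal)
  frac <- pupil_energy(masked) / pupil_energy(ideal)

  # independent chain: dense padded FFT -> Re -> inverse FFT -> radial mask,
  # written directly against stats::fft with plain index bookkeeping
  n <- grid257$n; npad <- 512L
  buf <- matrix(0 + 0i, npad, npad)
  ctr <- (n + 1L) / 2L
  ri <- ((seq_len(n) - ctr) %% npad) + 1L
  buf[ri, ri] <- ideal$field
  focal <- stats::fft(buf)
  back <- stats::fft(Re(focal) + 0i, inverse = TRUE) / npad^2
  pup2 <- back[ri, ri]
  k <- grid257$k
  kr <- sqrt(outer(k^2, k^2, `+`))
  pup2[kr < 0.36 | kr > 0.46] <- 0
  frac_oracle <- sum(Mod(pup2)^2) / sum(Mod(ideal$field)^2)
  expect_equal(frac, frac_oracle, tolerance = 0.01)
})

test_that("Parseval holds through the pupil-to-sample transform for every beam", {
  specs <- list(beam_spec("gaussian", na = 0.21),
                beam_spec("flat_top", na = 0.3),
                beam_spec("mb_square", na_max = 0.35, na_min = 0.25),
                beam_spec("hexagonal", na_max = 0.46, na_min = 0.36))
  for (spec in specs) {
    p <- beam_pupil(spec, grid257)
    ff <- propagate_to_y(p, 0, n_medium = 1, pad_factor = 2)
    e_pupil <- pupil_energy(p)
    dxz <- (ff$z[2L] - ff$z[1L])^2
    e_focal <- sum(Mod(ff$field)^2) * dxz
    expect_equal(e_focal, e_pupil, tolerance = 1e-6)
  }
})

test_that("beam_spec validates its invariants", {
  expect_error(beam_spec("gaussian"), "0 < na")
  expect_error(beam_spec("mb_square", na_max = 0.25, na_min = 0.35))
  expect_error(beam_spec("hexagonal", na_max = 0.46, na_min = 0.36,
                         fill_factor = -1))
  expect_error(beam_spec("mb_square", na_max = 0.35, na_min = 0.25,
                         side_beamlet_kx = 0.1), "side_beamlet_kx")
})
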