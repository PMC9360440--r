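#' Deterministic test fixtures
#'
#' Small seeded assets used by the test suite and examples: bead volumes, the
#' default beam trio configuration, a synthetic (separable Gaussian) PSF and a
#' paired noisy render for correlation analyses. Everything is generated in
#' code; the same seed yields identical objects.
#'
#' @param name one of `"delta_bead"`, `"two_bead"`, `"beam_trio"`,
#'   `"synthetic_psf"`, `"fpc_pair"`.
#' @param seed RNG seed for the stochastic fixtures.
#' @return The fixture object (an array, list of specs, or list of images).
#' @export
make_fixture <- function(name = c("delta_bead", "two_bead", "beam_trio",
                                  "synthetic_psf", "fpc_pair"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    delta_bead = {
      v <- array(0, c(16L, 16L, 16L))
      v[9L, 9L, 9L] <- 1
      v
    },
    two_bead = {
      v <- array(0, c(32L, 32L, 32L))
      v[17L, 17L, 17L] <- 1
      v[9L, 21L, 13L] <- 1
      v
    },
    beam_trio = default_beams(),
    synthetic_psf = {
      # separable Gaussian stand-in PSF (synthetic, not an optical model):
      # sigma (1.5, 1.5, 4) voxels, unit peak, 32^3
      ax <- seq_len(32L) - 17L
      gx <- exp(-ax^2 / (2 * 1.5^2))
      gz <- exp(-ax^2 / (2 * 4^2))
      vol <- outer(outer(gx, gx), gz)
      structure(vol, spacing = c(0.1, 0.1, 0.1), role = "synthetic",
                class = c("psf_volume", "array"))
    },
    fpc_pair = {
      em <- generate_emitters(3, volume_um = c(3.2, 3.2, 3.2),
                              voxel_um = 0.1, brightness = 1000, seed = seed)
      psf <- make_fixture("synthetic_psf")
      render_volume(em, psf, sbr = 3,
                    seed_pair = c(seed + 1000L, seed + 2000L))
    })
}
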