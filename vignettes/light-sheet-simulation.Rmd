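---
title: "Modelling and measuring light-sheet illumination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring light-sheet illumination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetsim)
```

# The model

`sheetsim` simulates dithered light-sheet illumination from first principles:
a complex field is defined on the back pupil of the excitation objective,
shaped by the experimental beam-forming chain, propagated to the sample, and
combined with a widefield detection model into overall PSFs and OTFs. This
vignette records the scientific and numerical choices behind the
implementation — what is modelled, what is deliberately simplified, and why
the defaults are what they are.

## Units and coordinates

Pupil coordinates (k_x, k_z) are expressed in numerical-aperture units, and
the propagation model converts them to **direction sines** s = k/n, with
n = 1.33 (aqueous media) by default. This choice is forced by the defocus
relation the model uses, k_y = sqrt(1 − k_x² − k_z²), which requires
normalized direction cosines; its corollary is that every real-space
distance the package reports is in units of the **wavelength in the medium**,
λ/n. We write these lengths simply as "λ". Two consequences are worth
internalizing:

* the 0.21-NA Gaussian sheet has a propagation half-length of 22λ and its
  main lobe doubles in width over that same distance, and the three default
  beams (Gaussian 0.21, MB-square 0.35/0.25, hexagonal 0.46/0.36) all come
  out 44–51λ long (full width), i.e. matched "20 µm-class" sheets;
* the detection model needs no explicit index factor: with lengths in medium
  wavelengths, the Richards–Wolf defocus phase is exp(2πi z cosθ) and the
  index enters only through the aperture half-angle sin α = NA/n.

Setting `n_medium = 1` recovers the vacuum-unit convention if needed.

## Beam definitions

The Gaussian sheet is a single pupil column E0·exp(−(k_z/NA)²) (amplitude
1/e at k_z = NA); the flat-top sheet a hard-cutoff column. Both bypass the
SLM/mask chain.

The MB-square lattice is four equal-amplitude beamlets: the 0°/180° pair on
k_x = 0, extended along k_z and cropped radially to [NA_min, NA_max]; the
90°/270° pair at ±k_x just outside the inner annulus, extended along k_z to
the outer-annulus chord. This geometry equalizes each beamlet's spread of
k_y, Δk_y = sqrt(1−NA_min²) − sqrt(1−NA_max²) in NA units, so all four
envelopes propagate the same distance.

The hexagonal lattice places six beamlets on the circle of radius
(NA_max+NA_min)/2 — two on the k_z axis and four at ±60° of azimuth, the
standard hexagonal-lattice geometry (the azimuths are a package choice; they
are what reproduces the characteristic hexagonal OTF structure). Each
beamlet is a single-sample-wide column with a Gaussian k_z envelope. We
interpret the envelope parameter Δk_z = FC·(NA_max−NA_min) as the **full 1/e
width of the beamlet intensity envelope** (field amplitude
exp(−2((k_z−c)/Δk_z)²)). Δ-quantities in this area conventionally denote
full widths, and this reading — unlike the half-width-of-amplitude one —
reproduces the established hexagonal benchmark values (overall FWHM ≈ 1.2λ,
sectioning ≈ 3.3λ for the 0.46/0.36, FC = 1 sheet) simultaneously with its
propagation length. Beamlet k_x width does not matter after dithering, which
is why delta columns suffice.

Lattice pupils then run through the beam-forming chain actually used on the
instrument: FT to the sample plane, discard the imaginary part (a 0/π SLM
phase pattern), FT back, annular mask. For the inversion-symmetric real
pupils above, the real-part step is mathematically the identity and the
chain reduces to the mask — the unit tests pin this down against a
brute-force FFT oracle — but the chain is implemented in full so asymmetric
or user-supplied pupils are treated correctly.

## Propagation, dithering, and the sparse fast path

Propagation multiplies the pupil by exp(2πi k_y y) and transforms to the
sample plane; dithering squares the field and averages along x (intensity
first, then average). Every supported pupil occupies only a few k_x columns
(one for Gaussian/flat-top, three for the masked lattices), and under the x
average the cross terms between distinct columns integrate to zero exactly,
so the dithered profile is computed as a sum of padded 1D transforms per
column. This is an algebraic identity, not an approximation; the test suite
verifies it sample-for-sample against the full 2D transform.

Defaults: a 1025² pupil spanning [−1, 1] NA (dk ≈ 1.95·10⁻³) and 16-fold
zero padding, giving dz ≈ 0.031λ; FWHM discretization error is well below
0.01λ at these settings. Excitation stacks default to 0.5λ steps in y.
Evanescent samples (s > 1) are zeroed.

## Detection and the overall PSF

Detection is the aplanatic vectorial Richards–Wolf model at NA 1.0 / n 1.33
with unpolarized emission — the incoherent azimuthal average
|I₀|² + 2|I₁|² + |I₂|² of the three annular integrals, evaluated by
trapezoidal quadrature (2000 aperture samples by default) and radially
interpolated onto the requested volume. Its axial FWHM is 2.62λ in medium
wavelengths. The overall PSF treats the dithered sheet as laterally uniform:
the excitation z-profile at the chosen propagation position multiplies the
detection volume pixel-wise; an optional z offset models
excitation–detection misalignment (the overall-PSF centroid then shifts
monotonically with the offset, which is how focal-plane artefacts from
sample-induced beam deflection arise). The overall OTF is the FT of that
product; along the k_x = k_y = 0 line it equals the 1D transform of the
laterally summed PSF, which `overall_otf_axial()` exploits.

## Metrics

All widths interpolate linearly between samples and are scale-invariant.

* **Axial FWHM** uses a prominence-based half level: the floor is the
  profile minimum within ±10λ of the peak (configurable), and the half level
  is floor + (peak − floor)/2; for multi-lobed beams only the central lobe
  is measured, by walking outward from the peak to the first crossing.
* **Main-lobe width** is the chord at 63% of peak. The 37% convention
  dramatically overestimates lattice lobes (the test suite checks the
  direction of that discrepancy).
* **Optical sectioning** is the smallest half-width about z = 0 containing
  63% of the profile's total integral (trapezoid quadrature expanding
  symmetrically from the focus); **h90** is the analogous 90% full height.
* **Propagation FWHM** is the full y-width at 50% of the focal on-axis
  intensity; the sectioning-doubling length is the y at which optical
  sectioning reaches twice its focal value.
* **OTF support** is the largest frequency with amplitude ≥ 0.1% of DC.
* Intensity equalization rescales beams to equal focal peaks or equal
  integrated intensity over a 24λ envelope (the 10 µm calibration range of
  the reference instrument at λ ≈ 0.42 µm).

With these definitions the three default beams give overall-PSF axial FWHMs
of 1.77 / 1.72 / 1.22λ (Gaussian / MB-square / hexagonal) at the focus,
2.31 / 1.89 / 1.30λ at each beam's propagation half-maximum, and optical
sectioning of 0.90 / 1.22 / 3.35λ — the hexagonal values and orderings
reproduce the published benchmarks for this instrument class; the MB-square
construction, built literally from equal-amplitude beamlets, yields a
profile whose side-beamlet term carries ~83% of the pupil energy, and its
sectioning consequently comes out tighter than the published 1.87λ. No
equal-amplitude or equal-energy variant of the stated construction
reproduces all three MB benchmarks at once, so the literal construction is
kept rather than tuning beamlet weights.

## Synthetic imaging

`generate_emitters()` draws a Poisson number of emitters at the requested
density (defaults follow the simulated-acquisition conditions: 3 /µm³, with
10 /µm³ as the high-density condition), places them uniformly, and snaps
them to 0.1 µm voxels as delta functions. `render_volume()` adds a constant
background — the "autofluorescence pedestal", sized so that the rendered
peak signal of an isolated emitter over the rendered background equals the
requested SBR (3 by default) — convolves with a Poisson-noised copy of the
PSF (peak scale 1000 counts, mimicking a measured PSF), and applies Poisson
noise to the result, independently for each member of a render pair.
Emitter brightness defaults to 1000 counts; 100 counts is the low-signal
condition. The generator emulates shot noise, background and PSF
measurement noise; it does not model camera read noise or gain, sub-voxel
emitter positions, or PSF variation across the volume (a single overall PSF
convolves the whole volume), so conclusions drawn from it concern
illumination structure and photon statistics, not camera- or
depth-dependent effects in real data.

## Fourier plane correlation

For each pixel q of a principal frequency plane, the correlating set is the
plane of 3D frequency samples perpendicular to q through q — implemented as
nearest-plane binning: samples whose signed projection onto q̂ lies within
half a frequency sample of |q|. Samples are grouped by primitive lattice
direction so one projection pass serves every pixel on a ray. The k_x = 0
and k_y = 0 plane maps are averaged first and the super-1/7 area is
measured on the average (threshold-after-average). DC and sub-sample radii
are set to 1 by convention; no spectral window is applied.

In our simulations the hexagonal and MB-square sheets match or exceed the
Gaussian's FPC area at high signal (1000 counts), and the hexagonal
advantage shrinks substantially at 100 counts as shot noise erodes the
poorly-sectioned lattices first — the direction of the published
signal-dependence. The advantage does not fully invert at these scene
sizes, so the test suite asserts the direction of the change rather than a
sign flip.

## Restoration

Deskewing shears each stage-scan plane by stage_step·sin(angle) laterally
(57.6° between stage motion and detection axis; 107 nm axial step per
200 nm stage step). Richardson–Lucy runs on a reflectively padded volume
(half a PSF support per side) to keep edge ringing out of the stopping
statistic, and stops when the RMS difference between successive iterates
falls below 25% of the first iteration's — "25% of the first iteration" is
read as RMS(est_k − est_{k−1}) < 0.25·RMS(est_1 − est_0), computed on raw
intensities. Wiener deconvolution is the standard conj(H)/(|H|²+NSR) filter
with NSR 0.005. Spectral fusion normalizes both image spectra at DC and
combines them with convex weights proportional to the two OTF amplitudes;
frequencies where both OTFs vanish get equal weights (they lie outside both
supports, where the spectrum is noise anyway), and the output is rescaled
to the mean input DC.

## Numerical edge cases

* Even-length FFT axes put the origin at sample n/2 + 1; the one extra
  negative sample makes perfectly symmetric profiles asymmetric at the
  10⁻³ level, which the centroid tests account for.
* TIFF float pages are clamped to [0, 1] by the underlying library, so
  float32 volumes are affinely normalized on write with offset and scale in
  the JSON sidecar; uint16 round trips are exact.
* FPC maps require cubic volumes (the two principal-plane maps must share a
  shape to be averaged).
* Degenerate inputs fail loudly: empty y grids without the focus,
  zero-energy profiles, zero-variance FPC inputs, NA above the medium
  index, non-positive SBR.

## Problem sizes

The default analyses run at the 1025² pupil with 16× padded 1D transforms,
a 96×96×1024 detection volume (0.1λ lateral, 0.05λ axial) for OTF lines,
and 32³–64³ volumes for rendering and FPC studies; the full
characterization of the three default beams completes in well under a
minute on one CPU, and the whole test suite in a few minutes.
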