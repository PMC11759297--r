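---
title: "Speckle-illumination SFDI with profile correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle-illumination SFDI with profile correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements:
the measurement model, the forward model and its validity domain, the
profilometry and correction chain, the synthetic instrument the tests
run against, and the numerical and design choices that were genuinely
open.

## 1. The measurement model

A turbid medium acts as a low-pass filter on spatially modulated
illumination: its spatial modulation transfer function is the diffuse
reflectance `Rd(fx; μa, μs′)`.  Absorption (μa) mainly depresses the
response near `fx = 0`; scattering (μs′) sets the transport length
`1/(μa + μs′)` and therefore how quickly `Rd` rolls off with `fx`.
Measuring the response at a near-DC and a higher-frequency band
decouples the two coefficients.

Speckle illumination samples that filter with a random pattern instead
of fringes.  For each sliding window `v` of the speckle (AC) image the
package computes, per the Wiener–Khinchin route,

* the linear (zero-padded) autocorrelation `a = F⁻¹[V·V*]` of the
  detrended window,
* its radial average over integer-rounded lag radii,
* the magnitude of the 1-D Fourier transform of that profile, summed
  into bins of width `Δf` centred at `0, Δf, 2Δf, …` (bin k spans
  `f_k ± Δf/2`), giving the radial power spectral density `Sv(kr)`.

The AC band response sums the bins centred at 0.2 and 0.4 mm⁻¹, i.e.
0.1–0.5 mm⁻¹ at the instrument's `Δf = 0.2 mm⁻¹`; the DC response is
the window mean of the speckle-reduced image.  Two points deserve
emphasis because they are easy to get wrong:

* **Amplitude versus power.**  `Sv` is quadratic in the sample's
  frequency response (`Sv = |H|²·S_U`).  The reference calibration
  `Rd = (M/M_ref)·Rd_ref,pred` is linear in `Rd`, and the lookup
  table's AC entry is a linear sum of `Rd(f)` over the band.  The AC
  modulation is therefore reported as the *square root* of the summed
  band power: the sample/reference ratio is then an `S_U`-weighted mean
  of `Rd_sam/Rd_ref` over the band, which the linear calibration maps
  correctly onto model reflectance.  Without the square root the
  pipeline recovers `Rd²` ratios and the inversion is badly biased.
* **Detrending.**  The autocorrelation must have zero mean.  The DC
  level could be taken from the speckle-reduced image (with a shared
  exposure the AC image mean equals it in expectation), but any
  residual offset — speckle sampling noise, or the `cos θ / z²` shading
  gradient across a window on a tilted or curved sample — leaks a
  strong `sinc²`-shaped term into the lowest AC bin.  Each AC window is
  therefore detrended by its least-squares plane before
  autocorrelation; on flat, evenly lit samples this is identical to
  mean subtraction.

The PSD estimator is deliberately unnormalized: every downstream use is
a sample/reference ratio, so any fixed normalization cancels (a test
asserts gain invariance explicitly).

## 2. Forward model and lookup table

The forward model is the diffusion approximation of
spatial-frequency-domain reflectance for a semi-infinite homogeneous
medium with a partial-current boundary:

`Rd(fx) = 3Aa′ / ((μeff′/μtr + 1)(μeff′/μtr + 3A))`,

with `μtr = μa + μs′`, `a′ = μs′/μtr`,
`μeff′ = sqrt(3 μa μtr + (2π fx)²)` and `A` from the Groenhuis
polynomial for the effective internal reflection coefficient at
refractive index ratio `n = 1.4` (the paper-grade alternative, a White
Monte Carlo table, can be supplied through the `imported_table` model).

The lookup table tabulates `Rd(0)` and `Σ Rd(f), f = 0.1…0.5 mm⁻¹` on
log-spaced grids (defaults μa ∈ [0.002, 0.12], μs′ ∈ [0.3, 3.0] mm⁻¹,
60 × 60), chosen to bracket tissue-phantom values with ~7% grid spacing
so that piecewise-linear inversion errors stay far below 2%.  Inversion
triangulates the forward image of the grid in `(Rd_DC, Rd_AC)` space
and interpolates barycentrically in log-property space; queries outside
the attainable gamut raise an error unless clamping to the nearest node
is requested explicitly, in which case the clamped pixels are flagged.

**Validity domain.**  A desk-scale photon Monte Carlo
(`mc_reflectance`: Henyey–Greenstein or isotropic scattering, Fresnel
internal reflection, Russian roulette) cross-checks the diffusion
model.  Agreement is ~0.5% at `fx = 0` and a few percent through the
band for strongly diffusive media (μs′ ≈ 2 mm⁻¹), but at μs′ ≈ 1 mm⁻¹
and `fx = 0.2 mm⁻¹` transport and diffusion genuinely part ways: the
gap is ≈ −21% against an isotropic-scattering MC and ≈ +17% against
`g = 0.9`, i.e. sub-transport-length remission is phase-function
dependent and no diffusion curve can match both.  Because both sample
and reference are calibrated through the same model, ratio-based
estimation tolerates this in practice, but the model should not be
trusted as an absolute `Rd` beyond `fx ≈ 0.2·μtr`.

## 3. Profilometry

The stereo chain is: flat-field both images (division by a σ = 55 px
Gaussian blur), normalized-cross-correlation block matching over an
image pyramid (full search at the coarsest level, ±2 px refinement per
level, parabolic subpixel fit, NCC-peak and secondary-peak confidence
masking), pinhole reprojection `Z = fB/d`, then cleaning: 2×2 average
downsampling, Savitzky–Golay smoothing of order 1 and frame 31 applied
along rows then columns, and a smoothness-penalized surface fit
`(W + λ LᵀL) ẑ = W z` with a five-point Laplacian (λ = 5) solved
sparsely, bilinearly upsampled on block-centre coordinates.  All three
stages reproduce planes exactly (order-1 Savitzky–Golay and the
Laplacian null space are both plane-preserving), which is what the
depth/angle recovery bounds rely on.

Normals come from a least-squares local plane through each pixel and
its k = 6 nearest (in 3-D) of the 8 grid neighbours; the polar angle θ
is the angle between the unit normal (oriented toward the camera) and
the optical axis.  A regression plane fit is used rather than a
total-least-squares eigenfit: on height-map surfaces with θ < 90° the
two coincide for noiseless data and the regression form vectorizes over
the whole image.  Pixels whose disparity was never observed (matching
shadow at the image edge, low-confidence texture) are interpolated for
continuity but carried in the validity mask, and every consumer honours
that mask — cells are never silently invented.

## 4. Profile correction

The reference phantom is measured at five distances (5.8–9.8 cm in
1 cm steps) and each channel's modulation is interpolated against
distance with a shape-preserving piecewise cubic Hermite (PCHIP); the
interpolant passes exactly through the calibration nodes and never
overshoots between monotone samples.  Queries outside the calibrated
range error by default — PCHIP extrapolation is untrustworthy — with an
explicit clamp-to-endpoint option.

At fixed angular field of view the object pixel size grows linearly
with distance, so the sliding window shrinks as
`window(z) = round_to_odd(85 · 7.8/z)` to hold the object-space
frequency resolution at 0.2 mm⁻¹ (ties round to the smaller odd
value).  Distances outside the speckle-contrast validity range
(default 4–10 cm) are masked with a warning.

Correction itself is per pixel: the height-interpolated "virtual
reference" replaces the calibration-pose reference in the denominator
of the calibration, and the result is multiplied by `1/cos θ` where
`θ ≤ θ_max`.  `θ_max` defaults to 40° because the Lambertian model
demonstrably fails on steeper tissue-like surfaces (inter-object
reflections, normal-estimation noise); steeper pixels are masked, not
corrected.  Shadowed pixels are masked by a percentile threshold
(default 5%) on the flat-fielded DC image.

## 5. The synthetic instrument

The simulator mirrors the physical system component by component:

* **Speckle**: circular complex Gaussian spectral samples on a circular
  Fourier support — exactly fully developed speckle (unit contrast,
  exponential intensities).  The support radius is set analytically so
  the intensity-ACF FWHM equals the requested grain (default 5 px on
  the sensor, at every distance, matching the equal-AFOV design).
* **Tissue**: multiplication of the intensity spectrum by the radially
  symmetric `Rd(f)` of the forward model at the scene's object pixel
  size.
* **LSR**: the DC image is the mean of `n_patterns` independent
  speckle fields (default 256, making residual contrast `1/16`)
  filtered the same way.
* **Geometry**: per-pixel Lambertian shading `cos θ · (z₀/z)²` relative
  to the calibration pose; the stereo pair is an RGB speckle texture
  warped by the pinhole disparity `fB/z`, with the focal length derived
  from the pixel scale (`f = z₀/pixel_size₀`) so the pinhole and
  object-pixel models describe one camera.
* **Sensor**: Gaussian read noise (1% of full scale) and 8-bit
  quantization, both switchable.  AC and DC images share one exposure
  scale (0.3 of full scale per unit remitted intensity), as in an
  instrument acquiring both with the same exposure time; the shared
  exposure is what makes the AC image mean equal the DC modulation.

What the simulator does *not* model: fiber-mode physics (only the
pattern's second-order statistics matter for si-SFDI), depth-of-field
blur, polarization, spatially varying point-spread functions at tilted
incidence (tilt enters only through shading and geometry), and
inter-object diffuse reflectance.  Passing tests therefore demonstrate
the correctness of the estimator and correction chain under the stated
optics model, not robustness to every artifact of real instruments.

## 6. Statistical design of the closed-loop tests

The 0.1–0.5 mm⁻¹ band over an 85 px (4.93 mm) window contains only
`π((0.5·4.93)² − (0.1·4.93)²) ≈ 19` independent Fourier modes, so a
single window's AC amplitude has an irreducible ≈ 16% coefficient of
variation, and a 256² scene holds only ~9 independent windows — the
scene-median AC modulation varies ≈ 5–8% between pattern realizations.
(The physical instrument's 784×960 sensor holds ~100 windows, which is
why single-shot operation works there.)  Test problem sizes reflect
this: cross-pattern robustness is asserted at the 5% level on 384²
scenes, end-to-end recovery is asserted on the median over nine
256² phantoms, and the height/angle correction loops are rendered with
one shared illumination pattern across poses — physically faithful,
since the equal-AFOV design projects the same sensor-side pattern at
every distance — so that the loops measure correction error rather than
pattern-sampling noise.  Unit tests run on a quarter-scale system
(128² scenes, 43 px windows at 0.116 mm pixels) that samples the same
0.2 mm⁻¹ resolution at a quarter of the cost.

## 7. Known limitations

* The diffusion forward model biases absolute `Rd` at high `fx` in
  weakly scattering media (Section 2); import a transport-grade table
  for absolute work.
* The AC band estimator's effective frequency weighting is the
  pattern-and-tissue power spectrum, not the uniform weighting of the
  lookup table's band sum; calibration absorbs most of the mismatch,
  but recovery degrades gracefully as the sample's MTF shape departs
  from the reference's (a few percent over the tested 0.01–0.04 /
  0.7–1.5 mm⁻¹ range).
* The angle correction assumes the illumination vector coincident with
  the optical axis; the simulator can render an oblique source to
  reproduce the resulting asymmetry, but the corrector intentionally
  never models it.
* Sliding-window estimates mix signal across height and angle
  discontinuities; maps near steep steps should be read with the
  window footprint in mind.
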