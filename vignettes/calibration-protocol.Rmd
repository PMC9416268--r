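---
title: "Calibrating and verifying a push-broom hyperspectral imager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and verifying a push-broom hyperspectral imager}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsical)
```

## The instrument and the protocol

A push-broom hyperspectral imager records, per camera frame, one spatial
line (the slit axis) times the full spectral axis; the second spatial axis
is built by scanning the sample or the optics. Before such a system can be
used quantitatively on biological samples — skin, vasculature, dyes — four
groups of questions must be answered, in order:

1. **Spectral calibration.** Which wavelength falls on which detector
   pixel, and what is the effective spectral resolution?
2. **Spatial calibration.** How large is an image pixel on the object
   plane, what spatial frequencies are resolvable along each axis, and is
   the scanning speed matched to the exposure so pixels are square?
3. **Characterization.** How large are the spectrograph aberrations —
   smile (bending of the spectral axis along the slit), keystone
   (wavelength-dependent spatial magnification) — and how homogeneous and
   stable is the illumination?
4. **Verification.** Does the spectral response agree with an independent
   reference spectrometer, and do application-level maps behave as
   expected?

Stages are ordered because later ones consume earlier results: smile can
only be expressed in nanometres once the wavelength axis exists, and the
verification needs both the wavelength axis and the reflectance
normalization. `run_protocol()` enforces this order and reports px-only
quantities when the spectral stage is absent.

Everything in this package can be exercised without hardware because the
forward simulator (`simulate_scan()`) generates raw frame stacks from a
parametric model of the instrument and attaches the injected ground truth
to each cube. The protocol's estimators are validated as round trips
against that ground truth.

## The dispersion model

The wavelength at 0-based spectral pixel $x$ is modelled as a cubic,

$$\lambda(x) = a + b\,x + c\,x^2 + d\,x^3,$$

the standard expansion when the spectrograph geometry is not known
precisely. The package's reference parameterisation
(`default_dispersion()`) uses $a = 337.7$ nm, $b = 0.306$ nm/px,
$c = 2.6\times10^{-5}$ nm/px², $d = -5.4\times10^{-9}$ nm/px³ on a
2048-pixel axis, which spans roughly 338–1027 nm — a typical visible/NIR
configuration. The pixel-index convention is 0-based; a calibration
performed with a different convention yields coefficients shifted by the
re-indexing, so agreement is always asserted on predicted wavelengths, not
on raw coefficients. Units of $c$ and $d$ are recorded as nm/px² and
nm/px³.

### Line detection and assignment

Calibration sources are gas-discharge tubes (mercury with argon fill,
hydrogen, helium, neon). The bundled line table
(`inst/extdata/lamp_lines.csv`) was compiled from standard atomic
air-wavelength references; its relative intensities are representative
values chosen to make rank-order identification of the bright lines
unambiguous, not radiometric claims.

Peak detection uses topographic prominence (a peak must rise above the
higher of its two key saddles), so noise ripples riding on bright broad
bands are rejected, and maxima closer than a configurable separation are
merged rather than split. Sub-pixel refinement is a 3-point log-parabolic
interpolation, exact for Gaussian profiles and robust at the ~3-px-wide
lines this class of spectrograph produces.

Assignment is iterative because neon and argon lines sit a few nm apart and
cannot be identified without a wavelength estimate:

* *Stage 1.* The brightest mercury and hydrogen peaks are selected by
  intensity rank and paired with the brightest tabulated lines. Because the
  dispersion is monotone, both sides are sorted by position before pairing;
  a provisional cubic is fitted with iterative trimming of gross outliers
  (a blended doublet or a swapped rank is caught here).
* *Stage 2.* Every peak from every lamp is mapped through the provisional
  model and matched to the nearest same-species reference within ±1.5 nm
  (about 5 px); the fit is refined and the matching repeated twice. Peaks
  with no candidate or more than one candidate in the window are dropped
  with a logged count, as are references with a same-species neighbour
  closer than 3.5 nm (≈1.2× the instrumental FWHM) — such lines are blends
  at the instrument's resolution and would bias the fit.

The final fit is ordinary least squares of wavelength on
$\{1, x, x^2, x^3\}$, computed on a centred/scaled pixel coordinate for
conditioning and mapped back, with coefficient covariance from the residual
variance. Typical simulated four-lamp runs match ~50 lines with maximum
residuals well under half a spectral pixel.

Spectral resolution is measured as the FWHM of an isolated line from
linearly interpolated half-maximum crossings on *both* flanks — no
symmetric model is assumed, so the asymmetric profiles real spectrographs
produce are handled faithfully. Pixel widths convert to nm through the
local dispersion $b + 2cx + 3dx^2$.

## Spatial calibration

Pixel pitch comes from Ronchi bar targets: the bar period in pixels is the
mean spacing of sub-pixel 50%-amplitude edge crossings, and
$\text{pitch} = (1/f)/\text{period}_{px}$; the direct form
$\text{span}_{mm}/\text{span}_{px}$ is also accepted. Amplitude bounds use
the 5th/95th percentiles, which makes the estimator invariant to intensity
scaling and contrast inversion.

Resolving power uses USAF1951 three-bar elements,
$f = 2^{g + (e-1)/6}$ lp/mm with bar width $w = 1/(2f)$. "Discernible" is
operationalised as Michelson contrast $(I_{max}-I_{min})/(I_{max}+I_{min})
\ge 0.1$ on **both** gaps of the element, evaluated independently per axis
— push-broom systems resolve differently along and across the scan (slit
width vs detector pitch), and the simulator reproduces this through an
anisotropic spatial PSF. The 0.1 threshold is configurable and recorded in
the result.

Scanning speed: a square-grid target is imaged, the grid period is measured
per axis, and the elongation $(P_{scan}/P_{slit}-1)\cdot100\%$ and the
corrective speed factor $P_{slit}/P_{scan}$ are reported. In the simulator
a speed factor of 1.06 produces 6% elongation by construction.

## Characterization

**Smile** is estimated from a spatially uniform scene under the LED panel:
each illumination peak is tracked per slit row and its centroid offset from
the slit-centre row is the smile profile. Two numerical choices matter
here:

* LED bands span tens of pixels, where a 3-point parabola is noise-dominated;
  tracking instead uses a centre-of-mass centroid over the contiguous region
  above 70% of the local maximum, bounded to a fixed search radius so the
  window cannot spill across a saddle into a stronger neighbouring band.
* The offset profile is smoothed over a 50-slit-pixel window, as is usual
  for this analysis. A plain running average is biased exactly where a
  quadratic bow peaks (the slit edges, where the window truncates), so the
  smoother is a local *quadratic* fit over the same window — identical
  noise averaging in the interior, unbiased at the edges. The reported
  maximum |offset| is taken from this smoothed profile, in px and (when a
  dispersion model is available) in nm.

**Keystone** is measured on a single hyperspectral frame of a bar/grid
scene: per band, each high-contrast edge is localised as a 50% crossing and
its shift relative to the central band is recorded; the maxima over the
full slit and over its central half are reported separately, because real
systems are usually much better behaved on-axis. In the simulator, keystone
is modelled as a distortion-like displacement — odd and quadratic in the
normalised field coordinate ($u|u|$, with $u=\pm1$ at the slit edges) and
linear in wavelength — parameterised by the px shift at the field edge.
A linear-magnification model was considered and rejected: it cannot
simultaneously produce several px of deformation at the field edges and
sub-2-px behaviour over the central half, which is the empirically typical
pattern for wide-field objectives.

**Homogeneity** integrates a uniform-slab cube spectrally, normalises the
slit profile to its maximum and compares it with a reference relative
illumination curve (e.g. the objective maker's), reporting the maximum
relative deviation, the sub-pixel peak-position offset and the first-moment
skew. It is invariant to exposure scaling by construction.

**Temporal stability** tracks each illumination peak over a time series of
white references: wavelength shift and intensity ratio relative to the
first time point, plus a warm-up time from a profiled least-squares fit of
$I(t) = I_\infty + (I_0-I_\infty)e^{-t/\tau}$, defined as the earliest time
at which the predicted relative intensity change per 10 minutes drops below
1%.

## Verification

Transmittance is the per-band mean of sample/blank over a homogeneous
region (20 × 20 px by default). Comparison with a reference spectrometer
uses the **normalized absorbance**

$$\tilde A(\lambda) = \frac{-\ln\!\big(T(\lambda)\,a\big)}
 {\max_\lambda\big[-\ln\!\big(T(\lambda)\,a\big)\big]},$$

which removes path-length and concentration differences; the factor $a$
absorbs the different light-collection of the two modalities and is fitted
by bounded 1-D search of the RMSE over the common grid ($a\in[0.5,2]$ by
default). As printed, a ratio of logarithms of sub-unity transmittances is
sign-ambiguous; the implementation defines absorbance as $-\ln(Ta)$ and
normalises by its maximum so the strongest absorption equals exactly +1,
and records this convention in the output. The whole construction is
invariant to rescaling $(T, a) \to (sT, a/s)$, which the tests assert to
1e-12.

Reference spectrometers that switch detectors mid-range can leave a step in
the curve; `correct_detector_switch()` keeps the visible segment and adds a
constant to the NIR segment to restore continuity at the stated switch
wavelength (860 nm default). The exact smoothing such instruments apply is
vendor-specific; a continuity offset is the documented, minimal stand-in.

The erythema index $E = \log_{10}(R_{red}/R_{green})$ is computed per pixel
with red-over-green ordering so better-perfused (redder) tissue scores
higher; a flag inverts the ratio for the opposite convention. Green 560 nm
and red 650 nm are the defaults.

The bundled ink spectra (`synthetic_ink_spectrum()`) are *synthetic* —
smooth Gaussian-band absorbers qualitatively like red/blue dyes — because
measured dye spectra are instrument-specific; they exist so the
verification stage and its tests run self-contained.

## The simulator: what it emulates, and what it does not

Per scan line, the detector frame is illumination × scene reflectance ×
vignetting, mapped through the dispersion with the smile offset
$\delta(y) = s\,u(y)^2$ spectral pixels, the keystone displacement above,
Gaussian slit-PSF broadening (applied analytically to the illumination
components; the broadening of smooth reflectance spectra is neglected, an
excellent approximation when spectral features are much wider than the
PSF), an optional anisotropic spatial PSF, scaled-Poisson shot noise and
Gaussian read noise. Scenes are rasterised with exact area-averaging of
axis-aligned region boundaries, so edges are band-limited only by the pixel
aperture and the spatial PSF.

Defaults are chosen once to represent the study conditions: 3.45 µm
detector pitch; 2.9 nm slit FWHM; 0.12 mm/px object-plane pitch (short
focal length) with 0.03 mm/px for the long one; a 10-LED panel on centres
420–990 nm with 35 nm FWHM — wide enough that the summed spectrum stays
above 10% of its peak across 400–1000 nm, separated enough that apparent
peak wavelengths stay stable (≲0.5 nm) under differential visible/NIR
warm-up; warm-up drift $\tau = 11$ min with a 20% NIR intensity drop (3%
visible) and a 0.4 nm initial wavelength offset decaying with the same
constant, which places the <1%-per-10-min stability point at ≈30 minutes;
peak counts ~4000 (12-bit camera scale) with unit shot gain and 2 counts
read noise. Where measurements average frames, the tests use 20–30 frames,
the usual practice for white references and lamp spectra.

What the simulator does **not** model: physical-optics diffraction,
polarization, lens distortion (barrel/pincushion), stray light, printed
target edge softness, and detector nonlinearity. Passing round-trip tests
therefore demonstrates that the estimators recover what the forward model
injects at realistic noise — not that any physical instrument meets these
numbers.

## Numerical choices and degenerate inputs

* Peak prominence is topographic; flat spectra return zero peaks rather
  than erroring.
* Band extraction ties break toward the lower index; out-of-range requests
  error.
* Non-positive white-minus-dark denominators are flagged in a mask, never
  silent NaNs; reflectance is clipped at 1.5 (configurable) so specular
  pixels stay visible.
* The cubic fit refuses designs spanning less than a third of the detector
  and conditions worse than 1e10.
* `measure_fwhm()` flags one-sided estimates and single-hot-pixel
  "under-resolved" cases instead of fabricating a width.
* All stochastic simulation calls require a seed; identical config + seed
  reproduces byte-identical cubes and protocol reports.

## Problem sizes

The shipped tests and the acceptance script run the full-resolution
spectral axis (2048 px) for wavelength calibration, and reduced axes
(512–1024 px spanning the same 400–1000 nm) for characterization round
trips and geometry work, with slit extents of 64–320 px and 1–30 frames per
measurement. These sizes were chosen so each estimator operates in the same
regime as on real data (peak widths in pixels, edge sampling, noise per
pixel) while a complete run stays interactive on a laptop.

## Known limitations

* Only the ENVI-style header+binary dialect is implemented for cube I/O.
* Smile/keystone are measured, not corrected; resampling cubes to remove
  them is out of scope.
* The reference-spectrometer arm of the verification is simulated (scaled
  synthetic transmittances); with real data, feed the measured two-column
  CSV into `fit_normalization_factor()` directly.
* Air wavelengths only; no air↔vacuum conversion is applied beyond the
  bundled table.
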