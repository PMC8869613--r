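---
title: "Stereo NIR-II vessel depth reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereo NIR-II vessel depth reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nirstereo)
```

## The measurement problem

Near-infrared-II (1000–1700 nm) fluorescence imaging sees blood vessels
several millimetres deep in tissue because scattering and
autofluorescence are low in that window. A single camera, however, only
gives a 2D projection. `nirstereo` implements the binocular-stereo route
to the third dimension: one InGaAs camera is translated laterally on a
stage by a baseline $b$, giving a left-eye and a right-eye view of the
same fluorescent vasculature. A scene point at distance $Z$ from the
camera images at horizontal positions differing by the *disparity*
$d = X_L - X_R$, and for $Z \gg f$,

$$Z \approx \frac{b\,f}{d},$$

with $f$ the focal length. Depth differences map to disparity
differences $\Delta d \approx b f \,\Delta Z / Z^2$, and a matching
error of $\Delta p$ (in metric sensor units) limits the achievable depth
resolution to

$$D_r \approx \frac{Z^2}{f\,b}\,\Delta p .$$

At the default geometry ($Z = 450$ mm, $b = 40$ mm, $f = 35$ mm, 20 µm
pixels) one pixel of disparity error is worth
`theoreticalDepthResolution(stereoRig(), 0.020)` ≈ 2.9 mm of depth, and
a 1 mm depth step moves the disparity by only ≈ 0.35 px. Everything in
this package exists to make the effective $\Delta p$ much smaller than a
pixel: sub-pixel cost interpolation brings the per-pixel error to a few
tenths of a pixel, and averaging over the hundreds of pixels of a
segmented vessel brings the per-vessel error down to the ≈ 0.2 px that a
0.6 mm depth resolution requires.

Because the camera moves on a pure horizontal stage, epipolar lines are
image rows and no rectification is applied; the package assumes
row-aligned input pairs throughout.

## Pipeline

`runPipeline()` chains five stages; each is exported on its own.

**1. Intensity normalization** (`normalizeIntensity`). Depth attenuation
makes vessel brightness span an order of magnitude within one frame.
Inputs are scaled by their 0.999 quantile, clipped to $[0,1]$ and
gamma-compressed ($\gamma = 0.5$). Without this, the structureness
normalization of the vesselness filter (whose reference is the brightest
structure in the frame) suppresses deep, dim vessels below the
segmentation threshold. The census matching cost is invariant to any
monotone intensity map, so this stage cannot bias disparities.

**2. Vessel enhancement** (`enhanceMultiscale`). The classical
two-eigenvalue 2D vesselness: at each Gaussian scale $\sigma$ the
$\sigma^2$-normalized Hessian is diagonalized per pixel
($|\lambda_1| \le |\lambda_2|$), and the response
$$\exp\!\left(-\frac{(\lambda_1/\lambda_2)^2}{2\beta^2}\right)
  \left(1 - e^{-S^2/2c^2}\right), \qquad
  S = \sqrt{\lambda_1^2 + \lambda_2^2},$$
is zeroed where $\lambda_2 \ge 0$ (bright vessels) and maximized over
scales. Defaults: $\beta = 0.5$; $c$ = half the maximum structureness at
each scale (with a numerical floor so flat images return exactly zero);
scales $\{1,2,4,6,8\}$ px spanning thin vessels to scattering-broadened
ones. For a Gaussian ridge of transverse width $\sigma_r$ the
$\sigma^2$-normalized crest response peaks at
$\sigma = \sqrt{2}\,\sigma_r$; the tests pin this closed form.
Segmentation is Otsu by default (deterministic, parameter-free) with
components under 50 px removed as speckle.

**3. Semi-global matching** (`computeDisparity`). Census descriptors
(7×7) are compared by Hamming distance — robust against the
view-to-view illumination changes a moving camera causes; a
window-mean absolute-difference cost is available as `cost = "sad"`.
Costs are aggregated along 8 paths with the standard recurrence
(penalties $P_1 = 10$ for ±1 disparity, $P_2 = 120$ otherwise,
census-scale defaults), followed by winner-take-all with ties broken
toward smaller disparity. The disparity search window is not guessed: it
is derived from the rig as $b f / (Z \pm z_\text{span})$ in pixels,
padded by 2 px (`disparitySearchRange`, $z_\text{span}$ = 15 mm
default). A left–right consistency check (tolerance 1 px) from a second,
right-referenced matching pass invalidates occlusions and mismatches.

**Sub-pixel refinement.** The integer winner $d$ is refined from the
aggregated costs at $d-1, d, d+1$. Two interpolants are implemented: the
parabola
$d^* = d + \frac{C(d-1)-C(d+1)}{2\,(C(d-1)-2C(d)+C(d+1))}$
and the equiangular (two-line) fit
$d^* = d + \frac{C(d-1)-C(d+1)}{2\,(\max(C(d-1),C(d+1))-C(d))}$.
Census and SAD costs grow essentially linearly in $|d - d_\text{true}|$
near the minimum, for which the equiangular fit is exact while the
parabola is biased toward integers by up to ≈ 0.09 px ("pixel
locking"); on rendered phantoms the equiangular default halves the
layer-separation bias. Offsets are clamped to $(-0.5, 0.5)$; boundary
winners and non-convex triples keep their integer value.

**4. Depth reconstruction** (`reconstructDepth`, `perVesselDepth`,
`colorizeDepth`). Valid disparities inside the vessel mask are
triangulated and reported as signed depth relative to a configurable
zero plane (negative = deeper), the display convention of the original
system. Per-vessel statistics use the mean over each connected
component (median optional). Depth renders interpolate linearly through
equally spaced red–yellow–green–blue anchors; the spacing is a package
choice, the sequence is the published one.

**5. I/O** (`readImageTiff`, `writeImageTiff`, `readPipelineConfig`).
Images are single-channel TIFF; disparity and depth maps are stored as
32-bit IEEE-float TIFF with NaN marking invalid pixels. The `tiff`
package clamps written data to $[0,1]$, so the package carries a
minimal single-strip float-TIFF writer of its own; reading uses
`tiff::readTIFF`, which handles float files correctly. Configuration is
YAML validated against a fixed schema (unknown keys and missing
required fields are errors that name the field); the shipped defaults
live in `inst/extdata/default_config.yaml`.

## The synthetic phantom simulator

The physical apparatus is replaced by a renderer that emulates the two
validation experiments: capillaries in 1% Intralipid, and a two-layer
3D-printed vessel phantom.

**Geometry.** Tubes are 3D polylines with radius and emission. A tube at
depth $z$ below the medium surface sits at camera distance
$Z_0 + s + z$ ($s$ = `surfaceOffset`, the surface position relative to
the reference plane). Pinhole projection displaces the camera centers by
$\mp b/2$, so a rendered tube carries exactly the disparity
$b f / Z$ — verified to < 0.05 px by sub-pixel centroid tests. The
transverse profile is the chord length $2\sqrt{r^2 - x^2}$ of the
cylinder (the line integral a fluorescent lumen produces), *not* a
Gaussian; its FWHM is $r\sqrt{3}$. Rendering supersamples 3×3 per pixel.

**Scattering medium.** Each tube's contribution is scaled by
$e^{-\mu_\text{eff} (z - 1\,\text{mm})}$ and convolved with a Gaussian
PSF of FWHM $w_1 + w' (z - 1\,\text{mm})$. The coefficients are
*calibrated to image-domain observables*, not taken from literature
optics: $\mu_\text{eff} = \ln 2 / 3$ mm⁻¹ (1100-LP) and $\ln 2$ mm⁻¹
(1300-LP) follow from the measured half-intensity depths of 4 mm and
2 mm, and $(w_1, w')$ are root-solved in `scripts/calibrate_medium.R` —
through the package's own render → profile → fit pipeline — so the
fitted capillary FWHM reproduces the measured 1.87/9.08 mm (1100-LP)
and 1.25/2.44 mm (1300-LP) at 1 and 6 mm depth. The committed script
makes the shipped numbers auditable. The 1400-LP band has no published
phantom measurements, so `mediumModel("LP1400")` requires explicit
coefficients.

**Noise.** Signal-dependent Gaussian noise (variance = signal /
`photonScale`) plus additive read noise, rounded and clipped to 16 bits;
bit-reproducible for a fixed seed. Defaults (`photonScale` 0.1, read
noise 100 counts, peak exposure 30 000 counts) give SNR ≈ 50 at the
vessel crest, representative of a cooled InGaAs camera at these
integration times.

**Canonical scenes.** `makeTwoLayerPhantom()` builds the validation
phantom: four 1 mm-diameter vessels in a 40 × 30 mm field, two at
7.5 mm and two at 8.5 mm depth (1 mm layer gap), as gently curved
near-vertical branches. With the surface 1.5 mm nearer the camera than
the reference plane, displayed depths fall at −6/−7 mm, inside the
−6…−10 mm window the original depth maps use. The exact branch
curvature of the printed phantom is only known pictorially; counts,
diameters, depths and extent are matched. `makeTubePairScene(gap)`
renders two tubes at a controlled depth gap for resolution studies; its
tubes carry gentle opposite tilts (1 mm over a 14 mm run) because
perfectly pixel-grid-aligned tubes would give every row the same
sub-pixel sampling phase — a coherent-bias worst case no real vessel
exhibits — whereas a tilt of a few pixels lets the phase average out
along the tube, exactly as the curved canonical phantom does.

**What the simulator does not model.** No radiative transfer or photon
Monte-Carlo; blur and attenuation are depth-parametrized Gaussians
calibrated at the measured endpoints. No tissue heterogeneity, no
motion, no camera fixed-pattern noise, no in vivo anatomy. Passing
tests therefore demonstrate that the *reconstruction chain* meets its
accuracy targets under the stated optical conditions, not that those
conditions exhaust real tissue.

## Profile analysis

`lineProfile` samples intensity along a segment with perpendicular
width-averaging (variance ↓ ≈ 1/width); `fitGaussianFwhm` fits
$A e^{-(x-\mu)^2/2\sigma^2} + b$ by Levenberg–Marquardt
(`minpack.lm::nls.lm`, residual form — the formula interface fails on
noise-free profiles) with deterministic moment-based initialization and
internal unit-scaling so fits are intensity-scale invariant;
FWHM $= 2\sqrt{2\ln 2}\,\sigma$ exactly. Non-convergence is flagged on
the returned object, never silent. `intensityVsDepth` normalizes mean
ROI intensity to the shallowest depth and interpolates the first 0.5
crossing linearly. Its default ROI is the full frame: blur redistributes
but conserves signal, so a wide ROI makes the normalized curve track
attenuation; a tight ROI around the tube would conflate attenuation
with blur leakage and could not reproduce the calibrated half-intensity
depths (measured half-depths come out ≈ 1 % short of the analytic
values because deeper tubes subtend marginally smaller solid angles —
real perspective, kept).

## Numerical choices and degenerate inputs

* Hessian kernels are sampled Gaussian derivatives with the
  second-derivative kernel projected to exact zero sum, so constant
  images give identically zero eigenvalues; the auto-$c$ rule floors the
  structureness reference at $10^{-8}$ to keep numerically flat images
  at zero response rather than amplifying FFT noise.
* Separable convolutions replicate borders; images smaller than the
  kernel are edge-padded first. FFT filtering can leave $O(10^{-12})$
  negative ringing, which the normalizer clips before gamma
  compression.
* Out-of-bounds matches carry a sentinel maximal cost; winner-take-all
  marks pixels with no in-bounds disparity invalid, and ties break
  toward the smaller disparity, deterministically.
* Zero-length profiles, empty masks, non-positive disparities,
  non-crossing intensity curves and non-convergent fits raise errors,
  warnings, or flagged results as documented — never silent numbers.
* All randomness (detector noise) flows through explicit integer seeds;
  renders and pipeline outputs are bit-reproducible.

## Problem sizes and validation design

The validation suite renders the canonical phantom at the full 640 × 512
sensor. The depth-resolution study (gaps 2.0/1.5/1.0/0.8/0.6 mm × 20
noise seeds) runs on a 224 × 112 crop of the same sensor with identical
optics: depth accuracy is set by the geometry and the matcher, not by
the sensor extent, and the crop keeps one hundred full pipeline runs to
about a minute. On these conditions the pipeline orders a 0.6 mm layer
gap correctly in ≥ 95 % of seeds and holds per-vessel RMSE near 0.2 mm,
comfortably inside the 0.6 mm theoretical unit.

## Known limitations

* Matching assumes row-aligned views; stage pitch/yaw is not modeled or
  corrected (the physical system's one-axis stage justifies this, but
  real stage wobble would need rectification).
* Per-vessel depth uses the segmented mask; for heavily blurred deep
  vessels the mask's halo pixels carry slightly biased disparities
  (≈ 0.1 px), visible as a few tenths of a millimetre on absolute layer
  depths while largely cancelling in layer separations.
* The medium model is band-specific and calibrated to 1 % Intralipid
  only; other concentrations or tissues require recalibration against
  their own depth series.
* Vesselness is 2D; overlapping vessels at different depths merge in
  the mask and are resolved only by their disparities.
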