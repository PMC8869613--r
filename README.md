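# nirstereo

3D reconstruction of blood-vessel depth from stereo NIR-II fluorescence
image pairs.

Near-infrared-II (1000–1700 nm) fluorescence imaging visualizes
vasculature millimetres deep in tissue, but a single camera only yields
a 2D projection. A practical route to depth is binocular stereo with
one InGaAs camera translated on a stage: a left-eye and a right-eye
view separated by a baseline *b*. A scene point at distance *Z* then
appears with horizontal disparity *d* = *X<sub>L</sub>* −
*X<sub>R</sub>*, and for *Z* ≫ *f*,

&nbsp;&nbsp;&nbsp;&nbsp;*Z* ≈ *b·f* / *d*,

so measuring per-pixel disparity measures per-pixel depth. A disparity
error Δp limits the depth resolution to

&nbsp;&nbsp;&nbsp;&nbsp;*D<sub>r</sub>* ≈ *Z*² · Δp / (*f·b*),

which at the default geometry (Z = 450 mm, b = 40 mm, f = 35 mm,
20 µm pixels) is 2.9 mm per pixel of matching error — hence the need
for sub-pixel matching and per-vessel averaging to reach sub-millimetre
depth resolution.

The package implements the full chain, plus the synthetic phantoms used
to validate it:

* **Vessel enhancement** — multiscale Hessian (two-eigenvalue)
  vesselness with Otsu segmentation (`enhanceMultiscale`,
  `segmentVessels`).
* **Stereo matching** — semi-global matching with census (or SAD)
  costs, 8-path aggregation, winner-take-all, sub-pixel refinement and
  left–right consistency (`computeDisparity` and its components).
* **Geometry** — disparity ↔ depth conversion and theoretical depth
  resolution (`disparityToDistance`, `disparityMapToDepthMap`,
  `theoreticalDepthResolution`).
* **Depth maps** — vessel-masked signed depth, per-vessel statistics,
  red–yellow–green–blue rendering (`reconstructDepth`,
  `perVesselDepth`, `colorizeDepth`).
* **Phantom simulator** — tube scenes projected through the stereo
  optics with a calibrated Intralipid-like scattering medium
  (attenuation + depth-growing PSF) and reproducible detector noise
  (`makeTwoLayerPhantom`, `renderStereoPair`,
  `makeCapillaryDepthSeries`).
* **Profile analysis** — line profiles, Gaussian FWHM fits,
  intensity-versus-depth curves, depth-recovery scoring
  (`lineProfile`, `fitGaussianFwhm`, `intensityVsDepth`,
  `depthRecoveryMetrics`).

`runPipeline()` ties the stages together (TIFF/PNG/CSV artifacts, YAML
configuration); `inst/cli/nirstereo.R` is a thin command-line front end
with `simulate`, `enhance`, `match`, `run` and `analyze` subcommands.

## Worked example

Render the canonical two-layer vessel phantom (four 1 mm vessels, two
at 7.5 mm depth and two at 8.5 mm, in a 40 × 30 mm field) through the
default rig and the 1300-LP scattering model, then reconstruct it:

```r
library(nirstereo)

rig  <- stereoRig()            # b = 40 mm, Z = 450 mm, f = 35 mm
scn  <- makeTwoLayerPhantom()
pair <- renderStereoPair(scn, rig, mediumModel("LP1300"),
                         noise = noiseModel(seed = 42))
res  <- runPipeline(pair$left, pair$right)
res$perVessel
#>   component meanDepthMm stdMm nPixels
#> 1         1       -5.91 0.512    1493
#> 2         2       -7.04 0.702    1023
#> 3         3       -6.02 0.527    1407
#> 4         4       -6.79 0.671    1122

m <- depthRecoveryMetrics(res$depth, pair$truth)
m$layerSeparationMm
#> [1] 0.94
```

Depths are signed millimetres relative to the reference plane
(negative = deeper). The phantom surface sits 1.5 mm nearer the camera
than that plane, so the 7.5 mm / 8.5 mm tube layers display at −6 and
−7 mm: components 1 and 3 are the upper layer, 2 and 4 the lower, and
the recovered layer separation (0.94 mm here) matches the phantom's
1 mm gap well inside the 0.6 mm depth-resolution unit of the geometry:

```r
theoreticalDepthResolution(rig, pixelsToMetricDisparity(0.21, rig@camera))
#> [1] 0.6
```

`res$color` holds the red–yellow–green–blue depth render;
`runPipeline(..., outDir = "out/")` writes all artifacts (enhanced
views, float-TIFF disparity and depth with NaN invalids, PNG render,
per-vessel CSV, resolved config).

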