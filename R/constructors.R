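#' Construct a CameraModel
#'
#' @param focalLength focal length in mm (default 35, the C-mount lens used
#'   on the stereo rig).
#' @param pixelPitch detector pixel pitch in um/pixel (default 20).
#' @param sensorWidth,sensorHeight sensor size in pixels (default 640 x 512).
#' @param principalPoint principal point (x, y) in 1-based pixel
#'   coordinates; default the sensor center.
#' @return a \linkS4class{CameraModel}.
#' @examples
#' cam <- cameraModel()
#' pixelSizeAt(cam, 450)  # object-plane pixel size at 450 mm, in mm
#' @export
cameraModel <- function(focalLength = 35, pixelPitch = 20,
                        sensorWidth = 640, sensorHeight = 512,
                        principalPoint = c((sensorWidth + 1) / 2,
                                           (sensorHeight + 1) / 2)) {
  new("CameraModel", focalLength = focalLength, pixelPitch = pixelPitch,
      sensorWidth = sensorWidth, sensorHeight = sensorHeight,
      principalPoint = principalPoint)
}

#' Construct a StereoRig
#'
#' Defaults reproduce the published system geometry: 40 mm baseline, 450 mm
#' object distance, 35 mm lens.
#'
#' @param camera a \linkS4class{CameraModel}.
#' @param baseline baseline in mm.
#' @param referenceDistance object distance of the reference plane, mm.
#' @param referencePlaneOffset depth of the zero plane relative to the
#'   reference distance, mm.
#' @return a \linkS4class{StereoRig}.
#' @export
stereoRig <- function(camera = cameraModel(), baseline = 40,
                      referenceDistance = 450, referencePlaneOffset = 0) {
  new("StereoRig", camera = camera, baseline = baseline,
      referenceDistance = referenceDistance,
      referencePlaneOffset = referencePlaneOffset)
}

#' Construct a DisparityMap
#' @param values numeric matrix of disparities (pixels).
#' @param valid logical matrix; default all finite values.
#' @param searchRange numeric(2) (d_min, d_max); default the value range.
#' @return a \linkS4class{DisparityMap}.
#' @export
disparityMap <- function(values, valid = is.finite(values),
                         searchRange = range(values[valid])) {
  if (!length(searchRange) || searchRange[1] >= searchRange[2])
    searchRange <- c(searchRange[1] - 0.5, searchRange[1] + 0.5)
  new("DisparityMap", values = values, valid = valid,
      searchRange = as.numeric(searchRange))
}

#' Construct a DepthMap
#' @param values numeric matrix of depths (mm); NA invalid.
#' @param valid logical matrix; default finite values.
#' @return a \linkS4class{DepthMap}.
#' @export
depthMap <- function(values, valid = is.finite(values)) {
  values[!valid] <- NA_real_
  new("DepthMap", values = values, valid = valid)
}

#' Construct vessel-enhancement parameters
#' @param scales Gaussian scales in pixels; default 1:4 doubled coverage
#'   c(1, 2, 4, 6, 8) spanning thin to scattering-broadened vessels.
#' @param beta blobness sensitivity (default 0.5).
#' @param c structureness sensitivity; NA (default) picks half the maximum
#'   structureness at each scale.
#' @param brightOnDark enhance bright vessels on dark background.
#' @return an \linkS4class{EnhancementParams}.
#' @export
enhancementParams <- function(scales = c(1, 2, 4, 6, 8), beta = 0.5,
                              c = NA_real_, brightOnDark = TRUE) {
  new("EnhancementParams", scales = scales, beta = beta, c = c,
      brightOnDark = brightOnDark)
}

#' Construct semi-global matching parameters
#' @param dMin,dMax integer disparity search bounds (pixels).
#' @param cost "census" (default, robust to view-to-view illumination
#'   changes) or "sad".
#' @param censusWindow odd window size (default 7).
#' @param P1,P2 small/large disparity-change penalties (census-scale
#'   defaults 10 and 120).
#' @param nPaths 4 or 8 aggregation directions (default 8).
#' @param lrTolerance left-right consistency threshold in pixels.
#' @param subpixel refine the integer winner by local cost interpolation.
#' @param subpixelMethod "equiangular" (default; exact for the V-shaped
#'   cost minima census and SAD produce) or "parabola".
#' @return an \linkS4class{SGMParams}.
#' @export
sgmParams <- function(dMin, dMax, cost = c("census", "sad"),
                      censusWindow = 7, P1 = 10, P2 = 120, nPaths = 8,
                      lrTolerance = 1, subpixel = TRUE,
                      subpixelMethod = c("equiangular", "parabola")) {
  new("SGMParams", dMin = dMin, dMax = dMax, cost = match.arg(cost),
      censusWindow = censusWindow, P1 = P1, P2 = P2, nPaths = nPaths,
      lrTolerance = lrTolerance, subpixel = subpixel,
      subpixelMethod = match.arg(subpixelMethod))
}

#' Construct a Tube
#' @param centerline n x 3 matrix (x, y, z) in mm, or n x 2 with a common
#'   depth given via `z`.
#' @param radius tube radius in mm (default 0.55, the ID 1.1 mm capillary).
#' @param emission relative emission intensity.
#' @param z common depth in mm when centerline is n x 2.
#' @return a \linkS4class{Tube}.
#' @export
tube <- function(centerline, radius = 0.55, emission = 1, z = NULL) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) == 2) {
    if (is.null(z)) stop("supply z when centerline has no depth column")
    centerline <- cbind(centerline, z)
  }
  colnames(centerline) <- c("x", "y", "z")
  new("Tube", centerline = centerline, radius = radius, emission = emission)
}

#' Construct a VesselScene
#' @param tubes list of \linkS4class{Tube}.
#' @param extent lateral field (width, height) in mm.
#' @param surfaceOffset depth of the medium surface relative to the
#'   reference distance, mm.
#' @return a \linkS4class{VesselScene}.
#' @export
vesselScene <- function(tubes, extent = c(40, 30), surfaceOffset = -1.5) {
  new("VesselScene", tubes = tubes, extent = extent,
      surfaceOffset = surfaceOffset)
}

#' Construct a detector noise model
#' @param photonScale counts per emission unit for the shot-noise term
#'   (variance = signal / photonScale); Inf disables shot noise.
#' @param readNoiseSd additive read noise sd in counts.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return a \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(photonScale = 0.1, readNoiseSd = 100, seed = 1) {
  new("NoiseModel", photonScale = photonScale, readNoiseSd = readNoiseSd,
      seed = seed)
}

# ---- accessors ----

#' Accessors for map-like objects
#'
#' `mapValues` returns the numeric matrix, `validMask` the logical validity
#' mask, `searchRange` the disparity search bounds.
#' @param x a \linkS4class{DisparityMap} or \linkS4class{DepthMap}.
#' @return matrix / logical matrix / numeric(2).
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname mapValues
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname mapValues
#' @export
setGeneric("searchRange", function(x) standardGeneric("searchRange"))

#' @rdname mapValues
setMethod("mapValues", "DisparityMap", function(x) x@values)
#' @rdname mapValues
setMethod("mapValues", "DepthMap", function(x) x@values)
#' @rdname mapValues
setMethod("validMask", "DisparityMap", function(x) x@valid)
#' @rdname mapValues
setMethod("validMask", "DepthMap", function(x) x@valid)
#' @rdname mapValues
setMethod("validMask", "VesselMask", function(x) x@mask)
#' @rdname mapValues
setMethod("searchRange", "DisparityMap", function(x) x@searchRange)

#' Object-plane pixel size
#'
#' Size in mm of one detector pixel back-projected to an object plane at
#' distance Z: pitch * Z / f.
#' @param camera a \linkS4class{CameraModel}.
#' @param distance object distance Z in mm.
#' @return pixel size in mm.
#' @export
pixelSizeAt <- function(camera, distance) {
  camera@pixelPitch * 1e-3 * distance / camera@focalLength
}

# ---- show methods ----

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel: f = %g mm, pitch = %g um, sensor %d x %d px\n",
              object@focalLength, object@pixelPitch,
              as.integer(object@sensorWidth),
              as.integer(object@sensorHeight)))
})

setMethod("show", "StereoRig", function(object) {
  cat(sprintf(
    "StereoRig: b = %g mm, Z = %g mm (zero plane %+g mm), f = %g mm\n",
    object@baseline, object@referenceDistance,
    object@referencePlaneOffset, object@camera@focalLength))
})

setMethod("show", "DisparityMap", function(object) {
  v <- object@values[object@valid]
  cat(sprintf(
    "DisparityMap: %d x %d px, search [%g, %g] px, %.1f%% valid%s\n",
    nrow(object@values), ncol(object@values), object@searchRange[1],
    object@searchRange[2], 100 * mean(object@valid),
    if (length(v)) sprintf(", median %.2f px", stats::median(v)) else ""))
})

setMethod("show", "DepthMap", function(object) {
  v <- object@values[object@valid]
  cat(sprintf("DepthMap: %d x %d px, %.1f%% valid%s\n",
              nrow(object@values), ncol(object@values),
              100 * mean(object@valid),
              if (length(v)) sprintf(", range [%.2f, %.2f] mm",
                                     min(v), max(v)) else ""))
})

setMethod("show", "VesselScene", function(object) {
  z <- vapply(object@tubes, function(t) mean(t@centerline[, 3]), numeric(1))
  cat(sprintf(
    "VesselScene: %d tubes, extent %g x %g mm, depths %s mm, surface %+g mm\n",
    length(object@tubes), object@extent[1], object@extent[2],
    paste(round(z, 2), collapse = "/"), object@surfaceOffset))
})

setMethod("show", "MediumModel", function(object) {
  cat(sprintf(
    "MediumModel %s: muEff = %.4g /mm, PSF FWHM %.3g mm @1mm + %.3g mm/mm\n",
    object@band, object@muEff, object@psfFwhmAt1mm, object@psfFwhmSlope))
})

setMethod("show", "ProfileFit", function(object) {
  cat(sprintf(
    "ProfileFit: FWHM = %.4g (sigma %.4g), center %.4g, amp %.4g, rmse %.3g%s\n",
    object@fwhm, object@sigma, object@center, object@amplitude, object@rmse,
    if (object@converged) "" else " [NOT CONVERGED]"))
})
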