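#' @import methods
NULL

#' Camera intrinsics for the NIR-II stereo rig
#'
#' Pinhole model of the InGaAs camera: focal length, detector pixel pitch,
#' sensor size and principal point. The default matches the 640 x 512
#' short-wave-infrared sensor class with a 35 mm lens; the pixel pitch is a
#' declared parameter (20 um typical for these detectors), since metric
#' disparity is pitch times pixel disparity.
#'
#' @slot focalLength focal length f in mm.
#' @slot pixelPitch detector pixel pitch in um/pixel.
#' @slot sensorWidth,sensorHeight sensor size in pixels (columns, rows).
#' @slot principalPoint numeric(2), principal point (x = column, y = row) in
#'   1-based pixel coordinates.
#' @export
setClass("CameraModel",
  representation(focalLength = "numeric", pixelPitch = "numeric",
                 sensorWidth = "numeric", sensorHeight = "numeric",
                 principalPoint = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@focalLength) != 1 || object@focalLength <= 0)
      msg <- c(msg, "focalLength must be a single positive number (mm)")
    if (length(object@pixelPitch) != 1 || object@pixelPitch <= 0)
      msg <- c(msg, "pixelPitch must be a single positive number (um)")
    if (object@sensorWidth < 1 || object@sensorHeight < 1)
      msg <- c(msg, "sensor dimensions must be positive")
    if (length(object@principalPoint) != 2)
      msg <- c(msg, "principalPoint must be length 2 (x, y)")
    else if (object@principalPoint[1] < 1 ||
             object@principalPoint[1] > object@sensorWidth ||
             object@principalPoint[2] < 1 ||
             object@principalPoint[2] > object@sensorHeight)
      msg <- c(msg, "principalPoint must lie inside the sensor")
    if (is.null(msg)) TRUE else msg
  })

#' Stereo rig geometry
#'
#' A single camera translated horizontally on a stage: baseline b between
#' the two optical centers, object (reference) distance Z, and the offset of
#' the depth zero plane relative to the reference distance. Epipolar lines
#' are image rows (pure horizontal translation), so no rectification is
#' applied.
#'
#' @slot camera a \linkS4class{CameraModel}.
#' @slot baseline baseline b in mm.
#' @slot referenceDistance object distance Z of the reference plane in mm;
#'   must be much larger than the focal length.
#' @slot referencePlaneOffset depth of the zero plane relative to
#'   referenceDistance, mm (default 0).
#' @export
setClass("StereoRig",
  representation(camera = "CameraModel", baseline = "numeric",
                 referenceDistance = "numeric",
                 referencePlaneOffset = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@baseline <= 0) msg <- c(msg, "baseline must be positive (mm)")
    if (object@referenceDistance <= 0)
      msg <- c(msg, "referenceDistance must be positive (mm)")
    if (object@referenceDistance <= 5 * object@camera@focalLength)
      msg <- c(msg, "referenceDistance must be much larger than focalLength")
    if (is.null(msg)) TRUE else msg
  })

#' Per-pixel horizontal disparity with validity mask
#'
#' Disparity d = X_L - X_R in pixels (signed; positive for objects nearer
#' than infinity), stored left-referenced, with a logical validity mask and
#' the disparity search range used.
#'
#' @slot values numeric matrix of disparities (pixels).
#' @slot valid logical matrix, same shape.
#' @slot searchRange numeric(2), (d_min, d_max) in pixels.
#' @export
setClass("DisparityMap",
  representation(values = "matrix", valid = "matrix",
                 searchRange = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@values) == dim(object@valid)))
      msg <- c(msg, "values and valid must have the same shape")
    if (!is.logical(object@valid)) msg <- c(msg, "valid must be logical")
    if (length(object@searchRange) != 2 ||
        object@searchRange[1] >= object@searchRange[2])
      msg <- c(msg, "searchRange must be (d_min, d_max) with d_min < d_max")
    else {
      v <- object@values[object@valid]
      v <- v[is.finite(v)]  # non-finite valid pixels drop out downstream
      if (length(v) && (min(v) < object@searchRange[1] - 1e-9 ||
                        max(v) > object@searchRange[2] + 1e-9))
        msg <- c(msg, "valid disparities must lie within searchRange")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Per-pixel metric depth relative to a reference plane
#'
#' Signed depth in mm; negative values are deeper than the reference plane
#' (the display convention used for the reconstructions). Invalid pixels are
#' NA and flagged in the mask.
#'
#' @slot values numeric matrix of depths (mm); NA where invalid.
#' @slot valid logical matrix, same shape.
#' @export
setClass("DepthMap",
  representation(values = "matrix", valid = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@values) == dim(object@valid)))
      msg <- c(msg, "values and valid must have the same shape")
    if (any(!is.finite(object@values[object@valid])))
      msg <- c(msg, "valid depths must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Parameters of the multiscale Hessian vessel-enhancement filter
#'
#' Standard two-eigenvalue 2D vesselness: blobness ratio R_B = l1/l2 with
#' sensitivity beta, structureness S = sqrt(l1^2 + l2^2) with sensitivity c
#' (NA = choose half the maximum structureness at each scale).
#'
#' @slot scales Gaussian scales sigma in pixels (vessel radius range).
#' @slot beta blobness sensitivity (> 0, dimensionless).
#' @slot c structureness sensitivity (> 0), or NA for automatic.
#' @slot brightOnDark TRUE for bright vessels on dark background.
#' @export
setClass("EnhancementParams",
  representation(scales = "numeric", beta = "numeric", c = "numeric",
                 brightOnDark = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@scales) == 0 || any(object@scales <= 0))
      msg <- c(msg, "scales must be nonempty and positive")
    if (object@beta <= 0) msg <- c(msg, "beta must be positive")
    if (!is.na(object@c) && object@c <= 0)
      msg <- c(msg, "c must be positive when numeric")
    if (is.null(msg)) TRUE else msg
  })

#' Binary vessel segmentation mask
#'
#' @slot mask logical matrix.
#' @slot minComponentSize smallest connected component retained (pixels).
#' @export
setClass("VesselMask",
  representation(mask = "matrix", minComponentSize = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) "mask must be logical" else TRUE
  })

#' Semi-global matching parameters
#'
#' @slot dMin,dMax disparity search bounds in integer pixels.
#' @slot cost "census" or "sad".
#' @slot censusWindow odd window size >= 3 (also the SAD window).
#' @slot P1 penalty for a one-pixel disparity change along a path.
#' @slot P2 penalty for larger changes (P2 > P1).
#' @slot nPaths number of aggregation directions, 4 or 8.
#' @slot lrTolerance left-right consistency threshold in pixels.
#' @slot subpixel logical, refine the winner by local cost interpolation.
#' @slot subpixelMethod "parabola" or "equiangular".
#' @export
setClass("SGMParams",
  representation(dMin = "numeric", dMax = "numeric", cost = "character",
                 censusWindow = "numeric", P1 = "numeric", P2 = "numeric",
                 nPaths = "numeric", lrTolerance = "numeric",
                 subpixel = "logical", subpixelMethod = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@dMin >= object@dMax) msg <- c(msg, "dMin must be < dMax")
    if (object@dMin != round(object@dMin) || object@dMax != round(object@dMax))
      msg <- c(msg, "dMin and dMax must be integers")
    if (!object@cost %in% c("census", "sad"))
      msg <- c(msg, "cost must be 'census' or 'sad'")
    w <- object@censusWindow
    if (w < 3 || w %% 2 != 1) msg <- c(msg, "censusWindow must be odd >= 3")
    if (object@cost == "census" && w > 7)
      msg <- c(msg, "censusWindow must be <= 7 for the census cost")
    if (object@P1 >= object@P2) msg <- c(msg, "P1 must be < P2")
    if (!object@nPaths %in% c(4, 8)) msg <- c(msg, "nPaths must be 4 or 8")
    if (!object@subpixelMethod %in% c("parabola", "equiangular"))
      msg <- c(msg, "subpixelMethod must be 'parabola' or 'equiangular'")
    if (is.null(msg)) TRUE else msg
  })

#' Matching cost volume (internal to SGM)
#'
#' @slot costs 3D array indexed (row, col, disparity).
#' @slot disparities disparity axis labels, dMin..dMax.
#' @slot sentinel cost assigned to out-of-bounds matches.
#' @slot inBounds logical matrix: any in-bounds disparity exists.
#' @export
setClass("CostVolume",
  representation(costs = "array", disparities = "numeric",
                 sentinel = "numeric", inBounds = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@costs)) != 3)
      msg <- c(msg, "costs must be a 3D array (row, col, disparity)")
    else if (dim(object@costs)[3] != length(object@disparities))
      msg <- c(msg, "third dimension must match disparities")
    if (any(object@costs < 0)) msg <- c(msg, "costs must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' A fluorescent tube (capillary or phantom vessel)
#'
#' @slot centerline n x 3 matrix of (x, y, z) in mm; x-y lateral, z depth
#'   below the medium surface (positive down).
#' @slot radius tube inner radius in mm.
#' @slot emission relative emission intensity (arbitrary units).
#' @export
setClass("Tube",
  representation(centerline = "matrix", radius = "numeric",
                 emission = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@centerline) != 3 || nrow(object@centerline) < 2)
      msg <- c(msg, "centerline must be an n x 3 matrix with n >= 2")
    if (object@radius <= 0) msg <- c(msg, "radius must be positive (mm)")
    if (object@emission < 0) msg <- c(msg, "emission must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' A 3D tube scene for the phantom simulator
#'
#' @slot tubes list of \linkS4class{Tube}.
#' @slot extent lateral field size (width, height) in mm, centered on the
#'   optical axis.
#' @slot surfaceOffset depth of the medium surface relative to the rig's
#'   reference distance, mm; a tube at depth z sits at camera distance
#'   referenceDistance + surfaceOffset + z.
#' @export
setClass("VesselScene",
  representation(tubes = "list", extent = "numeric",
                 surfaceOffset = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(vapply(object@tubes, is, logical(1), "Tube")))
      msg <- c(msg, "tubes must be a list of Tube objects")
    if (length(object@extent) != 2 || any(object@extent <= 0))
      msg <- c(msg, "extent must be positive (width, height) in mm")
    for (tb in object@tubes) {
      if (any(abs(tb@centerline[, 1]) > object@extent[1] / 2 + 1e-9) ||
          any(abs(tb@centerline[, 2]) > object@extent[2] / 2 + 1e-9)) {
        msg <- c(msg, "all tube centerlines must lie within extent")
        break
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Band-dependent scattering medium (1% Intralipid analog)
#'
#' Effective attenuation and linear PSF growth with depth, emulating the
#' long-pass collection bands: intensity scales as exp(-muEff * (z - 1)) and
#' the Gaussian PSF FWHM grows as psfFwhmAt1mm + psfFwhmSlope * (z - 1),
#' both relative to the shallowest measured depth (1 mm).
#'
#' @slot band "LP1100", "LP1300" or "LP1400".
#' @slot muEff effective attenuation coefficient, mm^-1.
#' @slot psfFwhmAt1mm PSF FWHM at 1 mm depth, mm.
#' @slot psfFwhmSlope PSF FWHM growth, mm per mm depth.
#' @export
setClass("MediumModel",
  representation(band = "character", muEff = "numeric",
                 psfFwhmAt1mm = "numeric", psfFwhmSlope = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@band %in% c("LP1100", "LP1300", "LP1400"))
      msg <- c(msg, "band must be LP1100, LP1300 or LP1400")
    if (object@muEff < 0) msg <- c(msg, "muEff must be >= 0")
    if (object@psfFwhmAt1mm < 0 || object@psfFwhmSlope < 0)
      msg <- c(msg, "PSF FWHM must be non-negative and non-decreasing in depth")
    if (is.null(msg)) TRUE else msg
  })

#' Detector noise model
#'
#' Signal-dependent (shot-like, variance = signal / photonScale) plus
#' additive Gaussian read noise; output is clipped to the 16-bit range and
#' bit-reproducible for a fixed seed.
#'
#' @slot photonScale counts per emission unit; Inf disables shot noise.
#' @slot readNoiseSd read noise standard deviation, counts.
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseModel",
  representation(photonScale = "numeric", readNoiseSd = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@photonScale <= 0) msg <- c(msg, "photonScale must be > 0")
    if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Gaussian fit of a line profile
#'
#' @slot amplitude,center,sigma,offset fitted Gaussian parameters
#'   (amplitude * exp(-(x - center)^2 / (2 sigma^2)) + offset).
#' @slot fwhm 2 sqrt(2 ln 2) * sigma, same units as center.
#' @slot rmse residual root-mean-square error.
#' @slot converged logical; FALSE flags an unreliable fit.
#' @export
setClass("ProfileFit",
  representation(amplitude = "numeric", center = "numeric",
                 sigma = "numeric", offset = "numeric", fwhm = "numeric",
                 rmse = "numeric", converged = "logical"),
  validity = function(object) {
    if (isTRUE(object@converged) &&
        (is.na(object@sigma) || object@sigma <= 0))
      "sigma must be positive for a converged fit" else TRUE
  })
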