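#' Triangulate object distance from metric disparity
#'
#' Binocular stereo with baseline b and focal length f: an object at
#' distance Z images with disparity d = X_L - X_R on the sensor, so
#' Z = b * f / d. Distance is strictly decreasing in disparity.
#'
#' @param disparityMetric disparity on the sensor in mm (> 0).
#' @param rig a \linkS4class{StereoRig}.
#' @return object distance Z in mm.
#' @examples
#' rig <- stereoRig()                      # b = 40 mm, f = 35 mm
#' disparityToDistance(40 * 35 / 450, rig) # 450 mm
#' @export
disparityToDistance <- function(disparityMetric, rig) {
  if (any(!is.finite(disparityMetric)) || any(disparityMetric <= 0))
    stop("invalid disparity: must be positive for triangulation")
  rig@baseline * rig@camera@focalLength / disparityMetric
}

#' Metric disparity of an object at distance Z
#'
#' Inverse of \code{\link{disparityToDistance}}: d = b * f / Z (mm on the
#' sensor).
#' @param distance object distance Z in mm (> 0).
#' @param rig a \linkS4class{StereoRig}.
#' @return disparity in mm.
#' @export
distanceToDisparity <- function(distance, rig) {
  if (any(!is.finite(distance)) || any(distance <= 0))
    stop("distance must be positive")
  rig@baseline * rig@camera@focalLength / distance
}

#' Convert pixel disparity to metric sensor disparity
#'
#' @param disparityPx disparity in pixels.
#' @param camera a \linkS4class{CameraModel}.
#' @return disparity in mm (pixels times pitch).
#' @export
pixelsToMetricDisparity <- function(disparityPx, camera) {
  disparityPx * camera@pixelPitch * 1e-3
}

#' Convert metric sensor disparity to pixels
#' @param disparityMm disparity in mm on the sensor.
#' @param camera a \linkS4class{CameraModel}.
#' @return disparity in pixels.
#' @export
metricToPixelDisparity <- function(disparityMm, camera) {
  disparityMm / (camera@pixelPitch * 1e-3)
}

#' Convert a disparity map to a signed depth map
#'
#' Per-pixel triangulation Z = b * f / d followed by conversion to signed
#' depth relative to the rig's zero plane:
#' depth = referenceDistance + referencePlaneOffset - Z, so negative values
#' are deeper than the reference plane. Pixels with invalid or non-positive
#' disparity propagate as invalid (NA).
#'
#' @param dmap a \linkS4class{DisparityMap} (pixel units).
#' @param rig a \linkS4class{StereoRig}.
#' @return a \linkS4class{DepthMap} in mm.
#' @export
disparityMapToDepthMap <- function(dmap, rig) {
  if (!any(dmap@valid)) warning("disparity map has no valid pixels")
  ok <- dmap@valid & is.finite(dmap@values) & dmap@values > 0
  depth <- matrix(NA_real_, nrow(dmap@values), ncol(dmap@values))
  if (any(ok)) {
    dMm <- pixelsToMetricDisparity(dmap@values[ok], rig@camera)
    z <- rig@baseline * rig@camera@focalLength / dMm
    depth[ok] <- rig@referenceDistance + rig@referencePlaneOffset - z
  }
  depthMap(depth, ok)
}

#' Theoretical depth resolution of a stereo system
#'
#' D_r = Z^2 * dp / (f * b): the depth change produced by a disparity error
#' dp at object distance Z. Proportional to Z^2, inversely proportional to
#' focal length and baseline, linear in the disparity error.
#'
#' @param rig a \linkS4class{StereoRig}.
#' @param disparityError disparity error dp in mm on the sensor (>= 0);
#'   one pixel pitch is the natural unit for unrefined matching.
#' @return depth resolution in mm.
#' @examples
#' rig <- stereoRig()
#' theoreticalDepthResolution(rig, 0.020)  # one 20-um pixel: ~2.9 mm
#' @export
theoreticalDepthResolution <- function(rig, disparityError) {
  if (any(disparityError < 0)) stop("disparityError must be >= 0")
  Z <- rig@referenceDistance
  Z^2 * disparityError / (rig@camera@focalLength * rig@baseline)
}

#' Disparity error implied by a depth resolution
#'
#' Inverts D_r = Z^2 * dp / (f * b) for dp; useful for asking what matching
#' accuracy a stated depth resolution requires (0.6 mm at the default
#' geometry needs about 0.21 px).
#' @param rig a \linkS4class{StereoRig}.
#' @param depthResolution D_r in mm (> 0).
#' @return disparity error in mm on the sensor.
#' @export
disparityErrorFor <- function(rig, depthResolution) {
  if (any(depthResolution <= 0)) stop("depthResolution must be positive")
  depthResolution * rig@camera@focalLength * rig@baseline /
    rig@referenceDistance^2
}

#' Disparity search range implied by the rig geometry
#'
#' Converts a depth span around the reference distance into integer pixel
#' disparity bounds via d = b * f / Z, padded by two pixels, tying the SGM
#' search window to the stated geometry.
#' @param rig a \linkS4class{StereoRig}.
#' @param zSpan half-width of the depth interval around referenceDistance,
#'   mm (default 15).
#' @param pad extra pixels on each side (default 2).
#' @return integer c(dMin, dMax) in pixels.
#' @export
disparitySearchRange <- function(rig, zSpan = 15, pad = 2) {
  Z <- rig@referenceDistance + c(zSpan, -zSpan)
  if (any(Z <= 0)) stop("zSpan too large for the reference distance")
  dPx <- metricToPixelDisparity(distanceToDisparity(Z, rig), rig@camera)
  c(floor(dPx[1]) - pad, ceiling(dPx[2]) + pad)
}
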