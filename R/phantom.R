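# Distance from the camera to a tube's (mean) depth plane.
.tubeDistance <- function(tb, scene, rig) {
  rig@referenceDistance + scene@surfaceOffset + mean(tb@centerline[, 3])
}

# Project one tube into a view ("left", "right" or "center") as its
# chord-length transverse profile; returns the ideal emission image and
# the geometric footprint mask.
.projectTube <- function(tb, scene, rig, view, supersample = 3) {
  cam <- rig@camera
  Z <- .tubeDistance(tb, scene, rig)
  xcam <- switch(view, left = -rig@baseline / 2,
                 right = rig@baseline / 2, center = 0)
  s <- pixelSizeAt(cam, Z)  # object-plane pixel size at this depth, mm
  nr <- as.integer(cam@sensorHeight); nc <- as.integer(cam@sensorWidth)
  x0 <- (1 - cam@principalPoint[1]) * s + xcam
  y0 <- (1 - cam@principalPoint[2]) * s
  poly <- tb@centerline[, 1:2, drop = FALSE]
  colPx <- (poly[, 1] - xcam) / s + cam@principalPoint[1]
  rowPx <- poly[, 2] / s + cam@principalPoint[2]
  if (any(colPx < 1 - 0.5 | colPx > nc + 0.5 |
          rowPx < 1 - 0.5 | rowPx > nr + 0.5)) {
    warning("tube projects (partly) outside the field of view; excluded")
    return(NULL)
  }
  chord <- .renderTubeCpp(nr, nc, x0, s, y0, s, poly, tb@radius,
                          as.integer(supersample))
  list(image = chord * tb@emission, mask = chord > 0, Z = Z,
       depth = mean(tb@centerline[, 3]), pixelSizeMm = s)
}

#' Project a tube scene through the stereo optics
#'
#' Ideal (pre-medium, noise-free) pinhole projection of all tubes into one
#' view; camera centers are displaced by -b/2 (left) and +b/2 (right), so a
#' tube at distance Z images with disparity b * f / Z between the views.
#' Each tube renders as its transverse chord-length profile (the line
#' integral through a cylinder).
#'
#' @param scene a \linkS4class{VesselScene}.
#' @param rig a \linkS4class{StereoRig}.
#' @param view "left", "right" or "center".
#' @param supersample sub-pixel sampling factor per axis (default 3).
#' @return emission image (matrix, chord-length units: mm times emission).
#' @export
projectScene <- function(scene, rig, view = c("left", "right", "center"),
                         supersample = 3) {
  view <- match.arg(view)
  validObject(scene)
  cam <- rig@camera
  out <- matrix(0, as.integer(cam@sensorHeight),
                as.integer(cam@sensorWidth))
  for (tb in scene@tubes) {
    p <- .projectTube(tb, scene, rig, view, supersample)
    if (!is.null(p)) out <- out + p$image
  }
  out
}

#' Add detector noise to an image
#'
#' Signal-dependent Gaussian noise with variance signal / photonScale plus
#' additive read noise, then rounding and clipping to the 16-bit range.
#' Bit-reproducible for a fixed seed.
#'
#' @param image numeric matrix in counts.
#' @param noise a \linkS4class{NoiseModel}.
#' @return noisy integer-valued matrix in [0, 65535].
#' @export
addNoise <- function(image, noise) {
  validObject(noise)
  withr::with_seed(as.integer(noise@seed), {
    shot <- if (is.finite(noise@photonScale))
      stats::rnorm(length(image), 0,
                   sqrt(pmax(image, 0) / noise@photonScale)) else 0
    read <- if (noise@readNoiseSd > 0)
      stats::rnorm(length(image), 0, noise@readNoiseSd) else 0
    out <- image + shot + read
  })
  matrix(pmin(pmax(round(out), 0), 65535), nrow(image))
}

#' Render a stereo pair of a tube scene with ground truth
#'
#' Projects every tube into the left and right views, applies the
#' scattering medium per tube depth, scales both views by a common
#' exposure, optionally adds detector noise, and returns per-pixel ground
#' truth (left-view depth map, vessel mask, and tube labels) for scoring.
#'
#' @param scene a \linkS4class{VesselScene}.
#' @param rig a \linkS4class{StereoRig}.
#' @param medium a \linkS4class{MediumModel}, or NULL for no medium.
#' @param noise a \linkS4class{NoiseModel}, or NULL for noise-free output.
#' @param exposure peak target in counts ("auto" scaling); a number scales
#'   the brightest pixel across both views to it (default 30000), NULL
#'   leaves chord-length units.
#' @param supersample renderer sub-pixel sampling factor.
#' @return list with `left`, `right` (matrices), and `truth`: a list with
#'   `depth` (left-view displayed depth, mm, NA off-vessel), `mask`
#'   (logical), `labels` (integer tube index), `tubeDepths` (mm below the
#'   surface, per tube), `pixelSizeMm`, and the displayed depth per tube
#'   `tubeDisplayDepths`.
#' @export
renderStereoPair <- function(scene, rig = stereoRig(),
                             medium = mediumModel("LP1300"), noise = NULL,
                             exposure = 30000, supersample = 3) {
  validObject(scene)
  views <- list()
  truthDepth <- matrix(NA_real_, as.integer(rig@camera@sensorHeight),
                       as.integer(rig@camera@sensorWidth))
  labels <- matrix(0L, nrow(truthDepth), ncol(truthDepth))
  best <- matrix(0, nrow(truthDepth), ncol(truthDepth))
  tubeDepths <- numeric(0)
  for (v in c("left", "right")) {
    acc <- matrix(0, nrow(truthDepth), ncol(truthDepth))
    for (i in seq_along(scene@tubes)) {
      p <- .projectTube(scene@tubes[[i]], scene, rig, v, supersample)
      if (is.null(p)) next
      contrib <- if (is.null(medium)) p$image
                 else applyMedium(p$image, p$depth, medium, p$pixelSizeMm)
      acc <- acc + contrib
      if (v == "left") {
        tubeDepths[i] <- p$depth
        take <- p$mask & (contrib > best)
        truthDepth[take] <- rig@referenceDistance +
          rig@referencePlaneOffset - p$Z
        labels[take] <- i
        best[take] <- contrib[take]
      }
    }
    views[[v]] <- acc
  }
  if (!is.null(exposure)) {
    peak <- max(max(views$left), max(views$right))
    if (peak > 0) {
      g <- exposure / peak
      views$left <- views$left * g
      views$right <- views$right * g
    }
  }
  if (!is.null(noise)) {
    views$left <- addNoise(views$left, noise)
    rightNoise <- new("NoiseModel", photonScale = noise@photonScale,
                      readNoiseSd = noise@readNoiseSd,
                      seed = noise@seed + 1e6)
    views$right <- addNoise(views$right, rightNoise)
  }
  list(left = views$left, right = views$right,
       truth = list(depth = truthDepth, mask = labels > 0L,
                    labels = labels, tubeDepths = tubeDepths,
                    tubeDisplayDepths = rig@referencePlaneOffset -
                      scene@surfaceOffset - tubeDepths,
                    pixelSizeMm = pixelSizeAt(rig@camera,
                                              rig@referenceDistance)))
}

#' The canonical two-layer abdominal-vessel phantom
#'
#' Four 1 mm diameter vessels in a 40 x 30 mm lateral extent, two at
#' 7.5 mm depth and two at 8.5 mm (1 mm layer gap), laid out as gently
#' curved, near-vertical branches. The medium surface sits 1.5 mm nearer
#' the camera than the reference plane, so the displayed depths fall in
#' the -6 to -10 mm window.
#'
#' @param surfaceOffset surface depth relative to the reference plane, mm.
#' @return a \linkS4class{VesselScene}.
#' @examples
#' makeTwoLayerPhantom()
#' @export
makeTwoLayerPhantom <- function(surfaceOffset = -1.5) {
  yy <- seq(-12, 12, length.out = 9)
  bend <- function(xb, amp, tilt)
    cbind(xb + amp * sin(pi * (yy + 12) / 24) + tilt * yy / 12, yy)
  tubes <- list(
    tube(bend(-12, 1.2, -1.0), radius = 0.5, z = 7.5),
    tube(bend(-4, -1.2, -0.3), radius = 0.5, z = 8.5),
    tube(bend(4, 1.2, 0.3), radius = 0.5, z = 7.5),
    tube(bend(12, -1.2, 1.0), radius = 0.5, z = 8.5))
  vesselScene(tubes, extent = c(40, 30), surfaceOffset = surfaceOffset)
}

#' A two-tube scene with a controlled depth gap
#'
#' Two parallel vertical 1 mm tubes separated laterally, one at `zUpper`
#' mm depth and one `gap` mm deeper; used for empirical depth-resolution
#' studies.
#'
#' @param gap depth gap in mm.
#' @param zUpper depth of the shallower tube, mm.
#' @param separation lateral separation, mm.
#' @param surfaceOffset surface depth relative to the reference plane, mm.
#' @return a \linkS4class{VesselScene}.
#' @export
makeTubePairScene <- function(gap = 1, zUpper = 7.5, separation = 8,
                              surfaceOffset = -1.5) {
  yy <- seq(-7, 7, length.out = 5)
  # gentle opposite tilts, as in the branching phantom: vessels are never
  # exactly pixel-grid aligned, which also decorrelates sampling phase
  # along the tube
  tubes <- list(
    tube(cbind(-separation / 2 + yy / 7, yy), radius = 0.5, z = zUpper),
    tube(cbind(separation / 2 - yy / 7, yy), radius = 0.5,
         z = zUpper + gap))
  vesselScene(tubes, extent = c(20, 16), surfaceOffset = surfaceOffset)
}

#' Render a single-capillary depth series
#'
#' One ID 1.1 mm glass capillary imaged (center view) at each requested
#' depth below the medium surface, through the band's scattering model —
#' the simulated analogue of the Intralipid depth series used to
#' characterize intensity and FWHM versus depth.
#'
#' @param depths capillary depths in mm (default 1:6).
#' @param medium a \linkS4class{MediumModel}.
#' @param rig a \linkS4class{StereoRig} (camera and distances).
#' @param noise optional \linkS4class{NoiseModel}; per-depth seeds are
#'   offset so frames are independent.
#' @param exposure counts for the shallowest frame's peak, or NULL for
#'   chord-length units. The same gain is applied to every depth so the
#'   attenuation profile is preserved.
#' @return list of records: depth, image, mask (geometric footprint),
#'   pixelSizeMm.
#' @export
makeCapillaryDepthSeries <- function(depths = 1:6,
                                     medium = mediumModel("LP1300"),
                                     rig = stereoRig(), noise = NULL,
                                     exposure = 30000) {
  stopifnot(all(depths > 0))
  out <- vector("list", length(depths))
  gain <- NULL
  for (i in seq_along(depths)) {
    z <- depths[i]
    scn <- vesselScene(list(tube(cbind(0, c(-8, 8)), radius = 0.55, z = z)),
                       extent = c(20, 20), surfaceOffset = 0)
    p <- .projectTube(scn@tubes[[1]], scn, rig, "center")
    im <- applyMedium(p$image, z, medium, p$pixelSizeMm)
    if (!is.null(exposure)) {
      if (is.null(gain)) gain <- exposure / max(im)
      im <- im * gain
    }
    if (!is.null(noise)) {
      ns <- new("NoiseModel", photonScale = noise@photonScale,
                readNoiseSd = noise@readNoiseSd, seed = noise@seed + i)
      im <- addNoise(im, ns)
    }
    out[[i]] <- list(depth = z, image = im, mask = p$mask,
                     pixelSizeMm = p$pixelSizeMm)
  }
  out
}
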