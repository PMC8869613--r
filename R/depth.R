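#' Reconstruct a vessel-masked depth map from disparity
#'
#' Triangulates every valid disparity pixel and keeps only pixels inside
#' the vessel mask. Depth is signed mm relative to the rig's zero plane
#' (negative = deeper).
#'
#' @param dmap a \linkS4class{DisparityMap}.
#' @param rig a \linkS4class{StereoRig}.
#' @param mask a \linkS4class{VesselMask} or logical matrix; NULL keeps all
#'   valid pixels.
#' @return a \linkS4class{DepthMap}.
#' @export
reconstructDepth <- function(dmap, rig, mask = NULL) {
  depth <- disparityMapToDepthMap(dmap, rig)
  if (!is.null(mask)) {
    m <- if (is(mask, "VesselMask")) mask@mask else mask
    stopifnot(all(dim(m) == dim(depth@values)))
    keep <- depth@valid & m
    if (!any(keep))
      warning("empty intersection of valid disparities and vessel mask")
    v <- depth@values
    v[!keep] <- NA_real_
    depth <- depthMap(v, keep)
  }
  depth
}

#' Per-vessel depth statistics
#'
#' One row per labeled vessel component: mean (or median) depth over its
#' valid pixels, standard deviation, and pixel count. Components with no
#' valid depth get NaN and a zero count.
#'
#' @param depth a \linkS4class{DepthMap}.
#' @param labels integer label matrix from \code{\link{labelVessels}}.
#' @param stat "mean" (default) or "median".
#' @return data.frame with columns component, meanDepthMm, stdMm, nPixels.
#' @export
perVesselDepth <- function(depth, labels, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(all(dim(labels) == dim(depth@values)))
  comps <- sort(unique(labels[labels > 0]))
  fun <- if (stat == "mean") mean else stats::median
  rows <- lapply(comps, function(k) {
    v <- depth@values[labels == k & depth@valid]
    data.frame(component = k,
               meanDepthMm = if (length(v)) fun(v) else NaN,
               stdMm = if (length(v) > 1) stats::sd(v)
                       else if (length(v) == 1) 0 else NaN,
               nPixels = length(v))
  })
  do.call(rbind, rows)
}

# anchor colors of the depth display scale
.depthAnchors <- rbind(red    = c(1, 0, 0),
                       yellow = c(1, 1, 0),
                       green  = c(0, 1, 0),
                       blue   = c(0, 0, 1))

#' Render a depth map on the red-yellow-green-blue scale
#'
#' Linear interpolation through equally spaced anchor colors
#' red - yellow - green - blue across `displayRange`; the first range
#' element is the shallow end (red). Out-of-range depths clamp to the end
#' colors, invalid pixels render black.
#'
#' @param depth a \linkS4class{DepthMap}.
#' @param displayRange numeric(2), shallow and deep display limits in mm
#'   (e.g. c(0, -5)); the two must differ.
#' @return numeric array (rows, cols, 3) of RGB in [0, 1].
#' @export
colorizeDepth <- function(depth, displayRange) {
  stopifnot(length(displayRange) == 2, displayRange[1] != displayRange[2])
  t <- (depth@values - displayRange[1]) / (displayRange[2] - displayRange[1])
  t <- pmin(pmax(t, 0), 1)
  pos <- t * 3  # anchor index position in 0..3
  lo <- pmin(floor(pos), 2)
  w <- pos - lo
  out <- array(0, c(nrow(t), ncol(t), 3))
  ok <- depth@valid
  for (ch in 1:3) {
    a <- .depthAnchors[lo + 1, ch]
    b <- .depthAnchors[lo + 2, ch]
    plane <- (1 - w) * a + w * b
    plane[!ok] <- 0
    out[, , ch] <- plane
  }
  out
}
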