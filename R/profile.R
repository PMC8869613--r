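# Bilinear sampling at fractional pixel positions (x = col, y = row);
# positions outside the image clamp to the border.
.bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1); y0 <- pmin(floor(y), nr - 1)
  fx <- x - x0; fy <- y - y0
  image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    image[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    image[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    image[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Sample an intensity profile along a line segment
#'
#' Intensities are sampled at unit-pixel steps along the segment and
#' averaged across `width` perpendicular samples. If `pixelSizeMm` is
#' given, positions are also reported in mm.
#'
#' @param image numeric matrix.
#' @param start,end numeric(2) endpoints (x = column, y = row), inside the
#'   image and distinct.
#' @param width number of perpendicular samples averaged (default 1);
#'   averaging `width` rows reduces noise variance by about 1/width.
#' @param pixelSizeMm optional physical pixel size in mm.
#' @return data.frame with `pos` (pixels from `start`), `value`, and
#'   `posMm` when `pixelSizeMm` is given; the spacing is stored in
#'   attribute "pixelSizeMm".
#' @export
lineProfile <- function(image, start, end, width = 1, pixelSizeMm = NULL) {
  stopifnot(length(start) == 2, length(end) == 2)
  len <- sqrt(sum((end - start)^2))
  if (len == 0) stop("degenerate line: start and end coincide")
  if (any(c(start, end) < 1) || start[1] > ncol(image) ||
      end[1] > ncol(image) || start[2] > nrow(image) ||
      end[2] > nrow(image))
    stop("profile endpoints must lie inside the image")
  n <- ceiling(len) + 1
  t <- seq(0, 1, length.out = n)
  ux <- (end[1] - start[1]) / len; uy <- (end[2] - start[2]) / len
  px <- -uy; py <- ux  # unit perpendicular
  offs <- seq_len(width) - (width + 1) / 2
  vals <- rowMeans(vapply(offs, function(o) {
    .bilinear(image, start[1] + t * len * ux + o * px,
              start[2] + t * len * uy + o * py)
  }, numeric(n)))
  out <- data.frame(pos = t * len, value = vals)
  if (!is.null(pixelSizeMm)) out$posMm <- out$pos * pixelSizeMm
  attr(out, "pixelSizeMm") <- pixelSizeMm
  out
}

#' Fit a Gaussian to a line profile and report its FWHM
#'
#' Least-squares fit of amplitude * exp(-(x - center)^2 / (2 sigma^2)) +
#' offset. Initialization is deterministic: amplitude = max - min, center
#' at the maximum, sigma from the second moment, offset = min. FWHM =
#' 2 sqrt(2 ln 2) sigma, in the units of `x`.
#'
#' @param profile data.frame from \code{\link{lineProfile}} (or any with
#'   columns `pos`/`value`), with >= 5 samples and nonzero dynamic range.
#' @param units "mm" to fit against `posMm` when present, else "px".
#' @return a \linkS4class{ProfileFit}; a failed fit returns
#'   `converged = FALSE` with NaN estimates and a warning rather than a
#'   silent number.
#' @examples
#' x <- seq(-10, 10, 0.5)
#' pf <- fitGaussianFwhm(data.frame(pos = x, value = exp(-x^2 / 2)))
#' pf@fwhm  # 2.3548
#' @export
fitGaussianFwhm <- function(profile, units = c("auto", "mm", "px")) {
  units <- match.arg(units)
  x <- if ((units == "mm" || units == "auto") && !is.null(profile$posMm))
    profile$posMm else profile$pos
  if (units == "mm" && is.null(profile$posMm))
    stop("profile has no posMm column; supply pixelSizeMm to lineProfile")
  yRaw <- profile$value
  if (length(x) < 5) stop("profile must have at least 5 samples")
  if (max(yRaw) == min(yRaw)) stop("profile has zero dynamic range")
  yScale <- max(yRaw) - min(yRaw)
  yBase <- min(yRaw)
  y <- (yRaw - yBase) / yScale  # fit on unit scale, rescale after
  off0 <- 0; amp0 <- 1
  ctr0 <- x[which.max(y)]
  w <- pmax(y - off0, 0)
  sig0 <- sqrt(sum(w * (x - ctr0)^2) / sum(w))
  if (!is.finite(sig0) || sig0 <= 0) sig0 <- diff(range(x)) / 6
  fail <- function(msg) {
    warning("Gaussian fit did not converge: ", msg)
    new("ProfileFit", amplitude = NaN, center = NaN, sigma = NaN,
        offset = NaN, fwhm = NaN, rmse = NaN, converged = FALSE)
  }
  residFn <- function(p)
    y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(A = amp0, mu = ctr0, s = sig0, b = off0), fn = residFn,
      lower = c(0, min(x), 1e-6, -Inf),
      upper = c(Inf, max(x), diff(range(x)) * 2, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  if (!fit$info %in% 1:4) return(fail(fit$message))
  p <- fit$par
  new("ProfileFit", amplitude = unname(p["A"]) * yScale,
      center = unname(p["mu"]), sigma = unname(p["s"]),
      offset = unname(p["b"]) * yScale + yBase,
      fwhm = 2 * sqrt(2 * log(2)) * unname(p["s"]),
      rmse = sqrt(mean(fit$fvec^2)) * yScale, converged = TRUE)
}

#' Normalized intensity versus depth and half-intensity depth
#'
#' Mean ROI intensity at each depth, normalized to the shallowest depth,
#' with the half-intensity depth found by piecewise-linear interpolation at
#' the first 0.5 crossing. The default ROI is the full frame: the blur a
#' scattering medium adds conserves total signal, so a wide ROI makes the
#' normalized curve track attenuation (a tight ROI would also measure blur
#' leakage).
#'
#' @param series list of records with `depth` and `image` (e.g. from
#'   \code{\link{makeCapillaryDepthSeries}}); >= 2 depths.
#' @param roi optional logical matrix selecting the ROI common to all
#'   depths.
#' @return list with `curve` (data.frame depthMm, normIntensity) and
#'   `halfIntensityDepthMm` (NA with a warning if the curve never crosses
#'   0.5; first crossing with a warning if not monotone).
#' @export
intensityVsDepth <- function(series, roi = NULL) {
  stopifnot(length(series) >= 2)
  depths <- vapply(series, `[[`, numeric(1), "depth")
  ord <- order(depths)
  means <- vapply(series[ord], function(s) {
    im <- s$image
    if (is.null(roi)) mean(im) else mean(im[roi])
  }, numeric(1))
  norm <- means / means[1]
  curve <- data.frame(depthMm = depths[ord], normIntensity = norm)
  if (any(diff(norm) > 0))
    warning("intensity-depth curve is not monotone; reporting first crossing")
  below <- which(norm <= 0.5)
  half <- if (!length(below)) {
    warning("normalized intensity never falls to 0.5 in the measured range")
    NA_real_
  } else {
    i <- below[1]
    if (i == 1) curve$depthMm[1] else {
      x0 <- curve$depthMm[i - 1]; x1 <- curve$depthMm[i]
      y0 <- norm[i - 1]; y1 <- norm[i]
      x0 + (0.5 - y0) * (x1 - x0) / (y1 - y0)
    }
  }
  list(curve = curve, halfIntensityDepthMm = half)
}

#' Score a reconstructed depth map against renderer ground truth
#'
#' @param measured a \linkS4class{DepthMap} (displayed-depth convention).
#' @param truth the `truth` list from \code{\link{renderStereoPair}}.
#' @return list with `perVessel` (data.frame: label, truthDepthMm,
#'   meanErrorMm, nPixels), `rmseMm` (pixelwise RMSE over valid & mask),
#'   `layerSeparationMm` (difference of the two layer-mean depths,
#'   deeper minus shallower, using the truth layer assignment; NA when the
#'   scene has fewer than two distinct depths), and `validFraction`.
#' @export
depthRecoveryMetrics <- function(measured, truth) {
  stopifnot(all(dim(measured@values) == dim(truth$depth)))
  ok <- measured@valid & truth$mask
  if (!any(ok)) stop("no overlap between measured depths and truth mask")
  err <- measured@values[ok] - truth$depth[ok]
  labs <- truth$labels[ok]
  perVessel <- do.call(rbind, lapply(sort(unique(labs)), function(k) {
    e <- err[labs == k]
    data.frame(label = k, truthDepthMm = truth$tubeDisplayDepths[k],
               meanErrorMm = if (length(e)) mean(e) else NaN,
               nPixels = length(e))
  }))
  zs <- truth$tubeDepths
  sep <- NA_real_
  if (length(unique(zs)) >= 2) {
    layers <- sort(unique(zs))
    meanAt <- function(z) {
      sel <- ok & matrix(truth$labels %in% which(zs == z),
                         nrow(truth$labels))
      mean(measured@values[sel])
    }
    # deeper layer has the more negative displayed depth
    sep <- meanAt(layers[1]) - meanAt(layers[length(layers)])
  }
  list(perVessel = perVessel, rmseMm = sqrt(mean(err^2)),
       layerSeparationMm = sep,
       validFraction = sum(ok) / sum(truth$mask))
}
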