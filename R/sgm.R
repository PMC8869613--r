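#' Census transform
#'
#' Per-pixel binary descriptor encoding, for each window neighbor, whether
#' its intensity is strictly below the center pixel's. Invariant to any
#' strictly monotone intensity remapping; border neighbors are replicated.
#' This is the reference (R-level) descriptor; the matching cost volume
#' computes the same bits in compiled code.
#'
#' @param image numeric matrix.
#' @param window odd window size >= 3, smaller than the image.
#' @return logical array (rows, cols, window^2 - 1) of descriptor bits, in
#'   column-major window order (the same order the cost volume uses).
#' @export
censusTransform <- function(image, window = 7) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd >= 3")
  if (window > min(dim(image))) stop("window larger than image")
  nr <- nrow(image); nc <- ncol(image); h <- window %/% 2
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  bits <- array(FALSE, c(nr, nc, nrow(offs)))
  ri <- matrix(seq_len(nr), nr, nc)
  ci <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(nrow(offs))) {
    rr <- pmin(pmax(ri + offs$dr[k], 1L), nr)
    cc <- pmin(pmax(ci + offs$dc[k], 1L), nc)
    bits[, , k] <- image[cbind(c(rr), c(cc))] < image
  }
  bits
}

# sentinel cost for out-of-bounds matches, per cost function
.costSentinel <- function(params) {
  if (params@cost == "census") params@censusWindow^2 - 1 else 100
}

#' Stereo matching cost volume
#'
#' cost(r, c, d) compares the reference pixel (r, c) with the target pixel
#' (r, c - d) (left reference; c + d for a right reference): Hamming
#' distance of census descriptors, or window-mean absolute difference
#' ("sad", scaled to [0, 100] for unit-range images). Out-of-bounds target
#' columns carry a sentinel maximal cost.
#'
#' @param left,right numeric matrices of equal shape (enhanced or raw
#'   views).
#' @param params an \linkS4class{SGMParams}.
#' @param reference "left" (default) or "right".
#' @return a \linkS4class{CostVolume}.
#' @export
matchingCostVolume <- function(left, right, params,
                               reference = c("left", "right")) {
  validObject(params)
  stopifnot(all(dim(left) == dim(right)))
  reference <- match.arg(reference)
  sgn <- if (reference == "left") 1L else -1L
  ref <- if (reference == "left") left else right
  tgt <- if (reference == "left") right else left
  sent <- .costSentinel(params)
  costs <- if (params@cost == "census") {
    .costVolumeCensusCpp(ref, tgt, as.integer(params@dMin),
                         as.integer(params@dMax),
                         as.integer(params@censusWindow), sgn, sent)
  } else {
    .costVolumeSadCpp(ref, tgt, as.integer(params@dMin),
                      as.integer(params@dMax),
                      as.integer(params@censusWindow), sgn, sent)
  }
  disp <- seq(params@dMin, params@dMax)
  cols <- matrix(seq_len(ncol(ref)), nrow(ref), ncol(ref), byrow = TRUE)
  tmin <- cols - sgn * params@dMax
  tmax <- cols - sgn * params@dMin
  inb <- (pmax(tmin, tmax) >= 1) & (pmin(tmin, tmax) <= ncol(ref))
  new("CostVolume", costs = costs, disparities = disp, sentinel = sent,
      inBounds = inb)
}

# aggregation path directions
.sgmPaths <- function(nPaths) {
  p4 <- rbind(c(0, -1), c(0, 1), c(-1, 0), c(1, 0))
  if (nPaths == 4) p4 else rbind(p4, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
}

#' Semi-global cost aggregation
#'
#' Sums, over the path directions, the standard recurrence
#' L_p(x, d) = C(x, d) + min(L_p(x-p, d), L_p(x-p, d+-1) + P1,
#' min_k L_p(x-p, k) + P2) - min_k L_p(x-p, k). With P1 = P2 = 0 this
#' collapses to nPaths times the raw cost.
#'
#' @param volume a \linkS4class{CostVolume}.
#' @param params an \linkS4class{SGMParams} (P1 < P2, nPaths 4 or 8).
#' @param paths optional custom path matrix (nPaths x 2 of row/col steps),
#'   e.g. a single direction for scanline optimization.
#' @return an aggregated \linkS4class{CostVolume}.
#' @export
aggregateCostsSGM <- function(volume, params, paths = NULL) {
  if (is.null(paths)) paths <- .sgmPaths(params@nPaths)
  agg <- .sgmAggregateCpp(volume@costs, paths, params@P1, params@P2)
  new("CostVolume", costs = agg, disparities = volume@disparities,
      sentinel = volume@sentinel * nrow(paths) +
        nrow(paths) * params@P2,  # conservative bound for validity checks
      inBounds = volume@inBounds)
}

#' Winner-take-all disparity selection
#'
#' Per-pixel argmin over the disparity axis; ties break toward the smaller
#' disparity. Pixels with no in-bounds disparity are invalid.
#'
#' @param aggregated a \linkS4class{CostVolume}.
#' @return an integer-valued \linkS4class{DisparityMap}.
#' @export
winnerTakeAll <- function(aggregated) {
  dm <- dim(aggregated@costs)
  m <- matrix(aggregated@costs, dm[1] * dm[2], dm[3])
  idx <- max.col(-m, ties.method = "first")
  vals <- matrix(aggregated@disparities[idx], dm[1], dm[2])
  dr <- range(aggregated@disparities)
  disparityMap(vals, valid = aggregated@inBounds,
               searchRange = c(dr[1] - 0.5, dr[2] + 0.5))
}

#' Sub-pixel disparity refinement
#'
#' Refines each integer winner d by interpolating the aggregated costs at
#' d-1, d, d+1. The parabola fit gives
#' d* = d + (C(d-1) - C(d+1)) / (2 (C(d-1) - 2 C(d) + C(d+1)));
#' the equiangular (two-line) fit,
#' d* = d + (C(d-1) - C(d+1)) / (2 (max(C(d-1), C(d+1)) - C(d))),
#' is exact for the V-shaped cost profiles that absolute-difference and
#' census costs produce. Offsets are clamped to (-0.5, 0.5); winners at the
#' search-range boundary and degenerate (non-convex) triples keep their
#' integer value.
#'
#' @param aggregated a \linkS4class{CostVolume}.
#' @param integerDisparity the \linkS4class{DisparityMap} from
#'   \code{\link{winnerTakeAll}}.
#' @param method "parabola" or "equiangular".
#' @return a float \linkS4class{DisparityMap}.
#' @export
subpixelRefine <- function(aggregated, integerDisparity,
                           method = c("parabola", "equiangular")) {
  method <- match.arg(method)
  dm <- dim(aggregated@costs)
  m <- matrix(aggregated@costs, dm[1] * dm[2], dm[3])
  idx <- match(c(integerDisparity@values), aggregated@disparities)
  px <- seq_len(nrow(m))
  interior <- idx > 1 & idx < dm[3]
  off <- numeric(nrow(m))
  i <- which(interior)
  if (length(i)) {
    cm <- m[cbind(px[i], idx[i] - 1L)]
    c0 <- m[cbind(px[i], idx[i])]
    cp <- m[cbind(px[i], idx[i] + 1L)]
    den <- if (method == "parabola") cm - 2 * c0 + cp
           else 2 * (pmax(cm, cp) - c0)
    num <- cm - cp
    o <- ifelse(den > 0,
                if (method == "parabola") num / (2 * den) else num / den,
                0)
    off[i] <- pmin(pmax(o, -0.5), 0.5)
  }
  vals <- integerDisparity@values + matrix(off, dm[1], dm[2])
  disparityMap(vals, valid = integerDisparity@valid,
               searchRange = integerDisparity@searchRange)
}

#' Left-right consistency check
#'
#' A left-view pixel is kept valid iff the right-view disparity at its
#' match position agrees: |d_L(r, c) - d_R(r, c - round(d_L))| <= tol.
#' Occlusions and mismatches fail the check.
#'
#' @param disparityL,disparityR \linkS4class{DisparityMap}s of equal shape
#'   (both expressed as positive left-minus-right disparities).
#' @param lrTolerance tolerance in pixels (Inf keeps everything).
#' @return logical validity matrix.
#' @export
lrConsistency <- function(disparityL, disparityR, lrTolerance = 1) {
  dL <- disparityL@values
  dR <- disparityR@values
  stopifnot(all(dim(dL) == dim(dR)))
  nr <- nrow(dL); nc <- ncol(dL)
  cL <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cR <- cL - round(dL)
  ok <- disparityL@valid & cR >= 1 & cR <= nc
  idx <- which(ok)
  agree <- matrix(FALSE, nr, nc)
  if (length(idx)) {
    rI <- ((idx - 1) %% nr) + 1
    dRv <- dR[cbind(rI, cR[idx])]
    vRv <- disparityR@valid[cbind(rI, cR[idx])]
    agree[idx] <- vRv & abs(dL[idx] - dRv) <= lrTolerance
  }
  agree
}

#' Compute a sub-pixel disparity map from a stereo pair
#'
#' Orchestrates the matching pipeline: cost volume, semi-global
#' aggregation, winner-take-all, sub-pixel refinement, and a left-right
#' consistency check (a second matching pass with the right view as
#' reference).
#'
#' @param left,right row-aligned numeric matrices (typically
#'   vessel-enhanced views).
#' @param params an \linkS4class{SGMParams}.
#' @return a \linkS4class{DisparityMap} (left-referenced, sub-pixel if
#'   `params@subpixel`).
#' @export
computeDisparity <- function(left, right, params) {
  volL <- matchingCostVolume(left, right, params, reference = "left")
  aggL <- aggregateCostsSGM(volL, params)
  intL <- winnerTakeAll(aggL)
  dL <- if (params@subpixel)
    subpixelRefine(aggL, intL, method = params@subpixelMethod) else intL
  valid <- intL@valid
  if (is.finite(params@lrTolerance)) {
    volR <- matchingCostVolume(left, right, params, reference = "right")
    aggR <- aggregateCostsSGM(volR, params)
    intR <- winnerTakeAll(aggR)
    valid <- valid & lrConsistency(intL, intR, params@lrTolerance)
  }
  disparityMap(dL@values, valid = valid, searchRange = dL@searchRange)
}
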