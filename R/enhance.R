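# Separable convolution with replicated borders, via EBImage's FFT filter.
# Images smaller than the kernel are edge-padded first (filter2 requires
# the filter to fit inside the image).
.sepConvolve <- function(image, kRow, kCol) {
  kern <- outer(kRow, kCol)
  pr <- max(0L, length(kRow) - nrow(image) + 1L)
  pc <- max(0L, length(kCol) - ncol(image) + 1L)
  if (pr > 0 || pc > 0) {
    top <- ceiling(pr / 2); left <- ceiling(pc / 2)
    ri <- c(rep(1L, top), seq_len(nrow(image)),
            rep(nrow(image), pr - top))
    ci <- c(rep(1L, left), seq_len(ncol(image)),
            rep(ncol(image), pc - left))
    out <- EBImage::filter2(image[ri, ci, drop = FALSE], kern,
                            boundary = "replicate")
    return(out[top + seq_len(nrow(image)), left + seq_len(ncol(image)),
               drop = FALSE])
  }
  EBImage::filter2(image, kern, boundary = "replicate")
}

# Sampled Gaussian and its derivatives at scale sigma (pixels).
.gaussKernels <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - sum(g2) * g  # exact zero response to constants
  list(g = g, g1 = -x / sigma^2 * g, g2 = g2)
}

#' Eigenvalues of the scale-normalized image Hessian
#'
#' Second derivatives are computed by convolution with Gaussian-derivative
#' kernels at scale sigma and normalized by sigma^2 (gamma = 2 scale
#' normalization), then the per-pixel 2 x 2 Hessian is diagonalized in
#' closed form. Eigenvalues are returned ordered by absolute value,
#' |lambda1| <= |lambda2|.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return list with matrices `l1`, `l2`.
#' @export
hessianEigenvalues <- function(image, sigma) {
  stopifnot(sigma > 0, all(is.finite(image)))
  k <- .gaussKernels(sigma)
  s2 <- sigma^2
  ixx <- s2 * .sepConvolve(image, k$g, k$g2)  # d2/dx2, x = columns
  iyy <- s2 * .sepConvolve(image, k$g2, k$g)
  ixy <- s2 * .sepConvolve(image, k$g1, k$g1)
  m <- (ixx + iyy) / 2
  sq <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  e1 <- m + sq
  e2 <- m - sq
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  list(l1 = matrix(l1, nrow(image)), l2 = matrix(l2, nrow(image)))
}

#' Two-eigenvalue 2D vesselness response
#'
#' Standard vesselness functional: with blobness R_B = l1/l2 and
#' structureness S = sqrt(l1^2 + l2^2), the response is
#' exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2))), set to zero where
#' l2 >= 0 (bright vessels on dark background) or l2 <= 0 in dark-on-bright
#' mode. Bounded in [0, 1].
#'
#' @param l1,l2 eigenvalue matrices from \code{\link{hessianEigenvalues}}.
#' @param params an \linkS4class{EnhancementParams}; an NA `c` picks half
#'   the maximum structureness of the input.
#' @return response matrix in [0, 1].
#' @export
vesselness2D <- function(l1, l2, params = enhancementParams()) {
  stopifnot(all(dim(l1) == dim(l2)))
  s2 <- l1^2 + l2^2
  cc <- if (is.na(params@c)) {
    m <- sqrt(max(s2))
    # a numerically flat image has no structure to normalize against
    if (m < 1e-8) Inf else m / 2
  } else params@c
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  resp <- exp(-rb2 / (2 * params@beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
  sign_ok <- if (params@brightOnDark) l2 < 0 else l2 > 0
  resp[!sign_ok] <- 0
  matrix(resp, nrow(l1))
}

#' Multiscale vessel enhancement
#'
#' Per-pixel maximum of the vesselness response over the given scales; the
#' scale achieving the maximum tracks the vessel half-width in pixels.
#' Invariant to additive intensity offsets (the Hessian kills constants).
#'
#' @param image numeric matrix (any intensity scale).
#' @param params an \linkS4class{EnhancementParams}.
#' @return enhanced matrix in [0, 1], same shape as the input.
#' @export
enhanceMultiscale <- function(image, params = enhancementParams()) {
  validObject(params)
  out <- matrix(0, nrow(image), ncol(image))
  for (s in params@scales) {
    ev <- hessianEigenvalues(image, s)
    out <- pmax(out, vesselness2D(ev$l1, ev$l2, params))
  }
  out
}

#' Segment vessels from an enhanced image
#'
#' Thresholds the vesselness image (Otsu by default, deterministic and
#' parameter-free) and removes connected components smaller than
#' `minComponentSize` pixels to suppress speckle.
#'
#' @param enhanced matrix in [0, 1] from \code{\link{enhanceMultiscale}}.
#' @param thresholdMethod "otsu" or "fixed".
#' @param threshold numeric threshold when `thresholdMethod = "fixed"`.
#' @param minComponentSize smallest component kept, pixels (default 50).
#' @return a \linkS4class{VesselMask}; an empty mask raises a warning.
#' @export
segmentVessels <- function(enhanced, thresholdMethod = c("otsu", "fixed"),
                           threshold = NULL, minComponentSize = 50) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(min(enhanced) >= 0, max(enhanced) <= 1)
  thr <- if (thresholdMethod == "fixed") {
    if (is.null(threshold)) stop("supply `threshold` for fixed thresholding")
    threshold
  } else if (max(enhanced) == 0) Inf else {
    EBImage::otsu(EBImage::Image(enhanced), range = c(0, 1))
  }
  mask <- enhanced > thr
  if (any(mask) && minComponentSize > 1) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(EBImage::imageData(lab)))
    keep <- which(sizes >= minComponentSize)
    mask <- matrix(as.integer(EBImage::imageData(lab)) %in% keep,
                   nrow(enhanced))
  }
  if (!any(mask)) warning("no vessels found: segmentation mask is empty")
  new("VesselMask", mask = mask, minComponentSize = minComponentSize)
}

#' Label connected vessel components
#'
#' @param mask a \linkS4class{VesselMask} or logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
labelVessels <- function(mask) {
  m <- if (is(mask, "VesselMask")) mask@mask else mask
  matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(m * 1)))), nrow(m))
}
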