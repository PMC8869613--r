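# Independent oracles and fixture builders shared across tests.

# smooth band-limited random image (blurred white noise)
smoothImage <- function(nr, nc, seed, blurSigma = 2) {
  withr::with_seed(seed, {
    im <- matrix(stats::rnorm(nr * nc), nr, nc)
  })
  r <- min(ceiling(4 * blurSigma), floor((min(nr, nc) - 1) / 2))
  k <- exp(-(-r:r)^2 / (2 * blurSigma^2))
  k <- k / sum(k)
  im <- EBImage::filter2(im, outer(k, k), boundary = "circular")
  im - min(im)
}

# exact band-limited horizontal shift by dx pixels (periodic), per row;
# content moves right by dx, so shifting the left view by -d builds a
# right view with disparity +d
fftShiftRows <- function(im, dx) {
  n <- ncol(im)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  ph <- exp(-2i * pi * k * dx / n)
  t(apply(im, 1, function(row) Re(stats::fft(stats::fft(row) * ph,
                                             inverse = TRUE) / n)))
}

# forward dynamic program over a single scanline: unnormalized cost-to-
# reach for the SGM transition model (0 / P1 for +-1 / P2 otherwise).
# costs: nd x N matrix (disparity x pixel). Returns nd x N matrix.
dpForwardOracle <- function(costs, P1, P2) {
  nd <- nrow(costs); N <- ncol(costs)
  L <- matrix(0, nd, N)
  L[, 1] <- costs[, 1]
  for (x in 2:N) {
    prev <- L[, x - 1]
    m <- min(prev)
    for (d in 1:nd) {
      cand <- c(prev[d],
                if (d > 1) prev[d - 1] + P1,
                if (d < nd) prev[d + 1] + P1,
                m + P2)
      L[d, x] <- costs[d, x] + min(cand)
    }
  }
  L
}

# exhaustive minimum total energy over all disparity sequences
enumMinEnergy <- function(costs, P1, P2) {
  nd <- nrow(costs); N <- ncol(costs)
  trans <- function(a, b) {
    dd <- abs(a - b)
    if (dd == 0) 0 else if (dd == 1) P1 else P2
  }
  best <- Inf
  seqs <- do.call(expand.grid, rep(list(1:nd), N))
  for (i in seq_len(nrow(seqs))) {
    s <- as.integer(seqs[i, ])
    e <- sum(costs[cbind(s, 1:N)]) +
      sum(vapply(seq_len(N - 1), function(j) trans(s[j], s[j + 1]),
                 numeric(1)))
    if (e < best) best <- e
  }
  best
}

# Hamming-distance cost from the R-level census descriptors; the
# independent reference for the compiled cost volume
censusCostOracle <- function(left, right, window, d) {
  bl <- censusTransform(left, window)
  br <- censusTransform(right, window)
  nr <- nrow(left); nc <- ncol(left)
  out <- matrix(NA_real_, nr, nc)
  for (c in seq_len(nc)) {
    c2 <- c - d
    if (c2 >= 1 && c2 <= nc)
      out[, c] <- rowSums(bl[, c, , drop = TRUE] != br[, c2, , drop = TRUE])
  }
  out
}

# small cropped-sensor rig: same optics, reduced field, for fast
# stereo runs on compact scenes
benchRig <- function(width = 224, height = 112) {
  stereoRig(cameraModel(sensorWidth = width, sensorHeight = height))
}

# shipped defaults adjusted to a cropped-sensor rig
benchConfig <- function(rig) {
  cfg <- readPipelineConfig()
  cfg$sensor_width_px <- rig@camera@sensorWidth
  cfg$sensor_height_px <- rig@camera@sensorHeight
  cfg
}

# Dice coefficient of two logical masks
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
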