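#' Construct a masked volume
#'
#' @param image numeric 3D array.
#' @param mask logical (or 0/1) 3D array of the same shape.
#' @param spacing voxel spacing in mm, length 3.
#' @return a [VolumeWithMask-class].
#' @export
volumeWithMask <- function(image, mask, spacing = c(1, 1, 1)) {
  mask <- array(as.logical(mask), dim = dim(mask))
  methods::new("VolumeWithMask", image = image, mask = mask,
               spacing = as.numeric(spacing))
}

#' Discretize in-mask intensities into equal-width gray levels
#'
#' Equal-width bins spanning the in-mask intensity range. A constant image
#' maps every voxel to level 1 with a single occupied level.
#'
#' @param vol a [VolumeWithMask-class].
#' @param nBins number of gray levels G (>= 2).
#' @return a [QuantizedVolume-class].
#' @export
discretizeVolume <- function(vol, nBins = 32L) {
  if (nBins < 2L) stop("nBins must be >= 2")
  x <- vol@image[vol@mask]
  if (length(x) == 0L) stop("empty mask")
  lv <- array(NA_integer_, dim = dim(vol@image))
  if (max(x) == min(x)) {
    lv[vol@mask] <- 1L
    return(methods::new("QuantizedVolume", levels = lv, G = 1L,
                        gEffective = 1L))
  }
  lev <- pmin(floor((x - min(x)) / (max(x) - min(x)) * nBins) + 1L, nBins)
  lv[vol@mask] <- as.integer(lev)
  methods::new("QuantizedVolume", levels = lv, G = as.integer(nBins),
               gEffective = length(unique(lev)))
}

#' First-order intensity statistics of the in-mask voxels
#'
#' Moments use the population convention (denominator N). Entropy and
#' uniformity are computed on the equal-width discretized histogram
#' (`nBins` levels, base-2 logarithm). Statistics whose normalizer vanishes
#' on a constant image (skewness, kurtosis) return 0.
#'
#' @param vol a [VolumeWithMask-class].
#' @param nBins histogram bins for entropy/uniformity; default 32.
#' @return named numeric vector of 15 features.
#' @export
firstOrderFeatures <- function(vol, nBins = 32L) {
  x <- vol@image[vol@mask]
  if (length(x) == 0L) stop("empty mask")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  q <- discretizeVolume(vol, nBins)
  p <- tabulate(q@levels[!is.na(q@levels)], nbins = q@G) / n
  p <- p[p > 0]
  c(mean = mu,
    median = median(x),
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    min = min(x),
    max = max(x),
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    rms = sqrt(mean(x^2)),
    uniformity = sum(p^2),
    p10 = unname(quantile(x, 0.10)),
    p90 = unname(quantile(x, 0.90)))
}

#' 3D size and shape descriptors of the mask
#'
#' Volume is voxel count times voxel volume; surface area counts exposed voxel
#' faces (a face is exposed when its neighbour is outside the mask or the
#' grid); sphericity is `pi^(1/3) * (6V)^(2/3) / A`; the maximum 3D diameter
#' is the largest pairwise distance between surface-voxel centres; elongation
#' and flatness are `sqrt(lambda2/lambda1)` and `sqrt(lambda3/lambda1)` from
#' the eigenvalues (decreasing) of the physical voxel-coordinate covariance.
#' A single-voxel mask has elongation and flatness 1 by convention.
#'
#' @param vol a [VolumeWithMask-class].
#' @return named numeric vector of 6 features.
#' @export
shapeFeatures <- function(vol) {
  sp <- vol@spacing
  idx <- which(vol@mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  nvox <- nrow(idx)
  volume <- nvox * prod(sp)

  d <- dim(vol@mask)
  faceArea <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  surface <- 0
  exposed <- rep(FALSE, nvox)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- idx
      nb[, axis] <- nb[, axis] + dir
      outside <- nb[, axis] < 1L | nb[, axis] > d[axis]
      inMask <- rep(FALSE, nvox)
      ok <- !outside
      if (any(ok)) inMask[ok] <- vol@mask[nb[ok, , drop = FALSE]]
      ex <- outside | !inMask
      surface <- surface + sum(ex) * faceArea[axis]
      exposed <- exposed | ex
    }
  }

  phys <- sweep(idx, 2, sp, `*`)
  surf <- phys[exposed, , drop = FALSE]
  maxDiam <- if (nrow(surf) > 1L) max(stats::dist(surf)) else 0

  if (nvox > 1L) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  } else {
    elong <- 1; flat <- 1
  }

  c(volume = volume,
    surface_area = surface,
    sphericity = pi^(1 / 3) * (6 * volume)^(2 / 3) / surface,
    max_diameter = maxDiam,
    elongation = elong,
    flatness = flat)
}
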