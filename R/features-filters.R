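# separable 1D convolution along the first array axis with replicate padding
.convolveAxis1 <- function(m, kern) {
  n <- nrow(m)
  h <- (length(kern) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  base <- seq_len(n)
  for (j in seq_along(kern)) {
    idx <- pmin(pmax(base + (j - 1L - h), 1L), n)
    out <- out + kern[j] * m[idx, , drop = FALSE]
  }
  out
}

.alongAxis <- function(arr, axis, f) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- f(m)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Gaussian smoothing of a 3D array
#'
#' Separable Gaussian convolution with per-axis sigma in voxel units and
#' replicate (nearest) edge padding. Kernels are truncated at 4 sigma.
#'
#' @param arr numeric 3D array.
#' @param sigmaVox length-3 sigma per axis, in voxels; entries of 0 skip the
#'   axis.
#' @return smoothed array of the same shape.
#' @export
gaussianSmooth3d <- function(arr, sigmaVox) {
  stopifnot(length(dim(arr)) == 3L, length(sigmaVox) == 3L)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    h <- max(1L, ceiling(4 * s))
    x <- (-h):h
    kern <- exp(-x^2 / (2 * s^2))
    kern <- kern / sum(kern)
    arr <- .alongAxis(arr, axis, function(m) .convolveAxis1(m, kern))
  }
  arr
}

# spacing-aware discrete Laplacian, replicate edges (so a constant image
# maps to exactly zero everywhere)
.laplacian3d <- function(arr, spacing) {
  out <- array(0, dim(arr))
  for (axis in 1:3) {
    h2 <- spacing[axis]^2
    out <- out + .alongAxis(arr, axis, function(m) {
      n <- nrow(m)
      up <- m[pmin(seq_len(n) + 1L, n), , drop = FALSE]
      dn <- m[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
      (up - 2 * m + dn) / h2
    })
  }
  out
}

# one-level orthonormal Haar analysis along one axis; returns the L or H half
.haarAxis <- function(m, keep) {
  n <- nrow(m)
  if (n %% 2L == 1L) m <- m[c(seq_len(n), n), , drop = FALSE]  # replicate pad
  odd <- m[seq(1L, nrow(m), by = 2L), , drop = FALSE]
  evn <- m[seq(2L, nrow(m), by = 2L), , drop = FALSE]
  if (keep == "L") (odd + evn) / sqrt(2) else (odd - evn) / sqrt(2)
}

# nearest-neighbour upsampling back to length n along the first axis
.upsampleAxis <- function(m, n) {
  idx <- pmin(rep(seq_len(nrow(m)), each = 2L), nrow(m))[seq_len(n)]
  m[idx, , drop = FALSE]
}

#' Filter a masked volume (Laplacian of Gaussian or Haar wavelet subband)
#'
#' `"log"` applies Gaussian smoothing at `sigmaMM` (converted to voxel units by
#' the spacing) followed by a spacing-aware discrete Laplacian. `"wavelet"`
#' computes a one-level separable orthonormal Haar transform and returns the
#' requested subband upsampled back to the grid shape (letters of `subband`
#' select L/H along the x, y, z axes in that order). The mask is unchanged.
#'
#' @param vol a [VolumeWithMask-class].
#' @param kind `"log"` or `"wavelet"`.
#' @param sigmaMM LoG scale in mm (> 0).
#' @param subband three-letter code such as `"LLL"` or `"HHL"`.
#' @return a [VolumeWithMask-class] holding the filtered image.
#' @export
filterImage <- function(vol, kind = c("log", "wavelet"), sigmaMM = 1,
                        subband = "LLL") {
  kind <- match.arg(kind)
  img <- vol@image
  if (kind == "log") {
    if (sigmaMM <= 0) stop("LoG sigma must be positive")
    sm <- gaussianSmooth3d(img, sigmaVox = sigmaMM / vol@spacing)
    out <- .laplacian3d(sm, vol@spacing)
  } else {
    letters3 <- strsplit(subband, "")[[1]]
    if (length(letters3) != 3L || !all(letters3 %in% c("L", "H")))
      stop("invalid subband code: ", subband)
    d <- dim(img)
    out <- img
    applyAxis <- function(arr, axis, f, newLen) {
      dcur <- dim(arr)
      perm <- c(axis, setdiff(1:3, axis))
      a <- aperm(arr, perm)
      m <- f(matrix(a, nrow = dcur[axis]))
      a <- array(m, dim = c(newLen, dcur[perm[2]], dcur[perm[3]]))
      aperm(a, order(perm))
    }
    for (axis in 1:3) {
      half <- ceiling(dim(out)[axis] / 2)
      out <- applyAxis(out, axis,
                       function(m) .haarAxis(m, letters3[axis]), half)
    }
    for (axis in 1:3)
      out <- applyAxis(out, axis,
                       function(m) .upsampleAxis(m, d[axis]), d[axis])
  }
  methods::new("VolumeWithMask", image = out, mask = vol@mask,
               spacing = vol@spacing)
}
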