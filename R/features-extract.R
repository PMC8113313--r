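#' Feature-extraction configuration
#'
#' @param nBins gray levels for discretization (equal-width over the in-mask
#'   range); default 32.
#' @param distance GLCM neighbour distance in voxels; default 1.
#' @param families texture families to compute; default all five.
#' @param logSigmas Laplacian-of-Gaussian scales in mm; default `c(1, 2, 3)`.
#'   Use `numeric(0)` to skip the LoG bank.
#' @param waveletSubbands one-level Haar subband codes; default all eight.
#'   Use `character(0)` to skip the wavelet bank.
#' @return a list of class `FeatureConfig`.
#' @export
featureConfig <- function(nBins = 32L, distance = 1L,
                          families = c("glcm", "glrlm", "glszm", "gldm",
                                       "ngtdm"),
                          logSigmas = c(1, 2, 3),
                          waveletSubbands = c("LLL", "LLH", "LHL", "LHH",
                                              "HLL", "HLH", "HHL", "HHH")) {
  structure(list(nBins = as.integer(nBins), distance = as.integer(distance),
                 families = families, logSigmas = logSigmas,
                 waveletSubbands = waveletSubbands),
            class = "FeatureConfig")
}

.imageFeatureBlock <- function(vol, config, tag, withShape = FALSE) {
  out <- firstOrderFeatures(vol, config$nBins)
  names(out) <- paste(tag, "firstorder", names(out), sep = "_")
  if (withShape) {
    sf <- shapeFeatures(vol)
    names(sf) <- paste(tag, "shape", names(sf), sep = "_")
    out <- c(out, sf)
  }
  q <- discretizeVolume(vol, config$nBins)
  for (fam in config$families) {
    tf <- textureFeatures(q, fam, distance = config$distance)
    names(tf) <- paste(tag, fam, names(tf), sep = "_")
    out <- c(out, tf)
  }
  out
}

#' Extract the full radiomic feature vector from a masked volume
#'
#' Concatenates first-order + shape + texture features on the original image,
#' then first-order + texture features on each configured filtered image
#' (LoG at each sigma, each Haar wavelet subband). Names follow
#' `<filter>_<family>_<feature>`; the order is deterministic.
#'
#' @param vol a [VolumeWithMask-class].
#' @param config a [featureConfig()].
#' @return named numeric vector; all values finite.
#' @export
extractFeatureVector <- function(vol, config = featureConfig()) {
  out <- .imageFeatureBlock(vol, config, "original", withShape = TRUE)
  for (s in config$logSigmas) {
    fv <- filterImage(vol, "log", sigmaMM = s)
    out <- c(out, .imageFeatureBlock(fv, config,
                                     sprintf("log.sigma.%g", s)))
  }
  for (code in config$waveletSubbands) {
    fv <- filterImage(vol, "wavelet", subband = code)
    out <- c(out, .imageFeatureBlock(fv, config, paste0("wavelet.", code)))
  }
  bad <- !is.finite(out)
  if (any(bad)) {
    noteWarning(paste("non-finite features set to 0:",
                      paste(names(out)[bad], collapse = ", ")))
    out[bad] <- 0
  }
  out
}

#' Write a 3D volume and mask as NIfTI files
#'
#' @param vol a [VolumeWithMask-class].
#' @param imagePath,maskPath output `.nii`/`.nii.gz` paths.
#' @return invisibly, the two paths.
#' @export
writeVolume <- function(vol, imagePath, maskPath) {
  img <- RNifti::asNifti(vol@image)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, imagePath)
  mk <- RNifti::asNifti(array(as.integer(vol@mask), dim = dim(vol@mask)))
  RNifti::pixdim(mk) <- vol@spacing
  RNifti::writeNifti(mk, maskPath)
  invisible(c(image = imagePath, mask = maskPath))
}

#' Read a NIfTI image + mask pair into a [VolumeWithMask-class]
#'
#' @param imagePath,maskPath NIfTI paths; mask voxels > 0 are in-mask.
#' @return a [VolumeWithMask-class] with spacing from the image header.
#' @export
readVolume <- function(imagePath, maskPath) {
  img <- RNifti::readNifti(imagePath)
  mk <- RNifti::readNifti(maskPath)
  spacing <- RNifti::pixdim(img)[1:3]
  volumeWithMask(array(as.numeric(img), dim = dim(img)),
                 array(as.numeric(mk) > 0, dim = dim(mk)), spacing)
}
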