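#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor cov sd median quantile rnorm rpois runif rbinom rexp
#'   rgamma hclust cutree as.dist prcomp kmeans mad pchisq pnorm pt qnorm
#'   fisher.test wilcox.test t.test ecdf setNames complete.cases
#' @importFrom utils head read.csv write.csv modifyList
NULL

#' Cohort container for radiomic feature matrices
#'
#' `RadiomicSet` extends [SummarizedExperiment::SummarizedExperiment] with the
#' conventions used throughout this package: the `"features"` assay holds the
#' radiomic feature matrix with features as rows and tumors as columns, and the
#' clinical table (age, sex, smoking status, ECOG grade, line of therapy,
#' ctDNA mutation count, EGFR mutation category, driver allele fraction and the
#' PFS/OS endpoints) lives in `colData`. For synthetic cohorts the planted
#' ground truth is carried in `rowData$true_feature_cluster`,
#' `colData$true_phenotype` and `metadata(x)$config`; the analysis path never
#' reads those columns.
#'
#' @seealso [simulateCohort()], [featureMatrix()], [clinicalData()]
#' @export
setClass("RadiomicSet", contains = "SummarizedExperiment")

setValidity("RadiomicSet", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  a <- SummarizedExperiment::assay(object, "features")
  if (!is.numeric(a)) return("'features' assay must be numeric")
  TRUE
})

#' Z-scored feature matrix
#'
#' Tumors-by-features matrix after per-feature standardization (sample sd,
#' denominator n - 1). Constant features are removed before scaling and their
#' names are retained in `@dropped`; the centering/scaling vectors are kept for
#' audit so any new tumor can be projected onto the same scale.
#'
#' @slot values numeric matrix, tumors x retained features.
#' @slot center,scale named numeric vectors of per-feature means and sds.
#' @slot dropped character vector of constant features that were removed.
#' @export
setClass("ZScoredMatrix", representation(
  values = "matrix", center = "numeric", scale = "numeric",
  dropped = "character"))

setValidity("ZScoredMatrix", function(object) {
  v <- object@values
  if (ncol(v) > 0) {
    if (max(abs(colMeans(v))) > 1e-8) return("columns must have mean ~ 0")
    sds <- apply(v, 2, sd)
    if (max(abs(sds - 1)) > 1e-8) return("columns must have sample sd ~ 1")
  }
  TRUE
})

#' Consensus clustering result
#'
#' Per-k consensus matrices from resampled hierarchical clustering, the
#' empirical CDFs of their upper-triangle entries, the area-under-CDF series
#' A(k), its relative forward change, and the k selected by the CDF delta-area
#' rule.
#'
#' @slot k integer vector of candidate cluster numbers (consecutive).
#' @slot consensus list of items x items consensus matrices, one per k.
#' @slot cdfGrid numeric grid on \[0, 1\] at which the CDFs are evaluated.
#' @slot cdf matrix, length(grid) x length(k), empirical CDFs per k.
#' @slot area numeric A(k) series.
#' @slot deltaArea relative change (A(k+1) - A(k)) / A(k); last entry NA.
#' @slot selectedK integer chosen by [selectKbyCDF()].
#' @slot items character item names.
#' @export
setClass("ConsensusResult", representation(
  k = "integer", consensus = "list", cdfGrid = "numeric", cdf = "matrix",
  area = "numeric", deltaArea = "numeric", selectedK = "integer",
  items = "character"))

setValidity("ConsensusResult", function(object) {
  if (length(object@k) != length(object@consensus))
    return("one consensus matrix per k is required")
  if (length(object@k) > 1 && any(diff(object@k) != 1L))
    return("k values must be consecutive")
  for (m in object@consensus) {
    if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
      return("consensus entries must lie in [0, 1]")
  }
  TRUE
})

#' Per-cluster first principal component signatures
#'
#' One column per feature cluster holding the first-PC scores of the tumors on
#' that cluster's z-scored features, sign-oriented so each PC correlates
#' non-negatively with the cluster's mean feature.
#'
#' @slot scores numeric matrix, tumors x clusters.
#' @slot explainedVariance fraction of the cluster's variance carried by PC1.
#' @slot featureClusters integer vector mapping each feature to its cluster.
#' @export
setClass("SignatureSet", representation(
  scores = "matrix", explainedVariance = "numeric",
  featureClusters = "integer"))

setValidity("SignatureSet", function(object) {
  if (ncol(object@scores) != length(object@explainedVariance))
    return("one explained-variance fraction per signature column")
  if (any(object@explainedVariance < -1e-9 | object@explainedVariance > 1 + 1e-9))
    return("explained variance fractions must lie in [0, 1]")
  TRUE
})

#' Radiomic phenotype assignment
#'
#' Per-tumor phenotype labels from tumor-level consensus clustering, with label
#' 1 assigned to the larger cluster (ties broken by order of first appearance),
#' plus the SigClust p-value for two clusters versus one when exactly two
#' phenotypes were selected.
#'
#' @slot labels integer vector of phenotype labels in 1..m.
#' @slot consensus the tumor-level [ConsensusResult-class].
#' @slot sigclustP SigClust p-value (NA unless m == 2 and the test was run).
#' @export
setClass("PhenotypeCall", representation(
  labels = "integer", consensus = "ConsensusResult", sigclustP = "numeric"))

setValidity("PhenotypeCall", function(object) {
  l <- object@labels
  if (length(l) && !identical(sort(unique(l)), seq_len(max(l))))
    return("labels must be exhaustive 1..m")
  TRUE
})

#' Fitted Cox proportional-hazards model
#'
#' Thin container around a partial-likelihood fit (Efron ties by default):
#' coefficients, covariance, log-likelihoods at the estimate and at beta = 0,
#' and the underlying data needed for prognostic scores.
#'
#' @slot coef named coefficient vector (log hazard ratios).
#' @slot vcov covariance matrix of the coefficients.
#' @slot loglik partial log-likelihood at the estimate.
#' @slot loglik0 partial log-likelihood at beta = 0 (null).
#' @slot n,nevent number of records and events.
#' @slot covariates covariate names, in model order.
#' @slot endpoint name of the time/event column pair used.
#' @slot fit the underlying `survival::coxph` object.
#' @export
setClass("CoxModel", representation(
  coef = "numeric", vcov = "matrix", loglik = "numeric", loglik0 = "numeric",
  n = "integer", nevent = "integer", covariates = "character",
  endpoint = "character", fit = "ANY"))

setValidity("CoxModel", function(object) {
  if (!isSymmetric(unname(object@vcov), tol = 1e-8))
    return("covariance must be symmetric")
  if (object@loglik < object@loglik0 - 1e-6)
    return("loglik at the estimate must be >= null loglik")
  TRUE
})

#' A 3D image with a binary tumor mask
#'
#' @slot image numeric 3D array of intensities on the full grid.
#' @slot mask logical 3D array, same shape, at least one `TRUE` voxel.
#' @slot spacing numeric length-3 voxel spacing in mm, all positive.
#' @export
setClass("VolumeWithMask", representation(
  image = "array", mask = "array", spacing = "numeric"))

setValidity("VolumeWithMask", function(object) {
  if (!identical(dim(object@image), dim(object@mask)))
    return("image and mask shapes must match")
  if (length(dim(object@image)) != 3L) return("volumes must be 3D")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive mm values")
  if (!any(object@mask)) return("mask must contain at least one voxel")
  TRUE
})

#' Gray-level discretized volume
#'
#' Integer gray levels 1..G inside the mask (NA outside), produced by
#' [discretizeVolume()]. `G` is the configured number of bins; `gEffective`
#' the number of occupied levels (1 for a constant image).
#'
#' @slot levels integer 3D array, NA outside the mask.
#' @slot G integer number of gray levels.
#' @slot gEffective integer number of occupied levels.
#' @export
setClass("QuantizedVolume", representation(
  levels = "array", G = "integer", gEffective = "integer"))

setValidity("QuantizedVolume", function(object) {
  v <- object@levels[!is.na(object@levels)]
  if (length(v) == 0) return("no in-mask voxels")
  if (min(v) < 1L || max(v) > object@G)
    return("levels must lie in 1..G inside the mask")
  TRUE
})

setMethod("show", "RadiomicSet", function(object) {
  cat("RadiomicSet:", nrow(object), "features x", ncol(object), "tumors\n")
  callNextMethod()
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k =", paste(range(object@k), collapse = ".."),
      "on", length(object@items), "items; selected k =", object@selectedK, "\n")
  cat("  A(k):", paste(sprintf("%.3f", object@area), collapse = " "), "\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet:", nrow(object@scores), "tumors x", ncol(object@scores),
      "PC1 signatures; median explained variance",
      sprintf("%.2f", median(object@explainedVariance)), "\n")
})

setMethod("show", "PhenotypeCall", function(object) {
  tab <- table(object@labels)
  cat("PhenotypeCall:", length(object@labels), "tumors in",
      length(tab), "phenotypes (", paste(tab, collapse = "/"), ")\n")
  if (!is.na(object@sigclustP))
    cat("  SigClust p (2 vs 1 clusters):", format.pval(object@sigclustP), "\n")
})

setMethod("show", "CoxModel", function(object) {
  cat("CoxModel [", object@endpoint, "]: ", object@nevent, " events / ",
      object@n, " records\n", sep = "")
  print(hazardRatios(object))
})

setMethod("show", "VolumeWithMask", function(object) {
  cat("VolumeWithMask:", paste(dim(object@image), collapse = " x "),
      "grid, spacing", paste(object@spacing, collapse = " x "), "mm,",
      sum(object@mask), "mask voxels\n")
})
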