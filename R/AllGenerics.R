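#' Accessors for radphen S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("clinicalData", function(x, ...) standardGeneric("clinicalData"))

#' @rdname accessors
#' @export
setGeneric("truePhenotype", function(x, ...) standardGeneric("truePhenotype"))

#' @rdname accessors
#' @export
setGeneric("trueFeatureClusters",
           function(x, ...) standardGeneric("trueFeatureClusters"))

#' @rdname accessors
#' @export
setGeneric("zvalues", function(x, ...) standardGeneric("zvalues"))

#' @rdname accessors
#' @export
setGeneric("droppedFeatures", function(x, ...) standardGeneric("droppedFeatures"))

#' @rdname accessors
#' @export
setGeneric("selectedK", function(x, ...) standardGeneric("selectedK"))

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x, ...) standardGeneric("consensusMatrix"))

#' @rdname accessors
#' @export
setGeneric("cdfArea", function(x, ...) standardGeneric("cdfArea"))

#' @rdname accessors
#' @export
setGeneric("signatureScores", function(x, ...) standardGeneric("signatureScores"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance",
           function(x, ...) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("phenotypeLabels", function(x, ...) standardGeneric("phenotypeLabels"))

#' @rdname accessors
#' @export
setGeneric("sigclustP", function(x, ...) standardGeneric("sigclustP"))

#' @rdname accessors
#' @export
setGeneric("hazardRatios", function(x, ...) standardGeneric("hazardRatios"))

#' @rdname accessors
#' @export
setGeneric("logLik0", function(x, ...) standardGeneric("logLik0"))

#' Feature matrix of a RadiomicSet, tumors x features
#'
#' Returns the `"features"` assay transposed to the tumors-by-features
#' orientation used by the phenotyping functions.
#' @param x a [RadiomicSet-class].
#' @param ... unused.
#' @return numeric matrix, tumors x features.
#' @export
setMethod("featureMatrix", "RadiomicSet", function(x, ...) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' @rdname accessors
#' @export
setMethod("clinicalData", "RadiomicSet", function(x, ...) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname accessors
#' @export
setMethod("truePhenotype", "RadiomicSet", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  if (!"true_phenotype" %in% names(cd)) return(NULL)
  setNames(cd$true_phenotype, rownames(cd))
})

#' @rdname accessors
#' @export
setMethod("trueFeatureClusters", "RadiomicSet", function(x, ...) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"true_feature_cluster" %in% names(rd)) return(NULL)
  setNames(rd$true_feature_cluster, rownames(rd))
})

#' @rdname accessors
#' @export
setMethod("zvalues", "ZScoredMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("droppedFeatures", "ZScoredMatrix", function(x, ...) x@dropped)

#' @rdname accessors
#' @export
setMethod("selectedK", "ConsensusResult", function(x, ...) x@selectedK)

#' @rdname accessors
#' @export
setMethod("selectedK", "PhenotypeCall", function(x, ...) x@consensus@selectedK)

#' Consensus matrix for one candidate k
#' @param x a [ConsensusResult-class].
#' @param k which candidate k; defaults to the selected one.
#' @param ... unused.
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k = x@selectedK, ...) {
  idx <- match(k, x@k)
  if (is.na(idx)) stop("k = ", k, " was not evaluated")
  x@consensus[[idx]]
})

#' @rdname accessors
#' @export
setMethod("cdfArea", "ConsensusResult", function(x, ...) {
  setNames(x@area, paste0("k", x@k))
})

#' @rdname accessors
#' @export
setMethod("signatureScores", "SignatureSet", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("explainedVariance", "SignatureSet", function(x, ...) {
  x@explainedVariance
})

#' @rdname accessors
#' @export
setMethod("phenotypeLabels", "PhenotypeCall", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("sigclustP", "PhenotypeCall", function(x, ...) x@sigclustP)

#' Hazard-ratio table of a fitted Cox model
#'
#' @param x a [CoxModel-class].
#' @param level confidence level for the Wald interval.
#' @param ... unused.
#' @return data.frame with covariate, coef, HR, CI bounds, se and Wald p.
#' @export
setMethod("hazardRatios", "CoxModel", function(x, level = 0.95, ...) {
  se <- sqrt(diag(x@vcov))
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(
    covariate = x@covariates,
    coef = unname(x@coef),
    hr = exp(unname(x@coef)),
    lower = exp(unname(x@coef) - z * se),
    upper = exp(unname(x@coef) + z * se),
    se = unname(se),
    p = 2 * pnorm(-abs(unname(x@coef) / se)),
    row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("logLik0", "CoxModel", function(x, ...) x@loglik0)
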