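#' Configuration for a full pipeline run
#'
#' Exactly one of `featurePath`/`clinicalPath` or `simulate` must be given.
#'
#' @param featurePath,clinicalPath delimited-text inputs as written by
#'   [writeCohort()].
#' @param simulate a [cohortConfig()] to generate the cohort instead.
#' @param endpoints endpoints to model; default `c("pfs", "os")`.
#' @param candidates covariates entering the univariable screen.
#' @param screenThreshold univariable retention threshold; default 0.2.
#' @param alwaysKeep covariates kept regardless of the screen.
#' @param featureKRange candidate feature-cluster numbers.
#' @param phenotypeKRange candidate phenotype numbers.
#' @param nResamples consensus resamples per k; default 500.
#' @param subsampleFrac consensus subsampling fraction; default 0.8.
#' @param cutoff CDF delta-area cutoff; default 0.10.
#' @param sigclustSims SigClust Monte-Carlo draws; default 1000.
#' @param nBoot bootstrap resamples for the c-statistic CI; default 1000.
#' @param seed mandatory integer seed controlling the entire run.
#' @param outDir output directory (NULL for no artifacts).
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(featurePath = NULL, clinicalPath = NULL,
                      simulate = NULL, endpoints = c("pfs", "os"),
                      candidates = c("age", "smoking", "ecog",
                                     "line_therapy", "n_mutations"),
                      screenThreshold = 0.2, alwaysKeep = "n_mutations",
                      featureKRange = 2:10, phenotypeKRange = 2:6,
                      nResamples = 500L, subsampleFrac = 0.8, cutoff = 0.10,
                      sigclustSims = 1000L, nBoot = 1000L, seed,
                      outDir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  fromFiles <- !is.null(featurePath) || !is.null(clinicalPath)
  if (fromFiles && !is.null(simulate))
    stop("give input paths or a simulation config, not both")
  if (fromFiles && (is.null(featurePath) || is.null(clinicalPath)))
    stop("both featurePath and clinicalPath are required")
  if (!fromFiles && is.null(simulate))
    stop("either input paths or a simulation config is required")
  structure(list(featurePath = featurePath, clinicalPath = clinicalPath,
                 simulate = simulate, endpoints = endpoints,
                 candidates = candidates,
                 screenThreshold = screenThreshold, alwaysKeep = alwaysKeep,
                 featureKRange = featureKRange,
                 phenotypeKRange = phenotypeKRange,
                 nResamples = as.integer(nResamples),
                 subsampleFrac = subsampleFrac, cutoff = cutoff,
                 sigclustSims = as.integer(sigclustSims),
                 nBoot = as.integer(nBoot), seed = as.integer(seed),
                 outDir = outDir), class = "RunConfig")
}

.coxBlock <- function(data, covariates, endpoint, nBoot, seed) {
  fit <- fitCox(data, covariates, endpoint = endpoint)
  hr <- hazardRatios(fit)
  cb <- unoCBoot(data, covariates, endpoint = endpoint, nBoot = nBoot,
                 seed = seed)
  null <- lrtVsNull(fit)
  list(fit = fit, hr = hr,
       cstat = list(c = cb$c, lower = cb$lower, upper = cb$upper,
                    tau = cb$tau),
       lrtVsNull = list(statistic = null$statistic, df = null$df,
                        p = null$p))
}

#' Run the full phenotyping and survival analysis
#'
#' Executes z-scoring, feature-level consensus clustering on the 1 - r^2
#' distance, PC1 signature derivation, tumor-level consensus phenotyping with
#' SigClust, the phenotype-covariate association block, the univariable Cox
#' screen, multivariable models with and without phenotype (with nested and
#' vs-null likelihood-ratio tests and Uno c-statistics), and the
#' median-prognostic-score dichotomization, per endpoint. All randomness
#' derives from `config$seed`; warnings raised along the way are collected
#' into the report's `log`.
#'
#' @param config a [runConfig()].
#' @return a list of class `AnalysisReport`.
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  warnings <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings[[length(warnings) + 1L]] <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  }

  if (!is.null(config$simulate)) {
    cohort <- simulateCohort(config$simulate)
    fm <- featureMatrix(cohort)
    clinical <- clinicalData(cohort)
    clinical <- clinical[, setdiff(names(clinical), "true_phenotype"),
                         drop = FALSE]
  } else {
    fm <- readFeatureMatrix(config$featurePath)
    clinical <- readClinical(config$clinicalPath)
    if (!identical(rownames(fm), rownames(clinical)))
      stop("stage input: feature matrix and clinical table ids disagree")
  }

  z <- collect(zscoreFeatures(fm))
  dist <- correlationDistance(z)
  featCons <- collect(consensusCluster(
    dist, kRange = config$featureKRange, nResamples = config$nResamples,
    subsampleFrac = config$subsampleFrac,
    seed = childSeed(config$seed, 1), cutoff = config$cutoff))
  kFeat <- selectedK(featCons)
  featLabels <- hierarchicalCut(1 - consensusMatrix(featCons, kFeat), kFeat)
  sigs <- deriveSignatures(z, featLabels)
  pheno <- collect(assignPhenotypes(
    sigs, kRange = config$phenotypeKRange, nResamples = config$nResamples,
    subsampleFrac = config$subsampleFrac,
    seed = childSeed(config$seed, 2),
    sigclustSims = config$sigclustSims, cutoff = config$cutoff))
  labels <- phenotypeLabels(pheno)

  assoc <- collect(associationTable(clinical, labels))
  data <- cbind(clinical, phenotype = labels)

  endpointReports <- list()
  for (ep in config$endpoints) {
    screen <- collect(univariableScreen(
      data, config$candidates, endpoint = ep,
      threshold = config$screenThreshold, alwaysKeep = config$alwaysKeep))
    uni <- list()
    for (nm in c(config$candidates, "phenotype")) {
      fit <- tryCatch(fitCox(data, nm, endpoint = ep),
                      error = function(e) NULL)
      if (!is.null(fit)) uni[[nm]] <- hazardRatios(fit)
    }
    without <- collect(.coxBlock(data, screen$retained, ep, config$nBoot,
                                 childSeed(config$seed, 3)))
    withPh <- collect(.coxBlock(data, c("phenotype", screen$retained), ep,
                              config$nBoot, childSeed(config$seed, 4)))
    nested <- lrtNested(withPh$fit, without$fit)
    split <- collect(prognosticDichotomize(withPh$fit, data))
    endpointReports[[ep]] <- list(
      screen = list(retained = screen$retained,
                    pvalues = as.list(screen$pvalues)),
      univariable = lapply(uni, function(h) h[, c("covariate", "hr", "lower",
                                                  "upper", "p")]),
      withoutPhenotype = list(
        covariates = screen$retained,
        hr = without$hr[, c("covariate", "hr", "lower", "upper", "p")],
        cstat = without$cstat, lrtVsNull = without$lrtVsNull),
      withPhenotype = list(
        covariates = c("phenotype", screen$retained),
        hr = withPh$hr[, c("covariate", "hr", "lower", "upper", "p")],
        cstat = withPh$cstat, lrtVsNull = withPh$lrtVsNull),
      lrtVsNested = nested,
      medianSplit = list(logrankP = split$logrank$p,
                         medianLow = split$kmLow$median,
                         medianHigh = split$kmHigh$median))
  }

  report <- structure(list(
    selectedFeatureK = kFeat,
    phenotypeCount = selectedK(pheno),
    phenotypeSizes = as.integer(table(labels)),
    sigclustP = sigclustP(pheno),
    cdfAreaFeatures = as.list(cdfArea(featCons)),
    association = assoc,
    endpoints = endpointReports,
    settings = list(seed = config$seed, nResamples = config$nResamples,
                    subsampleFrac = config$subsampleFrac,
                    cutoff = config$cutoff,
                    screenThreshold = config$screenThreshold),
    log = warnings), class = "AnalysisReport")

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(patient_id = names(labels),
                         phenotype = unname(labels)),
              file.path(config$outDir, "phenotypes.csv"), row.names = FALSE)
    write.csv(data.frame(patient_id = rownames(signatureScores(sigs)),
                         signatureScores(sigs), check.names = FALSE),
              file.path(config$outDir, "signatures.csv"), row.names = FALSE)
    write.csv(consensusMatrix(featCons, kFeat),
              file.path(config$outDir, "consensus_features.csv"))
    makeReport(report, "json", file.path(config$outDir, "report.json"))
  }
  report
}

# undefined survival medians render as "NR" (not reached)
.jsonReady <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, .jsonReady))
  if (is.numeric(x) && length(x) == 1 && is.na(x)) return("NR")
  x
}

#' Serialize an analysis report
#'
#' `"json"` writes the full report (deterministic, full precision;
#' unreached survival medians render as `"NR"`); `"tsv"` writes the tabular
#' blocks as tab-separated files next to `path`; `"markdown"` renders the
#' per-model hazard-ratio and c-statistic tables.
#'
#' @param report an `AnalysisReport` from [runAnalysis()].
#' @param format `"json"`, `"tsv"` or `"markdown"`.
#' @param path output file (json/markdown) or directory stem (tsv).
#' @return invisibly, the path(s) written.
#' @export
makeReport <- function(report, format = c("json", "tsv", "markdown"), path) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(.jsonReady(unclass(report)), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    return(invisible(path))
  }
  if (format == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    aPath <- file.path(path, "association.tsv")
    utils::write.table(report$association, aPath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- aPath
    for (ep in names(report$endpoints)) {
      for (model in c("withoutPhenotype", "withPhenotype")) {
        p <- file.path(path, paste0(ep, "_", model, ".tsv"))
        utils::write.table(report$endpoints[[ep]][[model]]$hr, p, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
      }
    }
    return(invisible(paths))
  }
  # round-tripped reports may carry "NR" strings where medians were NA
  fmtNum <- function(v) {
    if (!is.numeric(v)) return(as.character(v))
    ifelse(is.na(v), "NR", sprintf("%.3g", v))
  }
  fmtP <- function(p) {
    if (!is.numeric(p)) return(as.character(p))
    format.pval(p, digits = 2)
  }
  lines <- c("# Analysis report", "",
             sprintf("- derived feature clusters k = %d",
                     report$selectedFeatureK),
             sprintf("- phenotypes: %d (sizes %s), SigClust p = %s",
                     report$phenotypeCount,
                     paste(report$phenotypeSizes, collapse = "/"),
                     fmtP(report$sigclustP)), "")
  for (ep in names(report$endpoints)) {
    e <- report$endpoints[[ep]]
    lines <- c(lines, sprintf("## %s", toupper(ep)), "",
               "| Model | Covariate | HR (95% CI) | p |",
               "|---|---|---|---|")
    for (model in c("withoutPhenotype", "withPhenotype")) {
      hr <- e[[model]]$hr
      for (i in seq_len(nrow(hr)))
        lines <- c(lines, sprintf(
          "| %s | %s | %s (%s, %s) | %s |", model, hr$covariate[i],
          fmtNum(hr$hr[i]), fmtNum(hr$lower[i]), fmtNum(hr$upper[i]),
          fmtP(hr$p[i])))
      lines <- c(lines, sprintf(
        "| %s | c-statistic | %s (%s, %s) | vs null p = %s |", model,
        fmtNum(e[[model]]$cstat$c), fmtNum(e[[model]]$cstat$lower),
        fmtNum(e[[model]]$cstat$upper),
        fmtP(e[[model]]$lrtVsNull$p)))
    }
    lines <- c(lines, sprintf("| nested LRT | with vs without | - | %s |",
                              fmtP(e$lrtVsNested$p)),
               sprintf("| median split | log-rank | medians %s / %s | %s |",
                       fmtNum(e$medianSplit$medianLow),
                       fmtNum(e$medianSplit$medianHigh),
                       fmtP(e$medianSplit$logrankP)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
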