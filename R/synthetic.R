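#' Configuration for a synthetic radiomic cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate a
#' 40-patient EGFR-mutant advanced NSCLC cohort profiled with 429 CT radiomic
#' features: planted feature-cluster structure with strong within-cluster
#' correlation, two radiomic phenotypes separated on half of the feature
#' clusters, clinical covariate marginals matching the cohort's published
#' cross-tabulation, and exponential event/censoring times.
#'
#' @param nTumors number of tumors (patients); default 40.
#' @param nFeatures number of radiomic features; default 429.
#' @param kFeatureClusters number of planted feature clusters; default 27.
#' @param withinClusterCorr target pairwise Pearson correlation inside a
#'   planted feature cluster, in \[0, 1); default 0.8.
#' @param nPhenotypes number of planted tumor phenotypes; default 2.
#' @param phenotypeProportions phenotype mixing proportions (sum 1);
#'   default `c(0.525, 0.475)`.
#' @param phenotypeShift mean separation between adjacent phenotypes in
#'   feature-sd units, applied on the affected feature clusters; default 2.
#' @param affectedClusterFraction fraction of feature clusters that carry the
#'   phenotype shift, in (0, 1\]; default 0.5 so that not every derived PC is
#'   informative.
#' @param hazardCoefficients named log hazard ratios applied to the survival
#'   linear predictor; names must be clinical columns or `"phenotype"`
#'   (coded 0/1 for phenotype 2 vs 1). Default `c(phenotype = log(2.7))`.
#' @param baselineRate baseline event rate per day; scalar or named vector
#'   with entries `pfs` and `os`. Default `c(pfs = 0.0022, os = 0.0009)`.
#' @param censorRate exponential censoring rate per day; default 0.0018.
#' @param maxFollowup administrative censoring horizon in days; default 835.
#' @param lineFirstProb per-phenotype probability of first-line (vs later
#'   line) therapy, recycled over phenotypes; default `c(0.381, 0.789)`. Set
#'   both equal for phenotype-independent line of therapy.
#' @param seed integer seed driving all draws.
#' @return a list of class `CohortConfig`.
#' @export
cohortConfig <- function(nTumors = 40L, nFeatures = 429L,
                         kFeatureClusters = 27L, withinClusterCorr = 0.8,
                         nPhenotypes = 2L,
                         phenotypeProportions = c(0.525, 0.475),
                         phenotypeShift = 2, affectedClusterFraction = 0.5,
                         hazardCoefficients = c(phenotype = log(2.7)),
                         baselineRate = c(pfs = 0.0022, os = 0.0009),
                         censorRate = 0.0018, maxFollowup = 835,
                         lineFirstProb = c(0.381, 0.789), seed = 1L) {
  if (nFeatures < kFeatureClusters)
    stop("config error: nFeatures must be >= kFeatureClusters")
  if (kFeatureClusters < 1L) stop("config error: need >= 1 feature cluster")
  if (withinClusterCorr < 0 || withinClusterCorr >= 1)
    stop("config error: withinClusterCorr must lie in [0, 1)")
  if (length(phenotypeProportions) != nPhenotypes ||
      abs(sum(phenotypeProportions) - 1) > 1e-8)
    stop("config error: phenotype proportions must sum to 1")
  if (phenotypeShift < 0) stop("config error: phenotypeShift must be >= 0")
  if (affectedClusterFraction <= 0 || affectedClusterFraction > 1)
    stop("config error: affectedClusterFraction must lie in (0, 1]")
  if (any(baselineRate <= 0) || censorRate <= 0)
    stop("config error: rates must be positive")
  if (maxFollowup < 0) stop("config error: maxFollowup must be >= 0")
  structure(list(
    nTumors = as.integer(nTumors), nFeatures = as.integer(nFeatures),
    kFeatureClusters = as.integer(kFeatureClusters),
    withinClusterCorr = withinClusterCorr,
    nPhenotypes = as.integer(nPhenotypes),
    phenotypeProportions = phenotypeProportions,
    phenotypeShift = phenotypeShift,
    affectedClusterFraction = affectedClusterFraction,
    hazardCoefficients = hazardCoefficients,
    baselineRate = if (length(baselineRate) == 1)
      c(pfs = unname(baselineRate), os = unname(baselineRate)) else baselineRate,
    censorRate = censorRate, maxFollowup = maxFollowup,
    lineFirstProb = rep(lineFirstProb, length.out = nPhenotypes),
    seed = as.integer(seed)), class = "CohortConfig")
}

# deterministic phenotype label allocation: rounded counts, then a seeded
# shuffle so labels are not blocked by tumor index
.planPhenotypes <- function(config) {
  n <- config$nTumors
  cum <- round(cumsum(config$phenotypeProportions) * n)
  counts <- diff(c(0L, cum))
  labels <- rep(seq_len(config$nPhenotypes), counts)
  withSeed(childSeed(config$seed, 11), sample(labels))
}

#' Generate a planted-structure radiomic feature matrix
#'
#' Features inside a planted cluster share a latent Gaussian factor,
#' `feature = sqrt(rho) * factor + sqrt(1 - rho) * noise`, giving expected
#' pairwise within-cluster correlation `rho`. Tumors in different phenotypes
#' differ by `phenotypeShift` feature-sd units in mean on the affected feature
#' clusters (the first `ceiling(affectedClusterFraction * k)` clusters);
#' the remaining clusters carry no phenotype signal.
#'
#' @param config a [cohortConfig()].
#' @return list with `features` (tumors x features matrix),
#'   `featureCluster` (named integer vector, planted cluster per feature) and
#'   `phenotype` (named integer vector, planted phenotype per tumor).
#' @export
generateFeatureMatrix <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$nTumors; p <- config$nFeatures; k <- config$kFeatureClusters
  rho <- config$withinClusterCorr
  featureCluster <- sort(rep_len(seq_len(k), p))
  phenotype <- .planPhenotypes(config)
  nAffected <- ceiling(config$affectedClusterFraction * k)
  affected <- seq_len(nAffected)
  # centered per-phenotype offsets so the matrix stays mean-zero overall
  offsets <- (seq_len(config$nPhenotypes) - 1) * config$phenotypeShift
  offsets <- offsets - sum(offsets * config$phenotypeProportions)
  x <- withSeed(childSeed(config$seed, 12), {
    factors <- matrix(rnorm(n * k), n, k)
    noise <- matrix(rnorm(n * p), n, p)
    m <- sqrt(rho) * factors[, featureCluster, drop = FALSE] +
      sqrt(1 - rho) * noise
    shiftCols <- featureCluster %in% affected
    m[, shiftCols] <- m[, shiftCols] + offsets[phenotype]
    m
  })
  dimnames(x) <- list(sprintf("tumor%03d", seq_len(n)),
                      sprintf("feat%04d", seq_len(p)))
  list(features = x,
       featureCluster = setNames(featureCluster, colnames(x)),
       phenotype = setNames(phenotype, rownames(x)))
}

#' Generate clinical and ctDNA covariates (without outcomes)
#'
#' Marginals emulate the study cohort: age ~ round(Normal(62, 8)) clipped to
#' \[45, 82\]; sex Bernoulli(0.725 female); smoking Bernoulli(0.525 former);
#' ECOG multinomial on grades 0/1/2 (mean 0.55); line of therapy Bernoulli
#' with per-phenotype first-line probability; number of ctDNA mutations
#' 1 + Poisson(3) truncated to \[1, 8\]; EGFR mutation category multinomial
#' over the five observed variants; driver allele fraction Gamma with mean 7.6.
#'
#' @param config a [cohortConfig()].
#' @param truePhenotype integer phenotype labels, length `nTumors`.
#' @return data.frame keyed by `patient_id` with one row per tumor.
#' @export
generateClinical <- function(config, truePhenotype) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$nTumors
  if (length(truePhenotype) != n)
    stop("truePhenotype must have length nTumors")
  if (n == 0L) {
    return(data.frame(patient_id = character(), age = integer(),
                      sex = character(), smoking = character(),
                      ecog = integer(), line_therapy = character(),
                      n_mutations = integer(), egfr_status = character(),
                      driver_af = numeric(), stringsAsFactors = FALSE))
  }
  egfrLevels <- c("exon19del", "exon20ins", "G719C/S768I", "L858R", "T790M")
  egfrProbs <- c(0.35, 0.025, 0.025, 0.20, 0.40)
  withSeed(childSeed(config$seed, 13), {
    age <- pmin(pmax(round(rnorm(n, 62, 8)), 45L), 82L)
    sex <- ifelse(runif(n) < 0.725, "F", "M")
    smoking <- ifelse(runif(n) < 0.525, "former", "never")
    ecog <- sample(0:2, n, replace = TRUE, prob = c(0.50, 0.45, 0.05))
    pFirst <- config$lineFirstProb[truePhenotype]
    line <- ifelse(runif(n) < pFirst, "first", "later")
    muts <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        m <- 1L + rpois(1, 3)
        if (m <= 8L) break
      }
      muts[i] <- m
    }
    egfr <- sample(egfrLevels, n, replace = TRUE, prob = egfrProbs)
    af <- round(rgamma(n, shape = 0.8, scale = 9.5), 1)
    data.frame(patient_id = sprintf("tumor%03d", seq_len(n)),
               age = as.integer(age), sex = sex, smoking = smoking,
               ecog = as.integer(ecog), line_therapy = line,
               n_mutations = muts, egfr_status = egfr, driver_af = af,
               stringsAsFactors = FALSE)
  })
}

#' Generate right-censored survival endpoints
#'
#' Event times are exponential with rate
#' `baselineRate * exp(linear predictor)` where the linear predictor applies
#' `hazardCoefficients` to the clinical columns (binary covariates coded 0/1;
#' `phenotype` coded 0/1 for phenotype 2-vs-1). Censoring is an independent
#' exponential truncated at `maxFollowup` days (non-informative).
#'
#' @param clinical data.frame from [generateClinical()].
#' @param truePhenotype integer phenotype labels.
#' @param config a [cohortConfig()].
#' @param endpoints which endpoints to draw; default both.
#' @return `clinical` with `<endpoint>_time` / `<endpoint>_event` columns.
#' @export
generateSurvival <- function(clinical, truePhenotype, config,
                             endpoints = c("pfs", "os")) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- nrow(clinical)
  lp <- rep(0, n)
  coefs <- config$hazardCoefficients
  for (nm in names(coefs)) {
    xv <- switch(nm,
      phenotype = as.numeric(truePhenotype == 2L),
      smoking = as.numeric(clinical$smoking == "never"),
      line_therapy = as.numeric(clinical$line_therapy == "later"),
      sex = as.numeric(clinical$sex == "M"),
      {
        if (!nm %in% names(clinical))
          stop("hazard coefficient refers to unknown covariate: ", nm)
        as.numeric(clinical[[nm]])
      })
    lp <- lp + coefs[[nm]] * xv
  }
  for (ep in endpoints) {
    rate <- config$baselineRate[[ep]] %||% config$baselineRate[[1]]
    draws <- withSeed(childSeed(config$seed, 14 + match(ep, c("pfs", "os"))), {
      tEvent <- rexp(n, rate = rate * exp(lp))
      tCens <- pmin(rexp(n, rate = config$censorRate), config$maxFollowup)
      list(time = pmin(tEvent, tCens),
           event = as.integer(tEvent <= tCens))
    })
    clinical[[paste0(ep, "_time")]] <- draws$time
    clinical[[paste0(ep, "_event")]] <- draws$event
  }
  clinical
}

#' Simulate a complete synthetic cohort
#'
#' Runs the feature, clinical and survival generators under one config and
#' packs the result into a [RadiomicSet-class] with ground-truth labels in
#' `rowData`/`colData` and the config in `metadata`.
#'
#' @param config a [cohortConfig()].
#' @return a [RadiomicSet-class].
#' @export
simulateCohort <- function(config = cohortConfig()) {
  fm <- generateFeatureMatrix(config)
  clin <- generateClinical(config, fm$phenotype)
  clin <- generateSurvival(clin, fm$phenotype, config)
  rownames(clin) <- clin$patient_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(fm$features)),
    rowData = S4Vectors::DataFrame(
      true_feature_cluster = unname(fm$featureCluster),
      row.names = colnames(fm$features)),
    colData = S4Vectors::DataFrame(clin[, setdiff(names(clin), "patient_id")],
                                   true_phenotype = unname(fm$phenotype),
                                   row.names = rownames(clin)),
    metadata = list(config = config))
  methods::new("RadiomicSet", se)
}

#' Generate a 3D phantom volume with a tumor mask
#'
#' Test bed for the feature-extraction path: an ellipsoidal or spherical mask
#' on a regular grid with one of three textures (constant, 3D checkerboard, or
#' smoothed Gaussian noise) plus optional additive white noise.
#'
#' @param gridShape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm (length 3); default isotropic 1 mm.
#' @param shapeKind `"sphere"` or `"ellipsoid"`.
#' @param radius sphere radius (or length-3 semi-axes for an ellipsoid), in
#'   voxel units; default 40% of the smallest grid dimension.
#' @param texture `"constant"`, `"checker"` or `"smooth-noise"`.
#' @param checkerPeriod checker cell edge in voxels; default 2.
#' @param noiseSd sd of additive Gaussian noise; default 0.
#' @param seed integer seed.
#' @return a [VolumeWithMask-class].
#' @export
generatePhantom <- function(gridShape, spacing = c(1, 1, 1),
                            shapeKind = c("sphere", "ellipsoid"),
                            radius = NULL,
                            texture = c("constant", "checker", "smooth-noise"),
                            checkerPeriod = 2L, noiseSd = 0, seed = 1L) {
  shapeKind <- match.arg(shapeKind)
  texture <- match.arg(texture)
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L, all(gridShape >= 1L))
  if (is.null(radius)) radius <- 0.4 * min(gridShape)
  semi <- if (shapeKind == "sphere") rep(radius[1], 3) else {
    if (length(radius) != 3) stop("ellipsoid needs three semi-axes")
    radius
  }
  centre <- (gridShape + 1) / 2
  if (any(centre - semi < 0.5) || any(centre + semi > gridShape + 0.5))
    stop("mask does not fit inside the grid")
  co <- expand.grid(x = seq_len(gridShape[1]), y = seq_len(gridShape[2]),
                    z = seq_len(gridShape[3]))
  d2 <- ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2
  mask <- array(d2 <= 1, dim = gridShape)
  if (!any(mask)) stop("empty mask")
  img <- withSeed(seed, {
    base <- switch(texture,
      constant = array(100, dim = gridShape),
      checker = {
        parity <- (floor((co$x - 1) / checkerPeriod) +
                   floor((co$y - 1) / checkerPeriod) +
                   floor((co$z - 1) / checkerPeriod)) %% 2
        array(ifelse(parity == 0, 80, 120), dim = gridShape)
      },
      `smooth-noise` = {
        raw <- array(rnorm(prod(gridShape)), dim = gridShape)
        100 + 20 * gaussianSmooth3d(raw, sigmaVox = rep(1.5, 3))
      })
    if (noiseSd > 0) base <- base + array(rnorm(prod(gridShape), 0, noiseSd),
                                          dim = gridShape)
    base
  })
  methods::new("VolumeWithMask", image = img, mask = mask,
               spacing = as.numeric(spacing))
}

#' Write a synthetic cohort to delimited text
#'
#' Writes the feature matrix (`features.csv`, one row per tumor, named
#' columns), the clinical table (`clinical.csv`), and the ground-truth labels
#' (`truth.csv`) — the last is never read by the analysis path.
#'
#' @param cohort a [RadiomicSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fm <- featureMatrix(cohort)
  fp <- file.path(dir, "features.csv")
  write.csv(data.frame(patient_id = rownames(fm), fm, check.names = FALSE),
            fp, row.names = FALSE)
  clin <- clinicalData(cohort)
  clin <- clin[, setdiff(names(clin), "true_phenotype"), drop = FALSE]
  cp <- file.path(dir, "clinical.csv")
  write.csv(data.frame(patient_id = rownames(clin), clin,
                       check.names = FALSE), cp, row.names = FALSE)
  paths <- c(features = fp, clinical = cp)
  tp <- truePhenotype(cohort)
  if (!is.null(tp)) {
    gp <- file.path(dir, "truth.csv")
    write.csv(data.frame(patient_id = names(tp), true_phenotype = unname(tp)),
              gp, row.names = FALSE)
    paths <- c(paths, truth = gp)
  }
  invisible(paths)
}

#' Read a feature matrix written by [writeCohort()]
#' @param path csv path with a `patient_id` column and named feature columns.
#' @return numeric matrix, tumors x features.
#' @export
readFeatureMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"patient_id" %in% names(df)) stop("feature matrix needs a patient_id column")
  m <- as.matrix(df[, setdiff(names(df), "patient_id"), drop = FALSE])
  rownames(m) <- df$patient_id
  storage.mode(m) <- "double"
  m
}

#' Read a clinical table written by [writeCohort()]
#' @param path csv path with a `patient_id` column.
#' @return data.frame with patient ids as rownames.
#' @export
readClinical <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("clinical table needs a patient_id column")
  rownames(df) <- df$patient_id
  df
}
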