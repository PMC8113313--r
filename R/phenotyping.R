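#' Z-score the columns of a feature matrix
#'
#' Per-feature standardization with the sample standard deviation (n - 1).
#' Constant features cannot be scaled; they are dropped with a warning and
#' recorded in the result.
#'
#' @param x numeric matrix, tumors x features.
#' @return a [ZScoredMatrix-class].
#' @export
zscoreFeatures <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 tumors to z-score")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  constant <- scl == 0 | !is.finite(scl)
  if (any(constant))
    noteWarning(paste("dropping constant features:",
                      paste(colnames(x)[constant], collapse = ", ")))
  keep <- which(!constant)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep], `-`),
             2, scl[keep], `/`)
  methods::new("ZScoredMatrix", values = z, center = ctr[keep],
               scale = scl[keep],
               dropped = colnames(x)[constant] %||% character(0))
}

#' Correlation-based feature distance, d = 1 - r^2
#'
#' Pearson correlation across tumors; strongly covarying features (|r| near 1,
#' either sign) are close. The result is symmetric with zero diagonal but is
#' not a metric (the triangle inequality can fail), so downstream clustering
#' treats it as a dissimilarity only.
#'
#' @param z a [ZScoredMatrix-class] or plain tumors x features matrix.
#' @return features x features distance matrix.
#' @export
correlationDistance <- function(z) {
  v <- if (methods::is(z, "ZScoredMatrix")) z@values else as.matrix(z)
  if (nrow(v) < 2L) stop("need at least 2 tumors")
  r <- cor(v)
  d <- 1 - r^2
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering cut at a fixed cluster count
#'
#' Agglomerative clustering with maximum (complete) linkage on a precomputed
#' dissimilarity, cut to `nClusters`. Deterministic given the input order.
#'
#' @param distance symmetric dissimilarity matrix (or `dist`).
#' @param nClusters number of clusters, in 1..n_items.
#' @return integer cluster labels named by item.
#' @export
hierarchicalCut <- function(distance, nClusters) {
  d <- if (inherits(distance, "dist")) distance else as.dist(distance)
  n <- attr(d, "Size")
  if (nClusters < 1L || nClusters > n) stop("nClusters out of range")
  hc <- hclust(d, method = "complete")
  cutree(hc, k = nClusters)
}

#' Consensus clustering over resampled hierarchical cuts
#'
#' For each candidate k, items are subsampled `nResamples` times without
#' replacement and clustered by complete-linkage hierarchical clustering on
#' the restricted dissimilarity. The consensus matrix entry M(i, j) is the
#' proportion of co-clusterings among resamples where both items were drawn
#' (0 for never co-sampled pairs; diagonal 1). The empirical CDF of the
#' upper-triangle entries is evaluated on a regular grid and A(k) is the area
#' under that CDF; the relative forward change in A(k) drives k selection.
#'
#' @param distance symmetric dissimilarity matrix over the items.
#' @param kRange consecutive candidate cluster numbers within
#'   2..(n_items - 1).
#' @param nResamples resamples per k; default 500.
#' @param subsampleFrac subsampling fraction in (0, 1\]; default 0.8.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param cdfGridSize grid points on \[0, 1\] for the CDF; default 100.
#' @param cutoff relative-change cutoff passed to [selectKbyCDF()].
#' @return a [ConsensusResult-class] with `selectedK` filled in.
#' @export
consensusCluster <- function(distance, kRange = 2:6, nResamples = 500L,
                             subsampleFrac = 0.8, seed = 1L,
                             cdfGridSize = 100L, cutoff = 0.10) {
  dm <- as.matrix(distance)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 items for consensus clustering")
  kRange <- sort(as.integer(kRange))
  if (length(kRange) == 0L) stop("empty kRange")
  if (min(kRange) < 2L || max(kRange) > n - 1L)
    stop("kRange must lie within 2..(n_items - 1)")
  if (subsampleFrac <= 0 || subsampleFrac > 1)
    stop("subsampleFrac must lie in (0, 1]")
  m <- max(2L, round(subsampleFrac * n))
  items <- rownames(dm) %||% sprintf("item%03d", seq_len(n))

  grid <- seq(0, 1, length.out = cdfGridSize)
  consensus <- vector("list", length(kRange))
  cdfs <- matrix(0, cdfGridSize, length(kRange))
  areas <- numeric(length(kRange))
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    co <- matrix(0, n, n)     # co-cluster counts
    tog <- matrix(0, n, n)    # co-sample counts
    withSeed(childSeed(seed, 100 + k), {
      for (b in seq_len(nResamples)) {
        idx <- sort(sample.int(n, m))
        lab <- hierarchicalCut(dm[idx, idx, drop = FALSE], min(k, m))
        ind <- outer(lab, lab, `==`)
        co[idx, idx] <- co[idx, idx] + ind
        tog[idx, idx] <- tog[idx, idx] + 1
      }
    })
    M <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(M) <- 1
    dimnames(M) <- list(items, items)
    consensus[[ki]] <- M
    up <- M[upper.tri(M)]
    cdfs[, ki] <- ecdf(up)(grid)
    areas[ki] <- sum(cdfs[-1, ki] * diff(grid))
  }
  delta <- c((areas[-1] - areas[-length(areas)]) / areas[-length(areas)],
             NA_real_)
  res <- methods::new("ConsensusResult", k = kRange, consensus = consensus,
                      cdfGrid = grid, cdf = cdfs, area = areas,
                      deltaArea = delta, selectedK = kRange[1], items = items)
  res@selectedK <- selectKbyCDF(res, cutoff = cutoff)
  res
}

#' Select the number of clusters by the CDF delta-area rule
#'
#' Returns the smallest candidate k whose relative forward change in area
#' under the consensus CDF, `(A(k+1) - A(k)) / A(k)`, falls below `cutoff`.
#' If no k satisfies the rule the largest candidate is returned with a
#' warning.
#'
#' @param result a [ConsensusResult-class] covering consecutive k.
#' @param cutoff relative-change cutoff; default 0.10.
#' @return the selected k (integer).
#' @export
selectKbyCDF <- function(result, cutoff = 0.10) {
  a <- result@area
  k <- result@k
  if (length(k) == 0L) stop("empty k range")
  if (length(k) == 1L) return(k)
  rel <- (a[-1] - a[-length(a)]) / a[-length(a)]
  hit <- which(rel < cutoff)
  if (length(hit) == 0L) {
    noteWarning(paste0("relative CDF-area change never fell below ", cutoff,
                       "; returning the largest k = ", max(k)))
    return(max(k))
  }
  k[min(hit)]
}

#' First-principal-component signatures per feature cluster
#'
#' For each feature cluster, PCA on the tumors x cluster-features submatrix of
#' the z-scored data (covariance PCA; columns already standardized) and
#' retention of the first PC scores as the cluster's derived signature. Each
#' column is sign-oriented to correlate non-negatively with the cluster's mean
#' feature, so signatures are reproducible across platforms.
#'
#' @param z a [ZScoredMatrix-class] (or tumors x features matrix).
#' @param featureLabels integer cluster labels covering all retained features.
#' @return a [SignatureSet-class].
#' @export
deriveSignatures <- function(z, featureLabels) {
  v <- if (methods::is(z, "ZScoredMatrix")) z@values else as.matrix(z)
  if (length(featureLabels) != ncol(v))
    stop("featureLabels must cover all retained features")
  ks <- sort(unique(featureLabels))
  scores <- matrix(0, nrow(v), length(ks),
                   dimnames = list(rownames(v), paste0("PC1.cluster", ks)))
  ev <- numeric(length(ks))
  for (ci in seq_along(ks)) {
    sub <- v[, featureLabels == ks[ci], drop = FALSE]
    if (ncol(sub) == 0L) stop("cluster of size 0")
    if (ncol(sub) == 1L) {
      sc <- sub[, 1]
      ev[ci] <- 1
    } else {
      pc <- prcomp(sub, center = TRUE, scale. = FALSE)
      sc <- pc$x[, 1]
      ev[ci] <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
    meanFeat <- rowMeans(sub)
    if (sum(sc * (meanFeat - mean(meanFeat))) < 0) sc <- -sc
    scores[, ci] <- sc
  }
  methods::new("SignatureSet", scores = scores, explainedVariance = ev,
               featureClusters = as.integer(featureLabels))
}

#' Cluster tumors into radiomic phenotypes
#'
#' Tumor-level consensus clustering on the signature rows (Euclidean distance
#' by default; `1 - r^2` across signature vectors available), k selected by
#' the CDF delta-area rule, and final labels from a complete-linkage cut of
#' `1 - M` at the selected k, where M is that k's consensus matrix. Label 1
#' is the larger cluster (ties broken by order of first appearance). When two
#' phenotypes are selected, a SigClust test of two clusters versus one is run
#' on the signature rows.
#'
#' @param signatures a [SignatureSet-class] or tumors x k matrix.
#' @param kRange candidate phenotype counts; default 2:6.
#' @param nResamples consensus resamples per k; default 500.
#' @param subsampleFrac subsampling fraction; default 0.8.
#' @param seed integer seed.
#' @param distanceMethod `"euclidean"` (default) or `"cor"` for `1 - r^2`
#'   between tumor signature vectors.
#' @param sigclustSims Monte-Carlo draws for the SigClust test (0 skips it).
#' @param cutoff CDF delta-area cutoff; default 0.10.
#' @return a [PhenotypeCall-class].
#' @export
assignPhenotypes <- function(signatures, kRange = 2:6, nResamples = 500L,
                             subsampleFrac = 0.8, seed = 1L,
                             distanceMethod = c("euclidean", "cor"),
                             sigclustSims = 1000L, cutoff = 0.10) {
  distanceMethod <- match.arg(distanceMethod)
  s <- if (methods::is(signatures, "SignatureSet")) signatures@scores
       else as.matrix(signatures)
  if (nrow(s) < 4L) stop("need at least 4 tumors")
  dm <- if (distanceMethod == "euclidean") as.matrix(stats::dist(s))
        else correlationDistance(t(s))
  kRange <- kRange[kRange <= nrow(s) - 1L]
  res <- consensusCluster(dm, kRange = kRange, nResamples = nResamples,
                          subsampleFrac = subsampleFrac, seed = seed,
                          cutoff = cutoff)
  m <- selectedK(res)
  lab <- hierarchicalCut(1 - consensusMatrix(res, m), m)
  lab <- .relabelBySize(lab)
  p <- NA_real_
  if (m == 2L && sigclustSims > 0L)
    p <- sigclustTest(s, lab, nSim = sigclustSims,
                      seed = childSeed(seed, 999))
  methods::new("PhenotypeCall", labels = lab, consensus = res, sigclustP = p)
}

# relabel so that label 1 is the largest cluster; ties keep first-appearance
# order
.relabelBySize <- function(lab) {
  tab <- table(lab)
  sizes <- as.integer(tab)
  first <- match(names(tab), as.character(lab))
  ord <- order(-sizes, first)
  map <- integer(length(tab))
  map[as.integer(names(tab))[ord]] <- seq_along(ord)
  out <- map[lab]
  names(out) <- names(lab)
  out
}

#' SigClust test of two clusters versus one
#'
#' The cluster index CI is the within-cluster sum of squares of the observed
#' 2-way split divided by the total sum of squares. The null is a single
#' multivariate Gaussian with diagonal covariance whose eigenvalues are the
#' sample covariance eigenvalues floored at a background noise variance (the
#' squared MAD estimate of the pooled centered data values); each Monte-Carlo
#' draw is split by 2-means and its CI computed. The p-value is the
#' add-one-smoothed fraction of null CIs at or below the observed CI.
#'
#' @param x numeric matrix of data rows (tumors x dims).
#' @param labels 2-cluster assignment, each cluster with >= 2 members.
#' @param nSim Monte-Carlo draws (>= 1).
#' @param seed integer seed.
#' @return p-value in (0, 1\].
#' @export
sigclustTest <- function(x, labels, nSim = 1000L, seed = 1L) {
  x <- as.matrix(x)
  if (nSim < 1L) stop("nSim must be >= 1 (cannot form a null)")
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("exactly 2 clusters required")
  if (min(table(labels)) < 2L) stop("each cluster needs >= 2 members")
  ciOf <- function(m, lab) {
    tot <- sum(sweep(m, 2, colMeans(m), `-`)^2)
    wss <- 0
    for (g in unique(lab)) {
      sub <- m[lab == g, , drop = FALSE]
      wss <- wss + sum(sweep(sub, 2, colMeans(sub), `-`)^2)
    }
    if (tot == 0) return(1)
    wss / tot
  }
  ciObs <- ciOf(x, labels)
  centred <- sweep(x, 2, colMeans(x), `-`)
  lam <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  sigBg <- mad(as.vector(centred))^2
  lam <- pmax(lam, sigBg)
  n <- nrow(x); d <- ncol(x)
  ciNull <- withSeed(seed, vapply(seq_len(nSim), function(b) {
    sim <- matrix(rnorm(n * d), n, d) %*% diag(sqrt(lam), d)
    km <- kmeans(sim, centers = 2L, nstart = 3L)
    ciOf(sim, km$cluster)
  }, numeric(1)))
  (1 + sum(ciNull <= ciObs)) / (nSim + 1)
}
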