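test_that("z-scoring standardizes, drops constants, and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 4, 9))
  expect_warning(z <- zscoreFeatures(m), "constant")
  expect_equal(unname(zvalues(z)[, "a"]), c(-1, 0, 1))
  expect_identical(droppedFeatures(z), "b")
  expect_lt(max(abs(colMeans(zvalues(z)))), 1e-12)
  expect_lt(max(abs(apply(zvalues(z), 2, sd) - 1)), 1e-12)
  z2 <- zscoreFeatures(zvalues(z))
  expect_equal(zvalues(z2), zvalues(z), tolerance = 1e-12)
  expect_error(zscoreFeatures(m[1, , drop = FALSE]), "2 tumors")
})

test_that("1 - r^2 distance treats correlation and anti-correlation alike", {
  x <- c(1, 3, 2, 5, 4)
  m <- cbind(f1 = x, f2 = 2 * x, f3 = -x,
             f4 = c(1, -1, 1, -1, 0))
  m[, 4] <- m[, 4] - lm.fit(cbind(1, x), m[, 4])$fitted.values  # orthogonal
  d <- correlationDistance(zscoreFeatures(m))
  expect_equal(d["f1", "f2"], 0, tolerance = 1e-12)
  expect_equal(d["f1", "f3"], 0, tolerance = 1e-12)
  expect_equal(d["f1", "f4"], 1, tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # invariant to affine rescaling of a column
  m2 <- m; m2[, 1] <- 10 - 3 * m2[, 1]
  d2 <- correlationDistance(zscoreFeatures(m2))
  expect_equal(d, d2, tolerance = 1e-12)
})

test_that("hierarchical cut matches a brute-force complete-linkage oracle", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      pts <- matrix(rnorm(12), 6, 2)
      d <- as.matrix(dist(pts))
      hc <- hclust(as.dist(d), method = "complete")
      expect_equal(hc$height, completeLinkBrute(d), tolerance = 1e-10)
    }
  })
  # separable planted blocks
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
               matrix(rnorm(10, 50, 0.1), 5, 2))
  lab <- hierarchicalCut(as.matrix(dist(pts)), 2)
  expect_equal(length(unique(lab[1:5])), 1)
  expect_equal(length(unique(lab[6:10])), 1)
  expect_true(lab[1] != lab[6])
  # singleton cut
  expect_equal(sort(unique(hierarchicalCut(as.matrix(dist(pts)), 10))), 1:10)
  expect_error(hierarchicalCut(as.matrix(dist(pts)), 11), "range")
})

test_that("consensus matrices are crisp for separated blobs, diffuse for noise", {
  withr::with_seed(7, {
    blobs <- rbind(matrix(rnorm(20), 10, 2),
                   matrix(rnorm(20, 1e6), 10, 2))
    d <- as.matrix(dist(blobs))
    cr <- suppressWarnings(consensusCluster(d, kRange = 2:3,
                                            nResamples = 50, seed = 1))
    M <- consensusMatrix(cr, 2)
    expect_true(all(M %in% c(0, 1)))
    expect_true(all(M[1:10, 1:10] == 1))
    expect_true(all(M[1:10, 11:20] == 0))

    noise <- matrix(rnorm(60), 30, 2)
    crN <- suppressWarnings(consensusCluster(as.matrix(dist(noise)),
                                             kRange = 2:3, nResamples = 100,
                                             seed = 2))
    mN <- consensusMatrix(crN, 2)
    avg <- mean(mN[upper.tri(mN)])
    expect_gt(avg, 0.2); expect_lt(avg, 0.8)
  })
  # collapse case: single full-data cut
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  cr1 <- suppressWarnings(consensusCluster(d, kRange = 2:2, nResamples = 1,
                                           subsampleFrac = 1, seed = 3))
  lab <- hierarchicalCut(d, 2)
  expect_equal(unname(consensusMatrix(cr1, 2)),
               unname(outer(lab, lab, `==`) * 1))
})

test_that("the CDF delta-area rule picks the first sub-cutoff k", {
  mk <- function(areas) {
    ks <- seq(2, length.out = length(areas))
    methods::new("ConsensusResult", k = as.integer(ks),
                 consensus = rep(list(matrix(1, 2, 2)), length(areas)),
                 cdfGrid = c(0, 1),
                 cdf = matrix(0, 2, length(areas)), area = areas,
                 deltaArea = rep(NA_real_, length(areas)),
                 selectedK = 2L, items = c("a", "b"))
  }
  expect_equal(selectKbyCDF(mk(c(0.50, 0.80, 0.84, 0.85))), 3)
  expect_warning(k <- selectKbyCDF(mk(c(0.5, 0.6, 0.72, 0.9))), "largest")
  expect_equal(k, 5)
})

test_that("PC1 signatures match an eigendecomposition oracle", {
  withr::with_seed(13, {
    m <- matrix(rnorm(30 * 6), 30, 6)
    m[, 2] <- m[, 1] + rnorm(30, 0, 0.3)
    m[, 3] <- m[, 1] + rnorm(30, 0, 0.3)
    z <- zscoreFeatures(m)
    labels <- c(1, 1, 1, 2, 2, 3)
    sg <- deriveSignatures(z, labels)
    v <- zvalues(z)
    for (ci in 1:3) {
      sub <- v[, labels == ci, drop = FALSE]
      if (ncol(sub) == 1) {
        expect_equal(abs(signatureScores(sg)[, ci]), abs(sub[, 1]),
                     tolerance = 1e-10)
        next
      }
      cc <- cov(sub)
      evec <- eigen(cc, symmetric = TRUE)$vectors[, 1]
      oracle <- sweep(sub, 2, colMeans(sub), `-`) %*% evec
      got <- signatureScores(sg)[, ci]
      expect_lt(min(sum((got - oracle)^2), sum((got + oracle)^2)), 1e-16)
    }
    # sign convention: non-negative correlation with the cluster mean feature
    expect_gte(cor(signatureScores(sg)[, 1], rowMeans(v[, labels == 1])), 0)
  })

  # one-feature cluster passes through; duplicated column explains everything
  m2 <- cbind(a = rnorm(20), b = rnorm(20))
  m2 <- cbind(m2, c = m2[, "b"] + 1e-12 * rnorm(20))
  z2 <- zscoreFeatures(m2)
  sg2 <- deriveSignatures(z2, c(1, 2, 2))
  expect_equal(unname(signatureScores(sg2)[, 1]),
               unname(zvalues(z2)[, "a"]) *
                 sign(cor(zvalues(z2)[, "a"], zvalues(z2)[, "a"])),
               tolerance = 1e-10)
  expect_gt(explainedVariance(sg2)[2], 0.999)
  expect_error(deriveSignatures(z2, c(1, 2)), "cover")
})

test_that("phenotype assignment is duplicate-consistent and separates blobs", {
  withr::with_seed(17, {
    s <- rbind(matrix(rnorm(40), 20, 2),
               matrix(rnorm(36, 8), 18, 2))
    truth <- rep(1:2, c(20, 18))
    ph <- suppressWarnings(assignPhenotypes(s, kRange = 2:4,
                                            nResamples = 100, seed = 1,
                                            sigclustSims = 0))
    # the 2-cluster consensus cut itself recovers the blobs exactly
    lab2 <- hierarchicalCut(1 - consensusMatrix(ph@consensus, 2), 2)
    expect_equal(ari(lab2, truth), 1)
    # label 1 is the larger cluster
    expect_gte(sum(phenotypeLabels(ph) == 1),
               max(table(phenotypeLabels(ph))[-1]))

    dup <- rbind(s, s)
    phd <- suppressWarnings(assignPhenotypes(dup, kRange = 2:4,
                                             nResamples = 100, seed = 2,
                                             sigclustSims = 0))
    l <- phenotypeLabels(phd)
    expect_equal(l[1:38], l[39:76], ignore_attr = TRUE)
  })
})

test_that("SigClust separates strong splits and rejects invalid input", {
  withr::with_seed(19, {
    x <- rbind(matrix(rnorm(25 * 3), 25, 3),
               matrix(rnorm(25 * 3, 10), 25, 3))
    lab <- rep(1:2, each = 25)
    p <- sigclustTest(x, lab, nSim = 200, seed = 4)
    expect_lte(p, 0.01)
    expect_error(sigclustTest(x, lab, nSim = 0), "nSim")
    expect_error(sigclustTest(x, rep(1, 50), nSim = 10), "2 clusters")
  })
})
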