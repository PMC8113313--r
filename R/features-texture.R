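# the 13 unique 3D directions (one per +/- pair): first nonzero component +1
.directions13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first <- apply(g, 1, function(v) v[which(v != 0)[1]])
  unname(g[first > 0, , drop = FALSE])
}

# values of `lv` sampled at position + off; NA where the source is off-grid
.shiftArray <- function(lv, off) {
  d <- dim(lv)
  src <- lapply(1:3, function(a) seq_len(d[a]) + off[a])
  ok <- lapply(1:3, function(a) src[[a]] >= 1L & src[[a]] <= d[a])
  out <- array(NA_integer_, d)
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    lv[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

# GLCM for one direction: G x G count matrix (symmetric accumulation)
.glcmCounts <- function(lv, off, G, symmetric = TRUE) {
  sh <- .shiftArray(lv, off)
  keep <- !is.na(lv) & !is.na(sh)
  a <- lv[keep]; b <- sh[keep]
  cnt <- matrix(tabulate((a - 1L) * G + b, nbins = G * G), G, G, byrow = TRUE)
  if (symmetric) cnt <- cnt + t(cnt)
  cnt
}

.glcmStats <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  pz <- P[P > 0]
  c(contrast = sum((i - j)^2 * P),
    correlation = corr,
    joint_entropy = -sum(pz * log2(pz)),
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))))
}

# runs of equal gray level along one direction; returns matrix of
# (level, run length) counts
.glrlmCounts <- function(lv, off, G) {
  d <- dim(lv)
  co <- arrayInd(seq_len(prod(d)), d)  # all grid voxels
  # step index: coordinate along the first nonzero direction axis
  axis <- which(off != 0)[1]
  s <- co[, axis]
  # line identifier: origin of the line through the voxel (strides exceed the
  # coordinate ranges, so keys are collision-free for grids up to 2000^3)
  key <- (co[, 1] - s * off[1]) * 6.4e7 + (co[, 2] - s * off[2]) * 8e3 +
    (co[, 3] - s * off[3])
  ord <- order(key, s)
  vals <- lv[co[ord, , drop = FALSE]]
  keyo <- key[ord]
  newLine <- c(TRUE, keyo[-1] != keyo[-length(keyo)])
  same <- c(FALSE, !newLine[-1] &
              !is.na(vals[-1]) & !is.na(vals[-length(vals)]) &
              vals[-1] == vals[-length(vals)])
  runId <- cumsum(!same)
  inMask <- !is.na(vals)
  runLen <- tapply(inMask, runId, sum)
  runLev <- tapply(vals, runId, function(v) v[1])
  keep <- !is.na(runLev) & runLen > 0
  runLen <- as.integer(runLen[keep]); runLev <- as.integer(runLev[keep])
  maxLen <- max(runLen)
  matrix(tabulate((runLev - 1L) * maxLen + runLen, nbins = G * maxLen),
         G, maxLen, byrow = TRUE)
}

.runZoneStats <- function(R, Np, prefix) {
  Nr <- sum(R)
  lvl <- rowSums(R)           # per gray level
  len <- colSums(R)           # per run length / zone size
  l <- seq_along(len)
  out <- c(sum(sweep(R, 2, l^2, `/`)) / Nr,
           sum(sweep(R, 2, l^2, `*`)) / Nr,
           sum(lvl^2) / Nr,
           sum(len^2) / Nr,
           Nr / Np)
  names(out) <- paste0(prefix, c("_short_emphasis", "_long_emphasis",
                                 "_gln", "_length_nonuniformity",
                                 "_percentage"))
  out
}

# zones: 26-connected components of constant gray level inside the mask
.glszmCounts <- function(lv, G) {
  d <- dim(lv)
  inIdx <- which(!is.na(lv))
  n <- length(inIdx)
  id <- array(0L, d); id[inIdx] <- seq_len(n)
  co <- which(!is.na(lv), arr.ind = TRUE)
  vals <- lv[inIdx]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- rep(FALSE, n)
  zones <- list(); nz <- 0L
  for (start in seq_len(n)) {
    if (visited[start]) next
    lev <- vals[start]
    comp <- integer(0)
    frontier <- start
    visited[start] <- TRUE
    while (length(frontier)) {
      comp <- c(comp, frontier)
      fc <- co[frontier, , drop = FALSE]
      nb <- fc[rep(seq_len(nrow(fc)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(fc)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      cand <- unique(id[nb[ok, , drop = FALSE]])
      cand <- cand[cand > 0]
      cand <- cand[!visited[cand] & vals[cand] == lev]
      visited[cand] <- TRUE
      frontier <- cand
    }
    nz <- nz + 1L
    zones[[nz]] <- c(lev, length(comp))
  }
  zm <- do.call(rbind, zones)
  maxSize <- max(zm[, 2])
  matrix(tabulate((zm[, 1] - 1L) * maxSize + zm[, 2], nbins = G * maxSize),
         G, maxSize, byrow = TRUE)
}

# per-voxel count of 26-neighbours with identical level (GLDM, alpha = 0)
.gldmCounts <- function(lv, G) {
  dep <- array(0L, dim(lv))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    sh <- .shiftArray(lv, offs[r, ])
    eq <- !is.na(lv) & !is.na(sh) & lv == sh
    dep <- dep + eq
  }
  inMask <- !is.na(lv)
  i <- lv[inMask]; k <- dep[inMask] + 1L   # dependence column index k+1
  maxK <- max(k)
  matrix(tabulate((i - 1L) * maxK + k, nbins = G * maxK), G, maxK,
         byrow = TRUE)
}

.gldmStats <- function(D) {
  Nd <- sum(D)
  j <- seq_len(ncol(D))
  lvl <- rowSums(D); dep <- colSums(D)
  p <- D[D > 0] / Nd
  c(small_dependence_emphasis = sum(sweep(D, 2, j^2, `/`)) / Nd,
    large_dependence_emphasis = sum(sweep(D, 2, j^2, `*`)) / Nd,
    gln = sum(lvl^2) / Nd,
    dependence_nonuniformity = sum(dep^2) / Nd,
    dependence_entropy = -sum(p * log2(p)))
}

.ngtdmStats <- function(lv, G) {
  num <- array(0, dim(lv)); cnt <- array(0L, dim(lv))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (r in seq_len(nrow(offs))) {
    sh <- .shiftArray(lv, offs[r, ])
    ok <- !is.na(sh)
    num[ok] <- num[ok] + sh[ok]
    cnt <- cnt + ok
  }
  use <- !is.na(lv) & cnt > 0
  i <- lv[use]
  A <- num[use] / cnt[use]
  Nv <- length(i)
  s <- vapply(seq_len(G), function(g) sum(abs(g - A[i == g])), numeric(1))
  n <- tabulate(i, nbins = G)
  p <- n / Nv
  act <- which(p > 0)
  Ngp <- length(act)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 0
  if (Ngp > 1) {
    pij <- outer(p[act], p[act])
    dij <- outer(act, act, `-`)
    contrast <- sum(pij * dij^2) / (Ngp * (Ngp - 1)) * sum(s) / Nv
    ip <- act * p[act]
    busyDen <- sum(abs(outer(ip, ip, `-`)))
    busyness <- if (busyDen > 0) ps / busyDen else 0
    psAct <- (p * s)[act]
    complexity <- sum(abs(dij) * (outer(psAct, rep(1, Ngp)) +
                                    outer(rep(1, Ngp), psAct)) /
                        (outer(p[act], p[act], `+`))) / Nv
    strength <- if (sum(s) > 0)
      sum((outer(p[act], p[act], `+`)) * dij^2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' Texture-matrix features of a discretized volume
#'
#' Builds the requested family's matrix over the in-mask voxels and returns
#' its standard derived statistics. GLCM and GLRLM are directional and are
#' averaged over the 13 unique 3D directions; GLSZM, GLDM and NGTDM are
#' rotation-independent. GLCM uses symmetric accumulation at the given
#' Chebyshev distance; GLSZM zones and GLDM dependence use 26-connectivity
#' with a zero level-difference tolerance. On degenerate single-gray-level
#' input, statistics whose normalizer vanishes return 0.
#'
#' @param q a [QuantizedVolume-class].
#' @param family one of `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @param distance neighbour distance for GLCM; default 1.
#' @param symmetric symmetric GLCM accumulation; default TRUE.
#' @return named numeric vector of 5 features.
#' @export
textureFeatures <- function(q, family = c("glcm", "glrlm", "glszm", "gldm",
                                          "ngtdm"),
                            distance = 1L, symmetric = TRUE) {
  family <- match.arg(family)
  lv <- q@levels
  G <- q@G
  dirs <- .directions13()
  switch(family,
    glcm = {
      acc <- NULL; used <- 0L
      for (r in seq_len(nrow(dirs))) {
        cnt <- .glcmCounts(lv, dirs[r, ] * distance, G, symmetric)
        tot <- sum(cnt)
        if (tot == 0) next
        st <- .glcmStats(cnt / tot)
        acc <- if (is.null(acc)) st else acc + st
        used <- used + 1L
      }
      if (used == 0L) {
        noteWarning("GLCM: no voxel pairs in any direction; returning zeros")
        return(c(contrast = 0, correlation = 0, joint_entropy = 0,
                 energy = 0, homogeneity = 0))
      }
      acc / used
    },
    glrlm = {
      Np <- sum(!is.na(lv))
      acc <- NULL
      for (r in seq_len(nrow(dirs))) {
        st <- .runZoneStats(.glrlmCounts(lv, dirs[r, ], G), Np, "run")
        acc <- if (is.null(acc)) st else acc + st
      }
      acc / nrow(dirs)
    },
    glszm = .runZoneStats(.glszmCounts(lv, G), sum(!is.na(lv)), "zone"),
    gldm = .gldmStats(.gldmCounts(lv, G)),
    ngtdm = .ngtdmStats(lv, G))
}
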