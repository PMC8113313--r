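# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by enumeration/naive iteration, never by calling the
# package code paths they check.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxidx <- (sumA + sumB) / 2
  if (maxidx == expected) return(0)
  (sumij - expected) / (maxidx - expected)
}

# Cox partial log-likelihood for a single covariate, no tied event times
coxPartialLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# grid-search maximizer of the explicit partial likelihood
coxGridSearch <- function(time, event, x, lower = -5, upper = 5, step = 1e-4) {
  grid <- seq(lower, upper, by = step)
  ll <- vapply(grid, coxPartialLoglik, numeric(1), time = time,
               event = event, x = x)
  grid[which.max(ll)]
}

# exhaustive weighted-pair enumeration of the IPCW concordance
unoBrute <- function(time, event, lp, tau) {
  km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    idx <- which(km$time < t - 1e-12)
    if (length(idx) == 0) 1 else km$surv[max(idx)]
  }
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] != 1 || time[i] > tau || time[j] <= time[i]) next
    g <- G(time[i])
    if (g <= 0) next
    w <- 1 / g^2
    num <- num + w * (as.numeric(lp[i] > lp[j]) +
                        0.5 * as.numeric(lp[i] == lp[j]))
    den <- den + w
  }
  num / den
}

# naive agglomerative complete-linkage: returns merge heights
completeLinkBrute <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestH <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < bestH) { bestH <- h; best <- c(a, b) }
    }
    heights <- c(heights, bestH)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# exhaustive GLCM pair counts for one direction (symmetric)
glcmBrute <- function(lv, off, G) {
  d <- dim(lv)
  cnt <- matrix(0L, G, G)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    p <- c(x, y, z) + off
    if (any(p < 1) || any(p > d)) next
    b <- lv[p[1], p[2], p[3]]
    if (is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1L
    cnt[b, a] <- cnt[b, a] + 1L
  }
  cnt
}

# exhaustive run enumeration for one direction: matrix level x run length
glrlmBrute <- function(lv, off, G) {
  d <- dim(lv)
  runs <- list()
  inGrid <- function(p) all(p >= 1) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (inGrid(p - off)) next  # not a line start
    seqv <- integer(0)
    while (inGrid(p)) {
      seqv <- c(seqv, lv[p[1], p[2], p[3]])
      p <- p + off
    }
    r <- rle(seqv)
    for (k in seq_along(r$lengths))
      if (!is.na(r$values[k]))
        runs[[length(runs) + 1]] <- c(r$values[k], r$lengths[k])
  }
  rm <- do.call(rbind, runs)
  maxLen <- max(rm[, 2])
  out <- matrix(0L, G, maxLen)
  for (k in seq_len(nrow(rm))) out[rm[k, 1], rm[k, 2]] <-
      out[rm[k, 1], rm[k, 2]] + 1L
  out
}

# naive 26-connected zone enumeration: sorted zone (level, size) pairs
glszmBrute <- function(lv) {
  d <- dim(lv)
  visited <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (visited[x, y, z] || is.na(lv[x, y, z])) next
    lev <- lv[x, y, z]
    stack <- list(c(x, y, z))
    visited[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (visited[q[1], q[2], q[3]]) next
        v <- lv[q[1], q[2], q[3]]
        if (is.na(v) || v != lev) next
        visited[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  zm <- do.call(rbind, zones)
  zm[order(zm[, 1], zm[, 2]), , drop = FALSE]
}

# small helper: cohort clinical table with phenotype column attached
cohortWithPhenotype <- function(cfg) {
  co <- simulateCohort(cfg)
  d <- clinicalData(co)
  d$phenotype <- d$true_phenotype
  d
}
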