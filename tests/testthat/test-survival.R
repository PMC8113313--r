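test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  km <- kmEstimate(c(5, 8, 8, 12, 15), c(1, 1, 1, 0, 1))
  s <- setNames(km$surv, km$time)
  expect_equal(unname(s["5"]), 0.8)
  expect_equal(unname(s["8"]), 0.8 * (1 - 2 / 4))
  expect_equal(unname(s["15"]), 0)

  allCens <- kmEstimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(allCens$surv == 1))
  expect_true(is.na(allCens$median))

  # no censoring: survival equals the empirical complement
  t <- c(2, 4, 6, 8, 10)
  km2 <- kmEstimate(t, rep(1, 5))
  expect_equal(km2$surv, 1 - seq_len(5) / 5)

  # time-scale invariance
  km3 <- kmEstimate(t * 7, rep(1, 5))
  expect_equal(km3$surv, km2$surv)
  expect_equal(km3$time, km2$time * 7)
})

test_that("log-rank matches the O-E/V closed form and its null", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 1, 1, 0),
                  grp = c(1, 2, 1, 2, 1, 2))
  # hand computation of sum(O - E) and V for group 1
  oe <- 0; v <- 0
  for (tt in d$time[d$event == 1]) {
    risk <- d$time >= tt
    n <- sum(risk); n1 <- sum(risk & d$grp == 1)
    dthis <- sum(d$time == tt & d$event == 1)
    o1 <- sum(d$time == tt & d$event == 1 & d$grp == 1)
    e1 <- dthis * n1 / n
    oe <- oe + o1 - e1
    if (n > 1) v <- v + dthis * (n1 / n) * (1 - n1 / n) * (n - dthis) / (n - 1)
  }
  lr <- logrankTest(d$time, d$event, d$grp)
  expect_equal(lr$chisq, oe^2 / v, tolerance = 1e-10)

  dup <- rbind(d, d)
  dup$grp <- rep(1:2, each = 6)
  dup$time <- c(d$time, d$time); dup$event <- c(d$event, d$event)
  lrDup <- logrankTest(dup$time, dup$event, dup$grp)
  expect_equal(lrDup$chisq, 0, tolerance = 1e-10)
  expect_equal(lrDup$p, 1, tolerance = 1e-10)
  expect_error(logrankTest(d$time, d$event, rep(1, 6)), "2 groups")
})

test_that("Cox fits maximize the explicit partial likelihood", {
  d <- data.frame(
    pfs_time = c(3, 5, 7, 11, 13, 17, 19, 23),
    pfs_event = c(1, 0, 1, 1, 0, 1, 1, 0),
    x = c(1, 1, 0, 1, 0, 0, 1, 0))
  fit <- fitCox(d, "x", endpoint = "pfs")
  oracle <- coxGridSearch(d$pfs_time, d$pfs_event, d$x)
  expect_lt(abs(unname(fit@coef) - oracle), 1e-4)
  expect_gte(fit@loglik, fit@loglik0)
  # loglik at the estimate matches the explicit formula
  expect_equal(fit@loglik,
               coxPartialLoglik(unname(fit@coef), d$pfs_time, d$pfs_event,
                                d$x),
               tolerance = 1e-8)

  d$const <- 1
  expect_error(fitCox(d, "const", endpoint = "pfs"), "singular")
  d0 <- d; d0$pfs_event <- 0
  expect_error(fitCox(d0, "x", endpoint = "pfs"), "no events")
})

test_that("nested LRTs satisfy the bookkeeping identity and invariances", {
  cfg <- cohortConfig(nTumors = 150, nFeatures = 4, kFeatureClusters = 2,
                      seed = 61)
  d <- cohortWithPhenotype(cfg)
  full <- fitCox(d, c("phenotype", "ecog"), endpoint = "pfs")
  red <- fitCox(d, "ecog", endpoint = "pfs")
  lrt <- lrtNested(full, red)
  expect_equal(lrt$statistic, 2 * (full@loglik - red@loglik))
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)

  same <- lrtNested(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lrtNested(red, full), "nested")

  # LRT invariant to affine rescaling of a covariate
  d2 <- d; d2$ecog <- 10 * d2$ecog - 3
  full2 <- fitCox(d2, c("phenotype", "ecog"), endpoint = "pfs")
  red2 <- fitCox(d2, "ecog", endpoint = "pfs")
  expect_equal(lrtNested(full2, red2)$statistic, lrt$statistic,
               tolerance = 1e-6)

  null <- lrtVsNull(full)
  expect_equal(null$statistic, 2 * (full@loglik - full@loglik0))
  expect_equal(null$df, 2)
})

test_that("Uno's c equals exhaustive weighted pair enumeration", {
  # perfect rank-inverse predictor without censoring
  t <- c(1, 2, 3, 4, 5, 6)
  lp <- -t  # shorter survival = higher risk score
  expect_equal(unoC(t, rep(1, 6), lp)$c, 1)
  expect_equal(unoC(t, rep(1, 6), -lp)$c, 0)

  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- 10
      time <- round(rexp(n, 0.1) + 1)
      event <- rbinom(n, 1, 0.7)
      if (sum(event) == 0) event[1] <- 1
      lp <- rnorm(n)
      tau <- max(time[event == 1])
      got <- suppressWarnings(unoC(time, event, lp, tau = tau))
      expect_equal(got$c, unoBrute(time, event, lp, tau), tolerance = 1e-10)
    }
  })

  # without censoring and with tau beyond all times, equals Harrell's c
  withr::with_seed(29, {
    n <- 30
    time <- rexp(n); lp <- rnorm(n)
    harrell <- 0; tot <- 0
    for (i in 1:n) for (j in 1:n) {
      if (time[i] >= time[j]) next
      tot <- tot + 1
      harrell <- harrell + (lp[i] > lp[j]) + 0.5 * (lp[i] == lp[j])
    }
    expect_equal(unoC(time, rep(1, n), lp, tau = max(time) + 1)$c,
                 harrell / tot, tolerance = 1e-12)
  })
})

test_that("Uno's c agrees with the survival package's IPCW variant", {
  withr::with_seed(31, {
    n <- 120
    x <- rbinom(n, 1, 0.5)
    time <- rexp(n, 0.1 * exp(0.7 * x))
    cens <- rexp(n, 0.08)
    obs <- pmin(time, cens); event <- as.integer(time <= cens)
    lp <- x * 0.7
    tau <- max(obs[event == 1])
    ours <- suppressWarnings(unoC(obs, event, lp, tau = tau))$c
    cc <- survival::concordance(survival::Surv(obs, event) ~ lp,
                                timewt = "n/G2", reverse = TRUE,
                                ymax = tau)
    expect_equal(ours, unname(cc$concordance), tolerance = 0.02)
  })
})

test_that("median prognostic-score split is balanced and deterministic", {
  # continuous covariate so prognostic scores are tie-free
  withr::with_seed(71, {
    d <- data.frame(x = rnorm(41))
    d$pfs_time <- rexp(41, 0.01 * exp(d$x))
    d$pfs_event <- 1L
  })
  fit <- fitCox(d, "x", endpoint = "pfs")
  sp <- prognosticDichotomize(fit, d)
  expect_lte(abs(sum(sp$group == "low") - sum(sp$group == "high")), 1)
  sp2 <- prognosticDichotomize(fit, d)
  expect_identical(sp$group, sp2$group)
  # scores at the median go to the low group
  sc <- prognosticScore(fit, d)
  expect_true(all(sp$group[sc == median(sc)] == "low"))
})

test_that("the univariable screen honours threshold and always-keep", {
  cfg <- cohortConfig(nTumors = 120, nFeatures = 4, kFeatureClusters = 2,
                      hazardCoefficients = c(ecog = 1.2), seed = 81)
  d <- cohortWithPhenotype(cfg)
  scr <- suppressWarnings(
    univariableScreen(d, c("age", "smoking", "ecog", "n_mutations"),
                      threshold = 0.2, alwaysKeep = "n_mutations"))
  expect_true("ecog" %in% scr$retained)
  expect_true("n_mutations" %in% scr$retained)  # regardless of its p
  all1 <- suppressWarnings(
    univariableScreen(d, c("age", "smoking", "ecog"), threshold = 1,
                      alwaysKeep = character(0)))
  expect_setequal(all1$retained, c("age", "smoking", "ecog"))
})
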