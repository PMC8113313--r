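#' Encode clinical covariates as a numeric design matrix
#'
#' Binary covariates are coded 0/1 (smoking: never = 1 vs former = 0;
#' line of therapy: later = 1 vs first = 0; sex: M = 1; phenotype: 2 vs 1 as
#' 0/1). ECOG grade and ctDNA mutation count stay continuous (per one
#' increment). Numeric columns pass through unchanged.
#'
#' @param data data.frame of clinical columns (optionally with `phenotype`).
#' @param covariates names to encode, in order.
#' @return numeric matrix, records x covariates.
#' @export
encodeCovariates <- function(data, covariates) {
  cols <- lapply(covariates, function(nm) {
    if (!nm %in% names(data)) stop("unknown covariate: ", nm)
    v <- data[[nm]]
    if (is.numeric(v)) return(as.numeric(v))
    switch(nm,
      smoking = as.numeric(v == "never"),
      line_therapy = as.numeric(v == "later"),
      sex = as.numeric(v == "M"),
      phenotype = as.numeric(v == 2 | v == "2"),
      {
        u <- sort(unique(v))
        if (length(u) > 2) stop("cannot encode multi-level covariate: ", nm)
        as.numeric(v == u[length(u)])
      })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with ties at a time processed together. The median
#' is the earliest time at which the curve drops to 0.5 or below, `NA` (not
#' reached) if it never does.
#'
#' @param time positive follow-up times in days.
#' @param event 0/1 event indicators.
#' @return list with `time`, `nRisk`, `nEvent`, `surv` and `median`.
#' @export
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least 1 record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(summary(fit)$table["median"])
  list(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
       surv = fit$surv, median = med)
}

#' Two-group log-rank test
#'
#' @param time,event follow-up times and 0/1 indicators.
#' @param group two-level group labels.
#' @return list with `chisq` (1 df) and `p`.
#' @export
logrankTest <- function(time, event, group) {
  if (length(unique(group)) != 2L) stop("exactly 2 groups required")
  if (sum(event) < 1L) stop("need at least 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ factor(group))
  list(chisq = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood maximization via `survival::coxph` with Efron handling
#' of tied event times (Breslow available for cross-checks). Errors on
#' datasets with no events and on unidentifiable (singular) designs rather
#' than silently regularizing.
#'
#' @param data data.frame holding the endpoint columns and covariates.
#' @param covariates covariate names (encoded by [encodeCovariates()]).
#' @param endpoint endpoint prefix; columns `<endpoint>_time` /
#'   `<endpoint>_event` must exist. Default `"pfs"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a [CoxModel-class].
#' @export
fitCox <- function(data, covariates, endpoint = "pfs", ties = "efron") {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(data)))
    stop("missing endpoint columns ", tcol, "/", ecol)
  time <- data[[tcol]]; event <- data[[ecol]]
  if (sum(event) < 1L) stop("no events: cannot fit a Cox model")
  x <- encodeCovariates(data, covariates)
  for (j in seq_len(ncol(x)))
    if (length(unique(x[, j])) < 2L)
      stop("singular information matrix: covariate '", covariates[j],
           "' is constant")
  df <- data.frame(.time = time, .event = event, x, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(iter.max = 100,
                                                           eps = 1e-10))
  if (any(is.na(stats::coef(fit))))
    stop("singular information matrix: coefficients not estimable")
  methods::new("CoxModel",
               coef = stats::coef(fit), vcov = stats::vcov(fit),
               loglik = fit$loglik[2], loglik0 = fit$loglik[1],
               n = as.integer(fit$n), nevent = as.integer(fit$nevent),
               covariates = covariates, endpoint = endpoint, fit = fit)
}

#' Linear predictor (prognostic score) of a fitted Cox model
#'
#' `x %*% beta-hat` on the model's covariate coding; centering is immaterial
#' for ranking and median splits.
#'
#' @param fit a [CoxModel-class].
#' @param data data.frame with the model's covariates.
#' @return numeric vector of prognostic scores.
#' @export
prognosticScore <- function(fit, data) {
  x <- encodeCovariates(data, fit@covariates)
  drop(x %*% fit@coef)
}

#' Likelihood-ratio test of a Cox model versus the null model
#'
#' @param fit a [CoxModel-class].
#' @return list with `statistic`, `df`, `p`.
#' @export
lrtVsNull <- function(fit) {
  stat <- max(0, 2 * (fit@loglik - fit@loglik0))
  df <- length(fit@coef)
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested Cox models
#'
#' The reduced model's covariates must be a subset of the full model's and
#' both fits must use the same records and endpoint.
#'
#' @param full,reduced [CoxModel-class] fits.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrtNested <- function(full, reduced) {
  if (!all(reduced@covariates %in% full@covariates))
    stop("models are not nested")
  if (full@n != reduced@n || full@endpoint != reduced@endpoint)
    stop("models must be fit on the same records and endpoint")
  stat <- max(0, 2 * (full@loglik - reduced@loglik))
  df <- length(full@coef) - length(reduced@coef)
  if (df < 1L) return(list(statistic = 0, df = 0L, p = 1))
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Uno's IPCW concordance statistic
#'
#' Inverse-probability-of-censoring-weighted concordance restricted to the
#' horizon tau: over ordered pairs (i, j) with `event_i = 1`,
#' `time_i < time_j` and `time_i < tau`, the pair weight is
#' `1 / G(time_i-)^2` with G the Kaplan-Meier estimator of the censoring
#' distribution evaluated just before `time_i` (event-censoring ties treated
#' event-first). Concordant pairs have the higher linear predictor on the
#' earlier event; ties in the predictor count 1/2. Pairs at which G vanishes
#' are excluded with a warning.
#'
#' @param time,event follow-up times and 0/1 indicators.
#' @param lp linear predictors (higher = higher risk).
#' @param tau time horizon; default the longest observed event time.
#' @return list with `c`, `tau`, `numerator`, `denominator`, `nPairs`.
#' @export
unoC <- function(time, event, lp, tau = NULL) {
  if (is.null(tau)) {
    if (sum(event) == 0L) stop("no events: tau undefined")
    tau <- max(time[event == 1])
  }
  if (tau <= 0) stop("tau must be positive")
  # censoring distribution: KM of the flipped indicator
  gfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gminus <- function(t) {
    # left limit: survival just before t
    idx <- which(gfit$time < t - 1e-12)
    if (length(idx) == 0L) return(1)
    gfit$surv[max(idx)]
  }
  num <- 0; den <- 0; nPairs <- 0L; excluded <- 0L
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1L) next
    if (time[i] >= tau + 1e-12) next
    g <- Gminus(time[i])
    comp <- which(time > time[i])
    if (length(comp) == 0L) next
    if (g <= 0) {
      excluded <- excluded + length(comp)
      next
    }
    w <- 1 / g^2
    conc <- sum(lp[i] > lp[comp]) + 0.5 * sum(lp[i] == lp[comp])
    num <- num + w * conc
    den <- den + w * length(comp)
    nPairs <- nPairs + length(comp)
  }
  if (excluded > 0L)
    noteWarning(paste(excluded, "pairs excluded: censoring survival 0"))
  if (den == 0) stop("no usable pairs")
  list(c = num / den, tau = tau, numerator = num, denominator = den,
       nPairs = nPairs)
}

#' Dichotomize by the median prognostic score
#'
#' Splits records at the sample median of the fitted linear predictor (ties
#' go to the low-score group), then compares the two groups by the log-rank
#' test with per-group Kaplan-Meier curves.
#'
#' @param fit a [CoxModel-class].
#' @param data data.frame with the model's covariates and endpoint columns.
#' @return list with `group` ("low"/"high"), `logrank`, `kmLow`, `kmHigh`.
#' @export
prognosticDichotomize <- function(fit, data) {
  score <- prognosticScore(fit, data)
  medScore <- median(score)
  if (all(score == score[1])) stop("degenerate: all prognostic scores equal")
  group <- ifelse(score <= medScore, "low", "high")
  tcol <- paste0(fit@endpoint, "_time"); ecol <- paste0(fit@endpoint, "_event")
  lr <- logrankTest(data[[tcol]], data[[ecol]], group)
  list(group = group, logrank = lr,
       kmLow = kmEstimate(data[[tcol]][group == "low"],
                          data[[ecol]][group == "low"]),
       kmHigh = kmEstimate(data[[tcol]][group == "high"],
                           data[[ecol]][group == "high"]))
}

#' Univariable screen of candidate covariates
#'
#' Fits one univariable Cox model per candidate and retains those whose Wald
#' p-value is at or below the threshold, plus any `alwaysKeep` covariates
#' regardless of their p. Candidates whose fit fails are skipped with a
#' warning.
#'
#' @param data data.frame with endpoint columns and candidates.
#' @param candidates candidate covariate names.
#' @param endpoint endpoint prefix; default `"pfs"`.
#' @param threshold Wald p retention threshold; default 0.2.
#' @param alwaysKeep covariates always retained; default `"n_mutations"`.
#' @return list with `retained` (ordered names) and `pvalues`.
#' @export
univariableScreen <- function(data, candidates, endpoint = "pfs",
                              threshold = 0.2, alwaysKeep = "n_mutations") {
  if (length(candidates) == 0L) stop("no candidates")
  pv <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (nm in candidates) {
    fit <- tryCatch(fitCox(data, nm, endpoint = endpoint),
                    error = function(e) {
                      noteWarning(paste0("screen: skipping '", nm, "' (",
                                         conditionMessage(e), ")"))
                      NULL
                    })
    if (!is.null(fit)) pv[nm] <- hazardRatios(fit)$p[1]
  }
  keep <- candidates[!is.na(pv) & pv <= threshold]
  # candidate order preserved; alwaysKeep retained regardless of p
  ordered <- c(intersect(candidates, union(alwaysKeep, keep)),
               setdiff(alwaysKeep, candidates))
  list(retained = ordered, pvalues = pv)
}

#' Bootstrap percentile confidence interval for Uno's c-statistic
#'
#' Resamples records with replacement, recomputing the linear predictor from
#' a refit of the same model on each resample.
#'
#' @param data data.frame with endpoint columns and covariates.
#' @param covariates model covariates.
#' @param endpoint endpoint prefix.
#' @param nBoot bootstrap resamples; default 1000.
#' @param seed integer seed.
#' @param level confidence level; default 0.95.
#' @return list with `c`, `lower`, `upper`, `tau`.
#' @export
unoCBoot <- function(data, covariates, endpoint = "pfs", nBoot = 1000L,
                     seed = 1L, level = 0.95) {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  fit <- fitCox(data, covariates, endpoint = endpoint)
  lp <- prognosticScore(fit, data)
  tau <- max(data[[tcol]][data[[ecol]] == 1])
  obs <- unoC(data[[tcol]], data[[ecol]], lp, tau = tau)$c
  n <- nrow(data)
  reps <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    bd <- data[idx, , drop = FALSE]
    tryCatch({
      bf <- fitCox(bd, covariates, endpoint = endpoint)
      suppressWarnings(
        unoC(bd[[tcol]], bd[[ecol]], prognosticScore(bf, bd), tau = tau)$c)
    }, error = function(e) NA_real_)
  }, numeric(1)))
  reps <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  list(c = obs,
       lower = unname(quantile(reps, alpha)),
       upper = unname(quantile(reps, 1 - alpha)),
       tau = tau)
}
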