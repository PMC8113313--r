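#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the hypergeometric distribution of the observed
#' margins; the two-sided p-value sums the probabilities of all tables no
#' more probable than the observed one (with a small relative slack against
#' floating-point ties). A table with an empty row or column admits a single
#' table and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Two-sided Fisher's exact test for an r x c table (Freeman-Halton)
#'
#' Exact enumeration over all tables with the observed margins for totals up
#' to `maxN`; beyond that an error advises the seeded Monte-Carlo fallback
#' (`monteCarlo = TRUE`, 1e6 tabled draws).
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param maxN enumeration bound on the total count; default 200.
#' @param monteCarlo use the Monte-Carlo approximation; default FALSE.
#' @param seed seed for the Monte-Carlo draws.
#' @param B Monte-Carlo replicates; default 1e6.
#' @return two-sided p-value.
#' @export
fisherExactRxC <- function(table, maxN = 200L, monteCarlo = FALSE, seed = 1L,
                           B = 1e6) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (nrow(table) == 1L || ncol(table) == 1L) return(1)
  drop0 <- function(m) m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  tab <- drop0(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(1)
  if (monteCarlo)
    return(withSeed(seed,
      stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value))
  if (sum(tab) > maxN)
    stop("total count exceeds the enumeration bound (", maxN,
         "); rerun with monteCarlo = TRUE")
  stats::fisher.test(tab, workspace = 2e7)$p.value
}

#' Mann-Whitney-Wilcoxon rank-sum test, two-sided
#'
#' Exact enumeration when both samples have at most 8 values and no ties;
#' otherwise a normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (for `x`) and `p`.
#' @export
mannWhitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8L && length(y) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Welch's two-sample t-test, two-sided
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return list with `t`, Satterthwaite `df`, and `p`.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per sample")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both samples")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Phenotype-covariate association table
#'
#' Cross-tabulates each categorical covariate against the phenotype labels
#' and tests with Fisher's exact test (2x2 or Freeman-Halton r x c);
#' continuous covariates are compared between the two phenotypes with the
#' Mann-Whitney test (or Welch's t-test where configured). This is the
#' cohort-characteristics block of the analysis report and is also used for
#' acquisition-confounder checks.
#'
#' @param clinical data.frame of covariates.
#' @param phenotype per-record phenotype labels (2 levels for the continuous
#'   tests).
#' @param categorical names of categorical covariates; defaults to the
#'   character/factor columns.
#' @param continuous names of continuous covariates; defaults to the numeric
#'   columns (endpoints excluded).
#' @param welch continuous covariates to test with Welch's t instead of
#'   Mann-Whitney; default `"n_mutations"`.
#' @return data.frame with covariate, test and p.
#' @export
associationTable <- function(clinical, phenotype, categorical = NULL,
                             continuous = NULL, welch = "n_mutations") {
  phenotype <- as.factor(phenotype)
  isNum <- vapply(clinical, is.numeric, logical(1))
  drop <- grepl("_(time|event)$", names(clinical)) |
    names(clinical) %in% c("patient_id", "true_phenotype")
  if (is.null(categorical)) categorical <- names(clinical)[!isNum & !drop]
  if (is.null(continuous)) continuous <- names(clinical)[isNum & !drop]
  rows <- list()
  for (nm in categorical) {
    tab <- table(clinical[[nm]], phenotype)
    p <- if (all(dim(tab) == 2L)) fisherExact2x2(tab) else fisherExactRxC(tab)
    rows[[nm]] <- data.frame(covariate = nm, test = "fisher_exact", p = p)
  }
  lev <- levels(phenotype)
  for (nm in continuous) {
    a <- clinical[[nm]][phenotype == lev[1]]
    b <- clinical[[nm]][phenotype == lev[2]]
    if (nm %in% welch) {
      r <- welchT(a, b)
      rows[[nm]] <- data.frame(covariate = nm, test = "welch_t", p = r$p)
    } else {
      r <- mannWhitney(a, b)
      rows[[nm]] <- data.frame(covariate = nm, test = "mann_whitney", p = r$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Worked-example cross-tabulations from a 40-patient NSCLC cohort
#'
#' Printed phenotype cross-tabulations of an EGFR-mutant advanced NSCLC
#' cohort (40 patients, two radiomic phenotypes), used as worked examples for
#' the exact tests: smoking status, sex and line of therapy as 2x2 tables
#' (rows = covariate level, columns = phenotype 1/2) and the five-level EGFR
#' mutation category as a 5x2 table.
#'
#' @return named list of integer matrices.
#' @export
examplePhenotypeCrosstabs <- function() {
  list(
    line_therapy = matrix(c(8, 15, 13, 4), 2, 2, byrow = TRUE,
                          dimnames = list(c("first", "later"),
                                          c("phenotype1", "phenotype2"))),
    smoking = matrix(c(9, 12, 12, 7), 2, 2, byrow = TRUE,
                     dimnames = list(c("former", "never"),
                                     c("phenotype1", "phenotype2"))),
    sex = matrix(c(16, 13, 5, 6), 2, 2, byrow = TRUE,
                 dimnames = list(c("F", "M"),
                                 c("phenotype1", "phenotype2"))),
    egfr_status = matrix(c(5, 9, 1, 0, 0, 1, 3, 5, 12, 4), 5, 2, byrow = TRUE,
                         dimnames = list(c("exon19del", "exon20ins",
                                           "G719C/S768I", "L858R", "T790M"),
                                         c("phenotype1", "phenotype2"))))
}
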