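# radphen

Unsupervised radiomic phenotyping of tumors from CT feature matrices, with
survival models that quantify what the phenotypes add to clinical and
ctDNA (liquid-biopsy) prognostic variables. The package is aimed at imaging /
biostatistics groups who have a tumors-by-features radiomic matrix (or 3D
image + mask volumes) and right-censored outcomes, and want a reproducible,
seeded version of the two-level clustering + Cox modeling workflow that is
common in small-cohort radiomics studies of EGFR-mutant NSCLC treated with
tyrosine-kinase inhibitors.

## The method

**Two-level consensus clustering.** All features are z-scored. The distance
between features *i* and *j* is `d = 1 - r^2`, with *r* the Pearson
correlation across tumors, so strongly covarying features (either sign) are
close. Features are clustered by complete-linkage ("maximum distance")
hierarchical clustering inside a consensus-clustering loop: for each candidate
*k*, tumors of the feature set are repeatedly subsampled (80%, 500 resamples
by default), each subsample is clustered, and the consensus matrix entry
`M(i, j)` is the fraction of co-clusterings among resamples where both items
were drawn. The number of clusters is chosen by the CDF delta-area rule: with
`A(k)` the area under the empirical CDF of consensus entries, the selected
*k* is the smallest whose relative forward change `(A(k+1) - A(k)) / A(k)`
falls below 10%. Each feature cluster is then reduced to its first principal
component — the cluster's *signature*. The same consensus procedure applied to
tumors on their signature rows yields the radiomic phenotypes, and a SigClust
Monte-Carlo test (cluster index vs. a single-Gaussian null with
eigenvalue-floored diagonal covariance) asks whether two clusters beat one.

**Survival modeling.** Per endpoint (PFS, OS): Kaplan–Meier curves and
log-rank tests; univariable Cox models screening covariates at p ≤ 0.2
(mutation count always retained); multivariable Cox models with and without
phenotype compared by likelihood-ratio test; discrimination measured by Uno's
IPCW concordance `c = Σ w_ij 1(lp_i > lp_j) / Σ w_ij` over ordered event
pairs with weights `w = G(t_i-)^{-2}` from the censoring Kaplan–Meier, with
horizon τ = the longest event time; and a Kaplan–Meier split at the median
prognostic score `x'β̂`.

**Synthetic cohorts.** `simulateCohort()` generates a cohort with planted
ground truth — latent-factor feature clusters (`sqrt(ρ)·factor +
sqrt(1-ρ)·noise`), a mean shift between phenotypes on half the feature
clusters, clinical marginals matching a published 40-patient EGFR-mutant NSCLC
cohort, and exponential event/censoring times — so every stage has a
parameter-recovery test. A 3D phantom generator plus a documented radiomic
feature extractor (first-order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM,
Laplacian-of-Gaussian and Haar-wavelet families over NIfTI volumes) covers
the image-to-matrix path.

## Worked example

```r
library(radphen)
cfg <- cohortConfig(nTumors = 40, nFeatures = 120, kFeatureClusters = 8,
                    phenotypeShift = 3, seed = 7)
cohort <- simulateCohort(cfg)

z    <- zscoreFeatures(featureMatrix(cohort))
cons <- consensusCluster(correlationDistance(z), kRange = 2:10,
                         nResamples = 200, seed = 7)
cons
#> ConsensusResult over k = 2..10 on 120 items; selected k = 3
#>   A(k): 0.424 0.607 0.665 0.696 0.820 0.836 0.868 0.890 0.895

sigs  <- deriveSignatures(z, hierarchicalCut(1 - consensusMatrix(cons),
                                             selectedK(cons)))
pheno <- assignPhenotypes(sigs, kRange = 2:6, nResamples = 200, seed = 7)
pheno
#> PhenotypeCall: 40 tumors in 2 phenotypes ( 21/19 )
#>   SigClust p (2 vs 1 clusters): 0.000999

d   <- cbind(clinicalData(cohort), phenotype = phenotypeLabels(pheno))
fit <- fitCox(d, c("phenotype", "ecog", "n_mutations"), endpoint = "pfs")
fit
#> CoxModel [pfs]: 26 events / 40 records
#>     covariate       coef       hr    lower    upper        se          p
#> 1   phenotype 0.15323649 1.165601 0.493197 2.754730 0.4388260 0.72694179
#> 2        ecog 0.06867791 1.071091 0.530245 2.163597 0.3587281 0.84817431
#> 3 n_mutations 0.29143781 1.338350 0.955262 1.875069 0.1720478 0.09027756

unoC(d$pfs_time, d$pfs_event, prognosticScore(fit, d))$c
#> [1] 0.5953981
```

Reading the output: feature-level consensus settled on 3 derived signatures;
tumor-level clustering split the 40 tumors 21/19 with a significant SigClust
test (the two phenotypes are real structure, not a forced cut); the Cox table
gives per-covariate hazard ratios with Wald intervals, and the c-statistic
0.60 is this model's censoring-adjusted probability of ranking an
earlier-progressing patient as higher risk. The printed cross-tabulations of
the reference cohort are bundled for the exact tests, e.g.
`fisherExact2x2(examplePhenotypeCrosstabs()$line_therapy)` returns 0.0123.

`runAnalysis(runConfig(...))` chains all of the above (simulation or CSV
inputs through phenotyping, association tests, screened Cox models, LRTs,
c-statistics, median-score split) into one seeded, logged JSON report;
`inst/scripts/radphen.R` is a thin command-line wrapper with `simulate`,
`run` and `report` subcommands.

## Limitations

The CDF delta-area criterion is known to overshoot the number of clusters
when the true number is very small, and the hard-threshold SigClust null is
conservative; both behaviors are characterized in the methods vignette
(`vignettes/radiomic-phenotyping.Rmd`), along with every tunable default.
Exact numerical parity with any specific 429-feature CT extraction pipeline
is out of scope.
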