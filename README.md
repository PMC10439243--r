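# realcsf

Detection of central nervous system cancers from shallow
repetitive-element amplicon sequencing of cerebrospinal-fluid (CSF) DNA.

Most CNS cancers — glioblastoma, brain metastases, medulloblastoma, and a
majority of CNS lymphomas — are aneuploid: they gain or lose whole
chromosome arms and often focally amplify oncogenes. A single-primer-pair
assay amplifying short interspersed nuclear elements genome-wide turns
picogram quantities of CSF DNA into a genome-wide read-count profile in
which those copy-number changes are visible as depth shifts, diluted by the
tumor fraction of the sample. `realcsf` implements the analytic pipeline for
such profiles, for laboratories running repetitive-element copy-number
assays on CSF (or plasma) and for methodologists studying arm-level
aneuploidy statistics on count data.

## The method

For a test sample binned onto 500-kb autosomal intervals and normalized
against a euploid reference panel (depth normalization, then subtraction of
the panel's top PCA components, then per-interval standardization), each of
the 39 non-acrocentric chromosome arms is segmented by circular binary
segmentation, germline CNVs and outlier intervals are masked, and the arm is
summarized by the Stouffer statistic over its m retained intervals:

    Z_w = sum(z_i) / sqrt(m)          gain: Z_w > 7.5,  loss: Z_w < -7.5

The 39 Z_w features feed a radial-kernel SVM that outputs the **Global
Aneuploidy Score** (GAS), a calibrated probability of aneuploidy; a sample
is GAS-positive at GAS >= 0.25. In parallel, four oncogene windows (MDM4,
EGFR, CDK4, ERBB2) are scored against panel expectation under a Poisson
model:

    Z_gene = (Observed_gene - lambda_gene) / sqrt(lambda_gene),
    lambda_gene = mu_gene x Coverage

and a window is amplification-positive at Z_gene >= 7.5 (one-sided). The
composite call is a Boolean OR: a sample is positive if the GAS or any
focal window is positive. Cohort sensitivity/specificity are reported with
Wilson 95% confidence intervals.

A synthetic-sample simulator (log-normal amplicon propensities, copy-ratio
dilution `1 + tf (cn - 2) / 2`, Poisson or negative-binomial counts)
generates panels, test samples and the classifier training curriculum with
known truth, so the entire pipeline runs and is tested without patient data.
See `vignettes/realcsf-methods.Rmd` for the full model description and
design rationale.

## Worked example

A glioblastoma-like sample — gains of 7p and 7q, losses of 10p and 10q at
tumor fraction 0.2, with a 10-copy EGFR amplification — scored against a
simulated assay:

```r
library(realcsf)
layout <- hg19Layout()
grid <- buildIntervalGrid(layout)
grid
#> IntervalGrid: 5754 intervals of width 5e+05 bp on 22 chromosomes
#>   arm-assigned: 5458 | excluded: 296

# a simulated assay: shared amplicon propensities + euploid reference panel
prop <- simulatePropensities(grid, efficiencySd = 0.5, seed = 101)
panel <- simulateReferencePanel(grid, prop, nSamples = 20, depth = 1e6,
                                seed = subSeed(101, 1))
panel
#> ReferencePanel ( csf ) from 20 euploid samples; 5754 intervals; k = 5 components
#>   focal windows: MDM4, EGFR, CDK4, ERBB2

# the shipped fixed-seed classifier (trains once per session, ~1-2 min)
model <- defaultGASModel(17)

sim <- simulateSample(grid, prop, depth = 1e6, tumorFraction = 0.2,
                      armEvents = data.frame(arm = c("7p", "7q", "10p", "10q"),
                                             cn = c(3, 3, 1, 1)),
                      focalEvents = list(list(window = panel@windows[["EGFR"]],
                                              cn = 10)),
                      seed = 2024, sampleId = "GBM_like")
call <- scoreSample(sim$vector, panel, model, seed = 7)
call
#> RealCSFCall GBM_like: POSITIVE (evidence: both); GAS = 0.9859

subset(armScoreTable(call@arms), call != "neutral")
#>    arm        zw   m call borderline flagged
#> 13  7p  19.26931 116 gain      FALSE   FALSE
#> 14  7q  18.97621 195 gain      FALSE   FALSE
#> 19 10p -11.72208  77 loss      FALSE   FALSE
#> 20 10q -16.91738 185 loss      FALSE   FALSE

subset(focalScoreTable(call), positive)
#>   gene observed   lambda        z scorable positive
#> 2 EGFR      882 513.1087 16.28522     TRUE     TRUE
```

Reading the output: all four injected arm events are recovered far beyond
the |Z_w| > 7.5 call threshold; the EGFR window holds 882 reads against an
expected 513 (Z = 16.3, amplification-positive); the GAS of 0.986 and the
focal call together give a composite positive with evidence `both`.
A euploid sample through the same pipeline yields no arm calls, a GAS well
below 0.25, and a negative composite call.

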