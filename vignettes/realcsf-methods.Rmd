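---
title: "Methods: aneuploidy and focal amplification calling in realcsf"
author: "realcsf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aneuploidy and focal amplification calling in realcsf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the data model

Most central nervous system cancers are aneuploid: they gain or lose whole
chromosome arms, and many additionally amplify oncogenes focally. A
repetitive-element amplicon assay (one primer pair amplifying hundreds of
thousands of short interspersed nuclear elements genome-wide) turns a small
amount of cerebrospinal-fluid DNA into a genome-wide read-count profile in
which those copy-number changes are visible as coordinated depth shifts —
diluted toward the diploid baseline by the fraction of tumor-derived DNA in
the fluid.

`realcsf` implements the full analytic pipeline on such count profiles:

1. aggregate counts onto a fixed-width autosomal interval grid;
2. normalize against a euploid reference panel (depth + PCA denoising);
3. segment each chromosome arm (CBS), mask germline CNVs and outliers;
4. summarize each arm as a Stouffer statistic $Z_w$ and call gains/losses;
5. convert the 39 arm scores into a Global Aneuploidy Score (GAS) with a
   radial-kernel SVM;
6. score focal oncogene windows with a Poisson $Z$ test;
7. combine GAS and focal calls through a Boolean OR gate.

A synthetic-sample simulator with known truth makes every stage testable
without patient data.

# Coordinate model and interval grid

All internal coordinates are 0-based half-open (BED convention). The bundled
hg19 layout carries the 22 autosomes with UCSC gap-track centromere
coordinates; sex chromosomes are out of scope because only autosomes are
scored. Each autosome is tiled from position 0 in 500-kb bins; the trailing
partial bin is dropped so all bins share the same expected variance (a partial
bin would have systematically lower counts and higher relative noise). Bins
overlapping the centromere gap stay in the grid (they still inform
normalization) but are excluded from arm assignment, as are bins on the p arms
of the five acrocentric chromosomes (13, 14, 15, 21, 22), whose short arms are
satellite DNA without scorable unique sequence. That leaves 39 scored arms for
a standard human autosome layout.

The bundled grid has 5,754 intervals. Published pipelines of this kind quote
interval counts a few percent lower because they additionally drop intervals
with no usable amplicons; the grid here is treated as layout-derived and
configurable rather than as a fixed constant, and no amplicon-presence filter
is applied (the simulator has no missing amplicons to filter).

The four bundled focal windows are complete window coordinates (gene plus
surrounding context, rounded to 100-kb boundaries): MDM4 at 1q32.1 (1.5 Mb),
EGFR at 7p11.2 (1.5 Mb), CDK4 at 12q14.1 (3.5 Mb) and ERBB2/HER2 at 17q12
(2.5 Mb). User-supplied genes get the generic rule instead: gene span plus a
1-Mb flank on each side, clipped to the chromosome.

# Reference panel and normalization

Counts are first depth-normalized to proportions (each interval divided by
total autosomal coverage), which removes library-size differences and makes
the pipeline invariant to global coverage scaling.

A euploid reference panel (default: 20 samples, minimum 10) supplies, per
interval, the mean proportion $\mu_i$, a PCA basis of the top $k$ components
of the centered panel matrix, and the residual standard deviation $\sigma_i$
after removing those components (computed with $n - 1 - k$ degrees of
freedom). A test sample is normalized by centering on $\mu$, subtracting its
projection onto the panel components, and dividing by $\sigma_i$, giving
standardized residuals $z_i$ that are approximately standard normal for
euploid samples.

Design choices here:

- **$k = 5$ components** by default. The PCA step exists to absorb correlated
  technical structure shared across samples of one assay; small panels
  (15–20 samples) cannot support many components, and with 5 of ~19 degrees
  of freedom removed the residual SD remains well estimated.
- **$\sigma$ floor at the 5th percentile** of all interval SDs. Quiet
  intervals with near-zero estimated variance would otherwise turn small
  absolute residuals into huge $z$ values. A panel whose residual variance is
  (near-)zero everywhere — e.g. identical replicate inputs — is rejected
  outright.
- **CSF vs plasma is a panel attribute only.** The pipeline is identical; the
  panel records its provenance (`kind`), and swapping panels is how the
  plasma variant of the assay is analyzed.
- Panels serialize to versioned JSON with 17-significant-digit numerics, so
  they are diffable, portable, and round-trip bit-identically.

No GC-content or mappability correction is applied: amplicon efficiency
heterogeneity is a per-interval multiplicative effect absorbed by $\mu_i$,
and residual correlated structure is the PCA step's job.

# Segmentation, masking, and the arm statistic

Each scored arm's $z_i$ vector is segmented by circular binary segmentation
in its recursive max-$|t|$ binary-splitting form: the candidate split
maximizes the standardized mean difference between the two sides (using the
segment-wide SD), and a split is accepted when its permutation $p$-value
falls below $\alpha = 0.01$ (1,000 permutations, minimum segment width 3
intervals). Permutations for every recursion node are drawn from a seed
derived deterministically from the (sample, arm, node) coordinates, so
results are exactly reproducible and independent across nodes; permutations
whose maximum statistic ties the observed one (equal left/right multisets)
count as exceedances under a small numeric tolerance so the decision does not
depend on floating-point evaluation order. The permutation loop stops early
once the exceedance count can no longer reach significance, which leaves the
accept/reject decision identical to the full run.

Two masking rules then exclude intervals that carry copy-number signal not
attributable to tumor aneuploidy:

- **Germline rule**: segments narrower than 6 intervals (< 3 Mb at 500-kb
  bins) with $|\text{mean } z| > 4$ are masked entirely — the signature of an
  inherited copy-number variant, far too short to be an arm-level tumor
  event. Whole-arm shifts are wider than the cap and can never be masked by
  this rule.
- **Outlier rule**: within every other segment, intervals deviating from the
  segment mean by more than 4 times the segment MAD are masked.

The two rules are complementary: events of 1–2 intervals cannot form their
own segment (minimum width 3) and are caught by the outlier rule, while a
short high segment that CBS does isolate has near-zero within-segment
deviations and is caught by the germline rule. All four constants are
configurable arguments.

The arm-level statistic is the Stouffer combination over the $m$ retained
intervals:

$$Z_w = \frac{\sum_{i \in \text{retained}} z_i}{\sqrt{m}}$$

Under the euploid null, $Z_w$ is approximately standard normal — that
calibration is the contract the null-simulation tests enforce. Arms are
called **gain** at $Z_w > 7.5$ and **loss** at $Z_w < -7.5$; arms with
$5 < |Z_w| \le 7.5$ are flagged borderline (evidence just below positivity).
Arms with fewer than 10 retained intervals are flagged and contribute a
neutral 0 to the classifier features rather than dropping the sample.

$Z_w$ is computed on raw retained intervals, not on segment means: the
Stouffer form keeps the null calibration exact under the independence of
interval noise, whereas averaging correlated segment means would require an
effective-sample-size correction the data do not support at panel sizes of
15–20.

# The Global Aneuploidy Score

The 39 $Z_w$ values (fixed arm order, undefined arms imputed to 0, clipped to
$\pm 50$ so extreme aneuploidy saturates rather than destabilizes kernel
distances) feed a radial-basis-kernel SVM with the canonical default
hyperparameters (cost 1, $\gamma = 1/39$) and cross-validated Platt
probability calibration. The GAS is the calibrated probability of the
aneuploid class; a sample is GAS-positive at $\ge 0.25$, the operating
threshold of the assay.

The original clinical training cohort is controlled-access, so the package
ships a training *recipe* rather than trained weights: a fixed-seed synthetic
curriculum (`defaultGASModel(seed = 17)`, 100 euploid + 100 aneuploid
samples on the bundled hg19 grid at depth $10^6$), memoised per session.
Two design decisions here deserve explanation:

- **The positive class consists of samples that manifest aneuploidy.**
  Aneuploid draws carry 1–20 random arm events (copy numbers 0, 1, 3, 4) at
  tumor fractions log-uniform in $[0.01, 0.5]$, but a draw whose feature
  vector shows no called arm event (no arm at $|Z_w| > 7.5$, the arm-call
  threshold) is redrawn deterministically. This mirrors how such classifiers
  are trained in practice — on confirmed aneuploid samples, not on dilutions
  below the limit of detection. It is also what gives the calibrated
  probability its specificity: with sub-detection dilutions labeled
  "aneuploid", a correctly calibrated probability for a euploid-looking
  profile converges to the local class fraction (~0.2) rather than to a
  small value, and no threshold near 0.25 can then separate the classes.
- **Features stay on their native Z scale** (no per-column rescaling before
  the kernel). $Z_w$ is already standardized — unit variance under the
  euploid null. Rescaling each column by the class-mixture SD, which is
  dominated by arbitrary aneuploid tail magnitudes, shrinks the euploid
  cluster to a fraction of the kernel length scale; the decision surface is
  then nearly linear across the cluster and, because gains and losses cancel
  in the linear term, develops local non-monotonicities at sub-detection
  doses. On the native scale the kernel resolves the two-sided structure of
  the features and the score responds monotonically to tumor fraction.

The score's dose-response is assessed with matched noise draws (common
per-sample seeds across tumor-fraction levels), a standard variance-reduction
design for monotonicity comparisons.

Whether the original assay's score is a raw SVM margin or a calibrated
probability is not documented; the 0.25 operating threshold strongly
suggests a probability scale, which is adopted here. Models serialize to
full-precision JSON and prediction is a pure function of the serialized
numbers (support vectors, dual coefficients, kernel width, Platt
coefficients), so a written-and-reread model reproduces scores exactly.

# Focal amplification scoring

For each registered window, the observed read count over the window's member
intervals is compared with its panel expectation
$\lambda_{\text{gene}} = \mu_{\text{gene}} \times \text{Coverage}$, where
$\mu_{\text{gene}}$ is the panel-mean fraction of reads in the window and
Coverage the sample's total autosomal depth, under a Poisson model:

$$Z_{\text{gene}} = \frac{\text{Observed}_{\text{gene}} -
  \lambda_{\text{gene}}}{\sqrt{\lambda_{\text{gene}}}}$$

Calling is one-sided: only amplifications ($Z \ge$ threshold) gate
positivity; focal deletions appear in the report as negative $Z$ but never
trigger a call. The default threshold is 7.5, mirroring the arm-level
convention — the per-gene thresholds of the original assay were tuned on its
training cohort and are not public, so this is a declared package default and
a configuration key, not a reproduction. Arm-level aneuploidy overlapping a
window is deliberately not subtracted: $Z_{\text{gene}}$ measures total local
excess. A window with $\lambda = 0$ (zero panel coverage or zero sample
coverage) is reported not-scorable rather than given an infinite score.

# Composite call and cohort summaries

A sample is positive if it is GAS-positive **or** any focal window is
positive (Boolean OR), with evidence attribution (`gas`, `focal`, `both`,
`none`). Every call record echoes the thresholds used, so a call is
self-describing. Cohort sensitivity and specificity are reported with Wilson
score 95% confidence intervals (the appropriate binomial interval at the
small cohort sizes typical of CSF studies; it is never empty and never
crosses 0 or 1).

# The simulator: what it emulates, and what it does not

The simulator is the package's study-condition generator, not a test fixture:
its defaults are the conditions under which the pipeline's properties are
asserted.

- **Amplicon efficiency heterogeneity**: per-interval log-normal propensities
  (log-SD 0.5, giving a realistic several-fold spread in per-interval
  depth), normalized to sum to 1 and fixed per simulated "assay" — panel and
  test samples of one experiment share them, exactly as a real assay's
  amplicon biases are shared between panel and test libraries.
- **Copy-number dilution**: an event at copy number $c$ in tumor fraction
  $f$ scales an interval's expected weight by $1 + f(c - 2)/2$ against the
  diploid background — the standard cell-free DNA mixture algebra. Weights
  are renormalized (sequencing observes proportions, so a large gain
  slightly depletes everything else — a real compositional effect the
  pipeline must tolerate).
- **Counting noise**: Poisson by default; negative binomial over-dispersion
  is available to stress-test robustness but defaults to 0 so the focal
  Poisson calibration is exact by construction.
- **Default depth $10^6$** total reads and **panel size 20**: depth of the
  same order as the per-sample unique-read yield of the real assay after
  replicate merging (scaled down ~10x to keep simulations fast), and a panel
  size comparable to the 15 non-cancer CSF samples a laboratory would
  realistically accumulate.

Not emulated: GC/mappability structure beyond static propensities, batch
effects between panel and test samples, fragment-length biology, PCR
replicate structure, sequencing error, subclonal heterogeneity, and the real
germline CNV spectrum (germline events are injected explicitly in tests
rather than drawn from a population model). Passing tests therefore
demonstrate the pipeline's statistical calibration and recovery properties
under its own noise model — they do not certify clinical performance on
patient data, which the original study established on its cohorts.

# Numerical choices and problem sizes

- Split statistic ties in the permutation test are counted as exceedances
  under a $10^{-9}$ absolute tolerance.
- Residual orthogonality of PCA normalization is exact to $10^{-8}$.
- Serialization uses 17 significant digits (exact double round trip).
- The null-calibration suite runs 1,000 simulated euploid hg19-scale samples
  (zero arm calls expected at $|Z_w| > 7.5$; 39,000 arm draws), the dose
  response 50 samples per tumor-fraction level, and the curriculum 100 + 100
  samples — sizes chosen to give the binomial margins the assertions need
  while keeping a full run on one CPU within minutes.
- Arms shorter than the minimum segment width return a single flagged
  segment; arms with fewer than 10 retained intervals contribute feature 0.

# Known limitations

- Sensitivity at tumor fractions below ~2% at depth $10^6$ is intrinsically
  limited (a whole-arm gain at $f = 0.01$ shifts $Z_w$ by well under one
  null SD); the assay's detection limit scales with $\sqrt{\text{depth}}$.
- The binary-splitting CBS variant is weak at isolating short interior
  segments against permutation nulls that contain the same extreme values;
  the masking rules are designed so such events are still excluded from
  $Z_w$.
- The shipped classifier is a synthetic-curriculum stand-in with the same
  feature contract as the original; its scores are calibrated against the
  simulator's noise model, not against clinical cohorts.
- One reference panel serves all samples of an assay; cross-site batch
  harmonization is out of scope.
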