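---
title: "Methods: whole-blood miRNA preprocessing, moderated differential expression, and cell-specific deconvolution"
author: "bloodmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`bloodmiR` analyses multiplexed digital miRNA counts measured in whole
blood, where every profile is a mixture over leukocyte populations. It
covers four stages: (i) the nCounter-style preprocessing ladder from raw
counts to a log2 expression matrix, (ii) per-miRNA two-group differential
expression with empirical-Bayes variance moderation and BH FDR control,
(iii) cell-type-specific expression deconvolution with a pooled-SE contrast
statistic referenced to a permutation null, and (iv) an RT-qPCR delta-Ct
validation arm. A synthetic-cohort generator with known cell-specific
ground truth makes every stage testable end to end.

# The mixture model and the deconvolution statistic

Whole-blood expression of one miRNA in sample $s$ of group $g$ is modelled
as a fraction-weighted mixture over $K$ cell populations:

$$y_{g} = \beta_{1g} x_{1g} + \cdots + \beta_{Kg} x_{Kg} + \varepsilon_g,$$

with **no intercept**: zero cell frequency implies zero expression, so
$\beta_{kg}$ is the mean expression attributable to cell type $k$ in group
$g$ (per unit fraction; divide by 100 to read it per percentage point —
the rescaling cancels in every test statistic). `fitCellRegression()`
solves the normal equations through a Cholesky factorisation of
$X^\top X$; standard errors use the residual variance on $n_g - K$ degrees
of freedom.

Between two groups, the per-cell-type contrast is

$$t_{k21} = \frac{\hat\beta_{k2} - \hat\beta_{k1}}{se(\hat\beta_{k21})},
\qquad
se(\hat\beta_{k21}) = \sqrt{\frac{n_1\,se(\hat\beta_{k1})^2 +
  n_2\,se(\hat\beta_{k2})^2}{n_1 + n_2}},$$

a Wald-like statistic with a sample-size-weighted pooled standard error.
Because this pooled SE is *not* the standard deviation of the coefficient
difference, the statistic is not referenced to a t distribution but to an
empirical null built by reshuffling the group labels (`permutationTest()`,
default $B = 1000$). Each sample's (expression, fractions) pair travels
intact through the reshuffle — the only reading under which the statistic
is exchangeable under the null. The two-sided empirical p-value uses the
add-one convention $p = (1 + \#\{|t^{(b)}| \ge |t_{obs}|\})/(B+1)$, so the
smallest attainable p is $1/(B+1)$; sidedness is a package choice (the
Wald analogy suggests two-sided). The statistic is exactly antisymmetric
under group exchange, and permutations yielding a rank-deficient group
design are redrawn.

With the default two populations, granulocytes (neutrophils + eosinophils
+ basophils) and PBMCs (lymphocytes + monocytes), the fraction columns sum
to one, so the design is strongly collinear: identifiability of the
per-cell coefficients comes entirely from the between-sample spread of the
fractions. Grouped fraction rows are renormalised to sum to one because
printed leukocyte differentials need not close to 100% (the bundled
healthy-control means close to 98.2%).

## Statistical power at small-cohort scale

The package's own harnesses (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) show two things. First, the permutation null is
well calibrated: at $n = 7$ vs $7$, $K = 2$, $B = 1000$, the rejection
rate at $p \le 0.05$ over 200 null replicates sits inside the binomial
95% interval around 0.05. Second, power at small-cohort scale is low for
coefficient effects of a few residual sds: with 4 healthy controls versus
7 pre-challenge samples and a PBMC-only coefficient shift of 4
$\sigma_\varepsilon$, the harness detects the PBMC effect in roughly
5–10% of replicates, with granulocyte specificity near 95%. The driver is
the near-collinear two-column design combined with group SEs estimated on
only $n_g - K$ degrees of freedom, which gives the permutation null heavy
tails. Detection becomes reliable only for effects an order of magnitude
larger or for much wider fraction spread. Consequently a non-significant
cell-specific contrast at this scale is weak evidence of absence, and a
significant one in real data reflects a favourable fraction geometry as
much as the effect size.

# Preprocessing ladder

`runPreprocess()` applies, in order:

1. **Probe background correction** — user-supplied per-probe corrections
   (platform-lot-specific, default empty); corrected counts below zero are
   set to 1.
2. **Positive-control normalisation** — each sample is scaled by
   (mean positive-control sum across samples)/(its own sum). Any fixed
   scaling target would give identical downstream statistics; the
   cross-sample mean is used for interpretability.
3. **Negative-control thresholding and detection** — per sample,
   $T_s = \text{mean}(neg_s) + 2\,\text{sd}(neg_s)$ (sd with the $n-1$
   denominator) is subtracted from every endogenous count; the *detected
   set* is the probes non-negative in **every** sample, and all others are
   dropped. The subtracted counts are kept (the threshold-for-
   detection-only reading is available via `subtract = FALSE`).
4. **Content normalisation** — each sample is scaled so its detected-set
   total equals the cross-sample mean total; control probes never enter
   the scaling sum.
5. **Minimum-count filter** — probes whose *minimum* normalised count is
   at or above 100 are retained ("at least" is read as the minimum across
   samples; a mean convention is selectable).
6. **log2** — counts floored at 1 before log2, consistent with the
   set-to-1 convention in the correction step (rather than a $+1$ offset).

Both normalisations are idempotent, and rescaling one sample's raw counts
only shifts the final log2 matrix by a common constant (the scaling
target is a cross-sample mean), which cancels in every downstream
statistic. The `QCReport` tracks probe attrition per step plus the
per-sample scale factors and detection thresholds.

# Moderated differential expression

Contrasts are fitted as **independent two-group models** (healthy control
vs pre-challenge; pre vs post), deliberately ignoring the pre/post
pairing; this matches the unpaired design of the deconvolution statistic
and is the documented package default. Per probe, the default fit is
robust IRLS with Huber weights (tuning constant 1.345, at most 50
iterations, tolerance 1e-8, via `MASS::rlm`); probes where the robust fit
is undefined (e.g. constant expression) fall back to ordinary least
squares with a warning.

Residual variances are shrunk toward an ensemble prior estimated by
moment matching on $\log s^2$ with digamma/trigamma inversion (Newton
iteration on the trigamma equation). When the equation has no positive
solution, the prior degrees of freedom are infinite and every posterior
variance equals the arithmetic mean of the sample variances. The
moderated t uses

$$\tilde s^2 = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d},$$

with p-values on $\min(d + d_0, \sum_j d_j)$ degrees of freedom — the cap
expresses that shrinkage cannot carry more information than the pooled
ensemble. `priorDf = 0` recovers the ordinary t exactly and
`priorDf = Inf` pools completely; the moderated t interpolates
monotonically between these in $d_0$. Significance uses Benjamini–
Hochberg q-values (via `stats::p.adjust`) at a default FDR of 1%.

# RT-qPCR delta-Ct arm

Technical replicates are averaged per (sample, assay); a collapsed mean
Ct above 35 cycles is censored as below detection (censoring applies to
the measurement, not to individual wells). For uncensored samples,
$\Delta Ct = Ct_{target} - \text{mean}(Ct_{RNU44}, Ct_{RNU6B})$ and
relative expression is $2^{-\Delta Ct}$; "the mean of Ct values" is read
as the per-sample mean of the two reference assays (a global-mean reading
would not normalise per sample). Samples with a censored reference are
excluded with a message. The regression arm feeds $2^{-\Delta Ct}$ (or
$\Delta Ct$ by flag) into the same cell-regression and permutation
machinery.

# Cohort summaries

The demographics module reproduces the derived quantities of the worked
example: the allergen-induced shift is pre-PC20/post-PC20 (displayed at 2
significant figures, raw values retained); PC20 group summaries are
geometric means (this is the convention that reproduces both printed
summary values from the per-subject entries); and mean ± SE uses the
population (n-denominator) standard deviation by default, which again is
the convention that reproduces the printed summaries (the $n-1$
alternative is selectable). Group comparisons use one-way ANOVA, which
for two groups equals the equal-variance t-test.

# The synthetic-cohort generator

The generator emulates a small allergen-challenge study: 4 unpaired
healthy controls and 7 asthmatic subjects each contributing a paired pre-
and post-challenge sample; a codeset of 734 endogenous probes, 6 positive
spike-in controls on a geometric 0.125–128 fM ladder (4-fold spacing —
only the endpoints are anchored, the spacing is a configurable choice),
8 negative controls, and 5 housekeeping mRNAs.

* **Cell fractions** are Dirichlet per group. Mean proportions come from
  the bundled leukocyte differentials collapsed to granulocytes/PBMC
  (healthy controls 0.653/0.347; pre 0.631/0.369; post 0.687/0.313). The
  total concentration of 20 reproduces the between-subject spread implied
  by the printed standard errors (cell-fraction sd around 10 percentage
  points).
* **Counts** are negative binomial around the mixture expectation
  $lib_s \sum_k f_{sk}\,cellMeans_{pkg}$ with a single global dispersion
  (default 0.1, a typical digital-count overdispersion; 0 gives Poisson).
  Library-size factors are log-normal (sd 0.15), positive controls scale
  at 240 expected counts/fM, negative controls are rounded zero-floored
  normal draws (mean 10, sd 4).
* **True cell means** default to a global null: per-probe log-normal base
  (median 30 counts, log-sd 1.8, so that a minority of probes pass
  detection and fewer still the 100-count filter — the steep attrition
  typical of whole-blood miRNA codesets) modulated per cell type
  (log-sd 0.5). `spikeCellMeans()` injects known group or cell-specific
  effects.
* **Ct tables**: per-sample abundance is the biological mixture *without*
  the library-size factor (library size emulates counting-assay
  efficiency, which does not alter re-measured RNA); each well's Ct is
  `38 - log2(abundance)` plus normal noise (sd 0.15 cycles), so abundance
  below 8 falls past the 35-cycle censoring limit. The default
  validation-arm effect is a 4-fold PBMC reduction in asthmatics,
  representing the strong, technically-validatable signal the arm exists
  to confirm.

What the generator does **not** emulate: probe cross-hybridisation,
ligation chemistry, probe-specific efficiency, sequence content,
correlated multi-miRNA structure, or subject-level pairing of expression
beyond shared group means. Passing tests therefore demonstrate
correctness of the computations under a clean mixture model, not
robustness to those real-data artefacts. All generator distributions are
synthetic stand-ins (flagged as such in the emitted manifest); no public
raw data exists for this assay, so the cohort scale and attrition are
anchored to the printed study design rather than fitted to data.

# Numerical and reproducibility choices

* Normal equations are solved by Cholesky; rank deficiency raises an
  error suggesting cell-type merging.
* The contrast statistic treats a pooled SE below
  $10^{-12}(1 + \max|\beta|)$ as a degenerate exact fit: equal
  coefficients give $t = 0$, unequal ones signed infinity with a warning.
* Trigamma inversion runs Newton to a relative tolerance of $10^{-10}$.
* Every stochastic function takes an integer seed; derived streams use
  fixed offsets, and emitted CSVs are written in a canonical numeric
  format so a fixed seed fixes every artifact byte-for-byte.
* Simulation harness sizes (200 replicates for null calibration, 50 for
  power and validation-arm checks, $B = 1000$ permutations, 50 runs of
  1000 probes for FDR calibration) are the package's chosen trade-off
  between Monte-Carlo error and runtime.

# Known limitations

* The cell-specific contrast has very low power at small-cohort scale for
  modest effects (see above); a mixed-effects or paired extension is out
  of scope, as is SAM-style ensemble FDR across probes.
* The robust-regression flavour behind "moderated robust regression" is
  a documented stand-in (Huber IRLS); other psi functions are not
  exposed.
* Only CSV and a minimal sectioned text dialect are parsed; binary RCC
  archives and vendor project files are out of scope.
* No amplification-efficiency correction or standard curves in the qPCR
  arm.
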