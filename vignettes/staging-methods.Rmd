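---
title: "Staging Alzheimer's disease with stepwise regression and linear discriminant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging Alzheimer's disease with stepwise regression and linear discriminant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Alzheimer's disease (AD) progresses through recognizable stages: cognitively
normal (CN), early and late mild cognitive impairment (EMCI, LMCI), and
manifest AD. `adstager` implements a pairwise staging pipeline that, for each
of the six pairs of stages, (i) extracts a compact set of discriminating
features from a candidate pool of 120 variables — 3 demographic (age, gender,
education), 2 neuropsychological scores (MMSE, RAVLT) and 115 regional brain
volumes expressed as fractions of total intracranial volume (TIV) — and
(ii) classifies subjects with a two-class linear discriminant model evaluated
by repeated 2-fold cross-validation.

CDRSb, when present, is loaded as metadata but never used as a feature: it is
part of the diagnostic index itself, so using it as a predictor would leak
the label.

# Feature extraction: stepwise regression with R² increments

For a diagnostic pair, the response is the 0/1 group indicator (1 = more
severe stage) and the model is plain least squares,

$$ y = C_0 + C_1 F_1 + \dots + C_m F_m, $$

deliberately linear on the binary response — no logistic link. Selection is
greedy with fixed R² increment rules:

* **initialization** — the single feature with the highest R² enters
  unconditionally;
* **add** — the excluded feature with the largest R² gain enters iff the
  gain exceeds `add_threshold = 0.1`;
* **remove** — the included feature whose removal costs the least R²
  leaves iff that cost is below `remove_threshold = 0.05`;
* iterate add/remove until neither rule fires.

Because the add bar is strictly above the removal bar, a feature can never
cycle in and out indefinitely; the suite asserts this cycle guard. Plain
(not adjusted) R² is used: the thresholds are defined as increments of "the
R² of the model". Ties in gain or cost are broken lexicographically by
feature name, making the procedure deterministic and independent of any
random-number state. A `direction = "backward"` switch starts instead from
the full model and only prunes; the bidirectional grow-and-prune procedure
is the default because the operational description of the method is forward
growth from a single feature, even though the procedure is sometimes
summarily described as backward stepwise.

The candidate pool counts 3 + 2 + 115 = 120 features. One source text
figure of 121 likely counts the intercept $C_0$ as a parameter; the package
uses 120 throughout.

Implementation note: the add scan is vectorized. With $Q$ an orthonormal
basis of the current design (intercept plus selected columns), the gain of
candidate $f$ is $(f_\perp^\top r)^2 / (\|f_\perp\|^2 \,\mathrm{TSS})$ where
$f_\perp$ and $r$ are the projections of $f$ and $y$ off $Q$. Tests verify
the whole procedure against an exhaustive-search oracle that tabulates
subset R² by explicit normal equations.

# Stabilization by resampling consensus

A single stepwise fit on ~100 training subjects is unstable. The wrapper
`run_stability()` therefore repeats the selection 50 times; in each
repetition the subjects of the pair are split at random into two halves,
stratified by label (each group's count split as evenly as parity allows,
the training half receiving the ceiling), the stepwise model is fitted on
the training half only, and the other half is discarded. A feature is
retained if it appears in the final model in **more than 75%** of
repetitions.

The phrase "dividing the feature set into two groups" in the method's
source description is ambiguous; this package splits *subjects*, the only
reading under which a "training group" and a discarded half make sense and
which is coherent with the subject-level 2-fold evaluation downstream.

Retained features are ranked by coefficient p-value. Since each repetition
yields its own p-values, the package aggregates by the **median over the
repetitions that selected the feature** (robust, and defined exactly on the
selection events); ties are broken by higher selection frequency, then by
name. An optional `refit_all` flag reports the p-values of a final refit on
all subjects of the pair, for table-style reporting only — ranking always
uses the aggregated values.

Reproducibility contract: one master seed derives an independent stream per
repetition, and subjects are processed in subject-id order, so results are
invariant to row order of the input and each repetition can be reproduced
on its own.

# Classification: two-class linear discriminant analysis

With class means $\mu_k$ and pooled within-class covariance $\Sigma$
(denominator $n-2$), each class has a linear discriminant function

$$ \hat d_k(F) = -\tfrac12 \mu_k^\top \Sigma^{-1} \mu_k + (\Sigma^{-1}\mu_k)^\top F, $$

the unique textbook plug-in estimator yielding exactly this linear form.
Linear scores add the log prior, $L_k = \hat d_k(F) + \log p_k$, and
posteriors are the softmax $p_k = e^{L_k} / (e^{L_1} + e^{L_2})$, computed
stably by subtracting the larger score before exponentiation. The larger
posterior assigns the class.

* **Priors.** The default is 0.5/0.5, reflecting a clinical setting where
  the stage mix of incoming subjects is unknown. Empirical priors (e.g.
  125/180 vs 55/180 for CN vs AD) are an explicit opt-in; the per-class
  log-prior is the natural generalization of the equal-prior score.
* **Ties.** An exact posterior tie assigns the less severe class —
  conservative staging; ties have measure zero on continuous data.
* **Degeneracy.** If the pooled covariance is numerically singular
  (possible when the feature count approaches the fold size), a ridge
  $\lambda I$ with $\lambda = 10^{-6}\,\mathrm{tr}(\Sigma)/m$ is added and
  reported via a message.

Tests verify the equal-prior rule equals nearest-class-mean in Mahalanobis
distance, agreement with an independent reference implementation to 1e-8 in
posteriors, and convergence of held-out accuracy to the analytic Bayes rate
$\Phi(\Delta/2)$ on equal-covariance Gaussians.

# Evaluation

All performance numbers come from 2-fold cross-validation repeated 20
times: per repetition the subjects are split into two stratified halves
with fixed per-group counts, each half serves once for training and once
for testing, and both folds' test predictions are pooled into a single
confusion table (pooling, rather than averaging fold metrics, is the
standard unbiased choice). Accuracy, sensitivity, specificity, precision
and F-measure are computed per repetition and summarized as mean ± SD; the
F-measure is the harmonic mean of precision and sensitivity computed per
repetition *then* averaged, which is why a reported mean F is not the F of
the reported means. The positive class is always the more severe diagnosis,
so sensitivity is detection of the diseased group.

The **incremental analysis** evaluates the top-1, top-2, …, top-k ranked
features and reports the k maximizing mean accuracy (ties toward smaller
k). This k is selected on the same cross-validation estimates that are
reported — an optimistic-selection caveat retained deliberately for
fidelity to the method being implemented; see the README.

The **model comparison** runs the full selection-plus-evaluation pipeline
three times per pair with restricted candidate pools — neuropsychological +
demographic, volumetric + demographic, and all features (demographics enter
every pool to absorb age/gender/education-related variability) — and
reports each variant's maximum incremental accuracy. The relative
improvement of the combined model over a single-modality model is

$$ \frac{\text{combined} - \text{single}}{\text{single}} \times 100. $$

The footnote formula printed alongside the published comparison table,
"(Combined/Single)/Combined × 100", is garbled: it reproduces none of the
printed cells, while the formula above reproduces **all twelve** printed
improvement cells and both printed averages to three decimals (the package's
arithmetic suite verifies this). The discrepancy is documented here rather
than silently corrected. Report tables round to 3 decimals with R's
round-half-even.

# The synthetic cohort generator

Because the original subject-level data cannot be redistributed, the
package ships a simulator whose defaults reproduce the reference cohort
structure exactly: group sizes 125/114/91/55 (CN/EMCI/LMCI/AD; 385
subjects), the published group means ± SD for age, education, CDRSb, RAVLT,
MMSE and TIV, and exact gender counts (58/62/48/32 males), assigned
deterministically rather than sampled so the counts reproduce to the
subject. Scores are drawn from truncated normals (MMSE in [0, 30], RAVLT
and CDRSb ≥ 0, education in [6, 25], age in [50, 95], TIV > 0;
resample-until-valid).

Regional volumes follow

$$ V_{ij} = \mathrm{TIV}_i \cdot b_j \cdot m_{j,g(i)} \cdot
   \exp(\ell_j^\top z_i) \cdot (1 + \epsilon_{ij}), $$

with $b_j$ an order-of-magnitude realistic base fraction (e.g. hippocampus
≈ 0.0025 of TIV — config values, not claims), $m_{j,g}$ a per-group
multiplier monotone along the severity order (ventricular/CSF spaces
*enlarge* with severity, multiplier rising above 1, as a documented
exception to the shrinking-tissue rule), $z_i$ shared latent factors,
$\ell_j$ the region's loadings, and $\epsilon_{ij}$ multiplicative noise
with coefficient of variation `noise_cv` (default 0.08). Raw volumes thus
scale with head size — normalization by TIV removes that correlation, which
the suite checks (|r| < 0.05 at n ≥ 1000).

**Latent structure.** The default is a single global atrophy factor
(loading 0.06 everywhere): the minimal structure that makes feature
selection non-trivial, since correlated regions compete. The loading
argument also accepts a matrix (regions × factors). This generalization is
load-bearing: a population-level analysis of the greedy R² path shows that
with *one* shared factor at most about three features can each clear the
0.1 add threshold — after two features pin the factor, the remaining
candidates behave like independent measurements, whose fifth greedy
increment is mathematically capped near 0.056 — whereas real cohorts, whose
inter-regional covariance is rich, support the 5–14-feature decisional
spaces this method is designed to find. A small number of shared anatomical
factors restores that possibility in simulation.

**The planted-recovery benchmark** (`planted_recovery_specs()`) uses
exactly this: four groups of 400 with identically distributed demographics
and scores (hence uninformative), and five regions — left hippocampus
(−12%), right inferior temporal (−12%), both lateral ventricles (+36%,
+18.5%) and the third ventricle (+22.7%, changes CN→AD, interpolated
monotonically through EMCI/LMCI) — loading on four latent factors with low
region noise (CV 0.9–5%). The loadings and effect magnitudes were calibrated
once, by the population greedy analysis, so that each planted feature's add
gain is about 0.19–0.21, a comfortable margin over the 0.1 bar; a correct
implementation then retains exactly the planted five. The companion
negative control (`null_cohort_specs()`) keeps the reference group sizes
but removes every group difference; stability selection must retain nothing.

**What the simulator does not emulate:** real inter-regional covariance,
hemispheric asymmetry, scanner/site effects, and the actual RAVLT measure
underlying the published "5.7 ± 2.4" scale (which suggests a sub-score such
as delayed recall rather than the 0–75 total; the generator treats RAVLT as
an abstract score on that scale). Passing tests therefore demonstrate
correctness of the *procedure*, not expected accuracy on clinical data. In
particular, on the default single-factor cohort most pairs are dominated by
one strong feature (often MMSE or a ventricle), so selected models are
smaller than the 5–14 features reported on real data.

# Numerical choices and degenerate inputs

* OLS uses QR; rank-deficient designs and $n \le k+1$ are hard errors.
  Coefficient p-values come from $t = C_j/\mathrm{SE}(C_j)$ with $n-k-1$
  degrees of freedom.
* Candidate gains with near-zero residual norm (numerically collinear
  columns) are treated as zero gain rather than spurious R².
* Gender is coded male = 0, female = 1; any fixed binary coding only flips
  a coefficient sign.
* Missing values: rows with missing required values are dropped and
  counted; no imputation.
* Double TIV-normalization is a guarded error, never a silent rescale.
* Seed derivation uses named substreams (a stable string hash folded into
  the master seed, kept below 2³¹), so adding a pair to a run never
  perturbs another pair's results.

# Problem sizes used by the test suite

The suite exercises the full reference settings (50 selection repetitions,
0.75 retention, 2-fold × 20 evaluation, all six pairs on the 385-subject
default cohort). Calibration experiments use 20 master seeds for
planted-feature recovery at 400 subjects per group, 100 seeds for the
null-retention control at reference group sizes, 100 random instances for
the stepwise-vs-exhaustive-oracle comparison at n = 60, and 20,000 held-out
subjects for the Bayes-rate check — sizes at which the Monte-Carlo error of
each checked quantity is far below its acceptance margin.

# Known limitations

* The optimal feature count is chosen on the reported cross-validation
  estimates (no nested CV), faithful to the implemented method but
  optimistic.
* The stepwise R² thresholds are absolute increments; with very large
  cohorts every increment shrinks and selection becomes conservative.
* Multi-class staging is out of scope: the method is strictly pairwise.
* No ROC/AUC or calibration analysis; the metric suite mirrors the
  method's five reported metrics.
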